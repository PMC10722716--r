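test_that("rebalancing methods behave as specified", {
  set.seed(1)
  X <- matrix(rnorm(449 * 3), ncol = 3)
  y <- rep(c("HC", "MCI"), c(402, 47))
  rb <- rebalance(X, y, resample_spec("combined_over_under", seed = 5))
  expect_equal(length(rb$labels), 449)
  counts <- table(rb$labels)
  expect_true(all(counts > 449 * 0.5 - 4 * sqrt(449 * 0.25)))
  rb2 <- rebalance(X, y, resample_spec("combined_over_under", seed = 5))
  expect_identical(rb$features, rb2$features)
  # already balanced input is unchanged by random oversampling
  Xb <- X[1:40, ]; yb <- rep(c("HC", "MCI"), each = 20)
  ro <- rebalance(Xb, yb, resample_spec("random_oversample"))
  expect_identical(ro$features, Xb)
  # oversampling only appends duplicated minority rows
  ro2 <- rebalance(X, y, resample_spec("random_oversample", seed = 2))
  expect_equal(unname(table(ro2$labels)), c(402L, 402L), ignore_attr = TRUE)
  added <- ro2$features[450:nrow(ro2$features), ]
  expect_true(all(apply(added, 1, function(r)
    any(colSums(abs(t(X[403:449, ]) - r)) == 0))))
  # shrink = 0 makes every synthetic row an original row
  rs <- rebalance(X, y, resample_spec("rose_smoothed", shrink = 0, seed = 3))
  expect_true(all(apply(rs$features, 1, function(r)
    any(colSums(abs(t(X) - r)) == 0))))
  # smoothing perturbs rows
  rs1 <- rebalance(X, y, resample_spec("rose_smoothed", shrink = 1, seed = 3))
  expect_false(all(apply(rs1$features[1:20, ], 1, function(r)
    any(colSums(abs(t(X) - r)) == 0))))
  expect_error(rebalance(X, rep("HC", 449), resample_spec()), "two classes")
})

test_that("composite score weighting follows the clustering rule", {
  set.seed(2)
  g <- rep(c("HC", "MCI"), 30)
  z1 <- rnorm(60)
  L <- cbind(a = z1, b = 2 * z1 + 5, c = rnorm(60))
  cf <- fit_composite(L, g)
  expect_equal(unname(cf$weights), c(0.25, 0.25, 0.5))
  expect_equal(sum(cf$weights), 1)
  # single network: composite is exactly its z-score (HC-aligned sign)
  l1 <- matrix(rnorm(40) + rep(c(1, 0), 20), ncol = 1)
  g1 <- rep(c("HC", "MCI"), 20)
  c1 <- fit_composite(l1, g1)
  expect_equal(apply_composite(c1, l1),
               as.numeric(scale(l1)) * c1$signs)
  # invariance to affine rescaling of any input feature
  L2 <- L; L2[, 2] <- 10 * L2[, 2] - 3
  expect_equal(apply_composite(fit_composite(L2, g), L2),
               apply_composite(cf, L), tolerance = 1e-12)
  expect_error(fit_composite(cbind(L, d = rep(1, 60)), g), "zero-variance")
})

test_that("metrics match direct arithmetic and rank AUC", {
  m <- classification_metrics(3, 1, 1, 5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_rank(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  # zero denominators are NA, not 0
  expect_true(is.na(classification_metrics(0, 0, 3, 5)$precision))
  set.seed(4)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- sample(1:8, n, replace = TRUE)   # force ties
    lb <- runif(n) < 0.5
    if (all(lb) || !any(lb)) next
    expect_equal(auc_rank(sc, lb), pair_auc(sc, lb))
  }
})

test_that("model feature sets nest as defined", {
  f <- lapply(1:6, function(i) model_spec(i)$features)
  expect_true(all(f[[1]] %in% f[[3]]))
  expect_true(all(f[[3]] %in% f[[4]]))
  expect_true(all(f[[1]] %in% f[[5]]))
  expect_true(all(unique(unlist(f)) %in% f[[6]]))
  expect_equal(f[[2]], "composite")
  expect_error(model_spec(7))
})

test_that("cross-validation separates a planted effect and is deterministic", {
  set.seed(6)
  n <- 80
  sub <- data.frame(group = rep(c("HC", "MCI"), each = n / 2),
                    word_list_memory = rnorm(n), tmt_a = rnorm(n),
                    tmt_b = rnorm(n), sdst = rnorm(n))
  sub$loading_1 <- rnorm(n) + ifelse(sub$group == "MCI", -2, 2)
  for (cls in c("svm", "logistic")) {
    cv <- run_cv(sub, model_spec(2), classifier = cls, iters = 10, seed = 3)
    expect_gt(cv$aggregate[["auc"]], 0.95)
  }
  cv1 <- run_cv(sub, model_spec(3), "logistic", iters = 5, seed = 9)
  cv2 <- run_cv(sub, model_spec(3), "logistic", iters = 5, seed = 9)
  expect_identical(cv1$per_iteration, cv2$per_iteration)
  # paper-faithful mode runs on the resampled cohort
  cvp <- run_cv(sub, model_spec(2), "logistic", iters = 5,
                mode = "paper_faithful", seed = 2)
  expect_true(all(cvp$per_iteration$auc > 0.9))
  expect_error(run_cv(sub[sub$group == "HC", ], model_spec(1), "logistic"),
               "both classes")
})
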