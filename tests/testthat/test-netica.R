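test_that("group matrix flattening is band-major and invertible", {
  set.seed(1)
  imgs <- lapply(1:3, function(s)
    as_spectro_image(matrix(runif(50), 10, 5), id = s))
  gm <- build_group_matrix(imgs)
  expect_equal(dim(gm$X), c(3L, 50L))
  expect_equal(unflatten_image(gm, 2), imgs[[2]]$power, ignore_attr = TRUE)
  # enumeration oracle for the (band, voxel) -> column map
  P <- matrix(0, 10, 5); P[7, 3] <- 99   # voxel 7, band 3 (alpha)
  gm1 <- build_group_matrix(list(as_spectro_image(P)))
  expect_equal(which(gm1$X[1, ] == 99), 2 * 10 + 7)
  expect_equal(group_matrix_column(gm, "alpha", 7), 2 * 10 + 7)
  bad <- c(imgs, list(as_spectro_image(matrix(runif(40), 8, 5), id = "odd")))
  expect_error(build_group_matrix(bad), "odd")
})

test_that("group ICA recovers planted components and is seed-deterministic", {
  nv <- 300; nf <- 5
  maps <- planted_flat_maps(2, nv, nf, seed = 42)
  set.seed(43)
  L <- cbind(rlnorm(30, 0, 0.5), rlnorm(30, 0, 0.6))
  imgs <- images_from_mixing(L, maps, nv, nf)
  gm <- build_group_matrix(imgs)
  dec <- fit_group_ica(gm, k = 2, seed = 3)
  cc <- abs(cor(t(dec$maps), t(maps)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  dec2 <- fit_group_ica(gm, k = 2, seed = 3)
  expect_identical(dec$loadings, dec2$loadings)
  # ordering by total power is non-increasing; sign convention holds
  expect_true(all(diff(dec$total_power) <= 1e-9))
  expect_true(all(apply(dec$maps, 1, function(m) m[which.max(abs(m))]) > 0))
  expect_error(fit_group_ica(gm, k = 40), "exceeds")
})

test_that("rank-1 data is explained by a single component", {
  nv <- 200
  set.seed(9)
  m <- t(planted_flat_maps(1, nv, 5, seed = 9))
  L <- matrix(rlnorm(20), 20, 1)
  imgs <- images_from_mixing(L, t(m), nv, 5)
  gm <- build_group_matrix(imgs)
  dec <- fit_group_ica(gm, k = 1, seed = 2)
  Xc <- sweep(gm$X, 2, colMeans(gm$X), "-")
  resid <- Xc - dec$loadings %*% dec$maps
  expect_lt(sum(resid^2) / sum(Xc^2), 0.01)
})

test_that("projection reproduces training loadings and handles new subjects", {
  nv <- 300
  maps <- planted_flat_maps(2, nv, 5, seed = 20)
  set.seed(21)
  L <- cbind(rlnorm(25, 0, 0.5), rlnorm(25, 0, 0.5))
  imgs <- images_from_mixing(L, maps, nv, 5)
  dec <- fit_group_ica(build_group_matrix(imgs), k = 2, seed = 5)
  # training subject: own loadings within 1e-6
  p7 <- project_subject(dec, imgs[[7]])
  expect_lt(max(abs(p7 - dec$loadings[7, ])), 1e-6)
  # cohort mean image projects to ~0
  mean_img <- matrix(colMeans(do.call(rbind, lapply(imgs, function(i)
    as.numeric(i$power)))), nv, 5)
  p_mean <- project_subject(dec, mean_img)
  expect_lt(max(abs(p_mean)), 1e-6 * max(apply(dec$loadings, 2, sd)))
  # held-out noiseless subject: loadings recovered within 5% after the
  # affine alignment implied by the training fit
  l_true <- c(1.4, 0.7)
  x_new <- as.numeric(l_true %*% maps)
  p_new <- project_subject(dec, matrix(x_new, nv, 5))
  # alignment: regress training loadings on true training loadings
  pred <- vapply(1:2, function(j) {
    fit <- lm(dec$loadings[, j] ~ L)
    sum(coef(fit) * c(1, l_true))
  }, 0)
  expect_lt(max(abs(p_new - pred) / apply(dec$loadings, 2, sd)), 0.05)
  # projection is linear in the image
  a <- matrix(runif(nv * 5), nv, 5); b <- matrix(runif(nv * 5), nv, 5)
  lhs <- project_subject(dec, a + b) + project_subject(dec, matrix(0, nv, 5))
  rhs <- project_subject(dec, a) + project_subject(dec, b)
  expect_lt(max(abs(lhs - rhs)), 1e-8 * max(abs(rhs)))
  expect_error(project_subject(dec, matrix(0, 10, 5)), "shape")
})

test_that("network comparison is one-tailed with complementary alternatives", {
  set.seed(6)
  L <- matrix(rnorm(60), 30, 2)
  g <- rep(c("HC", "MCI"), each = 15)
  a <- compare_networks(L, g, n_perm = 500, seed = 9, alternative = "less")
  b <- compare_networks(L, g, n_perm = 500, seed = 9, alternative = "greater")
  # p_less + p_greater = 1 + P(t = t_obs) under the shared permutation set
  expect_true(all(a$p + b$p >= 1))
  expect_true(all(a$p + b$p <= 1 + 2 / 501 + 1e-12))
  expect_true(all(a$p > 0 & a$p <= 1))
  expect_equal(sign(a$t), sign(a$mean_mci - a$mean_hc))
  expect_error(compare_networks(L, c("HC", rep("MCI", 29)), n_perm = 10),
               "at least 2")
})

test_that("artifact-flagged components are excluded from comparison", {
  nv <- 200
  maps <- planted_flat_maps(3, nv, 5, seed = 31)
  set.seed(32)
  L <- matrix(rlnorm(90, 0, 0.4), 30, 3)
  dec <- fit_group_ica(build_group_matrix(images_from_mixing(L, maps, nv, 5)),
                       k = 3, seed = 2,
                       artifact_flags = c(TRUE, FALSE, FALSE))
  cmp <- compare_networks(dec, rep(c("HC", "MCI"), 15), n_perm = 100, seed = 1)
  expect_equal(nrow(cmp), 2)
  expect_false(1 %in% cmp$component)
})
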