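#' Resampling specification for class rebalancing
#'
#' @param method `"random_oversample"` (duplicate minority rows up to the
#'   majority count), `"rose_smoothed"` (bootstrap-based combined over/under
#'   sampling with Gaussian kernel smoothing) or `"combined_over_under"`
#'   (class drawn with probability `p`, rows resampled without smoothing;
#'   total size fixed at n).
#' @param p Target class probability (default 0.5).
#' @param shrink Kernel shrink factor for `rose_smoothed`; bandwidth per
#'   feature is `shrink` x the per-class Silverman rule. `shrink = 0`
#'   reproduces original rows exactly.
#' @param seed Integer seed.
#' @export
resample_spec <- function(method = c("rose_smoothed", "random_oversample",
                                     "combined_over_under"),
                          p = 0.5, shrink = 1, seed = 1) {
  method <- match.arg(method)
  stopifnot(p > 0, p < 1, shrink >= 0)
  structure(list(method = method, p = p, shrink = shrink, seed = seed),
            class = "resample_spec")
}

#' Rebalance a two-class data set
#'
#' @param features Numeric matrix or data.frame of features (rows = subjects).
#' @param labels Vector of class labels (exactly two classes).
#' @param spec A [resample_spec()].
#' @param seed Seed override (defaults to the spec's).
#' @return List with `features` and `labels` after resampling.
#' @export
rebalance <- function(features, labels, spec = resample_spec(),
                      seed = spec$seed) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2)
    stop("rebalancing requires two classes; got only '", classes, "'")
  if (length(classes) > 2) stop("rebalancing supports exactly two classes")
  set.seed(seed)
  n <- nrow(X)
  if (spec$method == "random_oversample") {
    counts <- table(labels)
    minority <- names(counts)[which.min(counts)]
    deficit <- max(counts) - min(counts)
    if (deficit == 0) return(list(features = X, labels = labels))
    pool <- which(labels == minority)
    extra <- pool[sample.int(length(pool), deficit, replace = TRUE)]
    return(list(features = rbind(X, X[extra, , drop = FALSE]),
                labels = c(labels, labels[extra])))
  }
  # bootstrap-based combined over/under sampling: draw the class, then a row
  draw_class <- ifelse(stats::runif(n) < spec$p, classes[1], classes[2])
  rows <- vapply(draw_class, function(cl) {
    pool <- which(labels == cl)
    pool[sample.int(length(pool), 1)]
  }, 0L)
  Xn <- X[rows, , drop = FALSE]
  if (spec$method == "rose_smoothed" && spec$shrink > 0) {
    d <- ncol(X)
    for (cl in classes) {
      sel <- draw_class == cl
      if (!any(sel)) next
      nc <- sum(labels == cl)
      h_const <- (4 / ((d + 2) * nc))^(1 / (d + 4))
      sds <- apply(X[labels == cl, , drop = FALSE], 2, stats::sd)
      bw <- spec$shrink * h_const * sds
      noise <- matrix(stats::rnorm(sum(sel) * d), sum(sel), d)
      Xn[sel, ] <- Xn[sel, , drop = FALSE] +
        sweep(noise, 2, bw, "*")
    }
  }
  rownames(Xn) <- NULL
  list(features = Xn, labels = draw_class)
}

#' Composite network-activity score
#'
#' Converts each significant network's loadings to a z-score, clusters the
#' networks by complete-linkage hierarchical clustering of the distance
#' 1 - |Spearman correlation| cut at 0.5, weights each network by
#' 1 / (cluster size x number of clusters) (weights sum to 1), aligns signs
#' so a higher composite points in the healthy direction, and sums. The fit
#' is estimated on training data only; apply it to held-out subjects with
#' [apply_composite()].
#'
#' @param loadings Numeric matrix, subjects x networks (training partition).
#' @param groups Group labels (HC / MCI) aligned with the rows.
#' @return A `composite_fit` with `center`, `scale`, `weights`, `signs`,
#'   `clusters`.
#' @export
fit_composite <- function(loadings, groups) {
  L <- as.matrix(loadings)
  stopifnot(ncol(L) >= 1, nrow(L) == length(groups))
  ctr <- colMeans(L)
  scl <- apply(L, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance network loading")
  Z <- sweep(sweep(L, 2, ctr, "-"), 2, scl, "/")
  m <- ncol(L)
  if (m == 1) {
    cl <- 1L
  } else {
    rs <- stats::cor(L, method = "spearman")
    d <- stats::as.dist(1 - abs(rs))
    cl <- stats::cutree(stats::hclust(d, method = "complete"), h = 0.5)
  }
  k <- length(unique(cl))
  sizes <- table(cl)
  w <- 1 / (as.numeric(sizes[as.character(cl)]) * k)
  gm <- as.character(groups)
  signs <- vapply(seq_len(m), function(j) {
    dd <- mean(Z[gm == "HC", j]) - mean(Z[gm == "MCI", j])
    if (is.na(dd) || dd >= 0) 1 else -1
  }, 0)
  structure(list(center = ctr, scale = scl, weights = w, signs = signs,
                 clusters = cl),
            class = "composite_fit")
}

#' @rdname fit_composite
#' @param fit A `composite_fit`.
#' @param newdata Loadings matrix with the fitted column count.
#' @return For `apply_composite`: numeric composite score per row.
#' @export
apply_composite <- function(fit, newdata) {
  Z <- sweep(sweep(as.matrix(newdata), 2, fit$center, "-"), 2, fit$scale, "/")
  as.numeric(Z %*% (fit$weights * fit$signs))
}

#' Feature sets for discrimination models 1--6
#'
#' Model 1: cognitive tests (word-list memory, TMT-A, TMT-B, SDST);
#' Model 2: the network-activity composite score; Model 3: 1 + 2;
#' Model 4: 3 + confounders (age, sex, education); Model 5: 1 + confounders +
#' MRI volumes; Model 6: everything.
#'
#' @param id Model number, 1--6.
#' @return A `model_spec` list with `id`, `features` (column names;
#'   `"composite"` is computed from the loading columns), `uses_composite`.
#' @export
model_spec <- function(id) {
  stopifnot(id %in% 1:6)
  cog <- c("word_list_memory", "tmt_a", "tmt_b", "sdst")
  conf <- c("age", "sex", "education")
  mri <- c("right_hippocampus", "left_hippocampus", "cerebral_white_matter",
           "subcortical_gray", "total_gray", "etiv")
  feats <- switch(id,
                  cog,
                  "composite",
                  c(cog, "composite"),
                  c(cog, "composite", conf),
                  c(cog, conf, mri),
                  c(cog, "composite", conf, mri))
  structure(list(id = id, features = feats,
                 uses_composite = "composite" %in% feats),
            class = "model_spec")
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity, specificity, precision and F1 from the confusion
#' counts, and AUC from the rank statistic over scores (tied scores receive
#' half credit). Ratios with a zero denominator are reported as `NA`, not 0.
#'
#' @param tp,fp,fn,tn Confusion counts (positive class = MCI).
#' @param scores Optional numeric scores (higher = more MCI-like).
#' @param labels Optional logical/binary vector of true positives, aligned
#'   with `scores`.
#' @return Named list of metrics.
#' @export
classification_metrics <- function(tp, fp, fn, tn, scores = NULL,
                                   labels = NULL) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(tp, tp + fn); prec <- rat(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  auc <- if (!is.null(scores)) auc_rank(scores, labels) else NA_real_
  list(accuracy = rat(tp + tn, tp + fp + fn + tn), sensitivity = sens,
       specificity = rat(tn, tn + fp), precision = prec, f1 = f1, auc = auc)
}

#' @rdname classification_metrics
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)              # average ranks: ties get 0.5 credit
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

build_feature_matrix <- function(subjects, features) {
  cols <- lapply(features, function(f) {
    x <- subjects[[f]]
    if (is.null(x)) stop("missing feature column: ", f)
    if (f == "sex") as.numeric(x == "woman") else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- features
  X
}

loading_columns <- function(subjects) {
  grep("^loading_", names(subjects), value = TRUE)
}

#' Monte-Carlo k-fold cross-validated MCI discrimination
#'
#' Repeats a random k-fold partition `iters` times; in each iteration the
#' classifier (radial-kernel SVM, cost 1, or unpenalized logistic
#' regression) is trained on k-1 folds and evaluated on the held-out fold,
#' and the six metrics are computed from the iteration's pooled held-out
#' predictions, then averaged over iterations. Two protocols are provided:
#' `paper_faithful` resamples the whole data set once before partitioning
#' (duplicated subjects can then appear on both sides of a fold boundary,
#' matching the reference protocol), while `leak_safe` resamples inside each
#' training split only and computes the composite-score parameters on
#' training data only — the recommended protocol.
#'
#' @param subjects Subject table with `group` and the model's feature
#'   columns; composite models additionally need `loading_*` columns.
#' @param model A [model_spec()].
#' @param classifier `"svm"` or `"logistic"`.
#' @param folds Number of folds (default 5).
#' @param iters Monte-Carlo iterations (default 100).
#' @param resample A [resample_spec()], or `NULL` for no rebalancing.
#' @param mode `"leak_safe"` (default) or `"paper_faithful"`.
#' @param seed Integer seed; the full result is deterministic given the seed.
#' @return A `cv_result`: `aggregate` (mean metrics), `per_iteration`
#'   data.frame, and the settings.
#' @export
run_cv <- function(subjects, model, classifier = c("svm", "logistic"),
                   folds = 5, iters = 100, resample = resample_spec(),
                   mode = c("leak_safe", "paper_faithful"), seed = 1) {
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "model_spec"))
  labels <- as.character(subjects$group)
  if (length(unique(labels)) < 2)
    stop("cross-validation requires both classes present")
  lcols <- loading_columns(subjects)
  if (model$uses_composite && length(lcols) == 0)
    stop("model ", model$id, " needs loading_* columns for the composite")
  plain <- setdiff(model$features, "composite")
  base_X <- build_feature_matrix(subjects,
                                 unique(c(plain, if (model$uses_composite) lcols)))
  set.seed(seed)
  if (mode == "paper_faithful") {
    rb <- if (is.null(resample)) list(features = base_X, labels = labels) else
      rebalance(base_X, labels, resample, seed = seed)
    X_all <- rb$features; y_all <- rb$labels
    if (model$uses_composite) {
      cf <- fit_composite(X_all[, lcols, drop = FALSE], y_all)
      comp <- apply_composite(cf, X_all[, lcols, drop = FALSE])
      X_all <- cbind(X_all[, plain, drop = FALSE], composite = comp)
    } else X_all <- X_all[, plain, drop = FALSE]
  }
  iter_rows <- vector("list", iters)
  for (it in seq_len(iters)) {
    if (mode == "paper_faithful") {
      X <- X_all; y <- y_all
    } else {
      X <- base_X; y <- labels
    }
    n <- nrow(X)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    pred <- character(n); score <- numeric(n)
    for (f in seq_len(folds)) {
      te <- fold_id == f
      Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
      Xte <- X[te, , drop = FALSE]
      if (mode == "leak_safe") {
        if (!is.null(resample)) {
          rb <- rebalance(Xtr, ytr, resample,
                          seed = seed + 1000L * it + f)
          Xtr <- rb$features; ytr <- rb$labels
        }
        if (model$uses_composite) {
          cf <- fit_composite(Xtr[, lcols, drop = FALSE], ytr)
          Xtr <- cbind(Xtr[, plain, drop = FALSE],
                       composite = apply_composite(cf, Xtr[, lcols, drop = FALSE]))
          Xte <- cbind(Xte[, plain, drop = FALSE],
                       composite = apply_composite(cf, Xte[, lcols, drop = FALSE]))
        } else {
          Xtr <- Xtr[, plain, drop = FALSE]
          Xte <- Xte[, plain, drop = FALSE]
        }
      }
      fitted <- fit_classifier(Xtr, ytr, classifier)
      pr <- predict_classifier(fitted, Xte)
      pred[te] <- pr$class
      score[te] <- pr$score
    }
    is_pos <- y == "MCI"
    tp <- sum(pred == "MCI" & is_pos); fp <- sum(pred == "MCI" & !is_pos)
    fn <- sum(pred != "MCI" & is_pos); tn <- sum(pred != "MCI" & !is_pos)
    m <- classification_metrics(tp, fp, fn, tn, scores = score,
                                labels = is_pos)
    iter_rows[[it]] <- as.data.frame(m)
  }
  per_iter <- do.call(rbind, iter_rows)
  aggregate <- colMeans(per_iter, na.rm = TRUE)
  structure(list(aggregate = aggregate, per_iteration = per_iter,
                 classifier = classifier, model = model$id, folds = folds,
                 iters = iters, mode = mode, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> model ", x$model, ", ", x$classifier, ", ", x$iters,
      " x ", x$folds, "-fold (", x$mode, ")\n", sep = "")
  print(round(x$aggregate, 4))
  invisible(x)
}

fit_classifier <- function(X, y, classifier) {
  yf <- factor(y, levels = c("HC", "MCI"))
  if (classifier == "svm") {
    list(type = "svm",
         fit = e1071::svm(X, yf, kernel = "radial", cost = 1, scale = TRUE))
  } else {
    df <- data.frame(X, check.names = FALSE)
    df$.y <- as.numeric(yf == "MCI")
    list(type = "logistic",
         fit = suppressWarnings(
           stats::glm(.y ~ ., data = df, family = stats::binomial())),
         cols = colnames(X))
  }
}

predict_classifier <- function(fitted, Xte) {
  if (fitted$type == "svm") {
    pr <- stats::predict(fitted$fit, Xte, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # orient the decision value toward MCI from the e1071 column label
    lab <- colnames(attr(pr, "decision.values"))[1]
    pos_first <- startsWith(lab, "MCI/")
    list(class = as.character(pr), score = if (pos_first) dv else -dv)
  } else {
    df <- data.frame(Xte, check.names = FALSE)
    p <- suppressWarnings(
      stats::predict(fitted$fit, newdata = df, type = "response"))
    list(class = ifelse(p >= 0.5, "MCI", "HC"), score = as.numeric(p))
  }
}
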