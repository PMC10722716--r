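#' Cue-locked ERP segment set
#'
#' Epochs stored as an `[epoch, channel, sample]` array spanning -200 to
#' +700 ms around cue onset (450 samples at 500 Hz; time 0 = cue onset at
#' sample 101). Carries a per-epoch condition label, a retention mask and the
#' rejection reason for rejected epochs.
#'
#' @param data Numeric array, epochs x channels x samples (uV).
#' @param condition Character vector, one label per epoch.
#' @param rate Sampling rate (500).
#' @param tmin_ms Epoch start relative to the cue (-200).
#' @param channel_names Channel labels (row names of the montage).
#' @return An `erp_segment_set`.
#' @export
erp_segment_set <- function(data, condition, rate = 500, tmin_ms = -200,
                            channel_names = montage_1020()$channel_names) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(condition),
            dim(data)[2] == length(channel_names))
  structure(list(data = data, condition = condition, rate = rate,
                 tmin_ms = tmin_ms, channel_names = channel_names,
                 retained = rep(TRUE, dim(data)[1]),
                 reject_reason = rep(NA_character_, dim(data)[1])),
            class = "erp_segment_set")
}

#' @export
print.erp_segment_set <- function(x, ...) {
  cat("<erp_segment_set> ", dim(x$data)[1], " epochs (",
      sum(x$retained), " retained) x ", dim(x$data)[2], " ch x ",
      dim(x$data)[3], " samples\n", sep = "")
  invisible(x)
}

#' Epoch time axis in ms
#' @param seg An `erp_segment_set`.
#' @export
epoch_times_ms <- function(seg) {
  seg$tmin_ms + (seq_len(dim(seg$data)[3]) - 1) * 1000 / seg$rate
}

#' Cue-locked segmentation of a continuous recording
#'
#' Cuts one epoch per cue event, from 200 ms before to 700 ms after cue onset
#' (900 ms, 450 samples at 500 Hz). Cues too close to the record edges are
#' skipped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param events data.frame with `time_s` (cue onset) and `condition`.
#' @return An `erp_segment_set`.
#' @export
segment_epochs <- function(rec, events) {
  stopifnot(inherits(rec, "eeg_recording"),
            all(c("time_s", "condition") %in% names(events)))
  r <- rec$rate
  n_pre <- round(0.2 * r); n_post <- round(0.7 * r)
  n_samp <- n_pre + n_post
  idx0 <- round(events$time_s * r) + 1
  ok <- idx0 - n_pre >= 1 & idx0 + n_post - 1 <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " cue(s) too close to the record edge were skipped")
  idx0 <- idx0[ok]
  arr <- array(0, c(length(idx0), nrow(rec$data), n_samp))
  for (e in seq_along(idx0))
    arr[e, , ] <- rec$data[, (idx0[e] - n_pre):(idx0[e] + n_post - 1)]
  erp_segment_set(arr, events$condition[ok], rate = r, tmin_ms = -200,
                  channel_names = rownames(rec$data))
}

#' Frontal blink scalp template
#'
#' Unit-norm channel weighting of an eye-blink field: maximal at Fp1/Fp2,
#' decaying with angular distance from the fronto-polar midline.
#'
#' @param montage An [montage_1020()] montage.
#' @export
blink_template <- function(montage = montage_1020()) {
  fp <- colMeans(montage$positions[c("Fp1", "Fp2"), ])
  fp <- fp / sqrt(sum(fp^2))
  ang <- acos(pmin(1, pmax(-1, montage$positions %*% fp)))
  w <- exp(-ang^2 / (2 * 0.5^2))
  as.numeric(w / sqrt(sum(w^2)))
}

#' ICA-based ocular artifact correction
#'
#' Runs infomax ICA on the concatenated epochs, zeroes components whose
#' scalp pattern correlates with the blink template beyond `threshold`, and
#' reconstructs the data. The epoch count never changes. If the ICA does not
#' converge the data are passed through unchanged with a warning and
#' `ica_converged = FALSE`.
#'
#' @param seg An `erp_segment_set` (>= 19 channels, >= 30 s of data).
#' @param template Channel-weight vector of the artifact field
#'   (default [blink_template()]).
#' @param threshold Absolute pattern correlation above which a component is
#'   removed (default 0.8).
#' @param seed Integer seed for the ICA.
#' @return The corrected `erp_segment_set`, with attributes
#'   `removed_components` and `ica_converged`.
#' @export
correct_artifacts_ica <- function(seg, template = blink_template(),
                                  threshold = 0.8, seed = 1) {
  stopifnot(inherits(seg, "erp_segment_set"))
  d <- dim(seg$data)
  if (d[2] < 19) stop("artifact ICA expects at least 19 channels")
  if (d[1] * d[3] / seg$rate < 30)
    stop("artifact ICA needs at least 30 s of concatenated data")
  # concatenate epochs: (epochs*samples) x channels
  X <- matrix(aperm(seg$data, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  # the unmixing is estimated on at most 30000 samples (ample for 19
  # channels) and then applied to the full record
  fit_rows <- if (nrow(X) > 30000) {
    set.seed(seed)
    sort(sample.int(nrow(X), 30000))
  } else seq_len(nrow(X))
  fit <- ica_decompose(X[fit_rows, , drop = FALSE], k = d[2],
                       algorithm = "infomax", seed = seed, max_iter = 1000)
  if (!fit$converged) {
    warning("infomax ICA did not converge; data passed through unchanged")
    seg$ica_converged <- FALSE
    seg$removed_components <- integer(0)
    return(seg)
  }
  pat_cor <- suppressWarnings(
    apply(fit$A, 2, function(a) stats::cor(a, template)))
  pat_cor[is.na(pat_cor)] <- 0
  drop_c <- which(abs(pat_cor) > threshold)
  S <- sweep(X, 2, fit$mean, "-") %*% fit$unmixing
  if (length(drop_c)) S[, drop_c] <- 0
  Xr <- S %*% t(fit$A)
  Xr <- sweep(Xr, 2, fit$mean, "+")
  seg$data <- aperm(array(Xr, c(d[1], d[3], d[2])), c(1, 3, 2))
  seg$ica_converged <- TRUE
  seg$removed_components <- drop_c
  seg
}

#' Automated artifact rejection rule
#'
#' An epoch is rejected if, on any channel, any sliding 200-ms window has a
#' peak-to-peak range above `max_diff_uv`, or any sliding 100-ms window has a
#' peak-to-peak range (the "activity") below `min_activity_uv`. Window stride
#' is one sample.
#'
#' @param max_diff_uv Maximal allowed value difference (default 200 uV) over
#'   `diff_window_ms` (default 200 ms).
#' @param min_activity_uv Minimal required activity (default 0.5 uV) over
#'   `flat_window_ms` (default 100 ms).
#' @export
rejection_rule <- function(max_diff_uv = 200, diff_window_ms = 200,
                           min_activity_uv = 0.5, flat_window_ms = 100) {
  stopifnot(max_diff_uv > 0, min_activity_uv > 0)
  structure(list(max_diff_uv = max_diff_uv, diff_window_ms = diff_window_ms,
                 min_activity_uv = min_activity_uv,
                 flat_window_ms = flat_window_ms),
            class = "rejection_rule")
}

#' Apply the rejection rule to an epoch set
#'
#' @param seg An `erp_segment_set`.
#' @param rule A [rejection_rule()].
#' @return The segment set with `retained` and `reject_reason` updated.
#' @export
reject_epochs <- function(seg, rule = rejection_rule()) {
  stopifnot(inherits(seg, "erp_segment_set"), inherits(rule, "rejection_rule"))
  d <- dim(seg$data)
  w_diff <- round(rule$diff_window_ms / 1000 * seg$rate)
  w_flat <- round(rule$flat_window_ms / 1000 * seg$rate)
  code <- epoch_reject_core(as.numeric(seg$data), d[1], d[2], d[3],
                            w_diff, rule$max_diff_uv,
                            w_flat, rule$min_activity_uv)
  seg$retained <- code == 0L
  seg$reject_reason <- c(NA_character_, "max_diff", "low_activity")[code + 1L]
  seg
}

#' Baseline correction
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -200 to 0 ms, i.e. the pre-cue interval).
#'
#' @param seg An `erp_segment_set`.
#' @param window Baseline window in ms, `c(lo, hi)`; samples with
#'   `lo <= t < hi` are used.
#' @export
baseline_correct <- function(seg, window = c(-200, 0)) {
  stopifnot(inherits(seg, "erp_segment_set"))
  t_ms <- epoch_times_ms(seg)
  if (window[1] < t_ms[1] - 1e-9 || window[2] > t_ms[length(t_ms)] + 1e-9)
    stop("baseline window outside the epoch")
  sel <- t_ms >= window[1] & t_ms < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- rowMeans(seg$data[, , sel, drop = FALSE], dims = 2)
  seg$data <- seg$data - as.numeric(base)   # recycles over the sample dim
  seg
}

# most extreme interior local extremum of a waveform inside [win] (ms);
# falls back to the window-edge extremum with edge_flag = TRUE
find_peak <- function(x, t_ms, win, type = c("min", "max")) {
  type <- match.arg(type)
  if (type == "max") return(within_peak(-x, t_ms, win, flip = TRUE))
  within_peak(x, t_ms, win, flip = FALSE)
}

within_peak <- function(x, t_ms, win, flip) {
  idx <- which(t_ms >= win[1] & t_ms <= win[2])
  interior <- idx[idx > 1 & idx < length(x)]
  is_min <- vapply(interior, function(i)
    x[i] < x[i - 1] && x[i] <= x[i + 1], TRUE)
  if (any(is_min)) {
    cand <- interior[is_min]
    i <- cand[which.min(x[cand])]
    edge <- FALSE
  } else {
    ends <- c(idx[1], idx[length(idx)])
    i <- ends[which.min(x[ends])]
    edge <- TRUE
  }
  amp <- if (flip) -x[i] else x[i]
  list(latency_ms = t_ms[i], amplitude_uv = amp, edge_flag = edge)
}

#' Condition averages and N2/P3 peak quantification
#'
#' Averages the retained epochs per condition and quantifies, at Fz, Cz and
#' Pz, the N2 (most negative local minimum, 151--230 ms) and P3 (most
#' positive local maximum, 300--600 ms). If a window contains no interior
#' extremum, the window-edge extremum is returned with `edge_flag = TRUE`.
#' Conditions with no retained epochs are dropped with a warning.
#'
#' @param seg An `erp_segment_set` (after rejection and baseline correction).
#' @param channels Channels to quantify (default Fz, Cz, Pz).
#' @param n2_window,p3_window Search windows in ms.
#' @return List with `averages` (per condition: channels x samples matrix)
#'   and `peaks` (data.frame: condition, component, channel, latency_ms,
#'   amplitude_uv, edge_flag, n_epochs).
#' @export
average_and_peaks <- function(seg, channels = c("Fz", "Cz", "Pz"),
                              n2_window = c(151, 230),
                              p3_window = c(300, 600)) {
  stopifnot(inherits(seg, "erp_segment_set"))
  t_ms <- epoch_times_ms(seg)
  conds <- unique(seg$condition)
  averages <- list(); rows <- list()
  for (cond in conds) {
    sel <- seg$condition == cond & seg$retained
    if (!any(sel)) {
      warning("condition '", cond, "' has no retained epochs; dropped")
      next
    }
    avg <- colMeans(seg$data[sel, , , drop = FALSE])
    rownames(avg) <- seg$channel_names
    averages[[cond]] <- avg
    for (ch in channels) {
      x <- avg[ch, ]
      n2 <- find_peak(x, t_ms, n2_window, "min")
      p3 <- find_peak(x, t_ms, p3_window, "max")
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, component = c("N2", "P3"), channel = ch,
        latency_ms = c(n2$latency_ms, p3$latency_ms),
        amplitude_uv = c(n2$amplitude_uv, p3$amplitude_uv),
        edge_flag = c(n2$edge_flag, p3$edge_flag), n_epochs = sum(sel))
    }
  }
  list(averages = averages, peaks = do.call(rbind, rows))
}
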