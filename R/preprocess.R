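#' Filter settings for an analysis branch
#'
#' The resting-state branch uses a 0.53--120 Hz band-pass with a 60 Hz notch;
#' the ERP branch uses 0.1--30 Hz with the same notch. Filtering is always
#' zero-phase (forward-backward) so ERP peak latencies are not shifted.
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param notch_hz Line frequency to notch out, or `NA` for none. Default 60.
#' @param order Butterworth section order; the band-pass is realised as an
#'   `order`/2 high-pass cascaded with an `order`/2 low-pass (4th-order
#'   band-pass overall by default).
#' @param notch_q Quality factor of the biquad notch (default 30).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz, high_hz, notch_hz = 60, order = 4,
                        notch_q = 30) {
  stopifnot(low_hz > 0, high_hz > low_hz, order %% 2 == 0)
  structure(list(low_hz = low_hz, high_hz = high_hz, notch_hz = notch_hz,
                 order = order, notch_q = notch_q, zero_phase = TRUE),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param branch `"rest"` (0.53--120 Hz) or `"erp"` (0.1--30 Hz).
#' @export
branch_filter <- function(branch = c("rest", "erp")) {
  branch <- match.arg(branch)
  if (branch == "rest") filter_spec(0.53, 120, 60) else filter_spec(0.1, 30, 60)
}

# Zero-phase filtering with reflection padding. Pad length covers the filter's
# impulse-response timescale (slow for sub-Hz high-pass edges), not just the
# polynomial length, so 5-min records show no onset transients.
zero_phase_filter <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[(pad + 1):2]
    tail_ref <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(head_ref, x, tail_ref)
  } else xe <- x
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# RBJ biquad notch at f0 with quality q
notch_coef <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter an EEG recording
#'
#' Applies a Butterworth band-pass (high-pass + low-pass cascade) and an IIR
#' biquad notch, each forward-backward for zero phase. Filtering is linear and
#' leaves the recording's shape unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass_notch <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$rate / 2
  if (spec$high_hz >= nyq)
    stop("high band edge ", spec$high_hz, " Hz is at or above Nyquist (",
         nyq, " Hz)")
  if (!is.na(spec$notch_hz) && spec$notch_hz >= nyq)
    stop("notch frequency above Nyquist")
  half <- spec$order / 2
  hp <- signal::butter(half, spec$low_hz / nyq, type = "high")
  lp <- signal::butter(half, spec$high_hz / nyq, type = "low")
  nt <- if (!is.na(spec$notch_hz))
    notch_coef(spec$notch_hz, rec$rate, spec$notch_q) else NULL
  pad <- ceiling(3 * rec$rate / spec$low_hz)
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    y <- zero_phase_filter(out[i, ], hp$b, hp$a, pad)
    y <- zero_phase_filter(y, lp$b, lp$a, pad)
    if (!is.null(nt)) y <- zero_phase_filter(y, nt$b, nt$a, pad)
    out[i, ] <- y
  }
  rec$data <- out
  rec
}

#' Re-reference an EEG recording
#'
#' Synthetic recordings are generated against the linked-ear reference, for
#' which the scheme is the identity; the common-average scheme subtracts the
#' instantaneous mean across channels, after which every column sums to zero.
#'
#' @param rec An [eeg_recording()].
#' @param scheme `"linked-ear"` or `"common-average"`.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, scheme = c("linked-ear", "common-average")) {
  stopifnot(inherits(rec, "eeg_recording"))
  scheme <- match.arg(scheme)
  if (scheme == "common-average") {
    rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  }
  rec$montage$reference <- scheme
  rec
}
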