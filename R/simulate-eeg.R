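# band-limited unit-variance Gaussian noise: white noise restricted to
# [lo, hi) by a spectral mask, so all of the series' power lies in its band
# and the planted band-power mixture is exact
bandlimited_noise <- function(n, fs, lo, hz_hi) {
  X <- stats::fft(stats::rnorm(n))
  freq <- (seq_len(n) - 1) * fs / n
  fpos <- pmin(freq, fs - freq)        # fold to the one-sided axis
  X[!(fpos >= lo & fpos < hz_hi)] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Planted spectrocortical network maps
#'
#' Builds sparse nonnegative Nf x Nv power maps: each network is a sum of
#' Gaussian blobs (25-mm spatial scale) placed at canonical scalp-brain
#' locations in specific frequency bands, normalized to unit maximum. Network
#' 1 couples frontal delta with bilateral parietal alpha (sensorimotor-like),
#' network 2 occipital delta with parietal theta and right temporal alpha
#' (memory-perception-like), network 3 bilateral superior parietal beta and
#' gamma (dorsal-attention-like); further networks reuse shifted blob sets.
#'
#' @param source_space A [source_space_grid()].
#' @param n_networks Number of maps (default 3).
#' @param bands A [band_scheme()].
#' @return List of Nf x Nv matrices (rows = bands), each in `[0, 1]`.
#' @export
default_networks <- function(source_space, n_networks = 3,
                             bands = band_scheme()) {
  pts <- source_space$voxel_coords
  blob <- function(center, width = 25)
    exp(-rowSums(sweep(pts, 2, center, "-")^2) / (2 * width^2))
  loc <- list(frontal = c(0, 50, 30), occipital = c(0, -60, 20),
              l_par = c(-35, -40, 45), r_par = c(35, -40, 45),
              r_temp = c(55, 0, 10), l_temp = c(-55, 0, 10),
              vertex = c(0, 0, 60))
  defs <- list(
    list(delta = "frontal", alpha = c("l_par", "r_par")),
    list(delta = "occipital", theta = c("l_par", "r_par"), alpha = "r_temp"),
    list(beta = c("l_par", "r_par"), gamma = c("l_par", "r_par")),
    list(theta = "vertex", alpha = "occipital"),
    list(gamma = c("r_temp", "frontal"), beta = "l_temp"))
  nets <- lapply(seq_len(n_networks), function(k) {
    d <- defs[[(k - 1) %% length(defs) + 1]]
    M <- matrix(0, nrow(bands), nrow(pts),
                dimnames = list(bands$band, NULL))
    for (bn in names(d))
      M[bn, ] <- rowSums(sapply(d[[bn]], function(l) blob(loc[[l]])))
    M / max(M)
  })
  nets
}

#' Simulate resting-state EEG with planted spectrocortical networks
#'
#' Each subject's source activity is a mixture of the planted networks: for
#' network k with subject loading l, every voxel receives band-limited
#' Gaussian noise with amplitude sqrt(l x map weight), so the source band
#' power equals the loading-weighted sum of the network maps. Scalp data are
#' the lead field applied to the sources plus white sensor noise. True
#' loadings are returned for recovery testing.
#'
#' @param spec A [cohort_spec()]; loadings are drawn from its
#'   `network_effects` (truncated at zero, since loadings scale power).
#' @param networks List of Nf x Nv maps (e.g. [default_networks()]).
#' @param lead_field A [build_forward()] lead field with matching Nv.
#' @param duration_s Record length per subject (default 300 s).
#' @param rate Sampling rate (default 500).
#' @param sensor_noise_uv Scalp white-noise SD; 0 disables.
#' @param seed Integer seed.
#' @param return_sources Keep each subject's Nv x samples source matrix
#'   (memory-heavy; for oracle tests only).
#' @return List with `recordings` (list of [eeg_recording()]), `loadings`
#'   (subjects x networks matrix of true loadings), `groups`, and optionally
#'   `sources`.
#' @export
simulate_resting_eeg <- function(spec, networks, lead_field,
                                 duration_s = 300, rate = 500,
                                 sensor_noise_uv = 1, seed = spec$seed,
                                 return_sources = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(lead_field, "lead_field"))
  nv <- ncol(lead_field$K)
  bands <- band_scheme()
  for (M in networks)
    if (ncol(M) != nv || nrow(M) != nrow(bands))
      stop("network maps must be ", nrow(bands), " x ", nv,
           " to match the band scheme and lead field")
  groups <- cohort_groups(spec)
  ne <- spec$network_effects
  if (nrow(ne) < length(networks))
    stop("cohort_spec defines effects for ", nrow(ne),
         " networks but ", length(networks), " maps were supplied")
  n <- round(duration_s * rate)
  set.seed(seed)
  L <- sapply(seq_along(networks), function(k) {
    pmax(0, ifelse(groups == "HC",
                   stats::rnorm(length(groups), ne$mean_hc[k], ne$sd_hc[k]),
                   stats::rnorm(length(groups), ne$mean_mci[k], ne$sd_mci[k])))
  })
  colnames(L) <- paste0("network_", seq_along(networks))
  recs <- vector("list", length(groups))
  srcs <- if (return_sources) vector("list", length(groups)) else NULL
  for (s in seq_along(groups)) {
    scalp <- matrix(0, nrow(lead_field$K), n)
    src <- if (return_sources) matrix(0, nv, n) else NULL
    for (k in seq_along(networks)) {
      if (L[s, k] <= 0) next
      M <- networks[[k]]
      for (b in seq_len(nrow(bands))) {
        if (all(M[b, ] == 0)) next
        amp <- sqrt(L[s, k] * M[b, ])
        sig <- bandlimited_noise(n, rate, bands$lo_hz[b], bands$hi_hz[b])
        scalp <- scalp + (lead_field$K %*% amp) %*% t(sig)
        if (return_sources) src <- src + amp %*% t(sig)
      }
    }
    if (sensor_noise_uv > 0)
      scalp <- scalp + matrix(stats::rnorm(length(scalp), 0, sensor_noise_uv),
                              nrow(scalp), n)
    recs[[s]] <- eeg_recording(scalp, rate = rate,
                               montage = lead_field$montage)
    if (return_sources) srcs[[s]] <- src
  }
  out <- list(recordings = recs, loadings = L, groups = groups)
  if (return_sources) out$sources <- srcs
  out
}

#' Simulate cue-locked ERP epochs for a cohort
#'
#' Generates, per subject, one -200..700 ms epoch per trial at 500 Hz with a
#' planted negative N2 (peaking in 151--230 ms, fronto-central topography)
#' and positive P3 (300--600 ms, centro-parietal topography) on top of white
#' noise. Component amplitudes at Cz and latencies vary between subjects
#' around the per-condition, per-group means in the cohort spec; the default
#' spec attenuates the MCI no-response N2 at Cz. A configurable fraction of
#' epochs carries a planted artifact: a > 200 uV step, a flatlined channel,
#' or a frontal blink (which is left for the ICA correction, not the
#' rejection rule).
#'
#' @param spec A [cohort_spec()].
#' @param trials A [make_trial_list()] table.
#' @param seed Integer seed.
#' @param montage An [montage_1020()] montage.
#' @return List with `epochs` (per-subject list of [erp_segment_set()]),
#'   `truth` (planted subject-level Cz amplitudes/latencies), `groups`.
#' @export
simulate_erp_epochs <- function(spec, trials = make_trial_list(seed = spec$seed),
                                seed = spec$seed, montage = montage_1020()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- cohort_groups(spec)
  rate <- 500
  t_ms <- seq(-200, 698, by = 2)
  n_s <- length(t_ms)
  nch <- length(montage$channel_names)
  pos <- montage$positions
  topo <- function(center, sigma) {
    center <- center / sqrt(sum(center^2))
    ang <- acos(pmin(1, pmax(-1, as.numeric(pos %*% center))))
    w <- stats::setNames(exp(-ang^2 / (2 * sigma^2)), rownames(pos))
    as.numeric(w / w["Cz"])            # configured amplitude applies at Cz
  }
  topo_n2 <- topo(pos["Fz", ] + pos["Cz", ], 1.4)
  topo_p3 <- topo(pos["Pz", ], 0.55)
  blink <- blink_template(montage)
  blink <- blink / max(blink)
  eff <- spec$erp_effects
  conds <- unique(trials$condition)
  set.seed(seed)
  truth <- list(); epochs <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    n_ep <- nrow(trials)
    arr <- array(stats::rnorm(n_ep * nch * n_s, 0, spec$erp_noise_uv),
                 c(n_ep, nch, n_s))
    for (cond in conds) {
      e <- eff[eff$condition == cond & eff$group == groups[s], ]
      amp_n2 <- pmin(stats::rnorm(1, e$n2_amp_cz, spec$erp_between_sd), -0.5)
      amp_p3 <- pmax(stats::rnorm(1, e$p3_amp_cz, spec$erp_between_sd), 0.5)
      lat_n2 <- min(max(stats::rnorm(1, e$n2_lat_ms, spec$erp_lat_sd), 160), 224)
      lat_p3 <- min(max(stats::rnorm(1, e$p3_lat_ms, spec$erp_lat_sd * 2), 315), 585)
      wave <- outer(topo_n2, amp_n2 * exp(-(t_ms - lat_n2)^2 / (2 * 22^2))) +
              outer(topo_p3, amp_p3 * exp(-(t_ms - lat_p3)^2 / (2 * 55^2)))
      idx <- which(trials$condition == cond)
      arr[idx, , ] <- arr[idx, , , drop = FALSE] +
        rep(wave, each = length(idx))
      truth[[length(truth) + 1]] <- data.frame(
        subject = s, group = groups[s], condition = cond,
        n2_amp_cz = amp_n2, n2_lat_ms = lat_n2,
        p3_amp_cz = amp_p3, p3_lat_ms = lat_p3)
    }
    if (spec$artifact_prob > 0) {
      bad <- which(stats::runif(n_ep) < spec$artifact_prob)
      for (e_i in bad) {
        type <- sample(c("step", "flat", "blink"), 1)
        ch <- sample.int(nch, 1)
        if (type == "step") {
          at <- sample.int(n_s - 10, 1)
          arr[e_i, ch, at:n_s] <- arr[e_i, ch, at:n_s] +
            sample(c(-250, 250), 1)
        } else if (type == "flat") {
          arr[e_i, ch, ] <- stats::rnorm(n_s, 0, 0.05)
        } else {
          at <- sample(50:300, 1)
          pulse <- 150 * exp(-(seq_len(n_s) - at)^2 / (2 * 20^2))
          arr[e_i, , ] <- arr[e_i, , ] + outer(blink, pulse)
        }
      }
    }
    epochs[[s]] <- erp_segment_set(arr, trials$condition, rate = rate,
                                   tmin_ms = -200,
                                   channel_names = montage$channel_names)
  }
  list(epochs = epochs, truth = do.call(rbind, truth), groups = groups)
}
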