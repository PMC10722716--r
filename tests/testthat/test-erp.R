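flat_epochs <- function(n_ep = 3, value = 0, n_s = 450) {
  erp_segment_set(array(value, c(n_ep, 19, n_s)),
                  condition = rep("congruent", n_ep))
}

test_that("segmentation is cue-locked with edge epochs skipped", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(19 * 500 * 240), 19))
  ev <- data.frame(time_s = seq(1, 224.5, by = 1.5)[1:150],
                   condition = rep(c("congruent", "incongruent",
                                     "no_response"), 50))
  seg <- segment_epochs(rec, ev)
  expect_equal(dim(seg$data), c(150L, 19L, 450L))
  # 900 ms segments: -200..700 at 500 Hz
  t_ms <- epoch_times_ms(seg)
  expect_equal(t_ms[1], -200)
  expect_equal(t_ms[length(t_ms)] + 2, 700)
  # sample at t = 0 equals the recording at the cue sample
  cue_idx <- round(ev$time_s[1] * 500) + 1
  expect_equal(seg$data[1, , which(t_ms == 0)], unname(rec$data[, cue_idx]))
  ev_bad <- rbind(data.frame(time_s = 0.05, condition = "congruent"), ev)
  expect_warning(seg2 <- segment_epochs(rec, ev_bad), "skipped")
  expect_equal(dim(seg2$data)[1], 150L)
})

test_that("rejection rule fires on max-diff and low-activity epochs", {
  clean <- flat_epochs(1)
  t_idx <- seq_len(450)
  for (ch in 1:19) clean$data[1, ch, ] <- 50 * sin(2 * pi * 5 * t_idx / 500)
  expect_true(reject_epochs(clean)$retained)
  step <- clean
  step$data[1, 4, 200:450] <- step$data[1, 4, 200:450] + 250
  r <- reject_epochs(step)
  expect_false(r$retained)
  expect_equal(r$reject_reason, "max_diff")
  lowact <- flat_epochs(1)
  lowact$data[1, , ] <- 0.15 * sin(2 * pi * 5 * t_idx / 500)  # 0.3 uV p-p
  r2 <- reject_epochs(lowact)
  expect_false(r2$retained)
  expect_equal(r2$reject_reason, "low_activity")
})

test_that("rejection is monotone in its thresholds", {
  spec <- cohort_spec(n_hc = 1, n_mci = 1, seed = 8, artifact_prob = 0.3)
  sim <- simulate_erp_epochs(spec, make_trial_list(90, 3, seed = 8), seed = 8)
  seg <- sim$epochs[[1]]
  base <- reject_epochs(seg, rejection_rule())
  looser_diff <- reject_epochs(seg, rejection_rule(max_diff_uv = 400))
  expect_true(all(looser_diff$retained >= base$retained))
  stricter_flat <- reject_epochs(seg, rejection_rule(min_activity_uv = 2))
  expect_true(all(stricter_flat$retained <= base$retained))
})

test_that("baseline correction zeroes the pre-cue mean and commutes with scaling", {
  set.seed(5)
  seg <- flat_epochs(4)
  seg$data <- array(rnorm(length(seg$data)) + 7, dim(seg$data))
  bc <- baseline_correct(seg)
  t_ms <- epoch_times_ms(seg)
  sel <- t_ms >= -200 & t_ms < 0
  expect_lt(max(abs(apply(bc$data[, , sel], c(1, 2), mean))), 1e-9)
  # constant offset is removed everywhere
  off <- flat_epochs(2, value = 7)
  expect_equal(max(abs(baseline_correct(off)$data)), 0)
  # commutes with channel scaling
  sc <- seg; sc$data <- 3 * seg$data
  expect_equal(baseline_correct(sc)$data, 3 * bc$data)
  expect_error(baseline_correct(seg, window = c(-300, 0)), "outside")
})

test_that("peak quantification finds planted extrema and flags edges", {
  t_ms <- seq(-200, 698, by = 2)
  wave <- -10 * exp(-(t_ms - 200)^2 / (2 * 20^2)) +
    12 * exp(-(t_ms - 450)^2 / (2 * 50^2))
  seg <- flat_epochs(2)
  for (e in 1:2) for (ch in 1:19) seg$data[e, ch, ] <- wave
  res <- average_and_peaks(seg)
  pk <- res$peaks[res$peaks$channel == "Cz", ]
  expect_equal(pk$latency_ms[pk$component == "N2"], 200)
  expect_equal(pk$amplitude_uv[pk$component == "N2"], -10, tolerance = 1e-4)
  expect_equal(pk$latency_ms[pk$component == "P3"], 450)
  expect_equal(pk$amplitude_uv[pk$component == "P3"], 12, tolerance = 1e-4)
  expect_false(any(pk$edge_flag))
  # monotone ramp across the N2 window: edge extremum, flagged
  ramp <- flat_epochs(1)
  for (ch in 1:19) ramp$data[1, ch, ] <- seq(0, 10, length.out = 450)
  rp <- average_and_peaks(ramp)$peaks
  n2 <- rp[rp$component == "N2" & rp$channel == "Cz", ]
  expect_true(n2$edge_flag)
  expect_equal(n2$latency_ms, 152)   # first sample inside the window
  # duplicating identical epochs leaves the peak unchanged
  dup <- flat_epochs(6)
  for (e in 1:6) for (ch in 1:19) dup$data[e, ch, ] <- wave
  expect_equal(average_and_peaks(dup)$peaks$amplitude_uv,
               res$peaks$amplitude_uv)
  # empty condition is dropped with a warning
  gone <- flat_epochs(2)
  gone$retained <- c(FALSE, FALSE)
  expect_warning(expect_null(average_and_peaks(gone)$peaks), "no retained")
})

test_that("infomax correction removes planted blinks but preserves data", {
  spec <- cohort_spec(n_hc = 1, n_mci = 1, seed = 2, artifact_prob = 0)
  sim <- simulate_erp_epochs(spec, make_trial_list(120, 3, seed = 2), seed = 2)
  seg <- sim$epochs[[1]]
  btn <- blink_template() / max(blink_template())
  set.seed(9)
  bad <- sample(120, 25)
  for (e in bad) {
    at <- sample(80:300, 1)
    seg$data[e, , ] <- seg$data[e, , ] +
      outer(btn, 150 * exp(-(seq_len(450) - at)^2 / (2 * 20^2)))
  }
  rms_before <- sqrt(mean(seg$data[bad, 1:2, ]^2))
  segc <- correct_artifacts_ica(seg, seed = 1)
  expect_true(segc$ica_converged)
  expect_gt(length(segc$removed_components), 0)
  expect_gt(1 - sqrt(mean(segc$data[bad, 1:2, ]^2)) / rms_before, 0.7)
  expect_equal(dim(segc$data)[1], dim(seg$data)[1])
  # with no component selected the reconstruction is a round trip
  seg0 <- correct_artifacts_ica(seg, template = rep(0, 19), seed = 1)
  expect_lt(max(abs(seg0$data - seg$data)), 1e-6)
})

test_that("planted peaks are recovered across noisy subjects", {
  spec <- cohort_spec(n_hc = 50, n_mci = 50, seed = 33, artifact_prob = 0,
                      erp_noise_uv = 2)
  tr <- data.frame(trial_index = 1:50, condition = "no_response",
                   cue_side = "left", cue_color = "yellow",
                   correct_response = "none", given_response = NA,
                   rt_s = NA, iti_ms = 1500)
  sim <- simulate_erp_epochs(spec, tr, seed = 33)
  err <- t(vapply(seq_len(100), function(s) {
    seg <- baseline_correct(sim$epochs[[s]])
    pk <- average_and_peaks(seg)$peaks
    n2 <- pk[pk$component == "N2" & pk$channel == "Cz", ]
    tru <- sim$truth[sim$truth$subject == s, ]
    c(lat = abs(n2$latency_ms - tru$n2_lat_ms),
      amp = abs(n2$amplitude_uv - tru$n2_amp_cz))
  }, c(lat = 0, amp = 0)))
  expect_lte(median(err[, "lat"]), 4)
  expect_lte(median(err[, "amp"]), 1)
})
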