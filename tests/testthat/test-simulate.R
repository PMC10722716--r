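test_that("trial lists have balanced conditions, fixed mappings and seeding", {
  tr <- make_trial_list(150, 3, seed = 11)
  expect_equal(unname(table(tr$condition)[c("congruent", "incongruent",
                                            "no_response")]),
               c(50L, 50L, 50L), ignore_attr = TRUE)
  expect_true(all(tr$iti_ms == 1500))
  pr <- make_trial_list(24, 3, seed = 11)
  expect_true(all(table(pr$condition) == 8))
  # color -> response mapping and condition consistency
  map <- c(blue = "right", red = "left", yellow = "none")
  expect_equal(tr$correct_response, unname(map[tr$cue_color]))
  cong <- tr$condition == "congruent"
  expect_true(all(tr$cue_side[cong] == tr$correct_response[cong]))
  inc <- tr$condition == "incongruent"
  expect_true(all(tr$cue_side[inc] != tr$correct_response[inc]))
  expect_true(all(tr$cue_color[tr$condition == "no_response"] == "yellow"))
  expect_identical(make_trial_list(3, 3, seed = 1),
                   make_trial_list(3, 3, seed = 1))
  expect_error(make_trial_list(100, 3), "remainder 1")
})

test_that("behavior simulation hits configured accuracy and RT medians", {
  spec <- cohort_spec(n_hc = 2, n_mci = 2, seed = 5)
  spec$behavior_effects$accuracy <- 1
  beh <- simulate_behavior(spec, make_trial_list(30, 3, seed = 1), seed = 2)
  expect_true(all(beh$summary$pct_correct == 100))
  # seeded determinism
  spec2 <- cohort_spec(n_hc = 3, n_mci = 3, seed = 9)
  b1 <- simulate_behavior(spec2, seed = 9)
  b2 <- simulate_behavior(spec2, seed = 9)
  expect_identical(b1$summary, b2$summary)
  # large cohort: HC congruent RT median within the published IQR
  big <- cohort_spec(n_hc = 150, n_mci = 1, seed = 21)
  bb <- simulate_behavior(big, make_trial_list(150, 3, seed = 3), seed = 21)
  hc_cong <- bb$summary[bb$summary$group == "HC" &
                          bb$summary$condition == "congruent", ]
  med <- median(hc_cong$rt_median_s)
  expect_gt(med, 0.521)
  expect_lt(med, 0.624)
  # no RT in the no-response condition
  expect_true(all(is.na(
    bb$summary$rt_median_s[bb$summary$condition == "no_response"])))
})

test_that("subject tables have planted cognition effects but equal volumes", {
  spec <- cohort_spec(n_hc = 402, n_mci = 47, seed = 7)
  tab <- simulate_subject_table(spec)
  expect_equal(nrow(tab), 449)
  expect_identical(tab, simulate_subject_table(spec))
  big <- simulate_subject_table(cohort_spec(n_hc = 300, n_mci = 300, seed = 3))
  # volumes: no planted group difference (standardized diff small)
  for (v in c("right_hippocampus", "total_gray", "etiv")) {
    d <- abs(mean(big[[v]][big$group == "HC"]) -
               mean(big[[v]][big$group == "MCI"])) / sd(big[[v]])
    expect_lt(d, 0.25)
  }
  # cognition: planted deficits in the MCI arm
  expect_lt(mean(big$word_list_memory[big$group == "MCI"]),
            mean(big$word_list_memory[big$group == "HC"]))
  expect_gt(mean(big$tmt_b[big$group == "MCI"]),
            mean(big$tmt_b[big$group == "HC"]))
})

test_that("planted group effects conserve their direction at cohort scale", {
  spec <- cohort_spec(n_hc = 250, n_mci = 250, seed = 13)
  tab <- simulate_subject_table(spec)
  for (k in seq_len(nrow(spec$network_effects))) {
    col <- paste0("loading_", k)
    expect_lt(mean(tab[[col]][tab$group == "MCI"]),
              mean(tab[[col]][tab$group == "HC"]))
  }
  beh <- simulate_behavior(spec, make_trial_list(150, 3, seed = 2), seed = 13)
  inc <- beh$summary[beh$summary$condition == "incongruent", ]
  expect_lt(mean(inc$pct_correct[inc$group == "MCI"]),
            mean(inc$pct_correct[inc$group == "HC"]))
  expect_gt(mean(inc$rt_median_s[inc$group == "MCI"]),
            mean(inc$rt_median_s[inc$group == "HC"]))
})

test_that("resting EEG is a loading-weighted network power mixture", {
  ss <- tiny_source_space()
  lf <- build_forward(montage_1020(), ss)
  nets <- default_networks(ss, 2)
  # zero loadings, zero sensor noise -> all-zero recordings
  spec0 <- cohort_spec(n_hc = 1, n_mci = 1, seed = 3)
  spec0$network_effects$mean_hc <- 0
  spec0$network_effects$sd_hc <- 0
  spec0$network_effects$mean_mci <- 0
  spec0$network_effects$sd_mci <- 0
  sim0 <- simulate_resting_eeg(spec0, nets[1:2], lf, duration_s = 12,
                               sensor_noise_uv = 0, seed = 3)
  expect_equal(max(abs(sim0$recordings[[1]]$data)), 0)
  # MCI true loadings below HC for every planted network
  spec <- cohort_spec(n_hc = 120, n_mci = 120, seed = 5)
  sim <- simulate_resting_eeg(spec, nets, lf, duration_s = 12, seed = 5)
  for (k in 1:2)
    expect_lt(mean(sim$loadings[sim$groups == "MCI", k]),
              mean(sim$loadings[sim$groups == "HC", k]))
  # one network, noiseless, one subject: source band power tracks the map
  spec1 <- cohort_spec(n_hc = 1, n_mci = 1, seed = 11)
  sim1 <- simulate_resting_eeg(spec1, nets[1], lf, duration_s = 60,
                               sensor_noise_uv = 0, seed = 11,
                               return_sources = TRUE)
  src <- sim1$sources[[1]]
  # direct FFT oracle for band power of the generated source series
  nseg <- ncol(src)
  F <- stats::mvfft(t(src))
  freq <- (seq_len(nseg) - 1) * 500 / nseg
  bp <- sapply(seq_len(5), function(b) {
    sel <- freq >= band_scheme()$lo_hz[b] & freq < band_scheme()$hi_hz[b]
    colSums(Mod(F[sel, , drop = FALSE])^2)
  })
  planted <- sim1$loadings[1, 1] * t(nets[[1]])
  cs <- sum(bp * planted) / sqrt(sum(bp^2) * sum(planted^2))
  expect_gt(cs, 0.99)
})

test_that("ERP generator plants the HC no-response N2 inside the clinical IQR", {
  spec <- cohort_spec(n_hc = 40, n_mci = 1, seed = 17)
  tr <- data.frame(trial_index = 1:50, condition = "no_response",
                   cue_side = "left", cue_color = "yellow",
                   correct_response = "none", given_response = NA,
                   rt_s = NA, iti_ms = 1500)
  sim <- simulate_erp_epochs(spec, tr, seed = 17)
  hc_truth <- sim$truth[sim$truth$group == "HC", ]
  expect_gt(mean(hc_truth$n2_amp_cz), -15.89)
  expect_lt(mean(hc_truth$n2_amp_cz), -6.72)
  # grand-average over measured subjects also lands in the IQR
  amps <- vapply(which(sim$groups == "HC"), function(s) {
    seg <- baseline_correct(reject_epochs(sim$epochs[[s]]))
    pk <- average_and_peaks(seg)$peaks
    pk$amplitude_uv[pk$component == "N2" & pk$channel == "Cz"]
  }, 0)
  expect_gt(mean(amps), -15.89)
  expect_lt(mean(amps), -6.72)
  # artifact_prob = 0 leads to zero rejections
  spec0 <- cohort_spec(n_hc = 1, n_mci = 1, seed = 2, artifact_prob = 0)
  sim0 <- simulate_erp_epochs(spec0, tr, seed = 2)
  expect_equal(sum(!reject_epochs(sim0$epochs[[1]])$retained), 0)
})
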