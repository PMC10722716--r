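#' Cohort specification for the synthetic study
#'
#' Bundles every generator parameter: group sizes, planted network-loading
#' effects, ERP component effects, Simon-task behavior parameters and the
#' artifact rate. Defaults encode the study conditions the pipeline assumes:
#' group effects point in the impaired-lower direction (network loadings and
#' no-response N2 at Cz attenuated in MCI; incongruent accuracy lower and RTs
#' slower), behavioral medians/IQRs follow the published descriptive values,
#' and the desk-scale cohort is 40 HC / 40 MCI (the clinical cohort's
#' 402 / 47 is reproducible by changing the counts).
#'
#' @param n_hc,n_mci Group sizes (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param network_effects data.frame with columns `network`, `mean_hc`,
#'   `sd_hc`, `mean_mci`, `sd_mci` on the source-power loading scale
#'   (uV^2/M^4/Hz). Default: three networks with a one-pooled-SD MCI deficit.
#' @param erp_effects data.frame of per-condition, per-group N2/P3 latency
#'   (ms) and Cz amplitude (uV) means; see Details.
#' @param erp_between_sd,erp_lat_sd,erp_noise_uv Between-subject amplitude SD
#'   (uV), between-subject latency SD (ms), and within-epoch noise SD (uV).
#' @param behavior_effects data.frame of per-condition, per-group response
#'   accuracy and lognormal RT parameters (seconds).
#' @param artifact_prob Fraction of ERP epochs carrying a planted artifact.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_hc = 40, n_mci = 40, seed = 1,
                        network_effects = default_network_effects(),
                        erp_effects = default_erp_effects(),
                        erp_between_sd = 3.5, erp_lat_sd = 12,
                        erp_noise_uv = 2,
                        behavior_effects = default_behavior_effects(),
                        artifact_prob = 0.1) {
  stopifnot(n_hc >= 1, n_mci >= 1,
            all(network_effects$sd_hc >= 0, network_effects$sd_mci >= 0))
  structure(list(n_hc = n_hc, n_mci = n_mci, seed = seed,
                 network_effects = network_effects,
                 erp_effects = erp_effects,
                 erp_between_sd = erp_between_sd, erp_lat_sd = erp_lat_sd,
                 erp_noise_uv = erp_noise_uv,
                 behavior_effects = behavior_effects,
                 artifact_prob = artifact_prob),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_network_effects <- function() {
  # HC location/scale from the published loading summaries; the MCI deficit is
  # planted at one pooled SD, the calibration at which a 40/40 desk cohort has
  # high power (the clinical effect sizes need the full 402/47 cohort).
  data.frame(network = 1:3,
             mean_hc = c(2760, 1958, 2738),
             sd_hc   = c(808, 654, 752),
             mean_mci = c(2760 - 808, 1958 - 654, 2738 - 752),
             sd_mci  = c(808, 654, 752))
}

#' @rdname cohort_spec
#' @export
default_erp_effects <- function() {
  conds <- c("congruent", "incongruent", "no_response")
  base <- expand.grid(condition = conds, group = c("HC", "MCI"),
                      stringsAsFactors = FALSE)
  base$n2_lat_ms <- 196
  base$p3_lat_ms <- c(425, 450, 505, 430, 455, 505)
  base$n2_amp_cz <- c(-6.3, -7.2, -10.3, -6.3, -7.2, -6.67)
  base$p3_amp_cz <- c(9.9, 9.6, 10.7, 9.7, 9.0, 8.3)
  base
}

#' @rdname cohort_spec
#' @export
default_behavior_effects <- function() {
  conds <- c("congruent", "incongruent", "no_response")
  eff <- expand.grid(condition = conds, group = c("HC", "MCI"),
                     stringsAsFactors = FALSE)
  eff$accuracy <- c(0.98, 0.98, 0.99, 0.98, 0.96, 0.99)
  # lognormal RT parameters fit to the published medians / IQRs (seconds)
  eff$rt_meanlog <- log(c(0.574, 0.615, 0.615, 0.602, 0.653, 0.653))
  eff$rt_sdlog <- c(0.134, 0.200, 0.200, 0.132, 0.146, 0.146)
  eff
}

cohort_groups <- function(spec) {
  c(rep("HC", spec$n_hc), rep("MCI", spec$n_mci))
}

#' Randomized Simon-task trial list
#'
#' Generates a seeded random permutation of equally many congruent,
#' incongruent and no-response trials. Cue colors map to responses as
#' blue -> right hand, red -> left hand, yellow -> withhold; a congruent trial
#' shows the cue on the side of its required response, an incongruent trial on
#' the opposite side. The intertrial interval is 1500 ms. The task block is
#' 150 trials (50 per condition); the practice block is 24 (8 per condition).
#'
#' @param n_trials Total trial count, divisible by `n_conditions`.
#' @param n_conditions Number of conditions (3).
#' @param seed Integer seed.
#' @return A `trial_table` data.frame with columns `trial_index`, `condition`,
#'   `cue_side`, `cue_color`, `correct_response`, `given_response`, `rt_s`,
#'   `iti_ms`.
#' @export
make_trial_list <- function(n_trials = 150, n_conditions = 3, seed = 1) {
  if (n_trials %% n_conditions != 0)
    stop("n_trials = ", n_trials, " is not divisible by n_conditions = ",
         n_conditions, " (remainder ", n_trials %% n_conditions, ")")
  conds <- c("congruent", "incongruent", "no_response")[seq_len(n_conditions)]
  per <- n_trials / n_conditions
  set.seed(seed)
  condition <- sample(rep(conds, each = per))
  cue_side <- sample(c("left", "right"), n_trials, replace = TRUE)
  cue_color <- ifelse(condition == "no_response", "yellow",
               ifelse(condition == "congruent",
                      ifelse(cue_side == "right", "blue", "red"),
                      ifelse(cue_side == "right", "red", "blue")))
  correct_response <- c(blue = "right", red = "left", yellow = "none")[cue_color]
  out <- data.frame(trial_index = seq_len(n_trials), condition = condition,
                    cue_side = cue_side, cue_color = cue_color,
                    correct_response = unname(correct_response),
                    given_response = NA_character_, rt_s = NA_real_,
                    iti_ms = 1500)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Simulate Simon-task responses for a cohort
#'
#' Fills a trial table per subject with responses drawn from per-group,
#' per-condition accuracy (Bernoulli) and lognormal RT parameters. Errors on
#' response trials are presses with the wrong hand; errors on no-response
#' trials are unwanted presses (which also carry an RT). By default the MCI
#' arm has lower incongruent accuracy and slower RTs.
#'
#' @param spec A [cohort_spec()].
#' @param trials A [make_trial_list()] table (shared design across subjects).
#' @param seed Integer seed.
#' @return List with `trials` (per-subject list of filled trial tables),
#'   `summary` (per subject x condition accuracy/RT summary via
#'   [score_trials()]), and `groups`.
#' @export
simulate_behavior <- function(spec, trials = make_trial_list(seed = spec$seed),
                              seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- cohort_groups(spec)
  eff <- spec$behavior_effects
  set.seed(seed)
  per_subject <- lapply(seq_along(groups), function(s) {
    tb <- trials
    row <- match(paste(tb$condition, groups[s]),
                 paste(eff$condition, eff$group))
    ok <- stats::runif(nrow(tb)) < eff$accuracy[row]
    flip <- c(left = "right", right = "left")
    is_nr <- tb$correct_response == "none"
    tb$given_response <- ifelse(is_nr,
      ifelse(ok, "none", sample(c("left", "right"), nrow(tb), replace = TRUE)),
      ifelse(ok, tb$correct_response, flip[tb$correct_response]))
    pressed <- tb$given_response != "none"
    rt <- stats::rlnorm(nrow(tb), eff$rt_meanlog[row], eff$rt_sdlog[row])
    tb$rt_s <- ifelse(pressed, rt, NA_real_)
    tb
  })
  summaries <- lapply(seq_along(per_subject), function(s) {
    sm <- score_trials(per_subject[[s]])
    sm$subject <- s; sm$group <- groups[s]
    sm
  })
  list(trials = per_subject, summary = do.call(rbind, summaries),
       groups = groups)
}

#' Simulate the per-subject clinical table
#'
#' Generates demographics, cognitive scores, brain volumes and true network
#' loadings for a cohort. Demographics and volumes are drawn from the same
#' distributions in both groups (the clinical comparison found no volume
#' differences); only cognition and network loadings carry planted effects.
#' Cognitive scores are drawn consistently with the MCI case definition:
#' HC subjects are redrawn until no domain falls 1.5 SD below the norm,
#' MCI subjects until at least one does, and both groups satisfy MMSE >= 24.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A `subject_table` data.frame, one row per subject.
#' @export
simulate_subject_table <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- cohort_groups(spec)
  n <- length(groups)
  set.seed(seed)
  norms <- default_cognitive_norms()
  # domain draw parameters: HC centred on the norms; MCI shifted downward
  dom <- list(
    word_list_memory = list(hc = c(12.3, 3.0), mci = c(8.5, 3.0), hb = TRUE),
    tmt_a = list(hc = c(18, 3), mci = c(24, 6), hb = FALSE),
    tmt_b = list(hc = c(31, 9), mci = c(45, 16), hb = FALSE),
    sdst  = list(hc = c(50, 7), mci = c(41, 8), hb = TRUE))
  draw_cog <- function(group) {
    for (try in 1:200) {
      sc <- vapply(dom, function(d) {
        p <- if (group == "HC") d$hc else d$mci
        stats::rnorm(1, p[1], p[2])
      }, 0)
      z <- vapply(names(dom), function(nm) {
        d <- dom[[nm]]
        if (d$hb) (sc[nm] - d$hc[1]) / d$hc[2] else (d$hc[1] - sc[nm]) / d$hc[2]
      }, 0)
      impaired <- any(z <= -1.5)
      if ((group == "HC" && !impaired) || (group == "MCI" && impaired))
        return(sc)
    }
    sc   # practically unreachable
  }
  cog <- t(vapply(groups, draw_cog, numeric(4)))
  mmse <- pmin(30, round(stats::rnorm(n, ifelse(groups == "HC", 28.5, 27.3),
                                      1.2)))
  mmse <- pmax(mmse, 24)   # both analysis groups are MMSE >= 24 by definition
  ne <- spec$network_effects
  loadings <- sapply(seq_len(nrow(ne)), function(k) {
    ifelse(groups == "HC",
           stats::rnorm(n, ne$mean_hc[k], ne$sd_hc[k]),
           stats::rnorm(n, ne$mean_mci[k], ne$sd_mci[k]))
  })
  colnames(loadings) <- paste0("loading_", ne$network)
  vol <- function(m, s) stats::rnorm(n, m, s)
  out <- data.frame(
    subject = seq_len(n), group = groups,
    age = round(stats::rnorm(n, 73.5, 6)),
    sex = sample(c("woman", "man"), n, replace = TRUE, prob = c(0.555, 0.445)),
    education = pmax(6, round(stats::rnorm(n, 13, 2.5))),
    mmse = mmse,
    word_list_memory = cog[, 1], tmt_a = cog[, 2], tmt_b = cog[, 3],
    sdst = cog[, 4],
    right_hippocampus = vol(3916, 420), left_hippocampus = vol(3746, 390),
    cerebral_white_matter = vol(410081, 43600),
    subcortical_gray = vol(51097, 4400), total_gray = vol(562344, 46800),
    etiv = vol(1357197, 148000))
  out <- cbind(out, loadings)
  class(out) <- c("subject_table", "data.frame")
  out
}
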