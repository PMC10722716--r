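#' Pipeline configuration
#'
#' Bundles every stage's settings with defaults equal to the protocol's
#' stated values: 150 task trials (50 per condition) with a 24-trial practice
#' block, 0.53--120 Hz resting / 0.1--30 Hz ERP filters with a 60 Hz notch,
#' the five clinical bands, k = 15 group ICA components, -200..700 ms
#' epochs with the 200 uV / 0.5 uV rejection rule and 151--230 / 300--600 ms
#' peak windows, and 100 iterations of five-fold Monte-Carlo CV. Cohort size
#' and the source grid are scaled for desk use (the clinical scale is
#' reproducible by raising them).
#'
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_hc = 40L, n_mci = 40L, seed = 1L,
    n_trials = 150L, n_conditions = 3L, practice_trials = 24L,
    rest_duration_s = 60, rate = 500L,
    grid_spacing_mm = 24, grid_radius_mm = 75,
    n_networks = 3L, ica_k = 15L, ica_seed = 7L,
    erp_ica = FALSE,
    cv_folds = 5L, cv_iters = 100L, cv_mode = "leak_safe",
    models = 1:6, classifiers = c("svm", "logistic"),
    resample_method = "rose_smoothed",
    run_resting_eeg = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  # normalize types so that save/load round-trips exactly
  ints <- c("n_hc", "n_mci", "seed", "n_trials", "n_conditions",
            "practice_trials", "rate", "n_networks", "ica_k", "ica_seed",
            "cv_folds", "cv_iters", "models")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  nums <- c("rest_duration_s", "grid_spacing_mm", "grid_radius_mm")
  for (f in nums) cfg[[f]] <- as.numeric(cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> preprocess -> inverse -> group ICA -> ERP -> behavior
#' -> group statistics -> discrimination on a synthetic cohort, and returns a
#' report bundle of the shaped tables the protocol reports: cohort
#' characteristics with group tests, network-loading comparison, ERP peak
#' summaries with the no-response N2 contrast at Cz, behavioral summaries,
#' and per-model cross-validated classification metrics. The bundle is a
#' deterministic function of the configuration (including its seeds).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list; see Details in the package vignette.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- data.frame(stage = stage,
                                          detail = paste0(...))
  }
  spec <- cohort_spec(n_hc = config$n_hc, n_mci = config$n_mci,
                      seed = config$seed)
  if (config$n_mci == 0) stop("discrimination requires both classes (n_mci = 0)")
  note("simulate", "cohort ", config$n_hc, "/", config$n_mci,
       " seed ", config$seed)

  subjects <- simulate_subject_table(spec, seed = config$seed)
  trials <- make_trial_list(config$n_trials, config$n_conditions,
                            seed = config$seed)
  beh <- simulate_behavior(spec, trials, seed = config$seed + 1L)
  erps <- simulate_erp_epochs(spec, trials, seed = config$seed + 2L)

  net_cmp <- NULL; dec <- NULL
  if (config$run_resting_eeg) {
    mon <- montage_1020()
    ss <- source_space_grid(config$grid_spacing_mm, config$grid_radius_mm)
    lf <- build_forward(mon, ss)
    nets <- default_networks(ss, config$n_networks)
    rest <- simulate_resting_eeg(spec, nets, lf,
                                 duration_s = config$rest_duration_s,
                                 rate = config$rate,
                                 seed = config$seed + 3L)
    note("inverse", "grid ", ss$n_voxels, " voxels @ ",
         config$grid_spacing_mm, " mm")
    inv <- compute_inverse(lf)
    images <- lapply(seq_along(rest$recordings), function(s) {
      rec <- bandpass_notch(rest$recordings[[s]], branch_filter("rest"))
      band_power_source(rec, inv, subject_id = as.character(s))
    })
    gm <- build_group_matrix(images)
    k_eff <- min(config$ica_k, nrow(gm$X) - 1L)
    dec <- fit_group_ica(gm, k = k_eff, seed = config$ica_seed)
    note("netica", "k = ", k_eff)
    net_cmp <- compare_networks(dec, rest$groups, seed = config$seed + 4L)
  }

  # ERP branch: rejection, baseline, peaks, no-response N2 contrast at Cz
  peak_rows <- lapply(seq_along(erps$epochs), function(s) {
    seg <- erps$epochs[[s]]
    if (config$erp_ica) seg <- correct_artifacts_ica(seg, seed = config$seed)
    seg <- reject_epochs(seg)
    seg <- baseline_correct(seg)
    pk <- average_and_peaks(seg)$peaks
    pk$subject <- s; pk$group <- erps$groups[s]
    pk
  })
  peaks <- do.call(rbind, peak_rows)
  n2 <- peaks[peaks$component == "N2" & peaks$channel == "Cz" &
                peaks$condition == "no_response", ]
  erp_test <- wilcoxon_ranksum(n2$amplitude_uv[n2$group == "HC"],
                               n2$amplitude_uv[n2$group == "MCI"])
  note("erp", "no-response N2 at Cz: p = ", signif(erp_test$p, 3))

  beh_sum <- beh$summary
  inc <- beh_sum[beh_sum$condition == "incongruent", ]
  beh_tests <- list(
    incongruent_accuracy = wilcoxon_ranksum(
      inc$pct_correct[inc$group == "HC"], inc$pct_correct[inc$group == "MCI"]),
    incongruent_rt = wilcoxon_ranksum(
      inc$rt_median_s[inc$group == "HC"], inc$rt_median_s[inc$group == "MCI"]))

  char_tab <- group_comparison_table(
    subjects, variables = c("age", "sex", "education", "mmse",
                            "word_list_memory", "tmt_a", "tmt_b", "sdst",
                            "right_hippocampus", "left_hippocampus",
                            "cerebral_white_matter", "subcortical_gray",
                            "total_gray", "etiv"))

  # discrimination on the loading columns (estimated loadings when the
  # resting branch ran and found discriminative networks, else true ones)
  subj_cv <- subjects
  if (!is.null(net_cmp)) {
    sig <- net_cmp$component[net_cmp$p < 0.05]
    if (length(sig) >= 1) {
      subj_cv <- subjects[, !grepl("^loading_", names(subjects))]
      L <- dec$loadings[, sig, drop = FALSE]
      colnames(L) <- paste0("loading_", seq_along(sig))
      subj_cv <- cbind(subj_cv, L)
      note("discern", "using ", length(sig), " discriminative network(s)")
    }
  }
  cv <- list()
  for (cls in config$classifiers) for (mid in config$models) {
    key <- paste0(cls, "_model", mid)
    cv[[key]] <- run_cv(subj_cv, model_spec(mid), classifier = cls,
                        folds = config$cv_folds, iters = config$cv_iters,
                        resample = resample_spec(config$resample_method,
                                                 seed = config$seed),
                        mode = config$cv_mode, seed = config$seed + 5L)
  }
  metrics_tab <- do.call(rbind, lapply(names(cv), function(key) {
    data.frame(model = key, t(round(cv[[key]]$aggregate, 4)))
  }))
  note("discern", nrow(metrics_tab), " model fits")

  structure(list(config = config, subjects = subjects,
                 characteristics = char_tab,
                 network_comparison = net_cmp,
                 erp_peaks = peaks, erp_n2_test = erp_test,
                 behavior_summary = beh_sum, behavior_tests = beh_tests,
                 cv_metrics = metrics_tab, cv_results = cv,
                 log = do.call(rbind, log)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$config$n_hc, " HC / ", x$config$n_mci,
      " MCI\n", sep = "")
  cat("stages:\n"); print(x$log)
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits the shaped TSV tables and a JSON metrics file.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$characteristics, file.path(dir, "characteristics.tsv"))
  if (!is.null(report$network_comparison))
    write_tsv(report$network_comparison, file.path(dir, "networks.tsv"))
  write_tsv(report$erp_peaks, file.path(dir, "erp_peaks.tsv"))
  write_tsv(report$behavior_summary, file.path(dir, "behavior.tsv"))
  write_tsv(report$cv_metrics, file.path(dir, "cv_metrics.tsv"))
  jsonlite::write_json(
    list(erp_n2_p = report$erp_n2_test$p,
         cv = report$cv_metrics),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  save_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
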