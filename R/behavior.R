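#' Score a Simon-task trial table
#'
#' A trial is correct when the given response equals the required response
#' (for no-response trials, when no key was pressed; a press on a yellow cue
#' counts as an error). Reaction-time summaries (median and IQR, type-7
#' quantiles) are computed over correct, responded trials, so the no-response
#' condition carries no RT.
#'
#' @param trials A filled [make_trial_list()] table.
#' @return A data.frame per condition: `condition`, `n_trials`,
#'   `pct_correct`, `rt_median_s`, `rt_q1_s`, `rt_q3_s`, `flag` (set when a
#'   condition has no trials).
#' @export
score_trials <- function(trials) {
  stopifnot(all(c("condition", "correct_response", "given_response")
                %in% names(trials)))
  conds <- unique(c(c("congruent", "incongruent", "no_response"),
                    unique(trials$condition)))
  out <- lapply(conds, function(cond) {
    tb <- trials[trials$condition == cond, ]
    if (nrow(tb) == 0)
      return(data.frame(condition = cond, n_trials = 0, pct_correct = NA_real_,
                        rt_median_s = NA_real_, rt_q1_s = NA_real_,
                        rt_q3_s = NA_real_, flag = "empty_condition"))
    correct <- tb$given_response == tb$correct_response
    rts <- tb$rt_s[correct & tb$given_response != "none" & !is.na(tb$rt_s)]
    q <- if (length(rts)) stats::quantile(rts, c(0.25, 0.5, 0.75), type = 7,
                                          names = FALSE) else rep(NA_real_, 3)
    data.frame(condition = cond, n_trials = nrow(tb),
               pct_correct = 100 * mean(correct),
               rt_median_s = q[2], rt_q1_s = q[1], rt_q3_s = q[3],
               flag = NA_character_)
  })
  out <- do.call(rbind, out)
  out[!duplicated(out$condition), ]
}

#' Synthetic cognitive norms
#'
#' Age- and education-stratified means and SDs for the four cognitive
#' domains, plus the MMSE cutoff. These norms are synthetic (they match the
#' simulator's healthy-control distributions); the clinical normative
#' database behind the original thresholds is unpublished, so the strata are
#' configuration. Timed domains (`higher_better = FALSE`) are sign-flipped
#' before z-scoring so that a more negative z always means worse performance.
#'
#' @param age_breaks,edu_breaks Stratum boundaries (right-open).
#' @return A `cognitive_norms` list with a `table` data.frame and
#'   `mmse_cutoff = 24`.
#' @export
default_cognitive_norms <- function(age_breaks = c(40, 75, 100),
                                    edu_breaks = c(0, 13, 30)) {
  doms <- data.frame(
    domain = c("memory", "attention", "executive", "processing_speed"),
    variable = c("word_list_memory", "tmt_a", "tmt_b", "sdst"),
    mean = c(12.3, 18, 31, 50),
    sd = c(3.0, 3, 9, 7),
    higher_better = c(TRUE, FALSE, FALSE, TRUE))
  strata <- expand.grid(age_band = seq_len(length(age_breaks) - 1),
                        edu_band = seq_len(length(edu_breaks) - 1))
  tab <- merge(strata, doms)
  structure(list(table = tab, age_breaks = age_breaks,
                 edu_breaks = edu_breaks, mmse_cutoff = 24),
            class = "cognitive_norms")
}

norm_stratum <- function(norms, age, education) {
  a <- findInterval(age, norms$age_breaks, rightmost.closed = TRUE)
  e <- findInterval(education, norms$edu_breaks, rightmost.closed = TRUE)
  if (a < 1 || a > length(norms$age_breaks) - 1 ||
      e < 1 || e > length(norms$edu_breaks) - 1)
    stop("no norm stratum for age ", age, " / education ", education)
  list(age_band = a, edu_band = e)
}

#' Domain z-scores against the norms
#'
#' @param record One-row data.frame (or list) with `age`, `education` and the
#'   four domain variables.
#' @param norms A [default_cognitive_norms()] object.
#' @return Named numeric vector of domain z-scores (negative = worse).
#' @export
domain_z_scores <- function(record, norms = default_cognitive_norms()) {
  st <- norm_stratum(norms, record$age, record$education)
  tab <- norms$table
  tab <- tab[tab$age_band == st$age_band & tab$edu_band == st$edu_band, ]
  z <- vapply(seq_len(nrow(tab)), function(i) {
    x <- record[[tab$variable[i]]]
    if (is.null(x) || is.na(x)) stop("missing score: ", tab$variable[i])
    raw <- (x - tab$mean[i]) / tab$sd[i]
    if (tab$higher_better[i]) raw else -raw
  }, 0)
  names(z) <- tab$domain
  z
}

#' MCI case definition
#'
#' Classifies a subject as `global_impairment` when MMSE < 24 (excluded from
#' the HC/MCI contrast), as `MCI` when any cognitive domain scores 1.5 SD or
#' more below its age- and education-specific norm (z <= -1.5, inclusive),
#' and as `HC` otherwise.
#'
#' @param record One-row data.frame/list with `mmse`, `age`, `education` and
#'   the domain variables.
#' @param norms A [default_cognitive_norms()] object.
#' @return `"HC"`, `"MCI"` or `"global_impairment"`.
#' @export
classify_mci <- function(record, norms = default_cognitive_norms()) {
  if (is.null(record$mmse) || is.na(record$mmse)) stop("missing MMSE")
  if (record$mmse < norms$mmse_cutoff) return("global_impairment")
  z <- domain_z_scores(record, norms)
  if (any(z <= -1.5)) "MCI" else "HC"
}

#' @rdname classify_mci
#' @param subjects A [simulate_subject_table()]-shaped data.frame.
#' @return For `classify_mci_table`: character vector of labels per row.
#' @export
classify_mci_table <- function(subjects, norms = default_cognitive_norms()) {
  vapply(seq_len(nrow(subjects)),
         function(i) classify_mci(subjects[i, ], norms), "")
}
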