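## Quantitative sensory testing and sensory-accuracy scorers. Each scorer
## turns the raw trial records of one test into the single subject-level
## outcome used by the group models.

#' Vibration threshold (Rydel-Seiffer tuning fork)
#'
#' Mean of three consecutive trials on the 0-8 tuning-fork scale; higher
#' means finer vibration sense.
#'
#' @param trials 3 values in [0, 8].
#' @return threshold on the 0-8 scale.
#' @export
vibration_threshold <- function(trials) {
  if (length(trials) != 3L) stop("exactly 3 trials required", call. = FALSE)
  if (any(trials < 0 | trials > 8)) {
    stop("vibration trials must lie on the 0-8 scale", call. = FALSE)
  }
  mean(trials)
}

#' Pressure pain threshold
#'
#' Mean of three algometer repetitions (Newton).
#'
#' @param trials 3 positive forces in N.
#' @return threshold in N.
#' @export
pressure_pain_threshold <- function(trials) {
  if (length(trials) != 3L) stop("exactly 3 trials required", call. = FALSE)
  if (any(trials <= 0)) stop("forces must be positive", call. = FALSE)
  mean(trials)
}

#' Temporal summation of pain
#'
#' Mean pain rating (0-10 NRS) after a train of 10 pinprick stimuli minus
#' the mean rating after a single stimulus, each over 5 repetitions.
#' Positive values indicate summation.
#'
#' @param single 5 ratings after single stimuli.
#' @param train 5 ratings after stimulus trains.
#' @return difference on the 0-10 scale (range -10..10).
#' @export
temporal_summation <- function(single, train) {
  if (length(single) != 5L || length(train) != 5L) {
    stop("5 ratings required for single and train", call. = FALSE)
  }
  if (any(c(single, train) < 0 | c(single, train) > 10)) {
    stop("ratings must lie on the 0-10 scale", call. = FALSE)
  }
  mean(train) - mean(single)
}

#' Conditioned pain modulation effects
#'
#' Pressure pain thresholds are measured before and during a cold-pressor
#' conditioning stimulus. With `B = mean(before)` and `D = mean(during)`:
#' absolute effect `D - B` (N) and relative effect `100 * (D - B) / B` (%).
#' Under this convention a positive effect means the threshold rose during
#' conditioning, i.e. efficient pain inhibition; `flip_sign = TRUE` returns
#' the opposite convention for comparability with studies reporting
#' `B - D`.
#'
#' @param ppt_before 3 positive forces (N) before conditioning.
#' @param ppt_during 3 positive forces (N) during conditioning.
#' @param flip_sign reverse the sign convention (default FALSE).
#' @return named numeric vector `c(cpm_abs = , cpm_rel = )` (N, %).
#' @export
cpm_effects <- function(ppt_before, ppt_during, flip_sign = FALSE) {
  b <- pressure_pain_threshold(ppt_before)
  d <- pressure_pain_threshold(ppt_during)
  s <- if (flip_sign) -1 else 1
  c(cpm_abs = s * (d - b), cpm_rel = s * 100 * (d - b) / b)
}

#' Graphaesthesia error rate
#'
#' Numbers drawn on the lower back; the outcome is the share of the 20
#' figures identified incorrectly.
#'
#' @param incorrect count of incorrect answers.
#' @param total number of figures presented (default 20).
#' @return error rate in [0, 1].
#' @export
graphaesthesia_error_rate <- function(incorrect, total = 20) {
  if (incorrect < 0 || incorrect > total) {
    stop("incorrect count must lie in [0, total]", call. = FALSE)
  }
  incorrect / total
}

#' Two-point discrimination threshold
#'
#' Mean over six paraspinal locations (L1, L3, L5 left/right) of the
#' per-location average distance at which two caliper points were first
#' identified as two.
#'
#' @param location_means 6 per-location distances in mm (each >= 20, the
#'   staircase start).
#' @return threshold in mm.
#' @export
two_point_threshold <- function(location_means) {
  if (length(location_means) != 6L) {
    stop("exactly 6 location averages required", call. = FALSE)
  }
  if (any(location_means < 20)) {
    stop("distances below the 20 mm staircase start", call. = FALSE)
  }
  mean(location_means)
}

#' Ascending two-point staircase for one location
#'
#' The calipers start at 20 mm; the distance is increased in 5 mm steps as
#' long as the participant reports a single point. The per-location
#' threshold is the first distance at which "two" is reported:
#' `20 + 5 * (number of "one" responses)`. A participant who never reports
#' "two" yields `NA` with a `ceiling` attribute set (or the configured
#' ceiling value).
#'
#' @param responses character vector of `"one"`/`"two"` judgements in
#'   presentation order, starting at 20 mm.
#' @param ceiling_value value to report when "two" is never reached
#'   (default `NA`, flagged).
#' @return threshold in mm, with attribute `ceiling` (logical).
#' @export
tpd_staircase <- function(responses, ceiling_value = NA_real_) {
  if (length(responses) == 0L) stop("no responses", call. = FALSE)
  if (!all(responses %in% c("one", "two"))) {
    stop('responses must be "one" or "two"', call. = FALSE)
  }
  first_two <- match("two", responses)
  if (is.na(first_two)) {
    return(structure(ceiling_value, ceiling = TRUE))
  }
  structure(20 + 5 * (first_two - 1), ceiling = FALSE)
}

#' Score a subject's raw QST records
#'
#' Applies all scorers to one subject's raw record list and returns the
#' subject-level outcome row. NPRS ratings of the conditioning hand, when
#' present in the raw records, are carried through unchanged and enter no
#' score.
#'
#' @param raw list with elements `vibration_trials` (3), `ppt_trials` (3),
#'   `cpm_ppt_during` (3), `ts_single` (5), `ts_train` (5),
#'   `graph_incorrect` (count), `tpd_location_means` (6).
#' @param cpm_flip_sign forwarded to [cpm_effects()].
#' @return one-row data.frame with columns `vibration`, `ppt`, `cpm_abs`,
#'   `cpm_rel`, `ts`, `graphaesthesia`, `tpd`.
#' @export
score_qst <- function(raw, cpm_flip_sign = FALSE) {
  cpm <- cpm_effects(raw$ppt_trials, raw$cpm_ppt_during,
                     flip_sign = cpm_flip_sign)
  data.frame(
    vibration = vibration_threshold(raw$vibration_trials),
    ppt = pressure_pain_threshold(raw$ppt_trials),
    cpm_abs = unname(cpm["cpm_abs"]),
    cpm_rel = unname(cpm["cpm_rel"]),
    ts = temporal_summation(raw$ts_single, raw$ts_train),
    graphaesthesia = graphaesthesia_error_rate(raw$graph_incorrect),
    tpd = two_point_threshold(raw$tpd_location_means)
  )
}
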