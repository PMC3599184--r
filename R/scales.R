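#' Scale definitions
#'
#' The configuration behind the scorers: item lists, recode tables and
#' dichotomy thresholds for the six embedded scales. Exposed (and
#' YAML-exportable via [yaml::write_yaml()]) so a corrected recode table can
#' be swapped in without code change.
#'
#' @return A named list of scale definitions.
#' @export
scale_definitions <- function() {
  list(
    adl_long_form = list(
      items = paste0("adl_", c("bed_mobility", "transfer", "locomotion_on_unit",
                               "dressing", "eating", "toilet_use",
                               "personal_hygiene"), "_perf"),
      recode = c("0" = 0, "1" = 1, "2" = 2, "3" = 3, "4" = 4, "8" = 4),
      aggregation = "sum", range = c(0, 28)),
    drs = list(
      items = paste0("mood_", c("negative_statements", "persistent_anger",
                                "unrealistic_fears", "health_complaints",
                                "anxious_complaints", "sad_expression",
                                "crying")),
      aggregation = "sum", range = c(0, 14), threshold = 3),
    abs = list(
      items = c("verbally_abusive", "physically_abusive",
                "socially_inappropriate", "resists_care"),
      aggregation = "sum", range = c(0, 12), threshold = 5),
    cps = list(
      items = c("comatose", "memory_problem", "decision_making",
                "making_self_understood", "adl_eating_perf"),
      aggregation = "decision_tree", range = c(0, 6), threshold = 3),
    rug_adl = list(
      items = c("adl_bed_mobility_perf", "adl_bed_mobility_supp",
                "adl_transfer_perf", "adl_transfer_supp",
                "adl_toilet_use_perf", "adl_toilet_use_supp",
                "adl_eating_perf"),
      aggregation = "recode_sum", range = c(4, 18), threshold = 11),
    pain = list(
      items = c("pain_frequency", "pain_intensity"),
      aggregation = "decision_tree", range = c(0, 3))
  )
}

sum_scale <- function(records, items, recode = NULL) {
  m <- as.matrix(records[, items])
  if (!is.null(recode)) {
    m[] <- unname(recode[as.character(m)])
  }
  out <- rowSums(m)
  out # NA whenever any contributing item is missing
}

#' Score the ADL Long Form scale (0-28)
#'
#' Sum of seven ADL self-performance items (bed mobility, transfer,
#' locomotion, dressing, eating, toilet use, personal hygiene), with code 8
#' ("activity did not occur") recoded to 4, the maximal-dependence
#' interpretation. Missing any item gives a missing score.
#'
#' @param records Assessment tibble.
#' @return Numeric vector, 0-28 or NA.
#' @export
score_adl_long_form <- function(records) {
  def <- scale_definitions()$adl_long_form
  sum_scale(records, def$items, def$recode)
}

#' Score the Depression Rating Scale (0-14)
#'
#' Simple sum of seven mood indicator items, each coded 0/1/2.
#'
#' @inheritParams score_adl_long_form
#' @return Numeric vector, 0-14 or NA.
#' @export
score_drs <- function(records) {
  sum_scale(records, scale_definitions()$drs$items)
}

#' Score the Aggressive Behaviour Scale (0-12)
#'
#' Sum of four behaviour items (verbally abusive, physically abusive,
#' socially inappropriate/disruptive, resists care), each 0-3.
#'
#' @inheritParams score_adl_long_form
#' @return Numeric vector, 0-12 or NA.
#' @export
score_abs <- function(records) {
  sum_scale(records, scale_definitions()$abs$items)
}

#' Score the Cognitive Performance Scale (0-6)
#'
#' Decision tree over comatose status, short-term memory problem, daily
#' decision-making, making self understood, and eating self-performance:
#' comatose gives 6; severely impaired decision-making (3) gives 5, or 6 when
#' eating is total dependence (4); otherwise the count of impairments
#' (memory problem, any decision-making impairment, any difficulty being
#' understood) maps 0 to 0 and 1 to 1, and two or more impairments map to
#' 2 + the count of severe impairments (decision-making >= 2, understood >= 2).
#'
#' @inheritParams score_adl_long_form
#' @return Numeric vector, 0-6 or NA.
#' @export
score_cps <- function(records) {
  com <- records$comatose
  mem <- records$memory_problem
  dec <- records$decision_making
  und <- records$making_self_understood
  eat <- records$adl_eating_perf

  n <- nrow(records)
  out <- rep(NA_real_, n)

  imp <- (mem >= 1) + (dec >= 1) + (und >= 1)
  sev <- (dec >= 2) + (und >= 2)
  base <- ifelse(imp == 0, 0, ifelse(imp == 1, 1, 2 + sev))

  out <- ifelse(
    !is.na(com) & com == 1, 6,
    ifelse(!is.na(dec) & dec == 3,
           ifelse(!is.na(eat) & eat %in% c(4, 8), 6,
                  ifelse(is.na(eat), NA_real_, 5)),
           base))
  out
}

#' Score the RUG-ADL index (4-18)
#'
#' Sum of four recoded components. Bed mobility, transfer and toilet use:
#' self-performance <= 1 contributes 1; = 2 contributes 3; >= 3 (including 8,
#' "did not occur", read as dependence) contributes 4, raised to 5 when the
#' paired support item indicates a two-or-more-person assist (support >= 3).
#' Eating: <= 1 contributes 1; = 2 contributes 2; >= 3 contributes 3.
#'
#' @inheritParams score_adl_long_form
#' @return Numeric vector, 4-18 or NA.
#' @export
score_rug_adl <- function(records) {
  comp <- function(perf, supp) {
    dep <- perf >= 3 # includes code 8
    base <- ifelse(perf <= 1, 1, ifelse(perf == 2, 3, 4))
    ifelse(dep & !is.na(supp) & supp >= 3 & supp != 8, 5,
           ifelse(dep & is.na(supp), NA_real_, base))
  }
  eat <- records$adl_eating_perf
  eat_c <- ifelse(eat <= 1, 1, ifelse(eat == 2, 2, 3))
  comp(records$adl_bed_mobility_perf, records$adl_bed_mobility_supp) +
    comp(records$adl_transfer_perf, records$adl_transfer_supp) +
    comp(records$adl_toilet_use_perf, records$adl_toilet_use_supp) +
    eat_c
}

#' Score the Pain Scale (0-3)
#'
#' 0 when pain frequency is none; 1 when less than daily; 2 when daily with
#' less-than-severe intensity; 3 when daily and severe.
#'
#' @inheritParams score_adl_long_form
#' @return Numeric vector, 0-3 or NA.
#' @export
score_pain <- function(records) {
  freq <- records$pain_frequency
  int <- records$pain_intensity
  ifelse(freq == 0, 0,
         ifelse(freq == 1, 1,
                ifelse(is.na(int), NA_real_, ifelse(int >= 3, 3, 2))))
}

#' Score all scales and dichotomy flags
#'
#' Appends the six scale scores and the four prevalence flags used by the
#' quarterly characteristic tables: `cps_ge3` (moderate or worse cognitive
#' impairment), `rugadl_ge11` (moderate or worse ADL impairment), `abs_ge5`
#' (high behaviour disturbance) and `drs_ge3` (possible depression). A flag
#' is missing when its score is missing.
#'
#' @param records Assessment tibble.
#' @return `records` with columns `adl_long_form`, `drs`, `abs`, `cps`,
#'   `rug_adl`, `pain`, `cps_ge3`, `rugadl_ge11`, `abs_ge5`, `drs_ge3`.
#' @export
score_scales <- function(records) {
  records$adl_long_form <- score_adl_long_form(records)
  records$drs <- score_drs(records)
  records$abs <- score_abs(records)
  records$cps <- score_cps(records)
  records$rug_adl <- score_rug_adl(records)
  records$pain <- score_pain(records)
  records$cps_ge3 <- records$cps >= 3
  records$rugadl_ge11 <- records$rug_adl >= 11
  records$abs_ge5 <- records$abs >= 5
  records$drs_ge3 <- records$drs >= 3
  records
}
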