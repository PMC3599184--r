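# Cross-sectional logical-error rules, service-use indicators, longitudinal
# reversal/autopopulation flags and sign-off lag categorization.

# Three-valued OR: TRUE dominates NA.
or_na <- function(...) {
  args <- list(...)
  out <- Reduce(function(a, b) a | b, args)
  any_true <- Reduce(function(a, b) (!is.na(a) & a) | (!is.na(b) & b), args)
  out[any_true] <- TRUE
  out
}

#' Mood-persistence inconsistency
#'
#' Flags records where the mood-persistence item reports that mood indicators
#' are present (>= 1) while none of the 16 individual mood indicator items is
#' coded as present. Missing persistence gives a missing flag; a record with
#' persistence coded 0 is consistent regardless of the items.
#'
#' @param records Assessment tibble.
#' @param dict An [rai_dictionary()].
#' @return Logical vector.
#' @export
check_mood_persistence <- function(records, dict = rai_dictionary()) {
  pers <- records$mood_persistence
  m <- as.matrix(records[, dict$blocks$MOOD])
  all_zero <- rowSums(m != 0) == 0 # NA if any item NA and rest zero
  all_zero[rowSums(m != 0, na.rm = TRUE) > 0] <- FALSE
  ifelse(is.na(pers), NA, pers >= 1 & all_zero)
}

#' ADL "did not occur" inconsistency
#'
#' Flags records where, for any of the 10 paired ADL items, exactly one of
#' the self-performance and support ratings is coded 8 ("activity did not
#' occur"). Both-8 is consistent.
#'
#' @inheritParams check_mood_persistence
#' @return Logical vector.
#' @export
check_adl_did_not_occur <- function(records, dict = rai_dictionary()) {
  perf <- as.matrix(records[, dict$blocks$ADL_PERF])
  supp <- as.matrix(records[, dict$blocks$ADL_SUPP])
  mism <- (perf == 8) != (supp == 8)
  or_na_rows(mism)
}

# rowwise or_na over a logical matrix
or_na_rows <- function(m) {
  any_true <- rowSums(m, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(m)) > 0
  ifelse(any_true, TRUE, ifelse(any_na, NA, FALSE))
}

#' Parenteral/enteral intake inconsistency
#'
#' Bidirectional mismatch between the feeding-route items and the reported
#' intake from those routes: a parenteral/IV or feeding-tube route with both
#' the calories-proportion and fluid-intake codes at zero, or reported
#' intake with neither route present.
#'
#' @inheritParams check_mood_persistence
#' @return Logical vector.
#' @export
check_nutrition <- function(records, dict = rai_dictionary()) {
  route <- or_na(records$parenteral_iv == 1, records$feeding_tube == 1)
  cal <- records$calories_proportion_code
  flu <- records$fluid_intake_code
  (route & cal == 0 & flu == 0) | (!route & or_na(cal > 0, flu > 0))
}

#' Ulcer staging inconsistency
#'
#' A highest-stage value of 1 or more for pressure/stasis ulcers with the
#' count of ulcers at that stage missing or zero.
#'
#' @inheritParams check_mood_persistence
#' @return Logical vector.
#' @export
check_ulcer <- function(records, dict = rai_dictionary()) {
  stage <- records$ulcer_highest_stage
  count <- records$ulcer_count_at_stage
  stage >= 1 & (is.na(count) | count == 0)
}

#' Therapy-coding inconsistencies
#'
#' Per-discipline (speech, occupational, physical therapy) checks on the
#' weekly days and minutes items, flagged at the record level when any
#' discipline triggers:
#' * `therapy_day15_err`: days counted without at least 15 minutes per
#'   counted day (days >= 1 and minutes < 15 x days);
#' * `therapy_nodays_err`: no days coded although minutes suffice for at
#'   least one day (days = 0 and minutes >= 15);
#' * `therapy_exceed_err`: weekly minutes exceed the minutes in the coded
#'   days (minutes > 1440 x max(days, 1)).
#'
#' @inheritParams check_mood_persistence
#' @return A tibble with the three flags plus `any_therapy_err`.
#' @export
check_therapy <- function(records, dict = rai_dictionary()) {
  one <- function(days, mins) {
    list(day15 = days >= 1 & mins < 15 * days,
         nodays = days == 0 & mins >= 15,
         exceed = mins > 1440 * pmax(days, 1))
  }
  s <- one(records$speech_days, records$speech_minutes)
  o <- one(records$ot_days, records$ot_minutes)
  p <- one(records$pt_days, records$pt_minutes)
  out <- tibble::tibble(
    therapy_day15_err = or_na(s$day15, o$day15, p$day15),
    therapy_nodays_err = or_na(s$nodays, o$nodays, p$nodays),
    therapy_exceed_err = or_na(s$exceed, o$exceed, p$exceed))
  out$any_therapy_err <- or_na(out$therapy_day15_err, out$therapy_nodays_err,
                               out$therapy_exceed_err)
  out
}

# Completed years between two dates (birthday-adjusted).
completed_years <- function(birth, ref) {
  by <- as.integer(format(birth, "%Y")); ry <- as.integer(format(ref, "%Y"))
  bm <- as.integer(format(birth, "%m")); rm_ <- as.integer(format(ref, "%m"))
  bd <- as.integer(format(birth, "%d")); rd <- as.integer(format(ref, "%d"))
  ry - by - as.integer(rm_ < bm | (rm_ == bm & rd < bd))
}

#' Height, weight and age plausibility errors
#'
#' `height_err`: height non-missing and outside 120-211 cm; `weight_err`:
#' weight non-missing and outside 20-200 kg; `age_err`: completed age at the
#' assessment reference date under 16 or over 115 years. Missing height or
#' weight is not an error (tracked by completeness, not plausibility);
#' missing birthdate gives a missing age flag.
#'
#' @inheritParams check_mood_persistence
#' @return A tibble with `height_err`, `weight_err`, `age_err`.
#' @export
check_vitals <- function(records, dict = rai_dictionary()) {
  h <- records$height_cm
  w <- records$weight_kg
  age <- completed_years(records$birthdate, records$reference_date)
  tibble::tibble(
    height_err = !is.na(h) & (h < 120 | h > 211),
    weight_err = !is.na(w) & (w < 20 | w > 200),
    age_err = age < 16 | age > 115)
}

#' Any logical coding problem
#'
#' Record-level OR of the mood-persistence, ADL did-not-occur, nutrition,
#' ulcer and (any) therapy flags.
#'
#' @param flags A tibble containing `mood_persistence_err`, `adl_dnoc_err`,
#'   `nutrition_err`, `ulcer_err`, `any_therapy_err`.
#' @return Logical vector.
#' @export
any_logical_problem <- function(flags) {
  or_na(flags$mood_persistence_err, flags$adl_dnoc_err, flags$nutrition_err,
        flags$ulcer_err, flags$any_therapy_err)
}

#' Sign-off lag and category
#'
#' Calendar days between the assessment reference date and the sign-off
#' date, categorized as `neg` (< 0, a date coding error), `d0_6`, `d7_30`,
#' `gt30`. Missing either date gives missing lag and category.
#'
#' @param records Assessment tibble.
#' @return A tibble with `signoff_lag_days` (integer) and `signoff_category`
#'   (factor).
#' @export
signoff_lag <- function(records) {
  days <- as.integer(records$signoff_date - records$reference_date)
  cat <- cut(days, breaks = c(-Inf, -1, 6, 30, Inf),
             labels = c("neg", "d0_6", "d7_30", "gt30"))
  tibble::tibble(signoff_lag_days = days, signoff_category = cat)
}

#' Cross-sectional audit of assessment records
#'
#' Runs every record-level rule and returns the quality-flag table: one row
#' per assessment with identifiers, all logical-error flags, the combined
#' `any_logical_err`, the vitals flags, and the sign-off lag columns.
#'
#' @inheritParams check_mood_persistence
#' @return A tibble (the per-record quality-flag table).
#' @export
audit_records <- function(records, dict = rai_dictionary()) {
  out <- records[, intersect(c("person_id", "facility_id", "sector",
                               "assessment_type", "reference_date",
                               "quarter", "quarter_index"), names(records))]
  out$mood_persistence_err <- check_mood_persistence(records, dict)
  out$adl_dnoc_err <- check_adl_did_not_occur(records, dict)
  out$nutrition_err <- check_nutrition(records, dict)
  out$ulcer_err <- check_ulcer(records, dict)
  out <- dplyr::bind_cols(out, check_therapy(records, dict))
  out$any_logical_err <- any_logical_problem(out)
  out <- dplyr::bind_cols(out, check_vitals(records, dict))
  out <- dplyr::bind_cols(out, signoff_lag(records))
  out
}

#' Service-use indicators
#'
#' The per-record service-utilization measures tracked quarterly: total
#' weekly therapy minutes across speech/OT/PT; receipt of two or more
#' nursing-rehabilitation procedures on 6+ days per week; receipt of any
#' occupational / any physical therapy; and the combined rehabilitation
#' intensity thresholds (3+ distinct therapy days with 45+ weekly minutes;
#' 5+ days with 150+ minutes). The nested thresholds imply
#' `rehab_5d150m` only when `rehab_3d45m`.
#'
#' @inheritParams check_mood_persistence
#' @return A tibble of indicator columns plus identifiers.
#' @export
service_indicators <- function(records, dict = rai_dictionary()) {
  nrehab <- as.matrix(records[, grep("^nrehab_", names(records), value = TRUE)])
  total <- records$speech_minutes + records$ot_minutes + records$pt_minutes
  out <- records[, intersect(c("person_id", "sector", "reference_date",
                               "quarter", "quarter_index"), names(records))]
  out$total_therapy_minutes <- total
  out$nursing_rehab_2plus <- rowSums(nrehab >= 6, na.rm = TRUE) >= 2
  out$any_ot <- or_na(records$ot_minutes > 0, records$ot_days > 0)
  out$any_pt <- or_na(records$pt_minutes > 0, records$pt_days > 0)
  out$rehab_3d45m <- records$distinct_therapy_days >= 3 & total >= 45
  out$rehab_5d150m <- records$distinct_therapy_days >= 5 & total >= 150
  out
}

#' Longitudinal diagnosis reversal
#'
#' For an uncurable diagnosis (multiple sclerosis, quadriplegia, cerebral
#' palsy, schizophrenia), flags pairs where the condition was recorded
#' present at T1 but absent at T2. Pairs without the diagnosis at T1 are not
#' eligible (NA, excluded from rate denominators).
#'
#' @param pairs Pair tibble from [make_pairs()].
#' @param dx_code Diagnosis item code, e.g. `"dx_multiple_sclerosis"`.
#' @return Logical vector (NA when not eligible).
#' @export
diagnosis_reversal <- function(pairs, dx_code) {
  t1 <- pairs[[paste0(dx_code, "_t1")]]
  t2 <- pairs[[paste0(dx_code, "_t2")]]
  ifelse(is.na(t1) | t1 != 1, NA, t2 == 0)
}

#' Autopopulation (carry-forward) flags for a pair
#'
#' For each screened block - all clinical quarterly variables, the 16 mood
#' items, the 20 ADL performance and support items - the flag is true when
#' every item in the block has an identical value at T1 and T2, with
#' missing-equals-missing counting as identical (a carry-forward copies
#' missingness too). Pairs whose two reference dates fall in the same
#' calendar quarter are not evaluated (NA): the screen compares values from
#' a previous quarter.
#'
#' @inheritParams diagnosis_reversal
#' @param dict An [rai_dictionary()].
#' @return A tibble with `auto_all_clinical`, `auto_mood16`, `auto_adl20`.
#' @export
autopopulation_flags <- function(pairs, dict = rai_dictionary()) {
  same_quarter <- quarter_label(pairs$reference_date_t1) ==
    quarter_label(pairs$reference_date_t2)
  block_same <- function(codes) {
    a <- as.matrix(pairs[, paste0(codes, "_t1")])
    b <- as.matrix(pairs[, paste0(codes, "_t2")])
    same <- (a == b) | (is.na(a) & is.na(b))
    same[is.na(same)] <- FALSE # one missing, one coded: a change
    ifelse(same_quarter, NA, rowSums(same) == ncol(same))
  }
  tibble::tibble(
    auto_all_clinical = block_same(dict$blocks$CLINICAL),
    auto_mood16 = block_same(dict$blocks$MOOD),
    auto_adl20 = block_same(c(dict$blocks$ADL_PERF, dict$blocks$ADL_SUPP)))
}

#' Longitudinal audit of assessment pairs
#'
#' Reversal flags for the four uncurable diagnoses plus the three
#' autopopulation flags, keyed by person, sector and the T2 reference date
#' (reversal and carry-forward rates are reported per T2 quarter).
#'
#' @inheritParams autopopulation_flags
#' @return A tibble (the per-pair quality-flag table).
#' @export
audit_pairs <- function(pairs, dict = rai_dictionary()) {
  out <- tibble::tibble(
    person_id = pairs$person_id,
    sector = pairs$sector,
    reference_date_t1 = pairs$reference_date_t1,
    reference_date_t2 = pairs$reference_date_t2,
    reversal_ms = diagnosis_reversal(pairs, "dx_multiple_sclerosis"),
    reversal_quad = diagnosis_reversal(pairs, "dx_quadriplegia"),
    reversal_cp = diagnosis_reversal(pairs, "dx_cerebral_palsy"),
    reversal_schiz = diagnosis_reversal(pairs, "dx_schizophrenia"))
  dplyr::bind_cols(out, autopopulation_flags(pairs, dict))
}
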