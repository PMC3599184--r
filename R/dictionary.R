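#' Item dictionary for RAI 2.0 style assessment records
#'
#' Builds the default item dictionary used throughout the pipeline: every
#' coded item with its value domain, plus named blocks of codes (the 16 mood
#' indicators, the 10 paired ADL self-performance/support items, the full
#' clinical block used by the whole-record autopopulation check, diagnoses,
#' therapy, nutrition, ulcer and vitals items).
#'
#' The clinical block defaults to 231 codes, the number of clinical quarterly
#' variables screened for identical values at reassessment. The named items
#' defined by the scales and audit rules cover 74 of these; the remainder are
#' generic coded clinical items (`clin_###`, values 0-3) so that whole-record
#' comparisons operate at full width.
#'
#' @param n_clinical Size of the clinical block (default 231). Must be at
#'   least the number of named clinical items.
#' @return An object of class `rai_dictionary`: a list with `items` (a tibble
#'   with columns `code`, `type`, `min`, `max`, `extra` - an additional
#'   allowed code such as 8 "did not occur" - and `block` membership is in
#'   `blocks`), and `blocks`, a named list of character vectors.
#' @export
#' @examples
#' d <- rai_dictionary()
#' length(d$blocks$MOOD) # 16
rai_dictionary <- function(n_clinical = 231) {
  int_item <- function(code, min, max, extra = NA_integer_) {
    tibble::tibble(code = code, type = "int", min = as.numeric(min),
                   max = as.numeric(max), extra = as.numeric(extra))
  }
  num_item <- function(code, min, max) {
    tibble::tibble(code = code, type = "num", min = min, max = max,
                   extra = NA_real_)
  }

  mood <- paste0("mood_", c(
    "negative_statements", "repetitive_questions", "repetitive_verbalizations",
    "persistent_anger", "self_deprecation", "unrealistic_fears",
    "health_complaints", "anxious_complaints", "sad_expression", "crying",
    "repetitive_movements", "withdrawal", "reduced_interaction", "insomnia",
    "appetite_change", "weight_change"))
  adl_base <- c("bed_mobility", "transfer", "walk_in_room", "walk_in_corridor",
                "locomotion_on_unit", "locomotion_off_unit", "dressing",
                "eating", "toilet_use", "personal_hygiene")
  adl_perf <- paste0("adl_", adl_base, "_perf")
  adl_supp <- paste0("adl_", adl_base, "_supp")
  behav <- c("verbally_abusive", "physically_abusive", "socially_inappropriate",
             "resists_care")
  therapy <- c("speech_days", "ot_days", "pt_days",
               "speech_minutes", "ot_minutes", "pt_minutes",
               "distinct_therapy_days")
  nrehab <- paste0("nrehab_", c(
    "rom_passive", "rom_active", "splint_brace", "bed_mobility", "walking",
    "dressing_grooming", "eating_swallowing", "communication"))
  dx <- paste0("dx_", c("multiple_sclerosis", "quadriplegia", "cerebral_palsy",
                        "schizophrenia", "diabetes", "dementia"))
  nutrition <- c("parenteral_iv", "feeding_tube", "calories_proportion_code",
                 "fluid_intake_code")
  ulcer <- c("ulcer_highest_stage", "ulcer_count_at_stage")

  named_clinical <- c("memory_problem", "decision_making",
                      "making_self_understood", mood, "mood_persistence",
                      adl_perf, adl_supp, behav, "pain_frequency",
                      "pain_intensity", "bowel_continence", nutrition, ulcer,
                      therapy, nrehab, dx)
  n_fill <- n_clinical - length(named_clinical)
  if (n_fill < 0) {
    rlang::abort(sprintf("n_clinical must be >= %d (the named clinical items)",
                         length(named_clinical)))
  }
  fillers <- if (n_fill > 0) sprintf("clin_%03d", seq_len(n_fill)) else character()

  items <- dplyr::bind_rows(
    int_item("comatose", 0, 1),
    int_item("memory_problem", 0, 1),
    int_item("decision_making", 0, 3),
    int_item("making_self_understood", 0, 4),
    int_item(mood, 0, 2),
    int_item("mood_persistence", 0, 2),
    int_item(adl_perf, 0, 4, extra = 8),
    int_item(adl_supp, 0, 3, extra = 8),
    int_item(behav, 0, 3),
    int_item("pain_frequency", 0, 2),
    int_item("pain_intensity", 0, 3),
    int_item("bowel_continence", 0, 4),
    int_item("parenteral_iv", 0, 1),
    int_item("feeding_tube", 0, 1),
    int_item("calories_proportion_code", 0, 4),
    int_item("fluid_intake_code", 0, 5),
    int_item("ulcer_highest_stage", 0, 4),
    int_item("ulcer_count_at_stage", 0, 9),
    int_item(c("speech_days", "ot_days", "pt_days"), 0, 7),
    int_item(c("speech_minutes", "ot_minutes", "pt_minutes"), 0, 10080),
    int_item("distinct_therapy_days", 0, 7),
    int_item(nrehab, 0, 7),
    int_item(dx, 0, 1),
    int_item(fillers, 0, 3),
    num_item("height_cm", 30, 272),
    num_item("weight_kg", 1, 450)
  )

  blocks <- list(
    MOOD = mood,
    ADL_PERF = adl_perf,
    ADL_SUPP = adl_supp,
    CLINICAL = c(named_clinical, fillers),
    DIAGNOSES = dx,
    THERAPY = therapy,
    NUTRITION = nutrition,
    ULCER = ulcer,
    VITALS = c("height_cm", "weight_kg", "birthdate"),
    BEHAVIOUR = behav
  )

  dict <- structure(list(items = items, blocks = blocks),
                    class = "rai_dictionary")
  validate_dictionary(dict)
  dict
}

#' Validate an item dictionary
#'
#' Checks the structural invariants: each code declared exactly once, block
#' membership a subset of declared codes (plus the `birthdate` date column),
#' 16 mood items, 10 + 10 paired ADL items.
#'
#' @param dict An `rai_dictionary`.
#' @return `dict`, invisibly; aborts on violation.
#' @export
validate_dictionary <- function(dict) {
  stopifnot(inherits(dict, "rai_dictionary"))
  codes <- dict$items$code
  if (anyDuplicated(codes)) {
    rlang::abort(paste0("duplicate item codes: ",
                        paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  }
  declared <- c(codes, "birthdate")
  for (b in names(dict$blocks)) {
    extra <- setdiff(dict$blocks[[b]], declared)
    if (length(extra)) {
      rlang::abort(sprintf("block %s references undeclared codes: %s", b,
                           paste(extra, collapse = ", ")))
    }
  }
  stopifnot(length(dict$blocks$MOOD) == 16,
            length(dict$blocks$ADL_PERF) == 10,
            length(dict$blocks$ADL_SUPP) == 10)
  invisible(dict)
}

#' @export
print.rai_dictionary <- function(x, ...) {
  cat(sprintf("<rai_dictionary> %d items, blocks: %s\n", nrow(x$items),
              paste(sprintf("%s[%d]", names(x$blocks),
                            lengths(x$blocks)), collapse = " ")))
  invisible(x)
}

#' Write / read an item dictionary as YAML
#'
#' The on-disk companion format declares every item's value domain and the
#' named blocks, so a site-specific dictionary can be swapped in without code
#' change.
#'
#' @param dict An `rai_dictionary`.
#' @param path File path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns an `rai_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  validate_dictionary(dict)
  out <- list(
    items = purrr::pmap(dict$items, function(code, type, min, max, extra) {
      it <- list(code = code, type = type, min = min, max = max)
      if (!is.na(extra)) it$extra <- extra
      it
    }),
    blocks = dict$blocks
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- purrr::map_dfr(raw$items, function(it) {
    tibble::tibble(code = it$code, type = it$type, min = as.numeric(it$min),
                   max = as.numeric(it$max),
                   extra = as.numeric(it$extra %||% NA_real_))
  })
  dict <- structure(list(items = items,
                         blocks = purrr::map(raw$blocks, as.character)),
                    class = "rai_dictionary")
  validate_dictionary(dict)
  dict
}

# Identity/date columns preceding the item columns in the record CSV.
identity_cols <- function() {
  c("person_id", "facility_id", "sector", "assessment_type",
    "reference_date", "signoff_date", "birthdate")
}

# Is each value of x in the domain of item `code`? NA counts as in-domain
# (missing token).
in_domain <- function(x, row) {
  ok <- is.na(x) | (x >= row$min & x <= row$max)
  if (!is.na(row$extra)) ok <- ok | (!is.na(x) & x == row$extra)
  if (row$type == "int") ok <- ok & (is.na(x) | x == floor(x))
  ok
}
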