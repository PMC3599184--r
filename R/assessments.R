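#' Read assessment records from CSV
#'
#' Reads a record file in the pipeline's tabular format: the identity and
#' date columns (`person_id`, `facility_id`, `sector`, `assessment_type`,
#' `reference_date`, `signoff_date`, `birthdate`), then one column per item
#' code from the dictionary. Empty cells are the missing token. Values
#' outside an item's declared domain are fatal, naming the offending cell.
#'
#' @param path CSV file path.
#' @param dict An [rai_dictionary()].
#' @return A tibble with one row per assessment.
#' @export
read_assessments <- function(path, dict = rai_dictionary()) {
  validate_dictionary(dict)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  expected <- c(identity_cols(), dict$items$code)
  missing_cols <- setdiff(expected, hdr)
  extra_cols <- setdiff(hdr, expected)
  if (length(missing_cols) || length(extra_cols)) {
    rlang::abort(paste0(
      "header does not match dictionary;",
      if (length(missing_cols)) paste0(" missing: ",
        paste(utils::head(missing_cols, 5), collapse = ", ")) else "",
      if (length(extra_cols)) paste0(" unexpected: ",
        paste(utils::head(extra_cols, 5), collapse = ", ")) else ""))
  }
  spec <- c(
    stats::setNames(rep(list(readr::col_character()), 4),
                    c("person_id", "facility_id", "sector", "assessment_type")),
    stats::setNames(rep(list(readr::col_date(format = "%Y-%m-%d")), 3),
                    c("reference_date", "signoff_date", "birthdate")),
    stats::setNames(rep(list(readr::col_double()), nrow(dict$items)),
                    dict$items$code)
  )
  rec <- readr::read_csv(path, col_types = do.call(readr::cols, spec),
                         na = "", progress = FALSE)
  rec <- rec[, expected]
  validate_assessments(rec, dict)
  rec
}

#' Write assessment records to CSV
#'
#' Inverse of [read_assessments()]: ISO-8601 dates, empty string as the
#' missing token. `write_assessments` then `read_assessments` round-trips.
#'
#' @param records Assessment tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(records, path) {
  # derived columns are recomputable; the record CSV stays canonical
  records <- records[, setdiff(names(records), c("quarter", "quarter_index"))]
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Validate assessment records against a dictionary
#'
#' Checks column presence, sector and assessment-type codes, valid reference
#' dates, and that every item value is in its declared domain. The first
#' violation aborts with the row number and column name.
#'
#' @inheritParams read_assessments
#' @param records Assessment tibble.
#' @return `records`, invisibly.
#' @export
validate_assessments <- function(records, dict = rai_dictionary()) {
  if (any(is.na(records$reference_date))) {
    rlang::abort(sprintf("missing reference_date at row %d",
                         which(is.na(records$reference_date))[1]))
  }
  bad_sector <- !records$sector %in% c("CCC", "LTC")
  if (any(bad_sector)) {
    rlang::abort(sprintf("invalid sector at row %d", which(bad_sector)[1]))
  }
  bad_type <- !records$assessment_type %in% c("admission", "quarterly", "annual")
  if (any(bad_type)) {
    rlang::abort(sprintf("invalid assessment_type at row %d", which(bad_type)[1]))
  }
  for (i in seq_len(nrow(dict$items))) {
    row <- dict$items[i, ]
    if (!row$code %in% names(records)) {
      rlang::abort(sprintf("missing item column: %s", row$code))
    }
    ok <- in_domain(records[[row$code]], row)
    if (!all(ok)) {
      rlang::abort(sprintf(
        "out-of-domain value %s in column %s, row %d",
        format(records[[row$code]][which(!ok)[1]]), row$code, which(!ok)[1]))
    }
  }
  invisible(records)
}

#' Exclude comatose assessments
#'
#' Assessments with `comatose == 1` are removed before any indicator or
#' scale computation; scoring and audit rules therefore never see them.
#' Missing `comatose` retains the record. Idempotent.
#'
#' @param records Assessment tibble.
#' @return Filtered tibble.
#' @export
exclude_comatose <- function(records) {
  dplyr::filter(records, is.na(.data$comatose) | .data$comatose != 1)
}

#' Calendar quarter label of a date
#'
#' @param date A Date vector.
#' @return Character `"YYYY_Q"` labels (calendar quarters, Jan-Mar = Q1).
#' @export
quarter_label <- function(date) {
  sprintf("%d_%d", as.integer(format(date, "%Y")),
          (as.integer(format(date, "%m")) - 1) %/% 3 + 1)
}

# year*4 + (quarter-1): integer quarter ordinal for index arithmetic
quarter_ordinal <- function(date) {
  as.integer(format(date, "%Y")) * 4L +
    (as.integer(format(date, "%m")) - 1L) %/% 3L
}

#' Assign calendar quarters and per-sector quarter indices
#'
#' Adds `quarter` (the `"YYYY_Q"` label of the reference date) and
#' `quarter_index`, counting calendar quarters since the sector's first
#' observed (or supplied origin) quarter, 0 at the origin. The index is the
#' x-axis of all trend fits and is stable under record reordering.
#'
#' @param records Assessment tibble.
#' @param sector_origin Optional named vector/list mapping sector to its
#'   origin date; defaults to each sector's earliest reference date.
#' @return `records` with `quarter` and `quarter_index` columns.
#' @export
assign_quarters <- function(records, sector_origin = NULL) {
  ords <- quarter_ordinal(records$reference_date)
  origin <- tapply(ords, records$sector, min)
  if (!is.null(sector_origin)) {
    for (s in names(sector_origin)) {
      origin[[s]] <- quarter_ordinal(as.Date(sector_origin[[s]]))
    }
  }
  records$quarter <- quarter_label(records$reference_date)
  records$quarter_index <- as.integer(ords - as.vector(origin[records$sector]))
  records
}

#' Build consecutive within-person assessment pairs
#'
#' Orders each person's assessments within a sector by reference date and
#' emits every chronologically consecutive (T1, T2) pair once, as a wide
#' tibble with all record columns suffixed `_t1` / `_t2`. Persons with a
#' single assessment yield no pair. Duplicate (person, sector,
#' reference_date) combinations are fatal.
#'
#' @param records Assessment tibble.
#' @return A tibble of pairs.
#' @export
make_pairs <- function(records) {
  key <- paste(records$person_id, records$sector, records$reference_date)
  if (anyDuplicated(key)) {
    rlang::abort(sprintf("duplicate (person, sector, reference_date): %s",
                         key[duplicated(key)][1]))
  }
  ord <- order(records$person_id, records$sector, records$reference_date)
  rec <- records[ord, ]
  grp <- paste(rec$person_id, rec$sector)
  same_next <- grp[-length(grp)] == grp[-1]
  i1 <- which(c(same_next, FALSE))
  t1 <- rec[i1, ]
  t2 <- rec[i1 + 1L, ]
  names(t1) <- paste0(names(t1), "_t1")
  names(t2) <- paste0(names(t2), "_t2")
  out <- dplyr::bind_cols(
    tibble::tibble(person_id = rec$person_id[i1], sector = rec$sector[i1]),
    t1, t2)
  out$person_id_t1 <- out$person_id_t2 <- out$sector_t1 <- out$sector_t2 <- NULL
  out
}
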