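#' Quarterly indicator tables for a cohort
#'
#' Runs the full audit on a record set and assembles the quarterly
#' stratified series behind each published-style table: population
#' characteristics (admission share and the four scale prevalence flags),
#' service use, convergent validity, scale reliability, cross-sectional
#' logical errors (clinical, therapy, vitals), longitudinal diagnosis
#' reversals and autopopulation (per T2 quarter), and annual sign-off lag
#' category shares. Comatose assessments are excluded first.
#'
#' @param records Assessment tibble (raw; will be quarter-assigned and
#'   scored internally if needed).
#' @param dict An [rai_dictionary()].
#' @return A named list of tidy tibbles
#'   (`characteristics`, `service`, `convergent`, `alphas`,
#'   `clinical_errors`, `therapy_errors`, `vitals_errors`, `reversals`,
#'   `autopopulation`, `signoff`), each `sector, indicator, quarter,
#'   quarter_index, value, n` (sign-off by year).
#' @export
quarterly_tables <- function(records, dict = rai_dictionary()) {
  records <- exclude_comatose(records)
  if (!"quarter" %in% names(records)) records <- assign_quarters(records)
  scored <- score_scales(records)
  scored$is_admission <- scored$assessment_type == "admission"
  flags <- audit_records(records, dict)
  flags$quarter <- records$quarter
  flags$quarter_index <- records$quarter_index
  svc <- service_indicators(records, dict)

  series <- function(data, vars) {
    dplyr::bind_rows(lapply(vars, function(v) {
      quarterly_rate(data, !!rlang::sym(v))
    }))
  }

  characteristics <- series(scored, c("is_admission", "cps_ge3",
                                      "rugadl_ge11", "abs_ge5", "drs_ge3"))
  characteristics$indicator[characteristics$indicator == "is_admission"] <-
    "admission_share"
  service <- series(svc, c("total_therapy_minutes", "nursing_rehab_2plus",
                           "any_ot", "any_pt", "rehab_3d45m", "rehab_5d150m"))
  service$indicator[service$indicator == "total_therapy_minutes"] <-
    "mean_therapy_minutes"
  clinical_errors <- series(flags, c("mood_persistence_err", "adl_dnoc_err",
                                     "nutrition_err", "ulcer_err"))
  therapy_errors <- series(flags, c("therapy_day15_err", "therapy_nodays_err",
                                    "therapy_exceed_err", "any_therapy_err",
                                    "any_logical_err"))
  vitals_errors <- series(flags, c("height_err", "weight_err", "age_err"))

  pairs <- make_pairs(records)
  pflags <- audit_pairs(pairs, dict)
  pflags <- assign_quarters(
    dplyr::rename(pflags, reference_date = "reference_date_t2"))
  reversals <- series(pflags, c("reversal_ms", "reversal_quad",
                                "reversal_cp", "reversal_schiz"))
  autopopulation <- series(pflags, c("auto_all_clinical", "auto_mood16",
                                     "auto_adl20"))

  lagtab <- dplyr::bind_cols(
    records[, c("sector", "reference_date")], signoff_lag(records))
  lagtab$year <- format(lagtab$reference_date, "%Y")
  signoff <- lagtab |>
    dplyr::filter(!is.na(.data$signoff_category)) |>
    dplyr::count(.data$sector, .data$year, .data$signoff_category) |>
    dplyr::group_by(.data$sector, .data$year) |>
    dplyr::mutate(value = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::transmute(sector = .data$sector,
                     indicator = paste0("signoff_", .data$signoff_category),
                     quarter = .data$year, quarter_index = NA_integer_,
                     value = .data$value, n = .data$n)

  list(characteristics = characteristics, service = service,
       convergent = convergent_validity_series(scored),
       alphas = alpha_series(records),
       clinical_errors = clinical_errors, therapy_errors = therapy_errors,
       vitals_errors = vitals_errors, reversals = reversals,
       autopopulation = autopopulation, signoff = signoff)
}

#' Write quarterly tables and trend fits to a directory
#'
#' One tidy CSV per table analogue, with an appended trend block (rows with
#' `quarter = "intercept"` / `"slope"`) for tables with at least two
#' quarters per series, plus a `run_log.txt` recording the configuration
#' fingerprint, seed, package version and row counts. Reruns on identical
#' inputs are byte-identical.
#'
#' @param tables A named list from [quarterly_tables()].
#' @param outdir Output directory (created if absent).
#' @param seed Seed to record in the run log (optional).
#' @return Invisibly, the written file paths.
#' @export
emit_report <- function(tables, outdir, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    out <- tab
    trendable <- !is.na(tab$quarter_index)
    if (any(trendable)) {
      counts <- table(paste(tab$sector[trendable], tab$indicator[trendable]))
      ok <- paste(tab$sector, tab$indicator) %in%
        names(counts)[counts >= 2] & trendable
      if (any(ok)) {
        td <- generics::tidy(fit_trend(tab[ok, ]))
        trows <- dplyr::bind_rows(
          dplyr::transmute(td, sector = .data$sector,
                           indicator = .data$indicator,
                           quarter = "intercept", quarter_index = NA_integer_,
                           value = .data$intercept, n = .data$n_quarters),
          dplyr::transmute(td, sector = .data$sector,
                           indicator = .data$indicator,
                           quarter = "slope", quarter_index = NA_integer_,
                           value = .data$slope, n = .data$n_quarters))
        out <- dplyr::bind_rows(out, trows)
      }
    }
    out$value <- round(out$value, 4)
    p <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(out, p, na = "")
    paths <- c(paths, p)
  }
  log <- c(sprintf("raiaudit %s", as.character(utils::packageVersion("raiaudit"))),
           sprintf("seed: %s", if (is.null(seed)) "NA" else seed),
           sprintf("tables: %s", paste(names(tables), collapse = ", ")),
           sprintf("rows: %s", paste(vapply(tables, nrow, 1L), collapse = ", ")))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(c(paths, file.path(outdir, "run_log.txt")))
}

#' Packaged published-series fixtures
#'
#' Loads one of the transcribed published quarterly series shipped with the
#' package (tidy columns `quarter, indicator, sector, value`), with a
#' 0-based `quarter_index` added per sector, ready for [fit_trend()].
#'
#' @param table One of `"table1_characteristics"`,
#'   `"table2_therapy_minutes"`, `"table5_alphas"`,
#'   `"table7_therapy_errors"`, `"table8_vitals_errors"`.
#' @return A tibble.
#' @export
published_series <- function(table = c("table1_characteristics",
                                       "table2_therapy_minutes",
                                       "table5_alphas",
                                       "table7_therapy_errors",
                                       "table8_vitals_errors")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, ".csv"), package = "raiaudit")
  d <- readr::read_csv(path, show_col_types = FALSE)
  d |>
    dplyr::group_by(.data$sector) |>
    dplyr::mutate(quarter_index = match(.data$quarter,
                                        sort(unique(.data$quarter))) - 1L) |>
    dplyr::ungroup()
}
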