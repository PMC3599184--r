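#' Quarterly stratified indicator series
#'
#' Aggregates an indicator per sector per calendar quarter: the proportion
#' (as a percentage by default, matching the reported units) for logical
#' indicators, or the mean for numeric ones. Records with a missing
#' indicator are excluded from that quarter's denominator. Empty quarters
#' are omitted.
#'
#' @param records A tibble carrying `sector`, `quarter`, `quarter_index`
#'   (see [assign_quarters()]) and the indicator column.
#' @param indicator Column name (string or bare name) of a logical or
#'   numeric indicator.
#' @param sector Optional sector filter (`"CCC"` or `"LTC"`).
#' @param percent Report proportions of logical indicators as percentages
#'   (default TRUE).
#' @return A tibble `sector, indicator, quarter, quarter_index, value, n`,
#'   quarters strictly increasing within sector.
#' @export
quarterly_rate <- function(records, indicator, sector = NULL, percent = TRUE) {
  ind <- rlang::as_name(rlang::ensym(indicator))
  if (!is.null(sector)) records <- records[records$sector == sector, ]
  x <- records[[ind]]
  is_prop <- is.logical(x)
  records$.val <- as.numeric(x)
  out <- records |>
    dplyr::filter(!is.na(.data$.val)) |>
    dplyr::group_by(.data$sector, .data$quarter, .data$quarter_index) |>
    dplyr::summarise(value = mean(.data$.val), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$sector, .data$quarter_index)
  if (is_prop && percent) out$value <- 100 * out$value
  tibble::tibble(sector = out$sector, indicator = ind, quarter = out$quarter,
                 quarter_index = out$quarter_index, value = out$value,
                 n = out$n)
}

#' Ordinary least-squares trend fit for quarterly series
#'
#' Fits an unweighted linear regression of the indicator value on the
#' quarter number within each (sector, indicator) series. The regressor is
#' the 1-based quarter number (`quarter_index + 1`), so the reported
#' intercept is anchored one quarter before the sector's first observed
#' quarter - the anchoring that reproduces the published intercept/slope
#' summary rows for these series. Series with fewer than two quarters are an
#' error.
#'
#' @param series A quarterly series tibble (from [quarterly_rate()] or of
#'   the same shape: `sector`, `indicator`, `quarter_index`, `value`).
#' @return A `trend_fit` object; see [tidy.trend_fit()] and
#'   [glance.trend_fit()].
#' @export
fit_trend <- function(series) {
  if (!"indicator" %in% names(series)) series$indicator <- "value"
  groups <- split(series, paste(series$sector, series$indicator, sep = "|"))
  fits <- purrr::map(groups, function(g) {
    if (nrow(g) < 2) {
      rlang::abort("fit_trend needs at least 2 quarters per series")
    }
    g$quarter_number <- g$quarter_index + 1
    stats::lm(value ~ quarter_number, data = g)
  })
  structure(list(fits = fits, series = series), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy a trend fit
#'
#' One row per fitted series with the intercept (value one quarter before
#' the sector's first observed quarter), the per-quarter slope, and the
#' number of quarters.
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A tibble `sector, indicator, intercept, slope, n_quarters`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    co <- stats::coef(fit)
    tibble::tibble(sector = parts[1], indicator = parts[2],
                   intercept = unname(co[1]), slope = unname(co[2]),
                   n_quarters = stats::nobs(fit))
  })
}

#' Glance at a trend fit
#'
#' @inheritParams tidy.trend_fit
#' @return A tibble with per-series `r.squared`, `sigma` and `n_quarters`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    s <- summary(fit)
    tibble::tibble(sector = parts[1], indicator = parts[2],
                   r.squared = s$r.squared, sigma = s$sigma,
                   n_quarters = stats::nobs(fit))
  })
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of scale items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of total)`, with
#' sample variances (denominator n-1) after listwise deletion of incomplete
#' rows. Needs at least 2 items and 3 complete rows; zero total variance
#' gives NA.
#'
#' @param data A data frame of item columns (or a wider frame with `items`
#'   selecting the columns).
#' @param items Optional character vector of item column names.
#' @return The alpha coefficient (double), or NA when undefined.
#' @export
cronbach_alpha <- function(data, items = NULL) {
  m <- as.matrix(if (is.null(items)) data else data[, items])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) return(NA_real_)
  vt <- stats::var(rowSums(m))
  if (!is.finite(vt) || vt == 0) return(NA_real_)
  (k / (k - 1)) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Bivariate association statistics
#'
#' Pearson or Spearman correlation for paired numeric vectors, or Cramer's V
#' for two categorical vectors: `V = sqrt(chi2 / (n * (min(r, c) - 1)))`
#' from the uncorrected chi-square statistic, without bias correction.
#' Incomplete pairs are dropped; degenerate (constant, or single-level)
#' input gives NA.
#'
#' @param xs,ys Paired observations.
#' @param kind `"pearson"`, `"spearman"` or `"cramers_v"`.
#' @return The statistic (double), or NA when undefined.
#' @export
association <- function(xs, ys, kind = c("pearson", "spearman", "cramers_v")) {
  kind <- match.arg(kind)
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 2) return(NA_real_)
  if (kind %in% c("pearson", "spearman")) {
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    return(stats::cor(xs, ys, method = kind))
  }
  tab <- table(xs, ys)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Quarterly convergent-validity series
#'
#' Per sector and quarter: Cramer's V of bowel continence against moderate+
#' cognitive impairment (CPS 3+), and Pearson correlations of the ADL Long
#' Form, Pain and Aggressive Behaviour scales with the CPS. Requires scored
#' records (see [score_scales()]) with quarter columns.
#'
#' @param records Scored assessment tibble with quarter columns.
#' @param sector Optional sector filter.
#' @return A long tibble `sector, indicator, quarter, quarter_index, value, n`.
#' @export
convergent_validity_series <- function(records, sector = NULL) {
  if (!is.null(sector)) records <- records[records$sector == sector, ]
  records |>
    dplyr::group_by(.data$sector, .data$quarter, .data$quarter_index) |>
    dplyr::reframe(
      indicator = c("bowel_cps_v", "adl_cps_r", "pain_cps_r", "abs_cps_r"),
      value = c(
        association(.data$bowel_continence, .data$cps_ge3, "cramers_v"),
        association(.data$adl_long_form, .data$cps, "pearson"),
        association(.data$pain, .data$cps, "pearson"),
        association(.data$abs, .data$cps, "pearson")),
      n = dplyr::n()) |>
    dplyr::arrange(.data$sector, .data$indicator, .data$quarter_index) |>
    dplyr::select("sector", "indicator", "quarter", "quarter_index",
                  "value", "n")
}

#' Quarterly internal-consistency (alpha) series
#'
#' Cronbach's alpha per sector and quarter for the three parallel-form
#' scales: ADL Long Form (7 items), Depression Rating Scale (7 items) and
#' Aggressive Behaviour Scale (4 items).
#'
#' @inheritParams convergent_validity_series
#' @return A long tibble `sector, indicator, quarter, quarter_index, value, n`.
#' @export
alpha_series <- function(records, sector = NULL) {
  if (!is.null(sector)) records <- records[records$sector == sector, ]
  defs <- scale_definitions()
  records |>
    dplyr::group_by(.data$sector, .data$quarter, .data$quarter_index) |>
    dplyr::group_modify(function(g, key) {
      tibble::tibble(
        indicator = c("alpha_adl_long_form", "alpha_drs", "alpha_abs"),
        value = c(cronbach_alpha(g, defs$adl_long_form$items),
                  cronbach_alpha(g, defs$drs$items),
                  cronbach_alpha(g, defs$abs$items)),
        n = nrow(g))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sector, .data$indicator, .data$quarter_index) |>
    dplyr::select("sector", "indicator", "quarter", "quarter_index",
                  "value", "n")
}

#' Named statistic list for cross-setting comparison
#'
#' The battery of association statistics compared between care settings:
#' Cronbach's alpha for the three parallel-form scales, Pearson correlations
#' among the 6 scale scores (15 pairs), and Spearman rank correlations among
#' 19 individual clinical items (171 pairs) - 189 statistics in all.
#'
#' @param records Scored assessment tibble (one sector's records).
#' @return A named numeric vector of statistics.
#' @export
statistic_list <- function(records) {
  defs <- scale_definitions()
  out <- c(
    alpha_adl = cronbach_alpha(records, defs$adl_long_form$items),
    alpha_drs = cronbach_alpha(records, defs$drs$items),
    alpha_abs = cronbach_alpha(records, defs$abs$items))
  scales <- c("cps", "adl_long_form", "rug_adl", "drs", "abs", "pain")
  for (i in seq_along(scales)) {
    for (j in seq_along(scales)) {
      if (i < j) {
        out[paste0("r_", scales[i], "_", scales[j])] <-
          association(records[[scales[i]]], records[[scales[j]]], "pearson")
      }
    }
  }
  items <- c(defs$drs$items, defs$abs$items, "bowel_continence",
             "pain_frequency", "pain_intensity", "memory_problem",
             "decision_making", "making_self_understood",
             "adl_bed_mobility_perf", "adl_eating_perf")
  for (i in seq_along(items)) {
    for (j in seq_along(items)) {
      if (i < j) {
        out[paste0("rho_", items[i], "_", items[j])] <-
          association(records[[items[i]]], records[[items[j]]], "spearman")
      }
    }
  }
  out
}

#' Cross-setting concordance of association statistics
#'
#' The squared correlation (R-squared of the least-squares line) between two
#' named lists of statistics computed in two care settings. Statistics are
#' matched by name; fewer than 3 shared names is an error. Identical lists
#' give exactly 1.
#'
#' @param stats_a,stats_b Named numeric vectors (e.g. from
#'   [statistic_list()]).
#' @return R-squared (double in `[0, 1]`).
#' @export
cross_setting_concordance <- function(stats_a, stats_b) {
  shared <- intersect(names(stats_a), names(stats_b))
  a <- stats_a[shared]; b <- stats_b[shared]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) {
    rlang::abort("cross_setting_concordance needs at least 3 shared statistics")
  }
  stats::cor(a, b)^2
}
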