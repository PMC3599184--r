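# Synthetic two-sector cohort generator with labelled error injection.
#
# Persons carry a 6-dimensional latent trait vector (cognition, function,
# mood, aggression, pain, continence) drawn from a multivariate normal with
# a configurable correlation matrix plus sector severity offsets; traits
# drift across reassessments as a stationary AR(1). Items are generated by
# thresholding loading * trait + noise at normal quantiles of configured
# category probabilities, so both target prevalences and target
# internal-consistency values can be hit by calibrating offsets and
# loadings. Clean generation never triggers a logical-error rule; every
# error type is injected explicitly and labelled in a truth table.

trait_names <- function() {
  c("cognition", "function", "mood", "aggression", "pain", "continence")
}

#' Cohort generator configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [generate_cohort()]: study window, per-sector admission volumes and stay
#' distributions, the latent trait correlation matrix and sector offsets,
#' item loadings and category probabilities, therapy/service intensity,
#' diagnosis prevalences, sign-off lag distribution, and the per-rule error
#' injection rates (all zero by default: a clean cohort).
#'
#' @param n_quarters Number of calendar quarters in the window.
#' @param start_date First day of the window (a quarter boundary).
#' @param cadence_days Days between scheduled reassessments.
#' @param trait_correlation 6x6 correlation matrix over the latent traits
#'   (cognition, function, mood, aggression, pain, continence).
#' @param drift_rho AR(1) coefficient of latent drift across reassessments.
#' @param sectors Per-sector list: `admissions_per_quarter`,
#'   `initial_residents` (persons already in residence at the window start,
#'   whose first observed assessment is a reassessment), `n_facilities`,
#'   `mean_assessments` (mean of the geometric stay-length distribution, in
#'   assessments), `trait_offset` (named severity shifts), `therapy`,
#'   `nrehab_p6`, `dx_prevalence`, `signoff_probs` (neg/d0_6/d7_30/gt30).
#' @param loadings Named loadings in (0, 1): `cognition`, `adl`, `mood`,
#'   `abs`, `pain`, `continence`, `clinical`.
#' @param probs Named list of item category probability vectors.
#' @param error_rates Per-rule injection probabilities (see
#'   [inject_errors()]).
#' @param reversal_rates Per-diagnosis probability that a T1-present
#'   diagnosis is cleared at the next assessment.
#' @param autopop_rates Per-block carry-forward probabilities
#'   (`all_clinical`, `mood`, `adl`).
#' @param comatose_rate Per-assessment probability of comatose status.
#' @param seed Default random seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_quarters = 8,
    start_date = as.Date("2005-07-01"),
    cadence_days = 92,
    trait_correlation = default_trait_correlation(),
    drift_rho = 0.9,
    sectors = default_sectors(),
    loadings = c(cognition = 0.85, adl = 0.86, mood = 0.62, abs = 0.72,
                 pain = 0.8, continence = 0.75, clinical = 0.4),
    probs = default_item_probs(),
    error_rates = zero_error_rates(),
    reversal_rates = c(dx_multiple_sclerosis = 0, dx_quadriplegia = 0,
                       dx_cerebral_palsy = 0, dx_schizophrenia = 0),
    autopop_rates = c(all_clinical = 0, mood = 0, adl = 0),
    comatose_rate = 0.004,
    seed = 1L) {
  cfg <- list(n_quarters = n_quarters, start_date = as.Date(start_date),
              cadence_days = cadence_days,
              trait_correlation = trait_correlation, drift_rho = drift_rho,
              sectors = sectors, loadings = loadings, probs = probs,
              error_rates = error_rates, reversal_rates = reversal_rates,
              autopop_rates = autopop_rates, comatose_rate = comatose_rate,
              seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_trait_correlation <- function() {
  nm <- trait_names()
  r <- diag(6)
  dimnames(r) <- list(nm, nm)
  set_r <- function(a, b, v) {
    r[a, b] <<- v; r[b, a] <<- v
  }
  set_r("cognition", "function", 0.70)
  set_r("cognition", "mood", 0.15)
  set_r("cognition", "aggression", 0.40)
  set_r("cognition", "pain", -0.30)
  set_r("cognition", "continence", 0.60)
  set_r("function", "mood", 0.15)
  set_r("function", "aggression", 0.20)
  set_r("function", "pain", -0.10)
  set_r("function", "continence", 0.50)
  set_r("mood", "aggression", 0.30)
  set_r("mood", "pain", 0.20)
  set_r("mood", "continence", 0.10)
  set_r("aggression", "continence", 0.30)
  set_r("pain", "continence", -0.10)
  r
}

# Category probabilities for thresholded items (base, before sector offsets).
default_item_probs <- function() {
  list(
    memory_problem = c(0.40, 0.60),
    decision_making = c(0.30, 0.25, 0.30, 0.15),
    making_self_understood = c(0.40, 0.25, 0.15, 0.12, 0.08),
    adl = c(0.18, 0.14, 0.18, 0.22, 0.28),
    mood = c(0.82, 0.12, 0.06),
    abs = c(0.82, 0.10, 0.05, 0.03),
    pain_frequency = c(0.40, 0.25, 0.35),
    pain_intensity = c(0.35, 0.45, 0.20),
    bowel_continence = c(0.42, 0.13, 0.10, 0.08, 0.27),
    clinical = c(0.55, 0.20, 0.15, 0.10))
}

default_sectors <- function() {
  list(
    CCC = list(
      admissions_per_quarter = 60, initial_residents = 30, n_facilities = 5,
      mean_assessments = 2.2,
      trait_offset = c(cognition = 0, `function` = 0.55, mood = 0,
                       aggression = -0.2, pain = 0.2, continence = 0.1),
      therapy = list(p_any = c(speech = 0.10, ot = 0.50, pt = 0.65),
                     minutes_per_day = c(15, 45)),
      nrehab_p6 = 0.25, nrehab_p_low = 0.20,
      feeding_tube_p = 0.06, parenteral_p = 0.02,
      dx_prevalence = c(dx_multiple_sclerosis = 0.03, dx_quadriplegia = 0.025,
                        dx_cerebral_palsy = 0.02, dx_schizophrenia = 0.04,
                        dx_diabetes = 0.25, dx_dementia = 0.30),
      signoff_probs = c(neg = 0.0173, d0_6 = 0.6708, d7_30 = 0.1971,
                        gt30 = 0.1147)),
    LTC = list(
      admissions_per_quarter = 25, initial_residents = 220, n_facilities = 8,
      mean_assessments = 11,
      trait_offset = c(cognition = 0.25, `function` = 0.10, mood = 0.25,
                       aggression = 0.10, pain = 0, continence = 0.20),
      therapy = list(p_any = c(speech = 0.02, ot = 0.03, pt = 0.50),
                     minutes_per_day = c(15, 25)),
      nrehab_p6 = 0.07, nrehab_p_low = 0.15,
      feeding_tube_p = 0.02, parenteral_p = 0.005,
      dx_prevalence = c(dx_multiple_sclerosis = 0.02, dx_quadriplegia = 0.01,
                        dx_cerebral_palsy = 0.015, dx_schizophrenia = 0.08,
                        dx_diabetes = 0.25, dx_dementia = 0.60),
      signoff_probs = c(neg = 0, d0_6 = 0.5162, d7_30 = 0.4398,
                        gt30 = 0.0440)))
}

#' @rdname cohort_config
#' @export
zero_error_rates <- function() {
  c(mood = 0, adl_dnoc = 0, nutrition = 0, ulcer = 0, therapy_day15 = 0,
    therapy_nodays = 0, therapy_exceed = 0, height = 0, weight = 0, age = 0)
}

validate_cohort_config <- function(cfg) {
  r <- cfg$trait_correlation
  stopifnot(is.matrix(r), nrow(r) == 6, isTRUE(all.equal(r, t(r))))
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    rlang::abort("trait correlation matrix is not positive semi-definite")
  }
  rates <- c(cfg$error_rates, cfg$reversal_rates, cfg$autopop_rates)
  stopifnot(all(rates >= 0 & rates <= 1))
  for (s in cfg$sectors) {
    # published category shares are rounded; allow rounding slack (sample()
    # renormalizes)
    stopifnot(s$mean_assessments >= 1,
              abs(sum(s$signoff_probs) - 1) < 5e-3)
  }
  invisible(cfg)
}

#' Calibrate an item loading against a Cronbach's alpha target
#'
#' Solves, by bisection on a fixed Monte-Carlo stream, for the common item
#' loading that makes a block of `k` thresholded items (category
#' probabilities `probs`) reach the target internal consistency. Used by
#' [ontario_preset()]; exported so recalibration against a different
#' target is a one-liner.
#'
#' @param alpha_target Target Cronbach's alpha.
#' @param k Number of items in the block.
#' @param probs Category probability vector of each item.
#' @param n Monte-Carlo sample size per evaluation.
#' @param seed Seed of the calibration stream.
#' @return The loading (double in (0, 1)).
#' @export
calibrate_loading <- function(alpha_target, k, probs, n = 3000, seed = 20) {
  cuts <- stats::qnorm(cumsum(probs))[-length(probs)]
  eval_alpha <- function(l) {
    set.seed(seed)
    trait <- stats::rnorm(n)
    m <- vapply(seq_len(k), function(j) {
      y <- l * trait + sqrt(1 - l^2) * stats::rnorm(n)
      findInterval(y, cuts)
    }, numeric(n))
    cronbach_alpha(as.data.frame(m))
  }
  lo <- 0.05; hi <- 0.995
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (eval_alpha(mid) < alpha_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Ontario-shape cohort preset
#'
#' A configuration reproducing the qualitative two-sector contrast of
#' Ontario continuing care: a short-stay, high-admission-share, high
#' ADL-impairment complex-continuing-care (CCC) sector versus a long-stay
#' long-term-care (LTC) sector with higher cognitive impairment and
#' depression prevalence; item loadings calibrated so the ADL Long Form
#' block targets alpha 0.92 and the mood and behaviour blocks sit in the
#' 0.71-0.77 band; latent correlations sized so the scale-level convergent
#' validity statistics land near their published magnitudes (ADL-CPS
#' strongly positive, Pain-CPS negative).
#'
#' @param scale Volume multiplier on admissions and initial residents
#'   (1 gives roughly 300 CCC + 700 LTC assessments per quarter at steady
#'   state; use larger values for recovery studies).
#' @param n_quarters Window length in quarters (default 20).
#' @return A `cohort_config`.
#' @export
ontario_preset <- function(scale = 1, n_quarters = 20) {
  loadings <- c(
    cognition = 0.85,
    adl = calibrate_loading(0.92, 7, default_item_probs()$adl),
    mood = calibrate_loading(0.74, 7, default_item_probs()$mood),
    abs = calibrate_loading(0.755, 4, default_item_probs()$abs),
    pain = 0.8, continence = 0.75, clinical = 0.4)
  sectors <- default_sectors()
  for (s in names(sectors)) {
    sectors[[s]]$admissions_per_quarter <-
      max(1L, as.integer(round(sectors[[s]]$admissions_per_quarter * scale)))
    sectors[[s]]$initial_residents <-
      as.integer(round(sectors[[s]]$initial_residents * scale))
  }
  cohort_config(n_quarters = n_quarters, sectors = sectors,
                loadings = loadings)
}

# value = findInterval on loading * trait + noise, against the standard
# normal quantiles of the category probabilities
ordinal_item <- function(trait, loading, probs) {
  cuts <- stats::qnorm(cumsum(probs))[-length(probs)]
  y <- loading * trait + sqrt(1 - loading^2) * stats::rnorm(length(trait))
  findInterval(y, cuts)
}

#' Generate a synthetic two-sector assessment cohort
#'
#' Draws persons per sector (quarterly admissions plus an initial resident
#' census), schedules admission and reassessments at the configured cadence
#' until the stay ends or the window closes, draws drifting latent traits,
#' and generates every dictionary item. The output is clean by
#' construction: no logical-error rule triggers, diagnoses are stable
#' within person, and vitals are in plausible ranges. Deterministic under
#' `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param dict An [rai_dictionary()].
#' @return A list with `records` (assessment tibble, quarter-assigned) and
#'   `truth` (empty injection truth table; see [inject_errors()]).
#' @export
generate_cohort <- function(config, seed = config$seed,
                            dict = rai_dictionary()) {
  validate_cohort_config(config)
  set.seed(seed)
  recs <- purrr::imap(config$sectors, function(sc, sector) {
    generate_sector(sc, sector, config, dict)
  })
  records <- dplyr::bind_rows(recs)
  records <- assign_quarters(
    records,
    sector_origin = stats::setNames(
      rep(list(config$start_date), length(config$sectors)),
      names(config$sectors)))
  list(records = records, truth = empty_truth())
}

empty_truth <- function() {
  tibble::tibble(person_id = character(), sector = character(),
                 reference_date = as.Date(character()), rule = character(),
                 detail = character())
}

generate_sector <- function(sc, sector, config, dict) {
  n_new <- sc$admissions_per_quarter * config$n_quarters
  n_init <- sc$initial_residents
  n_person <- n_new + n_init
  q_starts <- seq(config$start_date, by = "3 months",
                  length.out = config$n_quarters + 1)
  end_date <- q_starts[config$n_quarters + 1] - 1
  q_starts <- q_starts[-(config$n_quarters + 1)]

  person_id <- sprintf("%s%06d", substr(sector, 1, 1), seq_len(n_person))
  facility_id <- sprintf("%s_F%02d", sector,
                         sample.int(sc$n_facilities, n_person, replace = TRUE))
  # admission quarter (uniform over window) for new persons; initial
  # residents entered before the window and are first seen in quarter 0
  adm_q <- c(rep(seq_len(config$n_quarters),
                 each = sc$admissions_per_quarter),
             rep(NA_integer_, n_init))
  first_date <- dplyr::if_else(
    is.na(adm_q),
    config$start_date + sample.int(85, n_person, replace = TRUE) - 1,
    q_starts[dplyr::coalesce(adm_q, 1L)] +
      sample.int(85, n_person, replace = TRUE) - 1)
  is_new <- !is.na(adm_q)

  p_stop <- 1 / sc$mean_assessments
  n_assess <- 1L + stats::rgeom(n_person, p_stop)
  max_fit <- pmax(1L, as.integer((as.numeric(end_date - first_date)) %/%
                                   config$cadence_days) + 1L)
  n_assess <- pmin(n_assess, max_fit)

  # one row per assessment
  idx <- rep(seq_len(n_person), n_assess)
  rank <- sequence(n_assess)
  ref_date <- first_date[idx] + (rank - 1L) * config$cadence_days +
    ifelse(rank == 1L, 0L, sample.int(11, length(idx), replace = TRUE) - 6L)
  ref_date <- pmin(ref_date, end_date)
  a_type <- ifelse(rank == 1L & is_new[idx], "admission",
                   ifelse(rank %% 4L == 0L, "annual", "quarterly"))

  n_rec <- length(idx)
  # latent traits: person baseline MVN, then AR(1) drift per reassessment
  chol_r <- chol(config$trait_correlation +
                   diag(1e-10, nrow(config$trait_correlation)))
  base <- matrix(stats::rnorm(n_person * 6), n_person, 6) %*% chol_r
  traits <- matrix(NA_real_, n_rec, 6, dimnames = list(NULL, trait_names()))
  rho <- config$drift_rho
  traits[rank == 1L, ] <- base[idx[rank == 1L], ]
  gclin <- numeric(n_rec) # clinical filler latent: its own drifting chain
  gclin[rank == 1L] <- stats::rnorm(sum(rank == 1L))
  if (max(rank) >= 2) {
    for (k in 2:max(rank)) {
      cur <- which(rank == k) # records are person-major, rank-minor
      if (!length(cur)) break
      innov <- matrix(stats::rnorm(length(cur) * 6), ncol = 6) %*% chol_r
      traits[cur, ] <- rho * traits[cur - 1L, ] + sqrt(1 - rho^2) * innov
      gclin[cur] <- rho * gclin[cur - 1L] +
        sqrt(1 - rho^2) * stats::rnorm(length(cur))
    }
  }
  off <- sc$trait_offset[trait_names()]
  traits <- sweep(traits, 2, as.numeric(off), `+`)

  L <- config$loadings
  P <- config$probs
  rec <- tibble::tibble(
    person_id = person_id[idx], facility_id = facility_id[idx],
    sector = sector, assessment_type = a_type, reference_date = ref_date)

  # sign-off lag from the configured category distribution
  cat_draw <- sample(names(sc$signoff_probs), n_rec, replace = TRUE,
                     prob = sc$signoff_probs)
  lag <- dplyr::case_match(cat_draw,
    "neg" ~ -sample.int(5, n_rec, replace = TRUE),
    "d0_6" ~ sample.int(7, n_rec, replace = TRUE) - 1L,
    "d7_30" ~ sample.int(24, n_rec, replace = TRUE) + 6L,
    "gt30" ~ sample.int(60, n_rec, replace = TRUE) + 30L)
  rec$signoff_date <- rec$reference_date + lag

  # vitals: constant per person
  height <- pmin(205, pmax(125, stats::rnorm(n_person, 163, 10)))
  weight <- pmin(195, pmax(25, stats::rnorm(n_person, 72, 16)))
  age_adm <- pmin(108, pmax(20, stats::rnorm(n_person, 80, 10)))
  birth <- first_date - round(age_adm * 365.25)
  rec$birthdate <- birth[idx]
  rec$height_cm <- round(height[idx], 1)
  rec$weight_kg <- round(weight[idx], 1)

  rec$comatose <- stats::rbinom(n_rec, 1, config$comatose_rate)

  # cognition
  rec$memory_problem <- ordinal_item(traits[, "cognition"], L["cognition"],
                                     P$memory_problem)
  rec$decision_making <- ordinal_item(traits[, "cognition"], L["cognition"],
                                      P$decision_making)
  rec$making_self_understood <- ordinal_item(traits[, "cognition"],
                                             L["cognition"],
                                             P$making_self_understood)
  # mood block + persistence
  for (code in dict$blocks$MOOD) {
    rec[[code]] <- ordinal_item(traits[, "mood"], L["mood"], P$mood)
  }
  any_mood <- rowSums(as.matrix(rec[, dict$blocks$MOOD])) > 0
  rec$mood_persistence <- ifelse(
    any_mood, sample(0:2, n_rec, replace = TRUE, prob = c(0.3, 0.4, 0.3)), 0L)

  # ADL performance and support
  for (base_code in sub("_perf$", "", sub("^adl_", "", dict$blocks$ADL_PERF))) {
    perf <- ordinal_item(traits[, "function"], L["adl"], P$adl)
    supp <- pmin(3, pmax(0, round(perf * 0.75 +
                                    stats::rnorm(n_rec, 0, 0.6))))
    if (base_code %in% c("walk_in_room", "walk_in_corridor")) {
      dno <- perf == 4 & stats::runif(n_rec) < 0.3
      perf[dno] <- 8L
      supp[dno] <- 8L
    }
    rec[[paste0("adl_", base_code, "_perf")]] <- perf
    rec[[paste0("adl_", base_code, "_supp")]] <- supp
  }

  # behaviour, pain, continence
  for (code in dict$blocks$BEHAVIOUR) {
    rec[[code]] <- ordinal_item(traits[, "aggression"], L["abs"], P$abs)
  }
  rec$pain_frequency <- ordinal_item(traits[, "pain"], L["pain"],
                                     P$pain_frequency)
  intensity <- 1L + ordinal_item(traits[, "pain"], L["pain"],
                                 P$pain_intensity)
  rec$pain_intensity <- ifelse(rec$pain_frequency == 0, 0L, intensity)
  rec$bowel_continence <- ordinal_item(traits[, "continence"],
                                       L["continence"], P$bowel_continence)

  # nutrition: routes consistent with intake codes
  route <- stats::runif(n_rec) < sc$feeding_tube_p
  piv <- stats::runif(n_rec) < sc$parenteral_p
  any_route <- route | piv
  rec$feeding_tube <- as.integer(route)
  rec$parenteral_iv <- as.integer(piv)
  rec$calories_proportion_code <- ifelse(
    any_route, sample(1:4, n_rec, replace = TRUE), 0L)
  rec$fluid_intake_code <- ifelse(
    any_route, sample(1:5, n_rec, replace = TRUE), 0L)

  # ulcers: count present whenever a stage is assigned
  stage <- sample(0:4, n_rec, replace = TRUE,
                  prob = c(0.85, 0.05, 0.05, 0.03, 0.02))
  rec$ulcer_highest_stage <- stage
  rec$ulcer_count_at_stage <- ifelse(
    stage >= 1, sample(1:4, n_rec, replace = TRUE,
                       prob = c(0.6, 0.25, 0.1, 0.05)), 0L)

  # therapy: minutes always consistent with days (>= 15/day, <= 1440/day)
  mins_rng <- sc$therapy$minutes_per_day
  disc_days <- list()
  for (d in c("speech", "ot", "pt")) {
    any_d <- stats::runif(n_rec) < sc$therapy$p_any[[d]]
    days <- ifelse(any_d, sample(1:7, n_rec, replace = TRUE,
                                 prob = c(0.1, 0.15, 0.2, 0.2, 0.2, 0.1, 0.05)),
                   0L)
    mins <- round(days * stats::runif(n_rec, mins_rng[1], mins_rng[2]))
    rec[[paste0(d, "_days")]] <- days
    rec[[paste0(d, "_minutes")]] <- mins
    disc_days[[d]] <- days
  }
  dmax <- pmax(disc_days$speech, disc_days$ot, disc_days$pt)
  dsum <- pmin(7, disc_days$speech + disc_days$ot + disc_days$pt)
  extra <- stats::rbinom(n_rec, pmax(0, dsum - dmax), 0.3)
  rec$distinct_therapy_days <- dmax + extra

  # nursing rehabilitation items
  for (code in grep("^nrehab_", dict$items$code, value = TRUE)) {
    u <- stats::runif(n_rec)
    rec[[code]] <- ifelse(u < sc$nrehab_p6,
                          sample(6:7, n_rec, replace = TRUE),
                          ifelse(u < sc$nrehab_p6 + sc$nrehab_p_low,
                                 sample(1:5, n_rec, replace = TRUE), 0L))
  }

  # diagnoses: drawn once per person, stable across assessments
  for (dx in names(sc$dx_prevalence)) {
    has <- stats::rbinom(n_person, 1, sc$dx_prevalence[[dx]])
    rec[[dx]] <- has[idx]
  }

  # generic clinical filler items
  fillers <- grep("^clin_", dict$items$code, value = TRUE)
  cuts <- stats::qnorm(cumsum(P$clinical))[-length(P$clinical)]
  lcl <- L["clinical"]
  if (length(fillers)) {
    y <- lcl * gclin + sqrt(1 - lcl^2) *
      matrix(stats::rnorm(n_rec * length(fillers)), n_rec)
    m <- matrix(findInterval(y, cuts), n_rec)
    colnames(m) <- fillers
    rec <- dplyr::bind_cols(rec, tibble::as_tibble(m))
  }

  rec[, c(identity_cols(), dict$items$code)]
}

#' Inject labelled coding errors into a clean cohort
#'
#' With the configured per-rule probability, mutates records to create
#' exactly the rule's triggering condition; carries blocks forward from the
#' person's previous assessment with the configured autopopulation
#' probabilities; clears T1-present uncurable diagnoses at the next
#' assessment with the configured reversal rates. Every mutation is
#' recorded in the returned truth table (rule, record key, and the original
#' values of changed fields as `code=value` pairs, so corruption is
#' reversible).
#'
#' @param records Clean assessment tibble from [generate_cohort()].
#' @param config The [cohort_config()] carrying `error_rates`,
#'   `reversal_rates` and `autopop_rates`.
#' @param seed Integer seed for the injection draws.
#' @param dict An [rai_dictionary()].
#' @return A list with mutated `records` and the `truth` table.
#' @export
inject_errors <- function(records, config, seed = config$seed + 1L,
                          dict = rai_dictionary()) {
  set.seed(seed)
  n <- nrow(records)
  truth <- list()
  log_truth <- function(rows, rule, cols) {
    if (!length(rows)) return()
    detail <- if (length(cols)) {
      apply(as.data.frame(records[rows, cols, drop = FALSE]), 1,
            function(v) paste(cols, v, sep = "=", collapse = ";"))
    } else rep("", length(rows))
    truth[[length(truth) + 1]] <<- tibble::tibble(
      person_id = records$person_id[rows], sector = records$sector[rows],
      reference_date = records$reference_date[rows], rule = rule,
      detail = unname(detail))
  }
  pick <- function(rate) which(stats::runif(n) < rate)
  rates <- config$error_rates

  rows <- pick(rates[["mood"]])
  log_truth(rows, "mood", c("mood_persistence", dict$blocks$MOOD))
  records$mood_persistence[rows] <- sample(1:2, length(rows), replace = TRUE)
  for (code in dict$blocks$MOOD) records[[code]][rows] <- 0L

  rows <- pick(rates[["adl_dnoc"]])
  if (length(rows)) {
    base <- sample(sub("_perf$", "", dict$blocks$ADL_PERF), length(rows),
                   replace = TRUE)
    pc <- paste0(base, "_perf"); sc_ <- paste0(base, "_supp")
    log_truth(rows, "adl_dnoc", c(dict$blocks$ADL_PERF, dict$blocks$ADL_SUPP))
    for (i in seq_along(rows)) {
      records[[pc[i]]][rows[i]] <- 8L
      if (records[[sc_[i]]][rows[i]] == 8) {
        records[[sc_[i]]][rows[i]] <- sample(0:3, 1)
      }
    }
  }

  rows <- pick(rates[["nutrition"]])
  if (length(rows)) {
    log_truth(rows, "nutrition", dict$blocks$NUTRITION)
    has_route <- records$feeding_tube[rows] == 1 |
      records$parenteral_iv[rows] == 1
    records$calories_proportion_code[rows] <-
      ifelse(has_route, 0L, sample(1:4, length(rows), replace = TRUE))
    records$fluid_intake_code[rows] <- ifelse(has_route, 0L,
                                              records$fluid_intake_code[rows])
  }

  rows <- pick(rates[["ulcer"]])
  log_truth(rows, "ulcer", dict$blocks$ULCER)
  records$ulcer_highest_stage[rows] <- sample(1:4, length(rows),
                                              replace = TRUE)
  records$ulcer_count_at_stage[rows] <- 0L

  rows <- pick(rates[["therapy_day15"]])
  log_truth(rows, "therapy_day15", c("pt_days", "pt_minutes"))
  records$pt_days[rows] <- 2L
  records$pt_minutes[rows] <- sample(0:29, length(rows), replace = TRUE)

  rows <- pick(rates[["therapy_nodays"]])
  log_truth(rows, "therapy_nodays", c("ot_days", "ot_minutes"))
  records$ot_days[rows] <- 0L
  records$ot_minutes[rows] <- sample(15:90, length(rows), replace = TRUE)

  rows <- pick(rates[["therapy_exceed"]])
  log_truth(rows, "therapy_exceed", c("speech_days", "speech_minutes"))
  records$speech_days[rows] <- 1L
  records$speech_minutes[rows] <- 1441L + sample.int(500, length(rows),
                                                     replace = TRUE)

  rows <- pick(rates[["height"]])
  log_truth(rows, "height", "height_cm")
  records$height_cm[rows] <- sample(c(sample(60:119, n, replace = TRUE),
                                      sample(212:260, n, replace = TRUE)),
                                    length(rows))

  rows <- pick(rates[["weight"]])
  log_truth(rows, "weight", "weight_kg")
  records$weight_kg[rows] <- sample(c(sample(2:19, n, replace = TRUE),
                                      sample(201:320, n, replace = TRUE)),
                                    length(rows))

  rows <- pick(rates[["age"]])
  log_truth(rows, "age", "birthdate")
  bad_age <- sample(c(5, 10, 14, 117, 125), length(rows), replace = TRUE)
  records$birthdate[rows] <- records$reference_date[rows] -
    round(bad_age * 365.25)

  # longitudinal injections walk each person's chain in time order; within
  # ord, the row preceding a rank-k assessment is the same person's rank k-1
  ord <- order(records$person_id, records$sector, records$reference_date)
  rnk <- stats::ave(seq_along(ord), records$person_id[ord],
                    records$sector[ord], FUN = seq_along)
  max_rank <- max(rnk)

  for (dx in names(config$reversal_rates)) {
    r <- config$reversal_rates[[dx]]
    if (r == 0 || max_rank < 2) next
    for (k in 2:max_rank) {
      pos <- which(rnk == k)
      if (!length(pos)) break
      cur <- ord[pos]; prev <- ord[pos - 1L]
      keep <- records[[dx]][prev] == 1 & records[[dx]][cur] == 1
      eligible <- cur[keep]
      hit <- eligible[stats::runif(length(eligible)) < r]
      log_truth(hit, paste0("reversal_", dx), dx)
      records[[dx]][hit] <- 0L
    }
  }

  # the carried-forward mood section includes the persistence item, keeping
  # copied records internally consistent; detection still screens the 16
  # indicator items only
  blocks <- list(all_clinical = dict$blocks$CLINICAL,
                 mood = c(dict$blocks$MOOD, "mood_persistence"),
                 adl = c(dict$blocks$ADL_PERF, dict$blocks$ADL_SUPP))
  # rank-major so every copy reads the finalized state of the previous
  # assessment (chained and multi-block carry-forwards stay exact copies)
  if (max_rank >= 2 && any(config$autopop_rates > 0)) {
    for (k in 2:max_rank) {
      pos <- which(rnk == k)
      if (!length(pos)) break
      cur <- ord[pos]; prev <- ord[pos - 1L]
      for (b in names(config$autopop_rates)) {
        p <- config$autopop_rates[[b]]
        if (p == 0) next
        cols <- blocks[[b]]
        hit <- stats::runif(length(cur)) < p
        log_truth(cur[hit], paste0("autopop_", b), character())
        records[cur[hit], cols] <- records[prev[hit], cols]
      }
    }
  }

  truth <- if (length(truth)) dplyr::bind_rows(truth) else empty_truth()
  list(records = records, truth = truth)
}

#' Generate and corrupt a cohort in one call
#'
#' [generate_cohort()] followed by [inject_errors()] with the rates carried
#' by the configuration.
#'
#' @inheritParams generate_cohort
#' @return A list with `records` and `truth`.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            dict = rai_dictionary()) {
  clean <- generate_cohort(config, seed = seed, dict = dict)
  out <- inject_errors(clean$records, config, seed = seed + 1L, dict = dict)
  out$records <- assign_quarters(
    out$records,
    sector_origin = stats::setNames(
      rep(list(config$start_date), length(config$sectors)),
      names(config$sectors)))
  out
}

#' Injection-recovery verification
#'
#' The closed loop that makes the artifact testable: simulates a cohort
#' with the configured injection rates, audits it, and compares the audited
#' rate of every error type with its injection rate. Because the injection
#' processes interact - a carried-forward block replicates any error it
#' contains, and two adjacent mutated records can become identical by
#' construction - each comparison conditions on the truth table so that its
#' expectation is exact:
#' * cross-sectional rules: audited rate among records without a
#'   carry-forward injection, against the injected rate;
#' * diagnosis reversals: audited rate among eligible pairs whose T2 record
#'   was not whole-record carried forward, against the reversal rate;
#' * autopopulation: audited rate among pairs where neither record carries
#'   a cross-sectional injection, against
#'   `1 - (1 - p_block) (1 - p_clinical) (1 - baseline)` with the natural
#'   no-change baseline measured on the matching clean cohort.
#'
#' The `z` column is the discrepancy in binomial standard deviations.
#'
#' @inheritParams generate_cohort
#' @return A tibble `rule, injected, audited, expected, n, z`.
#' @export
verify_cohort <- function(config, seed = config$seed,
                          dict = rai_dictionary()) {
  clean <- generate_cohort(config, seed = seed, dict = dict)
  inj <- inject_errors(clean$records, config, seed = seed + 1L, dict = dict)
  rec <- exclude_comatose(inj$records)
  flags <- audit_records(rec, dict)
  truth <- inj$truth

  tkey <- function(d) paste(d$person_id, d$sector, d$reference_date)
  auto_keys <- tkey(truth[startsWith(truth$rule, "autopop"), ])
  clin_keys <- tkey(truth[truth$rule == "autopop_all_clinical", ])
  xsec_keys <- tkey(truth[!startsWith(truth$rule, "autopop") &
                            !startsWith(truth$rule, "reversal"), ])
  rec_key <- paste(rec$person_id, rec$sector, rec$reference_date)

  rule_cols <- c(mood = "mood_persistence_err", adl_dnoc = "adl_dnoc_err",
                 nutrition = "nutrition_err", ulcer = "ulcer_err",
                 therapy_day15 = "therapy_day15_err",
                 therapy_nodays = "therapy_nodays_err",
                 therapy_exceed = "therapy_exceed_err",
                 height = "height_err", weight = "weight_err",
                 age = "age_err")
  keep <- !rec_key %in% auto_keys
  res <- purrr::imap_dfr(rule_cols, function(col, rule) {
    p <- config$error_rates[[rule]]
    x <- flags[[col]][keep]
    tibble::tibble(rule = rule, injected = p,
                   audited = mean(x, na.rm = TRUE), expected = p,
                   n = sum(!is.na(x)))
  })

  pairs <- make_pairs(rec)
  pflags <- audit_pairs(pairs, dict)
  k1 <- paste(pflags$person_id, pflags$sector, pflags$reference_date_t1)
  k2 <- paste(pflags$person_id, pflags$sector, pflags$reference_date_t2)

  rev_cols <- c(dx_multiple_sclerosis = "reversal_ms",
                dx_quadriplegia = "reversal_quad",
                dx_cerebral_palsy = "reversal_cp",
                dx_schizophrenia = "reversal_schiz")
  keep_rev <- !k2 %in% clin_keys
  res_rev <- purrr::imap_dfr(rev_cols, function(col, dx) {
    r <- config$reversal_rates[[dx]]
    x <- pflags[[col]][keep_rev]
    tibble::tibble(rule = paste0("reversal_", dx), injected = r,
                   audited = mean(x, na.rm = TRUE), expected = r,
                   n = sum(!is.na(x)))
  })

  # natural no-change baseline from the clean cohort
  crec <- exclude_comatose(clean$records)
  cpflags <- audit_pairs(make_pairs(crec), dict)
  auto_cols <- c(all_clinical = "auto_all_clinical", mood = "auto_mood16",
                 adl = "auto_adl20")
  keep_auto <- !(k1 %in% xsec_keys | k2 %in% xsec_keys)
  p_clin <- config$autopop_rates[["all_clinical"]]
  res_auto <- purrr::imap_dfr(auto_cols, function(col, b) {
    p <- config$autopop_rates[[b]]
    baseline <- mean(cpflags[[col]], na.rm = TRUE)
    p_tot <- if (b == "all_clinical") p else 1 - (1 - p) * (1 - p_clin)
    x <- pflags[[col]][keep_auto]
    tibble::tibble(rule = paste0("autopop_", b), injected = p,
                   audited = mean(x, na.rm = TRUE),
                   expected = 1 - (1 - p_tot) * (1 - baseline),
                   n = sum(!is.na(x)))
  })

  out <- dplyr::bind_rows(res, res_rev, res_auto)
  se <- sqrt(pmax(out$expected * (1 - out$expected), 1e-12) / pmax(out$n, 1))
  out$z <- (out$audited - out$expected) / se
  out
}
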