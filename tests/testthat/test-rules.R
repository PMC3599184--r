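mood16 <- test_dict$blocks$MOOD

test_that("mood-persistence rule equals brute force over binarized items", {
  # persistence 0:2 x all 2^16 presence patterns of the 16 items
  pat <- expand.grid(rep(list(0:1), 16))
  g <- pat[rep(seq_len(nrow(pat)), 3), ]
  pers <- rep(0:2, each = nrow(pat))
  rec <- blank_records(nrow(g))
  for (i in 1:16) rec[[mood16[i]]] <- g[[i]]
  rec$mood_persistence <- pers
  got <- check_mood_persistence(rec, test_dict)
  want <- pers >= 1 & rowSums(g) == 0
  expect_identical(got, unname(want))
})

test_that("mood-persistence handles missingness per the denominators rule", {
  expect_true(is.na(check_mood_persistence(
    blank_record(mood_persistence = NA))))
  r <- blank_record(mood_persistence = 1)
  r[[mood16[4]]] <- NA
  expect_true(is.na(check_mood_persistence(r))) # cannot assert all-zero
  r[[mood16[5]]] <- 2
  expect_false(check_mood_persistence(r)) # a present item decides
})

test_that("ADL did-not-occur rule equals exhaustive pair enumeration", {
  g <- record_grid(adl_dressing_perf = c(0:4, 8),
                   adl_dressing_supp = c(0:3, 8))
  got <- check_adl_did_not_occur(g, test_dict)
  want <- xor(g$adl_dressing_perf == 8, g$adl_dressing_supp == 8)
  expect_identical(got, unname(want))
  # no 8 anywhere: never flagged
  g2 <- record_grid(adl_transfer_perf = 0:4, adl_transfer_supp = 0:3)
  expect_false(any(check_adl_did_not_occur(g2, test_dict)))
})

test_that("nutrition rule equals its truth table in both directions", {
  g <- record_grid(parenteral_iv = 0:1, feeding_tube = 0:1,
                   calories_proportion_code = 0:4, fluid_intake_code = 0:5)
  got <- check_nutrition(g, test_dict)
  route <- g$parenteral_iv == 1 | g$feeding_tube == 1
  intake <- g$calories_proportion_code > 0 | g$fluid_intake_code > 0
  expect_identical(got, unname((route & !intake) | (!route & intake)))
  expect_true(check_nutrition(blank_record(feeding_tube = 1)))
  expect_false(check_nutrition(blank_record(feeding_tube = 1,
                                            calories_proportion_code = 3,
                                            fluid_intake_code = 1)))
  expect_true(check_nutrition(blank_record(calories_proportion_code = 2)))
})

test_that("ulcer rule equals enumeration over stage x count incl. missing", {
  g <- record_grid(ulcer_highest_stage = 0:4,
                   ulcer_count_at_stage = c(NA, 0:9))
  got <- check_ulcer(g, test_dict)
  want <- g$ulcer_highest_stage >= 1 &
    (is.na(g$ulcer_count_at_stage) | g$ulcer_count_at_stage == 0)
  expect_identical(got, unname(want))
  expect_true(check_ulcer(blank_record(ulcer_highest_stage = 3)))
  expect_false(check_ulcer(blank_record()))
  expect_true(check_ulcer(blank_record(ulcer_highest_stage = 2,
                                       ulcer_count_at_stage = NA)))
})

test_that("therapy rules equal brute force on a days x minutes grid", {
  mins <- c(0, 10, 15, 100, 1440, 1441, 10080)
  for (d in c("speech", "ot", "pt")) {
    g <- record_grid(.grid_days = 0:7, .grid_mins = mins)
    g[[paste0(d, "_days")]] <- g$.grid_days
    g[[paste0(d, "_minutes")]] <- g$.grid_mins
    got <- check_therapy(g, test_dict)
    expect_identical(got$therapy_day15_err,
                     unname(g$.grid_days >= 1 &
                              g$.grid_mins < 15 * g$.grid_days))
    expect_identical(got$therapy_nodays_err,
                     unname(g$.grid_days == 0 & g$.grid_mins >= 15))
    expect_identical(got$therapy_exceed_err,
                     unname(g$.grid_mins > 1440 * pmax(g$.grid_days, 1)))
    expect_identical(got$any_therapy_err,
                     got$therapy_day15_err | got$therapy_nodays_err |
                       got$therapy_exceed_err)
  }
  one <- check_therapy(blank_record(pt_days = 2, pt_minutes = 20))
  expect_true(one$therapy_day15_err)
  expect_false(any(unlist(check_therapy(blank_record()))))
  expect_true(check_therapy(blank_record(speech_days = 1,
                                         speech_minutes = 1500))$therapy_exceed_err)
})

test_that("vitals rules flag exactly outside the plausibility boundaries", {
  expect_equal(check_vitals(blank_record(height_cm = 119))$height_err, TRUE)
  expect_equal(check_vitals(blank_record(height_cm = 120))$height_err, FALSE)
  expect_equal(check_vitals(blank_record(height_cm = 211))$height_err, FALSE)
  expect_equal(check_vitals(blank_record(height_cm = 212))$height_err, TRUE)
  expect_equal(check_vitals(blank_record(height_cm = NA))$height_err, FALSE)
  expect_equal(check_vitals(blank_record(weight_kg = 19.5))$weight_err, TRUE)
  expect_equal(check_vitals(blank_record(weight_kg = 20))$weight_err, FALSE)
  expect_equal(check_vitals(blank_record(weight_kg = 200))$weight_err, FALSE)
  expect_equal(check_vitals(blank_record(weight_kg = 201))$weight_err, TRUE)
  expect_equal(check_vitals(blank_record(weight_kg = NA))$weight_err, FALSE)
  # completed age boundaries at +/- 1 day around 16 and 115 years
  ref <- as.Date("2006-05-10")
  age_err_at <- function(birth) {
    check_vitals(blank_record(birthdate = as.Date(birth),
                              reference_date = ref))$age_err
  }
  expect_true(age_err_at("1990-05-11"))   # turns 16 tomorrow -> still 15
  expect_false(age_err_at("1990-05-10"))  # 16 today
  expect_false(age_err_at("1891-05-10"))  # 115 today
  expect_false(age_err_at("1891-05-09"))  # completed 115 yesterday
  expect_true(age_err_at("1890-05-10"))   # 116 today
})

test_that("any-logical flag equals a brute-force OR on random flag vectors", {
  set.seed(77)
  n <- 1000
  rnd <- function() sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                           prob = c(0.2, 0.7, 0.1))
  flags <- tibble::tibble(mood_persistence_err = rnd(), adl_dnoc_err = rnd(),
                          nutrition_err = rnd(), ulcer_err = rnd(),
                          any_therapy_err = rnd())
  got <- any_logical_problem(flags)
  m <- as.matrix(flags)
  want <- ifelse(rowSums(m, na.rm = TRUE) > 0, TRUE,
                 ifelse(rowSums(is.na(m)) > 0, NA, FALSE))
  expect_identical(got, unname(want))
  expect_false(any_logical_problem(tibble::tibble(
    mood_persistence_err = FALSE, adl_dnoc_err = FALSE,
    nutrition_err = FALSE, ulcer_err = FALSE, any_therapy_err = FALSE)))
})

test_that("sign-off lag categories partition the day boundaries", {
  ref <- as.Date("2006-05-10")
  rec <- blank_records(6)
  rec$reference_date <- ref
  rec$signoff_date <- ref + c(-1, 0, 6, 7, 30, 31)
  out <- signoff_lag(rec)
  expect_equal(out$signoff_lag_days, c(-1, 0, 6, 7, 30, 31))
  expect_equal(as.character(out$signoff_category),
               c("neg", "d0_6", "d0_6", "d7_30", "d7_30", "gt30"))
  miss <- signoff_lag(blank_record(signoff_date = as.Date(NA)))
  expect_true(is.na(miss$signoff_lag_days))
  # category shares sum to 100% per year in an aggregated table
  coh <- generate_cohort(cohort_config(n_quarters = 6), seed = 4)
  tabs <- quarterly_tables(coh$records)
  sums <- tapply(tabs$signoff$value,
                 paste(tabs$signoff$sector, tabs$signoff$quarter), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("service indicators follow their thresholds and nest", {
  x <- service_indicators(blank_record())
  expect_equal(x$total_therapy_minutes, 0)
  expect_false(any(x$nursing_rehab_2plus, x$any_ot, x$any_pt,
                   x$rehab_3d45m, x$rehab_5d150m))
  x <- service_indicators(blank_record(pt_days = 5, pt_minutes = 200,
                                       distinct_therapy_days = 5))
  expect_true(x$any_pt && x$rehab_3d45m && x$rehab_5d150m)
  x <- service_indicators(blank_record(nrehab_rom_active = 6,
                                       nrehab_walking = 7))
  expect_true(x$nursing_rehab_2plus)
  x <- service_indicators(blank_record(nrehab_rom_active = 6,
                                       nrehab_walking = 5))
  expect_false(x$nursing_rehab_2plus)
  # nesting: 5d150m implies 3d45m on random valid inputs
  set.seed(12)
  rec <- blank_records(300)
  rec$pt_days <- sample(0:7, 300, TRUE)
  rec$pt_minutes <- sample(0:1200, 300, TRUE)
  rec$ot_minutes <- sample(0:500, 300, TRUE)
  rec$distinct_therapy_days <- sample(0:7, 300, TRUE)
  s <- service_indicators(rec)
  expect_true(all(!s$rehab_5d150m | s$rehab_3d45m))
})

test_that("diagnosis reversal is defined only among T1 carriers", {
  rec <- dplyr::bind_rows(
    blank_record(person_id = "A", reference_date = as.Date("2006-01-01"),
                 dx_multiple_sclerosis = 1),
    blank_record(person_id = "A", reference_date = as.Date("2006-04-01"),
                 dx_multiple_sclerosis = 0),
    blank_record(person_id = "B", reference_date = as.Date("2006-01-01"),
                 dx_quadriplegia = 1),
    blank_record(person_id = "B", reference_date = as.Date("2006-04-01"),
                 dx_quadriplegia = 1),
    blank_record(person_id = "C", reference_date = as.Date("2006-01-01")),
    blank_record(person_id = "C", reference_date = as.Date("2006-04-01"),
                 dx_cerebral_palsy = 1))
  p <- make_pairs(rec)
  p <- p[order(p$person_id), ]
  expect_equal(diagnosis_reversal(p, "dx_multiple_sclerosis"),
               c(TRUE, NA, NA))
  expect_equal(diagnosis_reversal(p, "dx_quadriplegia"), c(NA, FALSE, NA))
  expect_equal(diagnosis_reversal(p, "dx_cerebral_palsy"), c(NA, NA, NA))
})

test_that("autopopulation flags detect identical blocks, missing included", {
  t1 <- blank_record(person_id = "A",
                     reference_date = as.Date("2006-01-15"))
  t1[[mood16[2]]] <- NA
  t2 <- t1
  t2$reference_date <- as.Date("2006-04-15")
  p <- make_pairs(dplyr::bind_rows(t1, t2))
  f <- autopopulation_flags(p, test_dict)
  expect_true(f$auto_all_clinical && f$auto_mood16 && f$auto_adl20)
  # one mood item changes: mood block no longer identical, ADL still is
  t2b <- t2
  t2b[[mood16[1]]] <- 2
  f <- autopopulation_flags(make_pairs(dplyr::bind_rows(t1, t2b)), test_dict)
  expect_false(f$auto_mood16)
  expect_false(f$auto_all_clinical)
  expect_true(f$auto_adl20)
  # missing at T1, coded at T2 is a change
  t2c <- t2
  t2c[[mood16[2]]] <- 0
  f <- autopopulation_flags(make_pairs(dplyr::bind_rows(t1, t2c)), test_dict)
  expect_false(f$auto_mood16)
  # same-quarter pairs are not evaluated
  t2d <- t1
  t2d$reference_date <- as.Date("2006-02-20")
  f <- autopopulation_flags(make_pairs(dplyr::bind_rows(t1, t2d)), test_dict)
  expect_true(is.na(f$auto_all_clinical))
})
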