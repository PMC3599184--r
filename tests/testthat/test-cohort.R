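small_cfg <- cohort_config(n_quarters = 6)

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(small_cfg, seed = 5)
  b <- generate_cohort(small_cfg, seed = 5)
  expect_identical(a$records, b$records)
  c_ <- generate_cohort(small_cfg, seed = 6)
  expect_false(identical(a$records, c_$records))
})

test_that("clean cohorts carry zero logical errors of every kind", {
  coh <- generate_cohort(small_cfg, seed = 17)
  rec <- exclude_comatose(coh$records)
  flags <- audit_records(rec)
  for (col in c("mood_persistence_err", "adl_dnoc_err", "nutrition_err",
                "ulcer_err", "therapy_day15_err", "therapy_nodays_err",
                "therapy_exceed_err", "any_logical_err", "height_err",
                "weight_err", "age_err")) {
    expect_equal(sum(flags[[col]], na.rm = TRUE), 0, label = col)
  }
  pf <- audit_pairs(make_pairs(rec))
  for (col in c("reversal_ms", "reversal_quad", "reversal_cp",
                "reversal_schiz")) {
    expect_equal(sum(pf[[col]], na.rm = TRUE), 0, label = col)
  }
})

test_that("generated records validate against the dictionary", {
  coh <- generate_cohort(small_cfg, seed = 23)
  expect_silent(validate_assessments(coh$records))
  expect_true(all(coh$records$reference_date >= small_cfg$start_date))
  # admission at most once per person x sector
  adm <- coh$records[coh$records$assessment_type == "admission", ]
  expect_false(anyDuplicated(paste(adm$person_id, adm$sector)) > 0)
})

test_that("zero injection rates leave records untouched", {
  coh <- generate_cohort(small_cfg, seed = 9)
  out <- inject_errors(coh$records, small_cfg, seed = 10)
  expect_identical(out$records, coh$records)
  expect_equal(nrow(out$truth), 0)
})

test_that("every injected error is detected (deterministic recall)", {
  cfg <- small_cfg
  cfg$error_rates[] <- 0.03
  cfg$reversal_rates[] <- 0.2
  cfg$autopop_rates[] <- c(0.02, 0.05, 0.05)
  coh <- generate_cohort(cfg, seed = 41)
  inj <- inject_errors(coh$records, cfg, seed = 42)
  rec <- inj$records
  flags <- audit_records(rec)
  key <- paste(rec$person_id, rec$sector, rec$reference_date)
  tkey <- paste(inj$truth$person_id, inj$truth$sector,
                inj$truth$reference_date)
  flag_col <- c(mood = "mood_persistence_err", adl_dnoc = "adl_dnoc_err",
                nutrition = "nutrition_err", ulcer = "ulcer_err",
                therapy_day15 = "therapy_day15_err",
                therapy_nodays = "therapy_nodays_err",
                therapy_exceed = "therapy_exceed_err",
                height = "height_err", weight = "weight_err",
                age = "age_err")
  # whole-record carry-forward may overwrite an earlier cross-sectional
  # mutation; recall is asserted on records not also carried forward
  carried <- tkey[startsWith(inj$truth$rule, "autopop")]
  for (rule in names(flag_col)) {
    hit <- key %in% setdiff(tkey[inj$truth$rule == rule], carried)
    expect_true(all(flags[[flag_col[rule]]][hit]), label = rule)
  }
  pf <- audit_pairs(make_pairs(rec))
  pkey2 <- paste(pf$person_id, pf$sector, pf$reference_date_t2)
  for (dx in c("dx_multiple_sclerosis", "dx_quadriplegia",
               "dx_cerebral_palsy", "dx_schizophrenia")) {
    col <- c(dx_multiple_sclerosis = "reversal_ms",
             dx_quadriplegia = "reversal_quad",
             dx_cerebral_palsy = "reversal_cp",
             dx_schizophrenia = "reversal_schiz")[dx]
    hit <- pkey2 %in% setdiff(tkey[inj$truth$rule == paste0("reversal_", dx)],
                              tkey[inj$truth$rule == "autopop_all_clinical"])
    expect_true(all(pf[[col]][hit]), label = dx)
  }
  auto_col <- c(autopop_all_clinical = "auto_all_clinical",
                autopop_mood = "auto_mood16", autopop_adl = "auto_adl20")
  for (rule in names(auto_col)) {
    hit <- pkey2 %in% tkey[inj$truth$rule == rule]
    got <- pf[[auto_col[rule]]][hit]
    expect_true(all(got[!is.na(got)]), label = rule) # NA = same-quarter pair
  }
})

test_that("pair counts follow the closed form on generated cohorts", {
  coh <- generate_cohort(small_cfg, seed = 3)
  per <- table(paste(coh$records$person_id, coh$records$sector))
  expect_equal(nrow(make_pairs(coh$records)), sum(pmax(0, per - 1)))
})

test_that("the Ontario-shape preset reproduces the two-sector contrast", {
  cfg <- ontario_preset(scale = 1, n_quarters = 12)
  coh <- generate_cohort(cfg, seed = 19)
  rec <- exclude_comatose(coh$records)
  by_sector <- split(rec, rec$sector)
  adm <- vapply(by_sector,
                function(d) mean(d$assessment_type == "admission"), 1)
  app <- vapply(by_sector,
                function(d) nrow(d) / length(unique(d$person_id)), 1)
  expect_gt(adm[["CCC"]], 3 * adm[["LTC"]]) # admission-heavy CCC
  expect_gt(app[["LTC"]], app[["CCC"]])     # longer stays in LTC
  s <- score_scales(rec)
  cps3 <- tapply(s$cps_ge3, s$sector, mean, na.rm = TRUE)
  expect_gt(cps3[["LTC"]], cps3[["CCC"]])   # more cognitive impairment in LTC
  expect_true(abs(cps3[["LTC"]] - 0.58) < 0.08)
  mins <- tapply(s$speech_minutes + s$ot_minutes + s$pt_minutes, s$sector,
                 mean)
  expect_gt(mins[["CCC"]], 2 * mins[["LTC"]]) # rehabilitation-heavy CCC
})

test_that("infeasible trait correlation matrices are fatal before sampling", {
  bad <- default_trait_correlation()
  bad[1, 2] <- bad[2, 1] <- 0.99
  bad[1, 3] <- bad[3, 1] <- 0.99
  bad[2, 3] <- bad[3, 2] <- -0.99
  expect_error(cohort_config(trait_correlation = bad),
               "positive semi-definite")
})
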