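adl7 <- scale_definitions()$adl_long_form$items
drs7 <- scale_definitions()$drs$items
abs4 <- scale_definitions()$abs$items

set_items <- function(codes, values, ...) {
  rec <- blank_record(...)
  for (i in seq_along(codes)) rec[[codes[i]]] <- values[i]
  rec
}

test_that("ADL Long Form sums seven items with 8 recoded to 4", {
  expect_equal(score_adl_long_form(set_items(adl7, rep(0, 7))), 0)
  expect_equal(score_adl_long_form(set_items(adl7, rep(4, 7))), 28)
  # hand sum: 1+2+3+0+4(from 8)+4+2 = 16
  expect_equal(score_adl_long_form(set_items(adl7, c(1, 2, 3, 0, 8, 4, 2))),
               16)
  rec <- set_items(adl7, c(1, 2, 3, 0, NA, 4, 2))
  expect_true(is.na(score_adl_long_form(rec)))
})

test_that("DRS and ABS are simple sums over their item sets", {
  expect_equal(score_drs(set_items(drs7, rep(0, 7))), 0)
  expect_equal(score_drs(set_items(drs7, rep(2, 7))), 14)
  expect_equal(score_drs(set_items(drs7, c(2, 1, 0, 0, 1, 0, 1))), 5)
  expect_equal(score_abs(set_items(abs4, rep(0, 4))), 0)
  expect_equal(score_abs(set_items(abs4, rep(3, 4))), 12)
  expect_equal(score_abs(set_items(abs4, c(3, 0, 1, 2))), 6)
})

# independent oracle: a literal transcription of the CPS decision tree,
# evaluated record-by-record
cps_oracle <- function(com, mem, dec, und, eat) {
  if (com == 1) return(6)
  if (dec == 3) return(if (eat == 4 || eat == 8) 6 else 5)
  imp <- (mem >= 1) + (dec >= 1) + (und >= 1)
  if (imp == 0) return(0)
  if (imp == 1) return(1)
  2 + (dec >= 2) + (und >= 2)
}

test_that("CPS matches exhaustive enumeration of its decision tree", {
  g <- record_grid(comatose = 0:1, memory_problem = 0:1,
                   decision_making = 0:3, making_self_understood = 0:4,
                   adl_eating_perf = c(0:4, 8))
  got <- score_cps(g)
  want <- mapply(cps_oracle, g$comatose, g$memory_problem,
                 g$decision_making, g$making_self_understood,
                 g$adl_eating_perf)
  expect_equal(got, unname(want))
  expect_true(all(got >= 0 & got <= 6))
})

test_that("CPS is non-decreasing in decision-making impairment", {
  g <- record_grid(comatose = 0, memory_problem = 0:1,
                   decision_making = 0:2, making_self_understood = 0:4,
                   adl_eating_perf = 0:4)
  bumped <- g
  bumped$decision_making <- bumped$decision_making + 1
  expect_true(all(score_cps(bumped) >= score_cps(g)))
})

test_that("CPS spot values from the tree branches", {
  expect_equal(score_cps(blank_record(comatose = 1)), 6)
  expect_equal(score_cps(blank_record()), 0)
  expect_equal(score_cps(blank_record(memory_problem = 1,
                                      decision_making = 1)), 2)
  expect_equal(score_cps(blank_record(decision_making = 3)), 5)
  expect_equal(score_cps(blank_record(decision_making = 3,
                                      adl_eating_perf = 4)), 6)
})

test_that("RUG-ADL recode table reproduces hand traces and its range", {
  expect_equal(score_rug_adl(blank_record()), 4)
  rec <- blank_record(adl_bed_mobility_perf = 4, adl_bed_mobility_supp = 3,
                      adl_transfer_perf = 4, adl_transfer_supp = 3,
                      adl_toilet_use_perf = 4, adl_toilet_use_supp = 3,
                      adl_eating_perf = 4)
  expect_equal(score_rug_adl(rec), 18)
  # bed 2 -> 3; transfer 3 one-person assist -> 4; toilet 0 -> 1; eating 2 -> 2
  rec <- blank_record(adl_bed_mobility_perf = 2, adl_transfer_perf = 3,
                      adl_transfer_supp = 2, adl_toilet_use_perf = 0,
                      adl_eating_perf = 2)
  expect_equal(score_rug_adl(rec), 10)
  g <- record_grid(adl_bed_mobility_perf = c(0:4, 8),
                   adl_bed_mobility_supp = c(0:3, 8),
                   adl_eating_perf = c(0:4, 8))
  s <- score_rug_adl(g)
  expect_true(all(s >= 4 & s <= 18))
})

test_that("pain scale matches enumeration of frequency x intensity", {
  pain_oracle <- function(freq, int) {
    if (freq == 0) return(0)
    if (freq == 1) return(1)
    if (int >= 3) 3 else 2
  }
  g <- record_grid(pain_frequency = 0:2, pain_intensity = 1:3)
  expect_equal(score_pain(g),
               unname(mapply(pain_oracle, g$pain_frequency,
                             g$pain_intensity)))
  expect_equal(score_pain(blank_record(pain_frequency = 0)), 0)
  expect_equal(score_pain(blank_record(pain_frequency = 2,
                                       pain_intensity = 3)), 3)
  expect_equal(score_pain(blank_record(pain_frequency = 2,
                                       pain_intensity = 1)), 2)
})

test_that("sum scales are monotone in their items and stay in range", {
  set.seed(31)
  rec <- blank_records(200)
  for (code in adl7) rec[[code]] <- sample(c(0:4, 8), 200, replace = TRUE)
  for (code in drs7) rec[[code]] <- sample(0:2, 200, replace = TRUE)
  s <- score_adl_long_form(rec)
  expect_true(all(s >= 0 & s <= 28))
  bumped <- rec
  bumped[[adl7[3]]] <- pmin(4, ifelse(rec[[adl7[3]]] == 8, 4,
                                      rec[[adl7[3]]] + 1))
  expect_true(all(score_adl_long_form(bumped) >= s))
  d <- score_drs(rec)
  expect_true(all(d >= 0 & d <= 14))
})

test_that("dichotomy flags equal direct threshold comparisons", {
  coh <- generate_cohort(cohort_config(n_quarters = 4), seed = 2)
  s <- score_scales(exclude_comatose(coh$records))
  expect_identical(s$cps_ge3, s$cps >= 3)
  expect_identical(s$rugadl_ge11, s$rug_adl >= 11)
  expect_identical(s$abs_ge5, s$abs >= 5)
  expect_identical(s$drs_ge3, s$drs >= 3)
  # missing score gives missing flag
  rec <- blank_record(decision_making = NA)
  sc <- score_scales(rec)
  expect_true(is.na(sc$cps) && is.na(sc$cps_ge3))
})
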