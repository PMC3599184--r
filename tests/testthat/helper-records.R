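# In-code fixtures: a minimal valid record and grid builders used across
# the rule/scale tests.

test_dict <- rai_dictionary()

# One fully-coded, internally consistent record; override any column via ...
blank_record <- function(..., dict = test_dict) {
  rec <- tibble::tibble(
    person_id = "P1", facility_id = "F1", sector = "CCC",
    assessment_type = "quarterly",
    reference_date = as.Date("2006-05-10"),
    signoff_date = as.Date("2006-05-12"),
    birthdate = as.Date("1930-06-15"))
  for (code in dict$items$code) rec[[code]] <- 0
  rec$height_cm <- 165
  rec$weight_kg <- 70
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

# n copies of the blank record with distinct person ids and dates
blank_records <- function(n, dict = test_dict) {
  rec <- blank_record(dict = dict)[rep(1, n), ]
  rec$person_id <- sprintf("P%03d", seq_len(n))
  rec
}

# expand.grid over item values, one record per combination
record_grid <- function(..., dict = test_dict) {
  g <- expand.grid(..., stringsAsFactors = FALSE)
  rec <- blank_records(nrow(g), dict = dict)
  for (nm in names(g)) rec[[nm]] <- g[[nm]]
  rec
}

# small random-but-valid cohort for IO round-trips
random_records <- function(n, seed = 42, dict = test_dict) {
  set.seed(seed)
  rec <- blank_records(n, dict = dict)
  rec$person_id <- sprintf("P%02d", sample.int(max(2, n %/% 3), n,
                                               replace = TRUE))
  rec$sector <- sample(c("CCC", "LTC"), n, replace = TRUE)
  rec$reference_date <- as.Date("2006-01-01") + sample.int(1000, n)
  for (i in seq_len(nrow(dict$items))) {
    row <- dict$items[i, ]
    vals <- if (row$type == "int") {
      sample(seq(row$min, min(row$max, row$min + 6)), n, replace = TRUE)
    } else {
      round(stats::runif(n, row$min + 10, row$max - 10), 1)
    }
    vals[sample.int(n, n %/% 10)] <- NA # sprinkle missingness
    rec[[row$code]] <- vals
  }
  # keep the (person, sector, date) key unique
  rec[!duplicated(paste(rec$person_id, rec$sector, rec$reference_date)), ]
}
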