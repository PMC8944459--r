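day0 <- as.Date("2020-01-01")

test_that("consecutive-day counts restart after gaps", {
  expect_identical(consecutive_days(day0 + 2)$run_day, 1L)
  expect_identical(consecutive_days(day0 + c(0, 1, 2, 4))$run_day, c(1L, 2L, 3L, 1L))
  # a one-day grace bridges a single missing day
  expect_identical(
    consecutive_days(day0 + c(0, 1, 2, 4), grace = 1)$run_day,
    1:4
  )
})

test_that("consecutive-day counts agree with a brute-force scan", {
  withr::local_seed(11)
  for (i in 1:25) {
    dates <- day0 + sample.int(40, sample(1:15, 1))
    expect_identical(
      consecutive_days(dates)$run_day,
      run_length_oracle(dates)
    )
  }
})

test_that("therapy records combine per-drug and overall run counts", {
  adm <- tibble::tibble(
    patient_id = "p1",
    drug = c("drugA", "drugA", "drugB", "drugB"),
    date = day0 + c(0, 1, 1, 2)
  )
  rec <- build_therapy_records(adm)
  # overall therapy spans the union of days 0,1,2
  expect_identical(rec$overall_days, 1:3)
  expect_identical(rec$drugA, c(1L, 2L, 0L))
  expect_identical(rec$drugB, c(0L, 1L, 2L))

  single <- build_therapy_records(tibble::tibble(
    patient_id = "p2", drug = "drugA", date = day0
  ), vocabulary = c("drugA", "drugB"))
  expect_identical(single$overall_days, 1L)
  expect_identical(single$drugA, 1L)
  expect_identical(single$drugB, 0L)
})

test_that("a 90-drug vocabulary yields 91-column patterns", {
  adm <- tibble::tibble(
    patient_id = "p1", drug = default_drug_vocabulary()[1], date = day0
  )
  rec <- build_therapy_records(adm, vocabulary = default_drug_vocabulary())
  expect_length(attr(rec, "pattern_cols"), 91)
  expect_error(
    build_therapy_records(
      tibble::tibble(patient_id = "p", drug = "notadrug", date = day0),
      vocabulary = default_drug_vocabulary()
    ),
    "notadrug"
  )
})

test_that("monitoring records bucket by hour and aggregate within the hour", {
  rd <- tibble::tibble(
    patient_id = "p1",
    timestamp = as.POSIXct("2020-01-01 10:00:00", tz = "UTC") +
      c(0, 1800, 3600),
    parameter = "heart_rate",
    value = c(80, 90, 101)
  )
  rec <- build_monitoring_records(rd, schema = c("heart_rate", "spo2"))
  expect_equal(nrow(rec), 2) # hours 10 and 11 only; empty hours emit nothing
  expect_equal(rec$heart_rate, c(85, 101)) # median of 80,90; then the lone 101
  expect_true(all(is.na(rec$spo2))) # in schema but never measured
  expect_identical(attr(rec, "pattern_cols"), c("heart_rate", "spo2"))

  last <- build_monitoring_records(rd,
    schema = c("heart_rate", "spo2"),
    aggregator = "last"
  )
  expect_equal(last$heart_rate, c(90, 101))

  expect_error(
    build_monitoring_records(
      dplyr::mutate(rd, parameter = "unknown_thing"),
      schema = c("heart_rate")
    ),
    "unknown_thing"
  )
  full <- build_monitoring_records(rd, schema = default_monitoring_schema()$parameter)
  expect_length(attr(full, "pattern_cols"), 46)
})

test_that("normalization fuzzifies values and maps absences to code 0", {
  d_days <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
  d_hr <- fuzzy_domain(40, 140, 85, 6)
  therapy <- tibble::tibble(
    patient_id = "p1", date = day0, overall_days = 1L, drugA = 0L
  )
  attr(therapy, "pattern_cols") <- c("overall_days", "drugA")
  norm <- normalize_records(therapy, list(overall_days = d_days),
    zero_as_missing = TRUE
  )
  expect_identical(norm$drugA, 0L) # drug never given: no domain needed
  expect_identical(norm$overall_days, 1L)

  long_course <- dplyr::mutate(therapy, overall_days = 25L)
  attr(long_course, "pattern_cols") <- c("overall_days", "drugA")
  norm25 <- normalize_records(long_course, list(overall_days = d_days),
    zero_as_missing = TRUE
  )
  expect_identical(norm25$overall_days, 5L) # beyond VHH -> ultra-long

  mon <- tibble::tibble(
    patient_id = "p1", date = day0, hour = 3L,
    heart_rate = 85, spo2 = NA_real_
  )
  attr(mon, "pattern_cols") <- c("heart_rate", "spo2")
  normm <- normalize_records(mon, list(heart_rate = d_hr))
  expect_identical(normm$heart_rate, 3L) # at the medium peak
  expect_identical(normm$spo2, 0L)

  bad <- dplyr::mutate(mon, spo2 = 97)
  attr(bad, "pattern_cols") <- c("heart_rate", "spo2")
  expect_error(normalize_records(bad, list(heart_rate = d_hr)), "spo2")
})

test_that("dedup collapses exact duplicates and keeps the back-map consistent", {
  pats <- tibble::tibble(a = c(1L, 2L, 1L), b = c(2L, 1L, 2L))
  up <- dedup_patterns(pats)
  expect_equal(nrow(up$patterns), 2)
  expect_equal(sort(up$patterns$multiplicity, decreasing = TRUE), c(2, 1))
  expect_equal(sum(up$patterns$multiplicity), nrow(pats))

  same <- tibble::tibble(a = rep(3L, 5), b = rep(1L, 5))
  up1 <- dedup_patterns(same)
  expect_equal(nrow(up1$patterns), 1)
  expect_equal(up1$patterns$multiplicity, 5)
})

test_that("stored unique patterns are pairwise distinct under Euclidean distance", {
  withr::local_seed(99)
  for (i in 1:10) {
    pats <- tibble::as_tibble(random_pattern_matrix(40, 3), .name_repair = "unique")
    up <- dedup_patterns(pats)
    expect_lte(nrow(up$patterns), nrow(pats))
    codes <- as.matrix(up$patterns[, -(1:2)])
    if (nrow(codes) > 1) {
      expect_true(all(stats::dist(codes) > 0))
    }
    # expanding by the back-map recovers the record multiset
    rebuilt <- codes[up$map, , drop = FALSE]
    expect_true(all(rebuilt == as.matrix(pats)))
  }
})

test_that("normalize-then-dedup is invariant to input row order", {
  withr::local_seed(5)
  mat <- random_pattern_matrix(30, 4)
  pats <- tibble::as_tibble(mat, .name_repair = "unique")
  up1 <- dedup_patterns(pats)
  up2 <- dedup_patterns(pats[sample.int(30), ])
  expect_equal(up1$patterns, up2$patterns)
})
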