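day0 <- as.Date("2021-03-01")

make_labels <- function() {
  therapy <- tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    date = c(day0, day0 + 1, day0),
    cluster = c(0L, 2L, 1L)
  )
  monitoring <- tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2", "p3"),
    date = c(day0, day0, day0 + 1, day0, day0),
    hour = c(0L, 5L, 23L, 12L, 2L),
    cluster = c(0L, 3L, 1L, 2L, 0L)
  )
  list(therapy = therapy, monitoring = monitoring)
}

test_that("stay table keeps treated patient-days and marks absent hours 0", {
  lb <- make_labels()
  st <- build_stay_table(lb$therapy, lb$monitoring)
  expect_equal(nrow(st), 3) # p3 has monitoring but no therapy: excluded
  expect_false("p3" %in% st$patient_id)
  hours <- sprintf("h%02d", 0:23)
  # hourly cells are monitoring cluster + 1, so cluster 0 stays distinguishable
  p1d1 <- st[st$patient_id == "p1" & st$date == day0, ]
  expect_equal(p1d1$h00, 1L)
  expect_equal(p1d1$h05, 4L)
  expect_equal(sum(p1d1[hours] > 0), 2)
  # total monitored cells = monitoring records on treated days
  expect_equal(sum(st[hours] > 0), 4)
  expect_equal(st$therapy_cluster, c(0L, 2L, 1L))
})

test_that("subset frequencies count codes 1-5 within each cluster", {
  pats <- tibble::tibble(a = c(1L, 2L, 3L), b = c(2L, 2L, 3L))
  freq <- subset_frequencies(c(0L, 0L, 1L), pats)
  c0 <- freq[freq$cluster == 0, ]
  expect_equal(c0$n_patterns, 2)
  expect_equal(c0$n_nonnull, 4)
  expect_equal(c0$F1, 0.25) # codes 1,2,2,2 across the two member patterns
  expect_equal(c0$F2, 0.75)
  c1 <- freq[freq$cluster == 1, ]
  expect_equal(c1$F3, 1)
  expect_equal(rowSums(freq[paste0("F", 1:5)]), rep(1, 2))
  # zeros are excluded from the non-null tally
  freq0 <- subset_frequencies(0L, tibble::tibble(a = 0L, b = 3L))
  expect_equal(freq0$n_nonnull, 1)
})

test_that("contingency table counts monitored hours and normalizes to the grand total", {
  lb <- make_labels()
  st <- build_stay_table(lb$therapy, lb$monitoring)
  ct <- contingency_table(st)
  expect_equal(sum(ct$freq), 1, tolerance = 1e-9)
  # manual tally: (T0,M0), (T0,M3), (T2,M1), (T1,M2) each once
  expect_equal(nrow(ct), 4)
  expect_true(all(ct$n == 1))
  expect_true(all(ct$freq == 0.25))
  counts <- attr(ct, "counts")
  expect_equal(sum(counts), 4)
  expect_error(contingency_table(st[0, ]), "empty")
})

test_that("chi-square matches the textbook formula and its invariances", {
  res <- chi_square(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 400 / 60, tolerance = 1e-9) # hand: n(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(res$dof, 1)

  same_rows <- matrix(c(5, 5, 10, 10, 15, 15), nrow = 2)
  expect_equal(chi_square(same_rows)$statistic, 0)

  m <- matrix(c(12, 7, 3, 9, 14, 6), nrow = 2)
  perm <- m[2:1, c(2, 3, 1)]
  expect_equal(chi_square(m)$statistic, chi_square(perm)$statistic)

  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "zero marginal")
})

test_that("chi-square agrees with an independent implementation on random tables", {
  withr::local_seed(77)
  for (i in 1:100) {
    m <- matrix(sample(1:80, 12, replace = TRUE), nrow = sample(2:4, 1))
    expect_equal(chi_square(m)$statistic, chisq_oracle(m), tolerance = 1e-9)
  }
})

test_that("Nabtcl stratification counts distinct therapy clusters per stay", {
  therapy <- tibble::tibble(
    patient_id = rep(c("a", "b"), each = 4),
    date = rep(day0 + 0:3, 2),
    cluster = c(1L, 1L, 1L, 1L, 0L, 2L, 0L, 3L)
  )
  monitoring <- tibble::tibble(
    patient_id = "a", date = day0, hour = 0:5, cluster = rep(0:2, 2)
  )
  st <- build_stay_table(therapy, monitoring)
  nab <- nabtcl_summary(st)
  expect_equal(sort(nab$strata$nabtcl), c(1, 3)) # constant stay vs {0,2,3}
  expect_equal(sum(nab$strata$n_stays), 2)
  expect_lte(max(nab$strata$nabtcl), 4)
  # stratum frequencies are conditional distributions
  sums <- tapply(nab$therapy_by_stratum$freq, nab$therapy_by_stratum$nabtcl, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)))
  expect_equal(sum(nab$strata$n_hours), 6)

  codes <- tibble::tibble(
    patient_id = therapy$patient_id, date = therapy$date,
    code = c(1L, 2L, 3L, 4L, 5L, 5L, 1L, 2L)
  )
  nab2 <- nabtcl_summary(st, codes)
  dsum <- tapply(nab2$duration_by_stratum$freq, nab2$duration_by_stratum$nabtcl, sum)
  expect_equal(as.vector(dsum), rep(1, length(dsum)))
})

test_that("stay charts render windows of paired bars and reject bad requests", {
  therapy <- tibble::tibble(
    patient_id = "p1", date = day0 + 0:1, cluster = c(1L, 2L)
  )
  monitoring <- tibble::tibble(
    patient_id = "p1",
    date = rep(day0 + 0:1, each = 12),
    hour = rep(0:11, 2),
    cluster = rep(0:3, 6)
  )
  st <- build_stay_table(therapy, monitoring)
  plt <- stay_chart(st, "p1", window = 14)
  expect_s3_class(plt, "ggplot")
  built <- ggplot2::ggplot_build(plt)
  expect_equal(nrow(built$data[[1]]), 28) # 14 hours x two bars
  expect_error(stay_chart(st, "nobody"), "unknown patient")

  empty_mon <- tibble::tibble(
    patient_id = character(), date = as.Date(character()),
    hour = integer(), cluster = integer()
  )
  st_empty <- build_stay_table(therapy, empty_mon)
  expect_error(stay_chart(st_empty, "p1"), "no monitored hours")
})
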