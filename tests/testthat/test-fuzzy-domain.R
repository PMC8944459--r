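test_that("upper trim keeps the smallest value set reaching the coverage target", {
  # frequencies engineered so the 95% cumulative mark falls on value 22
  x <- c(rep(1:22, each = 43), rep(23:30, each = 6))
  tt <- trim_values(x, mode = "upper")
  expect_equal(tt$m, 1)
  expect_equal(tt$M, 22)
  expect_gte(tt$coverage, 0.95)
  expect_true(all(tt$value_frequencies$value >= tt$m &
    tt$value_frequencies$value <= tt$M))
  expect_equal(sum(tt$value_frequencies$count), tt$n_retained)
})

test_that("central trim cuts at observed values on both tails", {
  tt <- trim_values(1:200, mode = "central")
  expect_equal(tt$m, 5) # cumulative count first reaches 2.5% of 200 at value 5
  expect_equal(tt$M, 195) # and 97.5% at value 195
  expect_gte(tt$coverage, 0.95)
  expect_equal(tt$median_t, 100)
})

test_that("trim handles constant and empty input", {
  tt <- trim_values(rep(7, 100), mode = "central")
  expect_equal(tt$m, 7)
  expect_equal(tt$M, 7)
  expect_equal(tt$coverage, 1)
  expect_true(tt$degenerate)
  expect_error(trim_values(numeric(0)), "no observations")
  expect_error(domain_from_values(rep(7, 100)), "degenerate range")
})

test_that("domain construction reproduces the therapy-days reference limits", {
  d <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
  printed <- c(
    VLL = -1.8, LL = 1.8, VLH = 3.6, NL = 7.3, LH = 9.1,
    HL = 12.8, NH = 14.6, VHL = 18.3, HH = 20.2, VHH = 23.8
  )
  expect_equal(d$limits[names(printed)], printed, tolerance = 0.1)
  # exact closed forms
  expect_equal(unname(d$limits), c(
    -1.8, 1.8, 3.6, 11 - 22 / 6, 11 - 22 / 6 + 1.8,
    11 + 22 / 6 - 1.8, 11 + 22 / 6, 18.4, 20.2, 23.8
  ))
})

test_that("a symmetric construction is symmetric about its median", {
  d <- fuzzy_domain(0, 6, 3, 0.5)
  expect_equal(unname(d$limits[c("NL", "NH", "VLL", "VHH")]), c(2, 4, -0.5, 6.5))
  expect_equal(unname(d$limits + rev(d$limits)), rep(6, 10))
})

test_that("an asymmetric construction matches the closed forms evaluated by hand", {
  d <- fuzzy_domain(10, 70, 30, 5)
  expect_equal(unname(d$limits), c(5, 15, 20, 20, 25, 35, 40, 60, 65, 75))
  # NL coincides with VLH here: the shoulder is exactly tangent to the triangle
  expect_equal(unname(d$limits[c("NL", "LH", "NH", "HL")]), c(20, 25, 40, 35))
})

test_that("invalid geometry is rejected", {
  expect_error(fuzzy_domain(0, 6, 3, 1.2), "overlap too wide")
  expect_error(fuzzy_domain(5, 5, 5, 0.1), "degenerate range")
  expect_error(fuzzy_domain(0, 6, 7, 0.5), "median_t")
  expect_error(fuzzy_domain(0, 60, 2, 5), "not strictly increasing")
})

test_that("membership matches hand-evaluated piecewise forms", {
  d <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
  l <- d$limits
  mu <- membership(d, c(25, l[["LL"]], 11, 2.4, -5))
  expect_equal(mu$mu5[1], 1) # beyond VHH: fully very-high
  expect_equal(mu$mu1[2], 1) # at LL: trapezoid still at plateau edge
  expect_equal(mu$mu2[2], 0) # triangle foot
  expect_equal(mu$mu3[3], 1) # medium peak at the median
  expect_equal(mu$mu2[3], 0)
  expect_equal(mu$mu4[3], 0)
  expect_equal(mu$mu1[4], (3.6 - 2.4) / 1.8) # on the F1 descending flank
  expect_equal(mu$mu1[5], 1) # clamped below VLL
  expect_error(membership(d, Inf), "finite")
})

test_that("fuzzify applies the argmax rule with missing, clamping and ties", {
  d <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
  expect_identical(fuzzify(d, NA), 0L)
  expect_identical(fuzzify(d, -5), 1L) # at/below VLL -> category 1
  expect_identical(fuzzify(d, 25), 5L) # at/over VHH -> category 5
  expect_identical(fuzzify(d, 2.4), 1L) # mu1 ~ 0.67 > 0.5 in the F1/F2 overlap
  # exactly representable crossing: mu1 = mu2 = 0.5, lower category wins
  d_tie <- fuzzy_domain(0, 12, 4, 1)
  mu <- membership(d_tie, 1.5)
  expect_identical(mu$mu1, mu$mu2)
  expect_identical(fuzzify(d_tie, 1.5), 1L)
})

test_that("random valid domains satisfy the geometric and membership invariants", {
  withr::local_seed(421)
  for (i in 1:60) {
    p <- random_domain_params()
    d <- fuzzy_domain(p$m, p$M, p$median_t, p$h)
    expect_true(all(diff(d$limits) > 0))
    l <- d$limits
    overlaps <- c(
      l[["VLH"]] - l[["LL"]], l[["LH"]] - l[["NL"]],
      l[["NH"]] - l[["HL"]], l[["HH"]] - l[["VHL"]]
    )
    expect_equal(unname(overlaps), rep(p$h, 4), tolerance = 1e-9)
    expect_equal((l[["NL"]] + l[["NH"]]) / 2, p$median_t)

    grid <- seq(l[["VLL"]] - p$h, l[["VHH"]] + p$h, length.out = 400)
    mu <- as.matrix(membership(d, grid)[, -1])
    expect_true(all(mu >= 0 & mu <= 1))
    expect_true(all(rowSums(mu > 1e-12) <= 2)) # subsets overlap pairwise only
    expect_true(all(rowSums(mu) > 0)) # total coverage of the real line
    # category sweep shows exactly the five plateaus, in order
    codes <- fuzzify(d, grid)
    expect_identical(unique(rle(codes)$values), 1:5)
  }
})

test_that("domains survive a JSON round trip", {
  d <- domain_from_values(rnorm(500, 80, 12),
    parameter_id = "heart_rate"
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_domains(list(heart_rate = d), path)
  d2 <- read_domains(path)[["heart_rate"]]
  expect_equal(d2$limits, d$limits)
  expect_equal(d2$labels, d$labels)
  expect_equal(d2$h, d$h)
})

test_that("domain charts render the five shapes with positive area", {
  d <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
  plt <- autoplot(d)
  expect_s3_class(plt, "ggplot")
  grid <- seq(d$limits[["VLL"]], d$limits[["VHH"]], length.out = 2000)
  mu <- as.matrix(membership(d, grid)[, -1])
  areas <- colSums(mu) * diff(grid[1:2]) # numeric integration oracle
  expect_true(all(areas > 0))
  expect_error(plot_domain(list(limits = 1:10)))
})
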