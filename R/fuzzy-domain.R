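#' Linguistic labels for the five fuzzy subsets
#'
#' Two vocabularies are used: bedside monitoring parameters are described as
#' "very low" through "very high", while therapy durations (in days) use
#' "ultra-short" through "ultra-long". Code 0 ("none") is reserved for absent
#' data and is never produced from a numeric value.
#'
#' @return A character vector of five subset labels, ordered F1 to F5.
#' @export
#' @examples
#' monitoring_labels()
#' therapy_labels()
monitoring_labels <- function() {
  c("very low", "low", "medium", "high", "very high")
}

#' @rdname monitoring_labels
#' @export
therapy_labels <- function() {
  c("ultra-short", "short", "medium", "long", "ultra-long")
}

#' Trim a distribution to the values covering at least 95% of observations
#'
#' Builds the "95% table" for one parameter: the smallest set of observed
#' values, cut at observed values only (never interpolated), whose cumulative
#' frequencies reach the coverage target. Two trim modes are supported:
#' `"upper"` removes only the upper tail (appropriate for nonnegative
#' duration-like variables whose minimum is meaningful), while `"central"`
#' removes `(1 - coverage)/2` from each tail (appropriate for vitals). The
#' cutoffs are the smallest observed values at which the cumulative frequency
#' reaches the tail / coverage thresholds, so realised coverage is always at
#' least the target.
#'
#' @param x Numeric vector of raw observations; `NA`s are dropped.
#' @param mode `"upper"` or `"central"`.
#' @param coverage Minimum fraction of observations to retain (default 0.95).
#' @param parameter_id Optional name carried through to the result.
#'
#' @return An object of class `trimmed_table`: a list with elements
#'   `parameter_id`, `m` (trimmed minimum), `M` (trimmed maximum), `median_t`
#'   and `sd_t` (median and standard deviation of the retained values),
#'   `coverage` (realised fraction retained), `n_total`, `n_retained`,
#'   `degenerate` (`TRUE` when `m == M`, e.g. constant input), `mode`, and
#'   `value_frequencies` (a tibble of `value`, `count` for retained values).
#' @export
#' @examples
#' tt <- trim_values(c(rep(1:20, 10), 50, 90), mode = "upper")
#' tt$M
trim_values <- function(x, mode = c("central", "upper"), coverage = 0.95,
                        parameter_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(coverage), length(coverage) == 1, coverage > 0, coverage <= 1)
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop("no observations", call. = FALSE)
  }
  n <- length(x)
  vals <- sort(unique(x))
  counts <- as.integer(table(factor(x, levels = vals)))
  cum <- cumsum(counts)

  tol <- 1e-8 * n # guards the >= comparisons against fp error in the thresholds
  if (mode == "upper") {
    lo_idx <- 1L
    hi_idx <- which(cum >= coverage * n - tol)[1]
  } else {
    tail_n <- (1 - coverage) / 2 * n
    lo_idx <- which(cum >= tail_n - tol)[1]
    hi_idx <- which(cum >= (1 - (1 - coverage) / 2) * n - tol)[1]
  }
  m <- vals[lo_idx]
  M <- vals[hi_idx]

  kept <- x[x >= m & x <= M]
  degenerate <- isTRUE(m == M)
  structure(
    list(
      parameter_id = parameter_id,
      m = m,
      M = M,
      median_t = stats::median(kept),
      sd_t = if (length(kept) > 1) stats::sd(kept) else 0,
      coverage = length(kept) / n,
      n_total = n,
      n_retained = length(kept),
      degenerate = degenerate,
      mode = mode,
      value_frequencies = tibble::tibble(
        value = vals[lo_idx:hi_idx],
        count = counts[lo_idx:hi_idx]
      )
    ),
    class = "trimmed_table"
  )
}

#' @export
print.trimmed_table <- function(x, ...) {
  cat(sprintf(
    "<trimmed_table%s> mode=%s  m=%g  M=%g  median=%g  sd=%g  coverage=%.3f (%d/%d)\n",
    if (is.null(x$parameter_id)) "" else paste0(" ", x$parameter_id),
    x$mode, x$m, x$M, x$median_t, x$sd_t, x$coverage, x$n_retained, x$n_total
  ))
  invisible(x)
}

#' Construct a fuzzy domain from trimmed-range statistics
#'
#' A fuzzy domain partitions one parameter's range into five linguistic
#' subsets F1..F5: two trapezoidal shoulders at the extremes and three
#' triangular subsets in between, each adjacent pair overlapping by a band of
#' width `h`. The geometry is fully determined by the trimmed minimum `m`,
#' trimmed maximum `M`, trimmed median `median_t` and the overlap width `h`
#' (conventionally half the standard deviation of the trimmed sample):
#'
#' \deqn{VLL = m - h,\; LL = m + h,\; VLH = m + 2h}
#' \deqn{NL = median_t - (M-m)/6,\; NH = median_t + (M-m)/6}
#' \deqn{LH = NL + h,\; HL = NH - h}
#' \deqn{VHL = M - 2h,\; HH = M - h,\; VHH = M + h}
#'
#' The medium triangle is centred on the trimmed median
#' (`(NL + NH)/2 == median_t`), and the four overlap bands
#' `[LL, VLH]`, `[NL, LH]`, `[HL, NH]`, `[VHL, HH]` all have width `h`.
#'
#' @param m,M Trimmed minimum and maximum (parameter units); `m < M`.
#' @param median_t Median of the trimmed sample; `m <= median_t <= M`.
#' @param h Overlap width in parameter units; `0 < h < (M - m)/6`.
#' @param labels Character vector of five subset labels
#'   (default [monitoring_labels()]).
#' @param parameter_id Optional parameter name.
#' @param sd_t Optional standard deviation of the trimmed sample, stored for
#'   provenance.
#'
#' @return An object of class `fuzzy_domain`: a list with `parameter_id`,
#'   `labels`, `m`, `M`, `median_t`, `sd_t`, `h`, and `limits` (named numeric
#'   vector `VLL, LL, VLH, NL, LH, HL, NH, VHL, HH, VHH`, strictly increasing).
#' @seealso [domain_from_values()], [membership()], [fuzzify()]
#' @export
#' @examples
#' d <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
#' d$limits
fuzzy_domain <- function(m, M, median_t, h, labels = monitoring_labels(),
                         parameter_id = NULL, sd_t = NULL) {
  stopifnot(is.numeric(m), is.numeric(M), is.numeric(median_t), is.numeric(h))
  if (!is.character(labels) || length(labels) != 5) {
    stop("`labels` must be five subset names", call. = FALSE)
  }
  if (m >= M) stop("degenerate range", call. = FALSE)
  if (median_t < m || median_t > M) {
    stop("`median_t` must lie in [m, M]", call. = FALSE)
  }
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  if (h >= (M - m) / 6) stop("overlap too wide for range", call. = FALSE)

  third <- (M - m) / 6
  limits <- c(
    VLL = m - h,
    LL  = m + h,
    VLH = m + 2 * h,
    NL  = median_t - third,
    LH  = median_t - third + h,
    HL  = median_t + third - h,
    NH  = median_t + third,
    VHL = M - 2 * h,
    HH  = M - h,
    VHH = M + h
  )
  # ties are admissible only where a shoulder meets the medium triangle
  # (VLH == NL or NH == VHL, the tangent case); anywhere else the geometry
  # is inverted
  strict <- diff(limits) <= 0
  strict[c(3, 7)] <- diff(limits)[c(3, 7)] < 0
  if (any(strict)) {
    stop(
      "domain limits are not strictly increasing; the median is too close ",
      "to the range edge for this overlap width",
      call. = FALSE
    )
  }
  structure(
    list(
      parameter_id = parameter_id,
      labels = labels,
      m = m, M = M, median_t = median_t, sd_t = sd_t, h = h,
      limits = limits
    ),
    class = "fuzzy_domain"
  )
}

#' Build a fuzzy domain directly from raw observations
#'
#' Convenience wrapper: trims the observations with [trim_values()] and
#' constructs the domain with [fuzzy_domain()], setting the overlap width
#' from the trimmed sample's standard deviation (`h = sd_t / 2`) unless a
#' fixed overlap is supplied.
#'
#' @inheritParams trim_values
#' @inheritParams fuzzy_domain
#' @param overlap `"half_sd"` (default) or a fixed positive number in
#'   parameter units.
#' @return A `fuzzy_domain`.
#' @export
#' @examples
#' set.seed(1)
#' domain_from_values(rnorm(1000, 80, 12), parameter_id = "heart_rate")
domain_from_values <- function(x, mode = c("central", "upper"), coverage = 0.95,
                               overlap = "half_sd", labels = monitoring_labels(),
                               parameter_id = NULL) {
  tt <- trim_values(x, mode = mode, coverage = coverage, parameter_id = parameter_id)
  if (tt$degenerate) {
    stop("degenerate range", call. = FALSE)
  }
  h <- if (identical(overlap, "half_sd")) tt$sd_t / 2 else as.numeric(overlap)
  fuzzy_domain(tt$m, tt$M, tt$median_t, h,
    labels = labels, parameter_id = parameter_id, sd_t = tt$sd_t
  )
}

#' @export
print.fuzzy_domain <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_domain%s> m=%g M=%g median=%g h=%g\n",
    if (is.null(x$parameter_id)) "" else paste0(" ", x$parameter_id),
    x$m, x$M, x$median_t, x$h
  ))
  print(round(x$limits, 3))
  invisible(x)
}

# Membership degree of x in each of the five subsets; x numeric vector,
# returns an n x 5 matrix. Shapes: F1 left shoulder (plateau below LL, falling
# on [LL, VLH]); F2/F3/F4 symmetric triangles on [LL, LH], [NL, NH], [HL, HH];
# F5 right shoulder (rising on [VHL, HH], plateau above HH).
membership_matrix <- function(domain, x) {
  stopifnot(inherits(domain, "fuzzy_domain"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  l <- domain$limits
  tri <- function(x, lo, hi) {
    peak <- (lo + hi) / 2
    up <- (x - lo) / (peak - lo)
    down <- (hi - x) / (hi - peak)
    pmax(0, pmin(up, down))
  }
  mu <- cbind(
    mu1 = pmin(1, pmax(0, (l[["VLH"]] - x) / (l[["VLH"]] - l[["LL"]]))),
    mu2 = tri(x, l[["LL"]], l[["LH"]]),
    mu3 = tri(x, l[["NL"]], l[["NH"]]),
    mu4 = tri(x, l[["HL"]], l[["HH"]]),
    mu5 = pmin(1, pmax(0, (x - l[["VHL"]]) / (l[["HH"]] - l[["VHL"]])))
  )
  rownames(mu) <- NULL
  mu
}

#' Membership degrees of values in a fuzzy domain
#'
#' Computes the degree (0 to 1) to which each value belongs to each of the
#' five subsets. Values at or below `LL` are fully "very low" (`mu1 = 1`);
#' values at or above `HH` are fully "very high" (`mu5 = 1`); inputs outside
#' `[VLL, VHH]` clamp to the corresponding shoulder. At most two degrees are
#' positive at any value, because subsets overlap only pairwise.
#'
#' @param domain A [fuzzy_domain()].
#' @param x Finite numeric vector.
#' @return A tibble with one row per value: `x`, `mu1` .. `mu5`.
#' @export
#' @examples
#' d <- fuzzy_domain(0, 22, 11, 1.8)
#' membership(d, c(2.4, 11, 25))
membership <- function(domain, x) {
  mu <- membership_matrix(domain, x)
  tibble::as_tibble(cbind(x = x, mu))
}

#' Assign values to a single fuzzy category
#'
#' Defuzzifies each value to the integer code of the subset with the highest
#' membership degree (ties broken toward the lower category). This reproduces
#' the assignment rule "take the subset whose membership exceeds 0.5"
#' wherever such a subset exists, and extends it deterministically at exact
#' crossing points. Missing values map to code 0 ("none"); no numeric value
#' ever maps to 0.
#'
#' @inheritParams membership
#' @param x Numeric vector; `NA` allowed.
#' @return Integer vector of codes in `0:5`.
#' @export
#' @examples
#' d <- fuzzy_domain(0, 22, 11, 1.8, labels = therapy_labels())
#' fuzzify(d, c(NA, -5, 2.4, 11, 25))
fuzzify <- function(domain, x) {
  out <- integer(length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    mu <- membership_matrix(domain, x[ok])
    out[ok] <- max.col(mu, ties.method = "first")
  }
  out
}

#' Plot the membership functions of a fuzzy domain
#'
#' Draws the five membership shapes over `[VLL, VHH]` with the four overlap
#' bands shaded.
#'
#' @param object A `fuzzy_domain`.
#' @param n Number of evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fuzzy_domain
#' @export
autoplot.fuzzy_domain <- function(object, n = 512, ...) {
  l <- object$limits
  grid <- seq(l[["VLL"]], l[["VHH"]], length.out = n)
  mu <- membership_matrix(object, grid)
  df <- tibble::tibble(
    x = rep(grid, 5),
    degree = as.vector(mu),
    subset = factor(
      rep(paste0("F", 1:5, ": ", object$labels), each = n),
      levels = paste0("F", 1:5, ": ", object$labels)
    )
  )
  overlaps <- tibble::tibble(
    xmin = l[c("LL", "NL", "HL", "VHL")],
    xmax = l[c("VLH", "LH", "NH", "HH")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$degree)) +
    ggplot2::geom_rect(
      data = overlaps,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 0, ymax = 1),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$subset), linewidth = 0.8) +
    ggplot2::labs(
      x = if (is.null(object$parameter_id)) "value" else object$parameter_id,
      y = "membership degree", colour = NULL,
      title = "Fuzzy domain"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fuzzy_domain
#' @param domain A `fuzzy_domain`.
#' @export
plot_domain <- function(domain, n = 512) {
  autoplot(domain, n = n)
}

#' Read and write fuzzy domains as JSON
#'
#' Domains serialize to a JSON array of objects with keys `parameter_id`,
#' `labels`, `m`, `M`, `median_t`, `sd_t`, `h` and `limits`.
#'
#' @param domains A `fuzzy_domain` or a (possibly named) list of them.
#' @param path File path.
#' @return `write_domains()` returns `path` invisibly; `read_domains()`
#'   returns a named list of `fuzzy_domain` objects.
#' @export
write_domains <- function(domains, path) {
  if (inherits(domains, "fuzzy_domain")) domains <- list(domains)
  payload <- purrr::map(domains, function(d) {
    list(
      parameter_id = d$parameter_id, labels = d$labels,
      m = d$m, M = d$M, median_t = d$median_t, sd_t = d$sd_t, h = d$h,
      limits = as.list(d$limits)
    )
  })
  jsonlite::write_json(unname(payload), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_domains
#' @export
read_domains <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- purrr::map(raw, function(d) {
    fuzzy_domain(
      m = d$m, M = d$M, median_t = d$median_t, h = d$h,
      labels = unlist(d$labels),
      parameter_id = d$parameter_id, sd_t = d$sd_t
    )
  })
  names(out) <- purrr::map_chr(out, function(d) d$parameter_id %||% NA_character_)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
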