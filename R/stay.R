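#' Per-stay synoptic table of therapy and monitoring clusters
#'
#' One row per treated patient-day: the day's therapy cluster and 24 hourly
#' cells holding the monitoring cluster of each clock hour. Hourly cells are
#' stored 1-based (`monitoring cluster id + 1`) with 0 reserved for hours
#' without monitoring, so "absent" never collides with monitoring cluster
#' M0. Only patient-days with a therapy label are retained (the analysis
#' population is treated patients); rows are chronologically ordered within
#' patient.
#'
#' @param therapy_labels Tibble with `patient_id`, `date`, `cluster`
#'   (0-based therapy cluster ids), e.g. from [assign_clusters()].
#' @param monitoring_labels Tibble with `patient_id`, `date`, `hour`,
#'   `cluster` (0-based monitoring cluster ids).
#' @return An object of class `stay_table`: a tibble with `patient_id`,
#'   `date`, `therapy_cluster`, and `h00` .. `h23`.
#' @export
build_stay_table <- function(therapy_labels, monitoring_labels) {
  stopifnot(
    all(c("patient_id", "date", "cluster") %in% names(therapy_labels)),
    all(c("patient_id", "date", "hour", "cluster") %in% names(monitoring_labels))
  )
  hours <- sprintf("h%02d", 0:23)
  mon <- monitoring_labels |>
    dplyr::mutate(
      hour_col = factor(sprintf("h%02d", .data$hour), levels = hours),
      cell = .data$cluster + 1L
    ) |>
    dplyr::select("patient_id", "date", "hour_col", "cell") |>
    tidyr::pivot_wider(
      names_from = "hour_col", values_from = "cell",
      values_fill = 0L, names_expand = TRUE
    )
  out <- therapy_labels |>
    dplyr::select("patient_id", "date", therapy_cluster = "cluster") |>
    dplyr::left_join(mon, by = c("patient_id", "date")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(hours), ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::arrange(.data$patient_id, .data$date)
  class(out) <- c("stay_table", class(out))
  out
}

#' Distribution of fuzzy subsets within each cluster
#'
#' For every cluster, the relative frequencies of subsets F1..F5 among the
#' non-null codes (codes 1-5) of the member patterns, plus the pattern count
#' and the total number of non-null codes.
#'
#' @param labels Integer vector of 0-based cluster labels, one per pattern.
#' @param patterns The clustered patterns (tibble of codes, matrix, or a
#'   [dedup_patterns()] result whose unique patterns align with `labels`).
#' @return A tibble with `cluster`, `n_patterns`, `n_nonnull`, `F1` .. `F5`
#'   (each row of frequencies sums to 1 when `n_nonnull > 0`).
#' @export
subset_frequencies <- function(labels, patterns) {
  x <- as_pattern_matrix(patterns)
  if (length(labels) != nrow(x)) {
    stop("`labels` must align with `patterns`", call. = FALSE)
  }
  clusters <- sort(unique(labels))
  rows <- purrr::map(clusters, function(cl) {
    codes <- as.vector(x[labels == cl, , drop = FALSE])
    nn <- codes[codes >= 1 & codes <= 5]
    counts <- tabulate(nn, nbins = 5)
    freq <- if (length(nn) > 0) counts / length(nn) else rep(NA_real_, 5)
    tibble::tibble(
      cluster = cl, n_patterns = sum(labels == cl), n_nonnull = length(nn),
      F1 = freq[1], F2 = freq[2], F3 = freq[3], F4 = freq[4], F5 = freq[5]
    )
  })
  dplyr::bind_rows(rows)
}

#' Therapy-by-monitoring contingency table over monitored hours
#'
#' Counts every (therapy cluster, monitoring cluster) pair across all
#' monitored hours of the stay table (hours with no monitoring are
#' excluded: 0 marks missingness, not a cluster) and expresses each cell as
#' a fraction of the grand total, so all cells sum to 1.
#'
#' @param stay_table A [build_stay_table()] result.
#' @return An object of class `contingency_table`: a tibble with
#'   `therapy_cluster`, `monitoring_cluster`, `n` (hour count) and `freq`
#'   (fraction of the grand total), with the raw count matrix (therapy rows,
#'   monitoring columns) in attribute `counts`.
#' @export
contingency_table <- function(stay_table) {
  if (nrow(stay_table) == 0) stop("empty stay table", call. = FALSE)
  hours <- sprintf("h%02d", 0:23)
  long <- stay_table |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(hours), names_to = "hour", values_to = "cell") |>
    dplyr::filter(.data$cell > 0) |>
    dplyr::mutate(monitoring_cluster = .data$cell - 1L)
  if (nrow(long) == 0) stop("no monitored hours in stay table", call. = FALSE)
  tab <- long |>
    dplyr::count(.data$therapy_cluster, .data$monitoring_cluster) |>
    dplyr::mutate(freq = .data$n / sum(.data$n))
  counts <- tab |>
    tidyr::pivot_wider(
      id_cols = "therapy_cluster", names_from = "monitoring_cluster",
      values_from = "n", values_fill = 0L, names_sort = TRUE
    )
  counts_m <- as.matrix(counts[-1])
  rownames(counts_m) <- paste0("T", counts$therapy_cluster)
  colnames(counts_m) <- paste0("M", sort(unique(tab$monitoring_cluster)))
  attr(tab, "counts") <- counts_m
  class(tab) <- c("contingency_table", class(tab))
  tab
}

#' Pearson chi-square test of independence on a counts table
#'
#' Computed on raw counts (not on the displayed frequencies), without
#' continuity correction; degrees of freedom `(r - 1)(c - 1)`.
#'
#' @param counts A [contingency_table()] result, or a numeric matrix /
#'   data frame of counts.
#' @return A tibble with `statistic`, `dof`, `p_value`.
#' @export
#' @examples
#' chi_square(matrix(c(10, 20, 20, 10), 2))
chi_square <- function(counts) {
  if (inherits(counts, "contingency_table")) {
    counts <- attr(counts, "counts")
  }
  m <- as.matrix(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    dof = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
}

#' Stratify stays by the number of distinct therapy clusters (Nabtcl)
#'
#' Counts, per patient stay, how many distinct therapy clusters the stay
#' visits (Nabtcl), then summarises the population by stratum: stay and
#' monitored-hour counts, the distribution of therapy clusters over
#' patient-days, the distribution of monitoring clusters over monitored
#' hours, and (when overall-duration codes are supplied) the distribution of
#' the overall consecutive-days-of-therapy fuzzy subset. Within each
#' stratum the cluster frequencies are fractions of that stratum's
#' patient-days / hours, so each stratum column sums to 1.
#'
#' @param stay_table A [build_stay_table()] result.
#' @param overall_codes Optional tibble with `patient_id`, `date`, `code`
#'   (fuzzy code 1-5 of the overall therapy duration for that patient-day).
#' @return An object of class `nabtcl_summary`: list of tibbles `strata`
#'   (`nabtcl`, `n_stays`, `n_hours`), `therapy_by_stratum`,
#'   `monitoring_by_stratum`, and `duration_by_stratum` (`NULL` when
#'   `overall_codes` is absent).
#' @export
nabtcl_summary <- function(stay_table, overall_codes = NULL) {
  if (nrow(stay_table) == 0) stop("empty stay table", call. = FALSE)
  hours <- sprintf("h%02d", 0:23)
  st <- tibble::as_tibble(stay_table)
  per_stay <- st |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(nabtcl = dplyr::n_distinct(.data$therapy_cluster), .groups = "drop")
  st <- dplyr::left_join(st, per_stay, by = "patient_id")

  long_hours <- st |>
    tidyr::pivot_longer(dplyr::all_of(hours), names_to = "hour", values_to = "cell") |>
    dplyr::filter(.data$cell > 0) |>
    dplyr::mutate(monitoring_cluster = .data$cell - 1L)

  strata <- per_stay |>
    dplyr::count(.data$nabtcl, name = "n_stays") |>
    dplyr::left_join(
      dplyr::count(long_hours, .data$nabtcl, name = "n_hours"),
      by = "nabtcl"
    ) |>
    dplyr::mutate(n_hours = tidyr::replace_na(.data$n_hours, 0L))

  therapy_by_stratum <- st |>
    dplyr::count(.data$nabtcl, .data$therapy_cluster) |>
    dplyr::group_by(.data$nabtcl) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  monitoring_by_stratum <- long_hours |>
    dplyr::count(.data$nabtcl, .data$monitoring_cluster) |>
    dplyr::group_by(.data$nabtcl) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  duration_by_stratum <- NULL
  if (!is.null(overall_codes)) {
    stopifnot(all(c("patient_id", "date", "code") %in% names(overall_codes)))
    duration_by_stratum <- st |>
      dplyr::select("patient_id", "date", "nabtcl") |>
      dplyr::inner_join(overall_codes, by = c("patient_id", "date")) |>
      dplyr::filter(.data$code >= 1, .data$code <= 5) |>
      dplyr::count(.data$nabtcl, .data$code) |>
      dplyr::group_by(.data$nabtcl) |>
      dplyr::mutate(freq = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::rename(fuzzy_subset = "code")
  }

  structure(
    list(
      strata = strata,
      therapy_by_stratum = therapy_by_stratum,
      monitoring_by_stratum = monitoring_by_stratum,
      duration_by_stratum = duration_by_stratum
    ),
    class = "nabtcl_summary"
  )
}

#' @export
print.nabtcl_summary <- function(x, ...) {
  cat("<nabtcl_summary>\n")
  print(x$strata)
  invisible(x)
}

#' Paired therapy/monitoring cluster bars for one patient's stay
#'
#' The synoptic view for bedside discussion: for a window of monitored
#' hours, paired bars show the therapy cluster of the day and the
#' monitoring cluster of each hour (bar heights are the cluster ids; report
#' labels T0.., M0..).
#'
#' @param stay_table A [build_stay_table()] result.
#' @param patient A patient id present in the table.
#' @param window Maximum number of monitored hours to draw (default 14);
#'   hours are taken chronologically from the start of the stay.
#' @return A ggplot object.
#' @export
stay_chart <- function(stay_table, patient, window = 14) {
  hours <- sprintf("h%02d", 0:23)
  st <- dplyr::filter(tibble::as_tibble(stay_table), .data$patient_id == patient)
  if (nrow(st) == 0) stop("unknown patient: ", patient, call. = FALSE)
  long <- st |>
    tidyr::pivot_longer(dplyr::all_of(hours), names_to = "hour", values_to = "cell") |>
    dplyr::filter(.data$cell > 0) |>
    dplyr::arrange(.data$date, .data$hour) |>
    dplyr::slice_head(n = window)
  if (nrow(long) == 0) stop("no monitored hours in window", call. = FALSE)
  df <- long |>
    dplyr::mutate(hour_index = dplyr::row_number()) |>
    dplyr::transmute(
      .data$hour_index,
      `therapy cluster` = .data$therapy_cluster,
      `monitoring cluster` = .data$cell - 1L
    ) |>
    tidyr::pivot_longer(-"hour_index", names_to = "series", values_to = "cluster")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$hour_index, y = .data$cluster, fill = .data$series
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::scale_fill_manual(values = c(
      `therapy cluster` = "#3B6FB6", `monitoring cluster` = "#C0392B"
    )) +
    ggplot2::labs(
      title = sprintf("Cluster trajectory, patient %s", patient),
      x = "monitored hour", y = "cluster id", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Fuzzified-parameter ribbon view for one patient
#'
#' Step lines of the fuzzy codes (0-5) of selected monitoring parameters
#' over a window of hours: the qualitative data flow a clinician would scan
#' in hand-over.
#'
#' @param normalized Normalized monitoring patterns
#'   (from [normalize_records()], keys `patient_id`, `date`, `hour`).
#' @param patient A patient id present in the table.
#' @param parameters Parameter columns to draw (default: up to 6 with the
#'   most non-null codes for this patient).
#' @param window Maximum number of hours to draw (default 14).
#' @return A ggplot object.
#' @export
plot_fuzzy_ribbon <- function(normalized, patient, parameters = NULL, window = 14) {
  cols <- attr(normalized, "pattern_cols") %||%
    setdiff(names(normalized), c("patient_id", "date", "hour"))
  pt <- dplyr::filter(tibble::as_tibble(normalized), .data$patient_id == patient)
  if (nrow(pt) == 0) stop("unknown patient: ", patient, call. = FALSE)
  pt <- pt |>
    dplyr::arrange(.data$date, .data$hour) |>
    dplyr::slice_head(n = window) |>
    dplyr::mutate(hour_index = dplyr::row_number())
  if (is.null(parameters)) {
    nonnull <- purrr::map_int(pt[cols], ~ sum(.x > 0))
    parameters <- names(sort(nonnull, decreasing = TRUE))[seq_len(min(6, length(cols)))]
  }
  df <- pt |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
      names_to = "parameter", values_to = "code"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$hour_index, y = .data$code, colour = .data$parameter
  )) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_y_continuous(
      breaks = 0:5,
      labels = c("none", paste0("F", 1:5)), limits = c(0, 5)
    ) +
    ggplot2::labs(
      title = sprintf("Fuzzified monitoring, patient %s", patient),
      x = "hour", y = "fuzzy category", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
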