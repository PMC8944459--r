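#' Consecutive-day run counts for a series of administration dates
#'
#' For each administration date, the number of consecutive calendar days of
#' treatment ending on that date: day 1 of a course, day 2, and so on. The
#' counter resets after any gap larger than `grace` days off (default 0, so
#' any missing calendar day starts a new course).
#'
#' @param dates A `Date` vector (duplicates are collapsed).
#' @param grace Number of days off tolerated inside one course (default 0).
#' @return A tibble with `date` (sorted, unique) and `run_day` (integer
#'   count, `1, 2, 3, ...` within each course).
#' @export
#' @examples
#' consecutive_days(as.Date("2020-01-01") + c(0, 1, 2, 4))
consecutive_days <- function(dates, grace = 0) {
  stopifnot(inherits(dates, "Date"))
  d <- sort(unique(dates))
  if (length(d) == 0) {
    return(tibble::tibble(date = d, run_day = integer()))
  }
  new_run <- c(TRUE, diff(as.integer(d)) > grace + 1)
  run_id <- cumsum(new_run)
  run_day <- stats::ave(rep(1L, length(d)), run_id, FUN = seq_along)
  tibble::tibble(date = d, run_day = as.integer(run_day))
}

#' Build per-day therapy records from an administrations table
#'
#' Converts a long table of drug administrations (one row per patient, drug
#' and calendar day) into one record per treated patient-day: the overall
#' consecutive days of any antimicrobial therapy, plus one column per
#' vocabulary drug holding that drug's consecutive-day count (0 when the drug
#' was not given that day). With a 90-drug vocabulary each record has 91
#' numeric columns. Overall duration is computed on the union of all drug
#' days for the patient.
#'
#' @param administrations Data frame with columns `patient_id`, `drug`,
#'   `date` (`Date` or ISO-8601 string). Duplicate rows are collapsed.
#' @param vocabulary Character vector of allowed drug names. Defaults to the
#'   drug names present in the data. Unknown drug names are an error.
#' @param grace Passed to [consecutive_days()].
#' @return A tibble with `patient_id`, `date`, `overall_days`, then one
#'   integer column per vocabulary drug, carrying attribute `pattern_cols`
#'   (the 1 + length(vocabulary) value columns).
#' @export
#' @examples
#' adm <- tibble::tibble(
#'   patient_id = "p1",
#'   drug = c("meropenem", "meropenem", "vancomycin"),
#'   date = as.Date("2020-01-01") + c(0, 1, 1)
#' )
#' build_therapy_records(adm)
build_therapy_records <- function(administrations, vocabulary = NULL, grace = 0) {
  req <- c("patient_id", "drug", "date")
  if (!all(req %in% names(administrations))) {
    stop("`administrations` needs columns patient_id, drug, date", call. = FALSE)
  }
  adm <- tibble::as_tibble(administrations)
  adm$date <- as.Date(adm$date)
  adm <- dplyr::distinct(adm, .data$patient_id, .data$drug, .data$date)
  if (is.null(vocabulary)) vocabulary <- sort(unique(adm$drug))
  unknown <- setdiff(unique(adm$drug), vocabulary)
  if (length(unknown) > 0) {
    stop(
      "drug names not in vocabulary: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  per_drug <- adm |>
    dplyr::group_by(.data$patient_id, .data$drug) |>
    dplyr::reframe(consecutive_days(.data$date, grace = grace))

  overall <- adm |>
    dplyr::distinct(.data$patient_id, .data$date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::reframe(consecutive_days(.data$date, grace = grace)) |>
    dplyr::rename(overall_days = "run_day")

  wide <- per_drug |>
    tidyr::pivot_wider(
      names_from = "drug", values_from = "run_day", values_fill = 0L
    )
  missing_drugs <- setdiff(vocabulary, names(wide))
  for (dr in missing_drugs) wide[[dr]] <- 0L

  out <- overall |>
    dplyr::left_join(wide, by = c("patient_id", "date")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vocabulary), ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::select("patient_id", "date", "overall_days", dplyr::all_of(vocabulary)) |>
    dplyr::arrange(.data$patient_id, .data$date)
  attr(out, "pattern_cols") <- c("overall_days", vocabulary)
  out
}

#' Build per-hour monitoring records from a readings table
#'
#' Buckets clinically validated readings by patient, calendar day and clock
#' hour (0-23) and reduces multiple readings of one parameter within an hour
#' with the chosen aggregator. Hours with no readings at all produce no
#' record; parameters not measured in an hour are `NA`.
#'
#' @param readings Data frame with columns `patient_id`, `timestamp`
#'   (`POSIXct` or ISO-8601 string, interpreted in UTC), `parameter`,
#'   `value`.
#' @param schema Character vector of allowed parameter names (the record
#'   columns, in order). Defaults to the parameters present. Unknown
#'   parameter names are an error.
#' @param aggregator `"median"` (default) or `"last"` (latest timestamp wins).
#' @return A tibble with `patient_id`, `date`, `hour`, then one numeric
#'   column per schema parameter, with attribute `pattern_cols`.
#' @export
build_monitoring_records <- function(readings, schema = NULL,
                                     aggregator = c("median", "last")) {
  aggregator <- match.arg(aggregator)
  req <- c("patient_id", "timestamp", "parameter", "value")
  if (!all(req %in% names(readings))) {
    stop("`readings` needs columns patient_id, timestamp, parameter, value",
      call. = FALSE
    )
  }
  rd <- tibble::as_tibble(readings)
  if (!inherits(rd$timestamp, "POSIXct")) {
    rd$timestamp <- as.POSIXct(rd$timestamp, tz = "UTC")
  }
  if (any(is.na(rd$timestamp))) stop("invalid timestamps", call. = FALSE)
  if (is.null(schema)) schema <- sort(unique(rd$parameter))
  unknown <- setdiff(unique(rd$parameter), schema)
  if (length(unknown) > 0) {
    stop(
      "parameters not in schema: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  rd <- rd |>
    dplyr::mutate(
      date = as.Date(.data$timestamp, tz = "UTC"),
      hour = as.integer(format(.data$timestamp, "%H", tz = "UTC"))
    )
  agg <- if (aggregator == "median") {
    rd |>
      dplyr::group_by(.data$patient_id, .data$date, .data$hour, .data$parameter) |>
      dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  } else {
    rd |>
      dplyr::group_by(.data$patient_id, .data$date, .data$hour, .data$parameter) |>
      dplyr::slice_max(.data$timestamp, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "date", "hour", "parameter", "value")
  }

  wide <- agg |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
  missing_pars <- setdiff(schema, names(wide))
  for (p in missing_pars) wide[[p]] <- NA_real_
  out <- wide |>
    dplyr::select("patient_id", "date", "hour", dplyr::all_of(schema)) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$hour)
  attr(out, "pattern_cols") <- schema
  out
}

#' Normalize records to fuzzy category patterns
#'
#' Fuzzifies every value column of a record table with its parameter's fuzzy
#' domain, yielding a category pattern per record: codes 1-5 for subsets
#' F1-F5 and 0 for absent data. Missing cells (and, when
#' `zero_as_missing = TRUE`, zero cells — the convention for drug
#' consecutive-day counts, where 0 means "not given") map to code 0.
#' Columns that contain no observable value at all (every cell absent) are
#' coded 0 without requiring a domain; any other column without a domain is
#' an error.
#'
#' @param records Output of [build_therapy_records()] or
#'   [build_monitoring_records()] (or any tibble with key columns among
#'   `patient_id`, `date`, `hour` and numeric value columns).
#' @param domains Named list of [fuzzy_domain()] objects, one per value
#'   column.
#' @param zero_as_missing Treat zeros as absent data (therapy duration
#'   semantics). Default `FALSE`.
#' @return A tibble with the key columns and one integer code column per
#'   value column, with attribute `pattern_cols`.
#' @export
normalize_records <- function(records, domains, zero_as_missing = FALSE) {
  keys <- intersect(c("patient_id", "date", "hour"), names(records))
  cols <- attr(records, "pattern_cols") %||% setdiff(names(records), keys)
  observable <- purrr::map_lgl(cols, function(cl) {
    v <- records[[cl]]
    if (zero_as_missing) any(!is.na(v) & v != 0) else any(!is.na(v))
  })
  need_domain <- cols[observable]
  missing_dom <- setdiff(need_domain, names(domains))
  if (length(missing_dom) > 0) {
    stop(
      "missing fuzzy domain for column(s): ", paste(missing_dom, collapse = ", "),
      call. = FALSE
    )
  }
  out <- records[keys]
  for (cl in cols) {
    v <- records[[cl]]
    if (zero_as_missing) v[!is.na(v) & v == 0] <- NA
    if (cl %in% need_domain) {
      out[[cl]] <- fuzzify(domains[[cl]], v)
    } else {
      out[[cl]] <- integer(nrow(records))
    }
  }
  attr(out, "pattern_cols") <- cols
  out
}

#' Deduplicate category patterns
#'
#' Collapses a normalized pattern table to its unique patterns. Two patterns
#' are identical exactly when their Euclidean distance is zero, so exact row
#' equality is used. Unique patterns are numbered in lexicographic order of
#' their codes; a back-map links every source record to its pattern id.
#'
#' @param patterns Output of [normalize_records()] (or a tibble/matrix of
#'   integer codes).
#' @return An object of class `unique_patterns`: a list with
#'   * `patterns`: tibble of `pattern_id`, `multiplicity`, and the code
#'     columns (one row per unique pattern, lexicographic order);
#'   * `map`: integer vector, `map[i]` = pattern_id of source record `i`;
#'   * `keys`: tibble of the source records' key columns plus `pattern_id`
#'     (empty when the input had no key columns).
#' @export
#' @examples
#' pats <- tibble::tibble(a = c(1L, 2L, 1L), b = c(2L, 1L, 2L))
#' dedup_patterns(pats)
dedup_patterns <- function(patterns) {
  if (is.matrix(patterns)) {
    patterns <- tibble::as_tibble(patterns, .name_repair = "unique")
  }
  keys <- intersect(c("patient_id", "date", "hour"), names(patterns))
  cols <- attr(patterns, "pattern_cols") %||% setdiff(names(patterns), keys)
  if (length(cols) == 0 || nrow(patterns) == 0) {
    stop("no patterns to deduplicate", call. = FALSE)
  }
  code_df <- patterns[cols]
  if (any(!purrr::map_lgl(code_df, is.numeric))) {
    stop("pattern columns must be numeric codes", call. = FALSE)
  }

  key_str <- do.call(paste, c(code_df, sep = "\r"))
  uniq <- !duplicated(key_str)
  uniq_df <- code_df[uniq, , drop = FALSE]
  ord <- do.call(order, as.list(uniq_df))
  uniq_df <- uniq_df[ord, , drop = FALSE]
  uniq_key <- key_str[uniq][ord]
  map <- match(key_str, uniq_key)
  mult <- tabulate(map, nbins = nrow(uniq_df))

  uniq_tbl <- tibble::as_tibble(uniq_df)
  uniq_tbl <- tibble::add_column(uniq_tbl,
    pattern_id = seq_len(nrow(uniq_df)),
    multiplicity = mult, .before = 1
  )
  out <- list(
    patterns = uniq_tbl,
    map = map,
    keys = dplyr::bind_cols(patterns[keys], tibble::tibble(pattern_id = map))
  )
  attr(out, "pattern_cols") <- cols
  class(out) <- "unique_patterns"
  out
}

#' @export
print.unique_patterns <- function(x, ...) {
  cat(sprintf(
    "<unique_patterns> %d unique of %d records, %d columns\n",
    nrow(x$patterns), length(x$map), length(attr(x, "pattern_cols"))
  ))
  invisible(x)
}
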