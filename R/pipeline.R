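#' Pipeline configuration
#'
#' Collects paths and settings for the staged pipeline. All stages read and
#' write under `out_dir`; inputs default to the files the `simulate` stage
#' writes there.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed used by every stochastic stage.
#' @param n_patients Cohort size for the `simulate` stage.
#' @param administrations,readings Input CSV paths (default: the simulated
#'   ones under `out_dir`).
#' @param trim_coverage Coverage target for the trimmed tables
#'   (default 0.95).
#' @param overlap Overlap rule: `"half_sd"` or a fixed numeric width.
#' @param therapy_k,monitoring_k `"auto"` (elbow selection) or a fixed
#'   integer; the presets used in practice are 4 and 7.
#' @param k_max Elbow scan range (default 25).
#' @param n_init Restarts per k-modes fit (default 20).
#' @param aggregator Within-hour aggregator for monitoring readings.
#' @param charts Write PNG charts during `report` (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_patients = 200,
                            administrations = file.path(out_dir, "administrations.csv"),
                            readings = file.path(out_dir, "readings.csv"),
                            trim_coverage = 0.95, overlap = "half_sd",
                            therapy_k = "auto", monitoring_k = "auto",
                            k_max = 25L, n_init = 20L,
                            aggregator = "median", charts = TRUE) {
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), n_patients = n_patients,
      administrations = administrations, readings = readings,
      trim_coverage = trim_coverage, overlap = overlap,
      therapy_k = therapy_k, monitoring_k = monitoring_k,
      k_max = k_max, n_init = n_init, aggregator = aggregator,
      charts = charts
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any key of [pipeline_config()] may appear in the file; `out_dir` is
#' required.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  do.call(pipeline_config, y)
}

artifact_path <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(path) {
  if (!file.exists(path)) {
    stop("missing upstream artifact: ", path, call. = FALSE)
  }
  path
}

write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fuzzystay")),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(
    manifest, artifact_path(config, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA
  )
}

# Domain construction with the pipeline's numerical safeguards: constant
# columns get the unit range widened by +-0.5 before construction, and the
# half-SD overlap is shrunk to half the admissible maximum when the rule
# h < (M - m)/6 would be violated (narrow per-drug duration ranges).
build_domain_safe <- function(values, mode, coverage, overlap, labels, id) {
  tt <- trim_values(values, mode = mode, coverage = coverage, parameter_id = id)
  m <- tt$m
  M <- tt$M
  if (tt$degenerate) {
    m <- m - 0.5
    M <- M + 0.5
  }
  h <- if (identical(overlap, "half_sd")) tt$sd_t / 2 else as.numeric(overlap)
  h_max <- (M - m) / 6
  if (h <= 0 || h >= h_max) h <- h_max / 2
  # The limit ordering requires the medium triangle to clear both shoulders:
  # median in (m + (M-m)/6 + 2h, M - (M-m)/6 - 2h). Strongly skewed columns
  # (e.g. short-course drugs) fall outside; clamp the anchor into the band.
  third <- (M - m) / 6
  margin <- 1e-3 * (M - m)
  lo <- m + third + 2 * h + margin
  hi <- M - third - 2 * h - margin
  med <- if (lo > hi) (m + M) / 2 else min(max(tt$median_t, lo), hi)
  fuzzy_domain(m, M, med, h,
    labels = labels, parameter_id = id, sd_t = tt$sd_t
  )
}

build_domain_set <- function(records, mode, coverage, overlap, labels,
                             zero_as_missing) {
  cols <- attr(records, "pattern_cols")
  domains <- list()
  for (cl in cols) {
    v <- records[[cl]]
    if (zero_as_missing) v <- v[!is.na(v) & v != 0] else v <- v[!is.na(v)]
    if (length(v) == 0) next # never-observed column: codes to 0 downstream
    domains[[cl]] <- build_domain_safe(v, mode, coverage, overlap, labels, cl)
  }
  domains
}

read_records_csv <- function(path, pattern_cols) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  attr(df, "pattern_cols") <- intersect(pattern_cols, names(df))
  df
}

fit_set <- function(patterns_unique, k_setting, k_max, seed, n_init) {
  if (identical(k_setting, "auto")) {
    curve <- elbow_select(patterns_unique,
      k_max = k_max, seed = seed, n_init = n_init
    )
    k <- curve$chosen_k
  } else {
    k <- as.integer(k_setting)
    curve <- NULL
  }
  fit <- kmodes(patterns_unique, k = k, seed = seed, n_init = n_init)
  list(fit = fit, curve = curve)
}

write_model_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      k = fit$k, cost = fit$cost, seed = fit$seed, n_init = fit$n_init,
      init = fit$init, modes = apply(fit$modes, 1, as.integer, simplify = FALSE),
      labels = fit$labels
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

save_chart <- function(plot, path, width = 8, height = 5) {
  suppressMessages(ggplot2::ggsave(path, plot,
    width = width, height = height,
    dpi = 110, device = grDevices::png, type = "cairo"
  ))
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` (write a synthetic cohort),
#' `domains` (build per-parameter fuzzy domains), `normalize` (records to
#' category patterns plus deduplication), `cluster` (k-modes with elbow
#' selection), `stays` (stay tables, frequency and contingency tables,
#' chi-square, Nabtcl stratification), `report` (charts), or `all`. Each
#' stage reads its upstream artifacts from `config$out_dir` (a missing
#' artifact is an explicit error) and writes its outputs there together
#' with a JSON manifest of input/output checksums, the seed and the
#' package version; rerunning a stage with unchanged inputs reproduces
#' identical tables.
#'
#' @param stage One of `"all"`, `"simulate"`, `"domains"`, `"normalize"`,
#'   `"cluster"`, `"stays"`, `"report"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the vector of artifact paths written.
#' @export
run_pipeline <- function(stage = c(
                           "all", "simulate", "domains", "normalize",
                           "cluster", "stays", "report"
                         ),
                         config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    out <- c(
      run_pipeline("simulate", config),
      run_pipeline("domains", config),
      run_pipeline("normalize", config),
      run_pipeline("cluster", config),
      run_pipeline("stays", config),
      run_pipeline("report", config)
    )
    return(invisible(out))
  }
  ap <- function(name) artifact_path(config, name)
  message(sprintf("[fuzzystay] stage %s -> %s", stage, config$out_dir))

  written <- switch(stage,
    simulate = {
      cohort <- simulate_cohort(sim_config(
        n_patients = config$n_patients, seed = config$seed
      ))
      readr::write_csv(cohort$administrations, ap("administrations.csv"),
        progress = FALSE
      )
      rd <- dplyr::mutate(cohort$readings,
        timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      )
      readr::write_csv(rd, ap("readings.csv"), progress = FALSE)
      out <- c(ap("administrations.csv"), ap("readings.csv"))
      write_manifest(config, "simulate", character(), out)
      out
    },
    domains = {
      adm <- readr::read_csv(require_artifact(config$administrations),
        show_col_types = FALSE, progress = FALSE
      )
      rdg <- readr::read_csv(require_artifact(config$readings),
        show_col_types = FALSE, progress = FALSE
      )
      therapy <- build_therapy_records(adm)
      monitoring <- build_monitoring_records(rdg, aggregator = config$aggregator)
      dom_t <- build_domain_set(therapy,
        mode = "upper", coverage = config$trim_coverage,
        overlap = config$overlap, labels = therapy_labels(),
        zero_as_missing = TRUE
      )
      dom_m <- build_domain_set(monitoring,
        mode = "central", coverage = config$trim_coverage,
        overlap = config$overlap, labels = monitoring_labels(),
        zero_as_missing = FALSE
      )
      write_domains(dom_t, ap("domains_therapy.json"))
      write_domains(dom_m, ap("domains_monitoring.json"))
      out <- c(ap("domains_therapy.json"), ap("domains_monitoring.json"))
      write_manifest(config, "domains", c(config$administrations, config$readings), out)
      out
    },
    normalize = {
      adm <- readr::read_csv(require_artifact(config$administrations),
        show_col_types = FALSE, progress = FALSE
      )
      rdg <- readr::read_csv(require_artifact(config$readings),
        show_col_types = FALSE, progress = FALSE
      )
      dom_t <- read_domains(require_artifact(ap("domains_therapy.json")))
      dom_m <- read_domains(require_artifact(ap("domains_monitoring.json")))
      therapy <- build_therapy_records(adm)
      monitoring <- build_monitoring_records(rdg, aggregator = config$aggregator)
      norm_t <- normalize_records(therapy, dom_t, zero_as_missing = TRUE)
      norm_m <- normalize_records(monitoring, dom_m)
      readr::write_csv(norm_t, ap("therapy_patterns.csv"), progress = FALSE)
      readr::write_csv(norm_m, ap("monitoring_patterns.csv"), progress = FALSE)
      jsonlite::write_json(
        list(
          therapy_columns = attr(norm_t, "pattern_cols"),
          monitoring_columns = attr(norm_m, "pattern_cols"),
          domain_files = c("domains_therapy.json", "domains_monitoring.json")
        ),
        ap("pattern_columns.json"),
        auto_unbox = FALSE
      )
      up_t <- dedup_patterns(norm_t)
      up_m <- dedup_patterns(norm_m)
      readr::write_csv(up_t$patterns, ap("unique_therapy_patterns.csv"), progress = FALSE)
      readr::write_csv(up_m$patterns, ap("unique_monitoring_patterns.csv"), progress = FALSE)
      readr::write_csv(up_t$keys, ap("therapy_pattern_map.csv"), progress = FALSE)
      readr::write_csv(up_m$keys, ap("monitoring_pattern_map.csv"), progress = FALSE)
      out <- ap(c(
        "therapy_patterns.csv", "monitoring_patterns.csv", "pattern_columns.json",
        "unique_therapy_patterns.csv", "unique_monitoring_patterns.csv",
        "therapy_pattern_map.csv", "monitoring_pattern_map.csv"
      ))
      write_manifest(config, "normalize",
        c(
          config$administrations, config$readings,
          ap("domains_therapy.json"), ap("domains_monitoring.json")
        ),
        out
      )
      out
    },
    cluster = {
      cols <- jsonlite::read_json(require_artifact(ap("pattern_columns.json")),
        simplifyVector = TRUE
      )
      up_t <- read_records_csv(
        require_artifact(ap("unique_therapy_patterns.csv")), cols$therapy_columns
      )
      up_m <- read_records_csv(
        require_artifact(ap("unique_monitoring_patterns.csv")), cols$monitoring_columns
      )
      res_t <- fit_set(up_t, config$therapy_k, config$k_max, config$seed, config$n_init)
      res_m <- fit_set(
        up_m, config$monitoring_k, config$k_max,
        config$seed + 1000L, config$n_init
      )
      write_model_json(res_t$fit, ap("therapy_model.json"))
      write_model_json(res_m$fit, ap("monitoring_model.json"))
      out <- c(ap("therapy_model.json"), ap("monitoring_model.json"))
      for (nm in c("therapy", "monitoring")) {
        curve <- if (nm == "therapy") res_t$curve else res_m$curve
        if (!is.null(curve)) {
          readr::write_csv(curve$curve, ap(sprintf("elbow_%s.csv", nm)), progress = FALSE)
          out <- c(out, ap(sprintf("elbow_%s.csv", nm)))
          if (config$charts) {
            save_chart(autoplot(curve), ap(sprintf("elbow_%s.png", nm)))
          }
        }
      }
      write_manifest(config, "cluster",
        ap(c("unique_therapy_patterns.csv", "unique_monitoring_patterns.csv")),
        out
      )
      out
    },
    stays = {
      cols <- jsonlite::read_json(require_artifact(ap("pattern_columns.json")),
        simplifyVector = TRUE
      )
      norm_t <- read_records_csv(
        require_artifact(ap("therapy_patterns.csv")), cols$therapy_columns
      )
      norm_m <- read_records_csv(
        require_artifact(ap("monitoring_patterns.csv")), cols$monitoring_columns
      )
      model_t <- jsonlite::read_json(require_artifact(ap("therapy_model.json")),
        simplifyVector = TRUE
      )
      model_m <- jsonlite::read_json(require_artifact(ap("monitoring_model.json")),
        simplifyVector = TRUE
      )
      up_t <- dedup_patterns(norm_t)
      up_m <- dedup_patterns(norm_m)
      lab_t <- dplyr::mutate(up_t$keys, cluster = model_t$labels[.data$pattern_id])
      lab_m <- dplyr::mutate(up_m$keys, cluster = model_m$labels[.data$pattern_id])
      st <- build_stay_table(lab_t, lab_m)
      readr::write_csv(st, ap("stay_table.csv"), progress = FALSE)

      freq_t <- subset_frequencies(
        model_t$labels[up_t$patterns$pattern_id],
        up_t$patterns
      )
      freq_m <- subset_frequencies(
        model_m$labels[up_m$patterns$pattern_id],
        up_m$patterns
      )
      readr::write_csv(freq_t, ap("cluster_frequencies_therapy.csv"), progress = FALSE)
      readr::write_csv(freq_m, ap("cluster_frequencies_monitoring.csv"), progress = FALSE)

      ct <- contingency_table(st)
      readr::write_csv(tibble::as_tibble(ct), ap("contingency.csv"), progress = FALSE)
      chi <- dplyr::mutate(chi_square(ct), table = "therapy_x_monitoring")
      readr::write_csv(chi, ap("chi_square.csv"), progress = FALSE)

      overall_codes <- dplyr::select(norm_t, "patient_id", "date",
        code = "overall_days"
      )
      nab <- nabtcl_summary(st, overall_codes)
      readr::write_csv(nab$strata, ap("nabtcl_strata.csv"), progress = FALSE)
      readr::write_csv(nab$therapy_by_stratum, ap("nabtcl_therapy.csv"), progress = FALSE)
      readr::write_csv(nab$monitoring_by_stratum, ap("nabtcl_monitoring.csv"),
        progress = FALSE
      )
      readr::write_csv(nab$duration_by_stratum, ap("nabtcl_duration.csv"),
        progress = FALSE
      )
      out <- ap(c(
        "stay_table.csv", "cluster_frequencies_therapy.csv",
        "cluster_frequencies_monitoring.csv", "contingency.csv",
        "chi_square.csv", "nabtcl_strata.csv", "nabtcl_therapy.csv",
        "nabtcl_monitoring.csv", "nabtcl_duration.csv"
      ))
      write_manifest(config, "stays",
        ap(c(
          "therapy_patterns.csv", "monitoring_patterns.csv",
          "therapy_model.json", "monitoring_model.json"
        )),
        out
      )
      out
    },
    report = {
      out <- character()
      if (config$charts) {
        dom_t <- read_domains(require_artifact(ap("domains_therapy.json")))
        save_chart(autoplot(dom_t[["overall_days"]]), ap("domain_overall_days.png"))
        cols <- jsonlite::read_json(require_artifact(ap("pattern_columns.json")),
          simplifyVector = TRUE
        )
        st <- readr::read_csv(require_artifact(ap("stay_table.csv")),
          show_col_types = FALSE, progress = FALSE
        )
        class(st) <- c("stay_table", class(st))
        hours <- sprintf("h%02d", 0:23)
        monitored <- rowSums(st[hours] > 0)
        pat <- st$patient_id[which.max(monitored)]
        save_chart(stay_chart(st, pat), ap("stay_chart.png"))
        norm_m <- read_records_csv(
          require_artifact(ap("monitoring_patterns.csv")), cols$monitoring_columns
        )
        save_chart(plot_fuzzy_ribbon(norm_m, pat), ap("fuzzy_ribbon.png"))
        out <- ap(c("domain_overall_days.png", "stay_chart.png", "fuzzy_ribbon.png"))
      }
      write_manifest(config, "report", ap("stay_table.csv"), out)
      out
    }
  )
  invisible(written)
}
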