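#' Default antimicrobial drug vocabulary
#'
#' A 90-name vocabulary of antibacterial, antifungal and antiviral agents in
#' ICU use, standing in for a hospital formulary. Course simulation samples
#' drugs with Zipf-like weights so a few workhorse agents dominate, as in
#' real prescribing.
#'
#' @param n Number of drug names (default 90).
#' @return Character vector of drug names.
#' @export
default_drug_vocabulary <- function(n = 90) {
  base <- c(
    "piperacillin-tazobactam", "meropenem", "ceftriaxone", "vancomycin",
    "levofloxacin", "amoxicillin-clavulanate", "cefepime", "linezolid",
    "ciprofloxacin", "fluconazole", "metronidazole", "gentamicin",
    "amikacin", "ceftazidime", "imipenem-cilastatin", "ampicillin-sulbactam",
    "daptomycin", "tigecycline", "colistin", "caspofungin",
    "teicoplanin", "clarithromycin", "azithromycin", "clindamycin",
    "trimethoprim-sulfamethoxazole", "cefazolin", "cefuroxime", "cefotaxime",
    "ertapenem", "aztreonam", "oxacillin", "ampicillin",
    "amoxicillin", "penicillin-g", "flucloxacillin", "cefoxitin",
    "ceftolozane-tazobactam", "ceftazidime-avibactam", "ceftaroline",
    "doripenem", "tobramycin", "streptomycin", "moxifloxacin", "ofloxacin",
    "norfloxacin", "erythromycin", "telavancin", "dalbavancin", "tedizolid",
    "doxycycline", "minocycline", "tetracycline", "polymyxin-b",
    "fosfomycin", "nitrofurantoin", "rifampicin", "rifabutin", "isoniazid",
    "ethambutol", "pyrazinamide", "chloramphenicol", "fusidic-acid",
    "quinupristin-dalfopristin", "voriconazole", "posaconazole",
    "isavuconazole", "itraconazole", "micafungin", "anidulafungin",
    "amphotericin-b", "liposomal-amphotericin-b", "flucytosine",
    "aciclovir", "ganciclovir", "valganciclovir", "foscarnet", "cidofovir",
    "oseltamivir", "zanamivir", "ribavirin", "remdesivir", "pentamidine",
    "atovaquone", "ceftobiprole", "temocillin", "mecillinam", "cefiderocol",
    "plazomicin", "lefamulin", "omadacycline", "eravacycline", "fidaxomicin"
  )
  if (n <= length(base)) {
    base[seq_len(n)]
  } else {
    c(base, sprintf("antimicrobial-%02d", seq_len(n - length(base))))
  }
}

#' Default bedside monitoring schema
#'
#' A 46-parameter hourly monitoring schema emulating an ICU patient data
#' management system: vitals, hemodynamics, ventilation, arterial blood gas
#' fields, core labs and fluid-balance terms. Each row gives the parameter's
#' population mean and SD in native clinical units, its per-hour
#' missingness probability, and a subpopulation `gate` (the fraction of
#' patients monitored for it at all, e.g. intracranial pressure only in
#' neuro patients).
#'
#' @return A tibble with columns `parameter`, `unit`, `mean`, `sd`,
#'   `missingness`, `gate`.
#' @export
default_monitoring_schema <- function() {
  tibble::tribble(
    ~parameter, ~unit, ~mean, ~sd, ~missingness, ~gate,
    "heart_rate", "bpm", 86, 17, 0.05, 1,
    "systolic_bp", "mmHg", 121, 22, 0.10, 1,
    "diastolic_bp", "mmHg", 64, 13, 0.10, 1,
    "mean_arterial_pressure", "mmHg", 81, 15, 0.10, 1,
    "central_venous_pressure", "mmHg", 9, 4, 0.35, 0.7,
    "intracranial_pressure", "mmHg", 12, 5, 0.20, 0.10,
    "cerebral_perfusion_pressure", "mmHg", 70, 10, 0.25, 0.10,
    "spo2", "%", 96, 2.5, 0.05, 1,
    "respiratory_rate", "breaths/min", 18, 5, 0.10, 1,
    "temperature", "degC", 37.1, 0.8, 0.25, 1,
    "etco2", "mmHg", 35, 6, 0.40, 0.6,
    "fio2", "fraction", 0.48, 0.15, 0.20, 0.8,
    "peep", "cmH2O", 7, 3, 0.25, 0.6,
    "tidal_volume", "mL", 450, 80, 0.30, 0.6,
    "peak_airway_pressure", "cmH2O", 23, 6, 0.30, 0.6,
    "minute_ventilation", "L/min", 8.2, 2.1, 0.35, 0.6,
    "cardiac_index", "L/min/m2", 3.0, 0.8, 0.30, 0.2,
    "svo2", "%", 70, 8, 0.40, 0.2,
    "abg_ph", "pH", 7.38, 0.07, 0.55, 1,
    "abg_pao2", "mmHg", 95, 24, 0.55, 1,
    "abg_paco2", "mmHg", 41, 8, 0.55, 1,
    "abg_hco3", "mmol/L", 24, 3.5, 0.55, 1,
    "abg_base_excess", "mmol/L", 0, 3.5, 0.55, 1,
    "abg_lactate", "mmol/L", 1.9, 1.1, 0.55, 1,
    "abg_sao2", "%", 96, 2.8, 0.55, 1,
    "sodium", "mmol/L", 139, 4.5, 0.60, 1,
    "potassium", "mmol/L", 4.1, 0.5, 0.60, 1,
    "chloride", "mmol/L", 104, 5, 0.65, 1,
    "ionized_calcium", "mmol/L", 1.15, 0.09, 0.65, 1,
    "glucose", "mg/dL", 136, 38, 0.50, 1,
    "hemoglobin", "g/dL", 10.4, 1.8, 0.70, 1,
    "hematocrit", "%", 31, 5, 0.70, 1,
    "platelets", "10^3/uL", 215, 95, 0.80, 1,
    "white_cell_count", "10^3/uL", 11.5, 5, 0.80, 1,
    "creatinine", "mg/dL", 1.2, 0.7, 0.80, 1,
    "urea", "mg/dL", 48, 26, 0.80, 1,
    "bilirubin_total", "mg/dL", 1.1, 0.9, 0.85, 1,
    "albumin", "g/dL", 2.8, 0.6, 0.88, 1,
    "inr", "ratio", 1.3, 0.4, 0.85, 1,
    "aptt", "s", 36, 11, 0.85, 1,
    "crp", "mg/L", 115, 75, 0.85, 1,
    "gcs", "score", 11, 3, 0.40, 1,
    "infusion_rate", "mL/h", 120, 55, 0.15, 1,
    "diuresis", "mL/h", 90, 55, 0.15, 1,
    "ultrafiltrate", "mL/h", 85, 40, 0.25, 0.15,
    "fluid_balance", "mL/h", 20, 140, 0.25, 1
  )
}

#' Simulation configuration for a synthetic ICU cohort
#'
#' Defines the study conditions the generator emulates: cohort size,
#' log-normal stay lengths, a drug vocabulary with a two-component
#' course-length mixture (a short geometric component plus a long tail, so
#' all five duration categories are populated), and an hourly monitoring
#' schema with structured missingness and subpopulation gating.
#'
#' @param n_patients Number of patients.
#' @param seed Mandatory integer seed.
#' @param stay_meanlog,stay_sdlog Log-normal stay length (days); defaults
#'   give a median stay of 6 days with a long tail.
#' @param vocabulary Drug vocabulary (default [default_drug_vocabulary()]).
#' @param schema Monitoring schema tibble
#'   (default [default_monitoring_schema()]).
#' @param treated_prob Probability a patient receives antimicrobials.
#' @param courses_lambda Mean number of additional drug courses per treated
#'   patient (1 + Poisson).
#' @param course_geom_prob Success probability of the short (geometric)
#'   course-length component.
#' @param course_long_prob Mixture weight of the long-course component.
#' @param course_long_extra Mean extra days of the long component
#'   (length = 8 + Poisson).
#' @param ar1 AR(1) autocorrelation of vitals within patient (default 0:
#'   i.i.d. hours, which is what the tests assume; positive values only for
#'   chart realism).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200, seed = 1L,
                       stay_meanlog = log(6), stay_sdlog = 0.6,
                       vocabulary = default_drug_vocabulary(),
                       schema = default_monitoring_schema(),
                       treated_prob = 0.8, courses_lambda = 1.2,
                       course_geom_prob = 0.35, course_long_prob = 0.15,
                       course_long_extra = 10, ar1 = 0) {
  stopifnot(
    n_patients >= 1, is.numeric(seed), length(seed) == 1,
    treated_prob >= 0, treated_prob <= 1,
    course_geom_prob > 0, course_geom_prob <= 1,
    course_long_prob >= 0, course_long_prob <= 1,
    ar1 >= 0, ar1 < 1,
    all(c("parameter", "mean", "sd", "missingness", "gate") %in% names(schema)),
    all(schema$missingness >= 0 & schema$missingness <= 1),
    all(schema$gate >= 0 & schema$gate <= 1)
  )
  structure(
    list(
      n_patients = n_patients, seed = as.integer(seed),
      stay_meanlog = stay_meanlog, stay_sdlog = stay_sdlog,
      vocabulary = vocabulary, schema = schema,
      treated_prob = treated_prob, courses_lambda = courses_lambda,
      course_geom_prob = course_geom_prob, course_long_prob = course_long_prob,
      course_long_extra = course_long_extra, ar1 = ar1
    ),
    class = "sim_config"
  )
}

#' Simulate an ICU cohort of administrations and monitoring readings
#'
#' Generates, reproducibly from the config seed, (a) a long administrations
#' table of contiguous drug courses (so consecutive-day counters are
#' exercised with known answers) and (b) a long hourly readings table drawn
#' per parameter from the schema's normal distributions with per-hour
#' missingness and per-patient gating.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: list with `administrations`
#'   (`patient_id`, `drug`, `date`), `readings` (`patient_id`, `timestamp`,
#'   `parameter`, `value`) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 5, seed = 42))
#' head(cohort$administrations)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config
  withr::with_seed(sc$seed, {
    ids <- sprintf("P%04d", seq_len(sc$n_patients))
    stay <- pmin(60, pmax(2, round(rlnorm(sc$n_patients, sc$stay_meanlog, sc$stay_sdlog))))
    admit <- as.Date("2012-01-01") +
      sample.int(2100, sc$n_patients, replace = TRUE)

    # --- drug courses -----------------------------------------------------
    treated <- runif(sc$n_patients) < sc$treated_prob
    drug_w <- 1 / seq_along(sc$vocabulary) # Zipf-like prescribing frequency
    adm_list <- list()
    for (i in which(treated)) {
      n_courses <- 1L + rpois(1, sc$courses_lambda)
      for (cs in seq_len(n_courses)) {
        drug <- sample(sc$vocabulary, 1, prob = drug_w)
        len <- if (runif(1) < sc$course_long_prob) {
          8L + rpois(1, sc$course_long_extra)
        } else {
          1L + rgeom(1, sc$course_geom_prob)
        }
        start <- sample.int(stay[i], 1)
        days <- seq(start, min(stay[i], start + len - 1L))
        adm_list[[length(adm_list) + 1L]] <- tibble::tibble(
          patient_id = ids[i], drug = drug, date = admit[i] + days - 1L
        )
      }
    }
    administrations <- dplyr::distinct(
      dplyr::bind_rows(adm_list),
      .data$patient_id, .data$drug, .data$date
    ) |>
      dplyr::arrange(.data$patient_id, .data$drug, .data$date)

    # --- hourly monitoring ------------------------------------------------
    n_hours_pat <- stay * 24L
    pat_idx <- rep(seq_len(sc$n_patients), n_hours_pat)
    hour_of_stay <- unlist(lapply(n_hours_pat, seq_len)) - 1L
    ts <- as.POSIXct(admit[pat_idx], tz = "UTC") + hour_of_stay * 3600
    n_slots <- length(ts)

    gates <- matrix(
      runif(sc$n_patients * nrow(sc$schema)) < rep(sc$schema$gate, each = sc$n_patients),
      nrow = sc$n_patients
    )
    chunks <- vector("list", nrow(sc$schema))
    for (p in seq_len(nrow(sc$schema))) {
      present <- gates[pat_idx, p] & (runif(n_slots) >= sc$schema$missingness[p])
      if (!any(present)) next
      mu <- sc$schema$mean[p]
      sdev <- sc$schema$sd[p]
      if (sc$ar1 > 0) {
        noise <- as.vector(stats::filter(
          rnorm(n_slots, 0, sdev * sqrt(1 - sc$ar1^2)),
          sc$ar1,
          method = "recursive"
        ))
        vals <- (mu + noise)[present]
      } else {
        vals <- rnorm(sum(present), mu, sdev)
      }
      chunks[[p]] <- tibble::tibble(
        patient_id = ids[pat_idx[present]],
        timestamp = ts[present],
        parameter = sc$schema$parameter[p],
        value = vals
      )
    }
    readings <- dplyr::bind_rows(chunks) |>
      dplyr::arrange(.data$patient_id, .data$timestamp, .data$parameter)
  })
  structure(
    list(administrations = administrations, readings = readings, config = sc),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d patients, %d administration rows, %d readings (seed %d)\n",
    x$config$n_patients, nrow(x$administrations), nrow(x$readings),
    x$config$seed
  ))
  invisible(x)
}

#' Simulate category patterns from planted modes
#'
#' Generates `n` category patterns from `K` planted modes: each pattern is a
#' copy of its mode with every attribute independently resampled uniformly
#' over codes 0-5 with probability `eps` (so a fraction `eps * 5/6` of
#' attributes is expected to actually change). Ground-truth labels are
#' returned for cluster-recovery testing.
#'
#' @param K Number of planted modes.
#' @param length Pattern length (attributes).
#' @param n Number of patterns.
#' @param eps Per-attribute perturbation probability.
#' @param seed Integer seed.
#' @return List with `patterns` (n x length integer matrix), `labels`
#'   (0-based true mode of each pattern) and `modes` (K x length matrix).
#' @export
#' @examples
#' sim <- simulate_patterns(K = 4, length = 10, n = 100, eps = 0.05, seed = 7)
#' table(sim$labels)
simulate_patterns <- function(K, length, n, eps = 0.05, seed = 1L) {
  stopifnot(K >= 1, length >= 1, n >= 1, eps >= 0, eps <= 1)
  if (K > 6^length) stop("more modes than distinct patterns", call. = FALSE)
  withr::with_seed(seed, {
    repeat {
      modes <- matrix(sample(0:5, K * length, replace = TRUE), nrow = K)
      if (!anyDuplicated(do.call(paste, c(as.data.frame(modes), sep = "\r")))) break
    }
    labels <- sample.int(K, n, replace = TRUE)
    patterns <- modes[labels, , drop = FALSE]
    flip <- matrix(runif(n * length) < eps, nrow = n)
    patterns[flip] <- sample(0:5, sum(flip), replace = TRUE)
  })
  list(patterns = patterns, labels = labels - 1L, modes = modes)
}
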