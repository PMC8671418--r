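## CSV interchange formats and the end-to-end pipeline.
##
## All times are timezone-naive local clock time: clock time, not elapsed
## time, drives every circadian quantity. Schemas:
##   actigraphy:  timestamp (ISO-8601 "YYYY-MM-DD HH:MM:SS"), counts
##   diary:       date (YYYY-MM-DD), bed_start (HH:MM), bed_end (HH:MM)
##   urine:       patient_id, nucleoside, time_h, concentration_ug_per_g_creatinine
##   courses:     patient_id, day, concentration  (day 0 = course start)
##   cea:         patient_id, day, cea_mg_per_l   (day offsets from course start)
##   outcomes:    patient_id, survival_months, toxicity_grade

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_param(basename(path), ": missing columns: ",
               paste(miss, collapse = ", "))
}

#' Read an actigraphy recording from CSV
#'
#' @param counts_path CSV with `timestamp` (ISO-8601) and `counts`; epochs
#'   must be uniformly spaced and counts non-negative.
#' @param diary_path optional CSV with `date`, `bed_start`, `bed_end`.
#' @return an [actigraphy_series()].
#' @export
read_actigraphy <- function(counts_path, diary_path = NULL) {
  df <- read.csv(counts_path, stringsAsFactors = FALSE)
  .require_cols(df, c("timestamp", "counts"), counts_path)
  ts <- as.POSIXct(df$timestamp, tz = "UTC")
  if (anyNA(ts)) {
    row <- which(is.na(ts))[1]
    stop_param(basename(counts_path), " row ", row,
               ": unparseable timestamp '", df$timestamp[row], "'")
  }
  d <- diff(as.numeric(ts)) / 60
  if (length(d)) {
    bad <- which(abs(d - d[1]) > 1e-6)
    if (length(bad))
      stop_param(basename(counts_path), " row ", bad[1] + 1,
                 ": non-uniform epoch spacing (", d[bad[1]],
                 " min, expected ", d[1], " min)")
    if (d[1] != round(d[1]) || d[1] < 1)
      stop_param(basename(counts_path), ": epoch spacing must be a ",
                 "whole positive number of minutes")
  }
  bad <- which(!is.finite(df$counts) | df$counts < 0)
  if (length(bad))
    stop_param(basename(counts_path), " row ", bad[1],
               ", column counts: negative or non-finite value")
  day0 <- as.Date(ts[1], tz = "UTC")
  start_min <- as.numeric(difftime(ts[1],
                                   as.POSIXct(paste(day0, "00:00:00"),
                                              tz = "UTC"), units = "mins"))
  diary <- NULL
  if (!is.null(diary_path)) {
    dd <- read.csv(diary_path, stringsAsFactors = FALSE)
    .require_cols(dd, c("date", "bed_start", "bed_end"), diary_path)
    diary <- data.frame(day = as.integer(as.Date(dd$date) - day0),
                        bed_start = dd$bed_start, bed_end = dd$bed_end)
  }
  actigraphy_series(df$counts,
                    epoch_minutes = if (length(d)) as.integer(round(d[1])) else 1L,
                    start_min = start_min, diary = diary)
}

#' Write an actigraphy recording to CSV
#'
#' Inverse of [read_actigraphy()]; timestamps are anchored at `origin_date`.
#'
#' @param series an [actigraphy_series()].
#' @param counts_path,diary_path output paths (`diary_path` optional).
#' @param origin_date date of study day 0.
#' @export
write_actigraphy <- function(series, counts_path, diary_path = NULL,
                             origin_date = as.Date("2020-01-01")) {
  t0 <- as.POSIXct(paste(origin_date, "00:00:00"), tz = "UTC") +
    epoch_start_minutes(series) * 60
  write.csv(data.frame(timestamp = format(t0, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                       counts = series$counts),
            counts_path, row.names = FALSE)
  if (!is.null(diary_path) && !is.null(series$diary)) {
    write.csv(data.frame(date = as.character(origin_date + series$diary$day),
                         bed_start = format_clock(series$diary$bed_start / 60),
                         bed_end = format_clock(series$diary$bed_end / 60)),
              diary_path, row.names = FALSE)
  }
  invisible(counts_path)
}

#' Read a timed-urine panel from CSV
#'
#' @param path CSV with `patient_id`, `nucleoside`, `time_h` and
#'   `concentration_ug_per_g_creatinine` (strictly positive).
#' @return data.frame `patient_id`, `nucleoside`, `time_h`, `concentration`.
#' @export
read_urine <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("patient_id", "nucleoside", "time_h",
                      "concentration_ug_per_g_creatinine"), path)
  bad <- which(!is.finite(df$concentration_ug_per_g_creatinine) |
                 df$concentration_ug_per_g_creatinine <= 0)
  if (length(bad))
    stop_param(basename(path), " row ", bad[1],
               ", column concentration_ug_per_g_creatinine: ",
               "non-positive or non-finite value")
  key <- paste(df$patient_id, df$nucleoside, df$time_h)
  if (anyDuplicated(key))
    stop_param(basename(path), " row ", which(duplicated(key))[1],
               ": duplicate (patient, nucleoside, time)")
  data.frame(patient_id = df$patient_id, nucleoside = df$nucleoside,
             time_h = df$time_h,
             concentration = df$concentration_ug_per_g_creatinine,
             stringsAsFactors = FALSE)
}

#' @rdname read_urine
#' @param urine data.frame as returned by [read_urine()].
#' @export
write_urine <- function(urine, path) {
  write.csv(data.frame(patient_id = urine$patient_id,
                       nucleoside = urine$nucleoside, time_h = urine$time_h,
                       concentration_ug_per_g_creatinine = urine$concentration),
            path, row.names = FALSE)
  invisible(path)
}

#' Read treatment courses from CSVs
#'
#' @param course_path CSV `patient_id`, `day`, `concentration`.
#' @param cea_path CSV `patient_id`, `day`, `cea_mg_per_l`.
#' @param outcomes_path CSV `patient_id`, `survival_months` and optional
#'   `toxicity_grade`.
#' @return named list of `treatment_course` objects.
#' @export
read_courses <- function(course_path, cea_path, outcomes_path) {
  ex <- read.csv(course_path, stringsAsFactors = FALSE)
  .require_cols(ex, c("patient_id", "day", "concentration"), course_path)
  bad <- which(!is.finite(ex$concentration) | ex$concentration <= 0)
  if (length(bad))
    stop_param(basename(course_path), " row ", bad[1],
               ", column concentration: non-positive or non-finite value")
  cea <- read.csv(cea_path, stringsAsFactors = FALSE)
  .require_cols(cea, c("patient_id", "day", "cea_mg_per_l"), cea_path)
  oc <- read.csv(outcomes_path, stringsAsFactors = FALSE)
  .require_cols(oc, c("patient_id", "survival_months"), outcomes_path)

  lapply(setNames(nm = unique(ex$patient_id)), function(pid) {
    e <- ex[ex$patient_id == pid, setdiff(names(ex), "patient_id"),
            drop = FALSE]
    structure(list(
      patient_id = pid,
      excretion = e[order(e$day), , drop = FALSE],
      cea = cea[cea$patient_id == pid, c("day", "cea_mg_per_l"), drop = FALSE],
      survival_months = oc$survival_months[match(pid, oc$patient_id)],
      toxicity_grade = if ("toxicity_grade" %in% names(oc))
        oc$toxicity_grade[match(pid, oc$patient_id)] else NA_integer_),
      class = "treatment_course")
  })
}

#' Write a synthetic cohort to the interchange CSV formats
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nucleoside_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write_urine(cohort$urine, file.path(dir, "urine.csv"))
  for (pid in names(cohort$actigraphy)) {
    write_actigraphy(cohort$actigraphy[[pid]]$series,
                     file.path(dir, paste0("actigraphy_", pid, ".csv")),
                     file.path(dir, paste0("diary_", pid, ".csv")))
  }
  ex <- do.call(rbind, lapply(cohort$courses, function(cs)
    data.frame(patient_id = cs$patient_id, cs$excretion)))
  write.csv(ex, file.path(dir, "courses.csv"), row.names = FALSE)
  cea <- do.call(rbind, lapply(cohort$courses, function(cs)
    data.frame(patient_id = cs$patient_id, cs$cea)))
  write.csv(cea, file.path(dir, "cea.csv"), row.names = FALSE)
  oc <- do.call(rbind, lapply(cohort$courses, function(cs)
    data.frame(patient_id = cs$patient_id,
               survival_months = cs$survival_months,
               toxicity_grade = cs$toxicity_grade)))
  write.csv(oc, file.path(dir, "outcomes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Pipeline configuration
#'
#' @param scenario simulation scenario for [generate_cohort()] (ignored when
#'   input paths are given).
#' @param n_patients simulated cohort size.
#' @param seed integer seed governing every stochastic step.
#' @param alpha_rhythm cosinor rhythm threshold (default 0.1).
#' @param alpha_trend trend slope threshold (default 0.05).
#' @param bootstrap_B residual-bootstrap trials (default 1000; 0 skips the
#'   bootstrap stage).
#' @param bootstrap_quantile quantile compared to `alpha_rhythm` in the
#'   bootstrap check (default 0.9).
#' @param hmm_restarts EM restarts per patient (default 10 in the pipeline).
#' @param out_dir optional directory for the emitted tables and manifest.
#' @param config_path optional YAML/JSON file whose fields override the
#'   defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = "mixed", n_patients = 29L, seed = 1L,
                            alpha_rhythm = 0.1, alpha_trend = 0.05,
                            bootstrap_B = 1000L, bootstrap_quantile = 0.9,
                            hmm_restarts = 10L, out_dir = NULL,
                            config_path = NULL) {
  cfg <- list(scenario = scenario, n_patients = as.integer(n_patients),
              seed = as.integer(seed), alpha_rhythm = alpha_rhythm,
              alpha_trend = alpha_trend, bootstrap_B = as.integer(bootstrap_B),
              bootstrap_quantile = bootstrap_quantile,
              hmm_restarts = as.integer(hmm_restarts), out_dir = out_dir)
  if (!is.null(config_path)) {
    ext <- tolower(tools::file_ext(config_path))
    over <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config_path)
            else jsonlite::read_json(config_path, simplifyVector = TRUE)
    cfg[names(over)] <- over
  }
  ## alpha_rhythm = 0 is an allowed boundary (flags nothing); the other
  ## levels must be proper probabilities
  if (cfg$alpha_rhythm < 0 || cfg$alpha_rhythm >= 1)
    stop_param("alpha_rhythm must lie in [0, 1)")
  check_prob(cfg$alpha_trend, "alpha_trend")
  check_prob(cfg$bootstrap_quantile, "bootstrap_quantile")
  structure(cfg, class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full study pipeline on a (simulated) cohort
#'
#' Executes the stages in study order: cohort simulation, rest-activity
#' quantification (HMM + indices), cosinor rhythm analysis with eligibility
#' accounting, the Spearman correlation grid with the bootstrap uncertainty
#' check, and the chemotherapy-response analysis (trend x CEA exact test,
#' survival contrast). Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built [generate_cohort()] object (the
#'   simulation stage is then skipped).
#' @return a report list: `cohort`, `rest_activity` (per-patient indices),
#'   `cosinor_fits`, `parameter_table`, `cohort_summary`, `eligibility`,
#'   `correlations`, `bootstrap_checks`, `chemo` (table + p + survival),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    .stage_log("simulate", "generating cohort: n = ", config$n_patients,
               ", scenario = ", config$scenario)
    cohort <- generate_cohort(config$n_patients, config$scenario, config$seed)
  }
  ids <- cohort$covariates$patient_id

  .stage_log("actigraphy", "fitting HMM and indices for ", length(ids),
             " patients")
  ra <- do.call(rbind, lapply(seq_along(ids), function(i) {
    s <- cohort$actigraphy[[ids[i]]]$series
    cbind(data.frame(patient_id = ids[i], stringsAsFactors = FALSE),
          rest_activity_indices(s, n_restarts = config$hmm_restarts,
                                seed = config$seed + i))
  }))

  .stage_log("cosinor", "fitting two-component cosinor models")
  elig <- list(); fits <- list()
  for (pid in ids) {
    for (nuc in unique(cohort$urine$nucleoside)) {
      d <- cohort$urine[cohort$urine$patient_id == pid &
                          cohort$urine$nucleoside == nuc, ]
      el <- check_eligibility(d$time_h, d$concentration)
      elig[[length(elig) + 1L]] <-
        data.frame(patient_id = pid, nucleoside = nuc,
                   n_valid = el$n_valid, eligible = el$eligible,
                   stringsAsFactors = FALSE)
      if (el$eligible) {
        fits[[paste(pid, nuc, sep = ".")]] <-
          fit_multicomponent_cosinor(d$time_h, d$concentration,
                                     alpha = config$alpha_rhythm,
                                     patient_id = pid, nucleoside = nuc)
      }
    }
  }
  elig <- do.call(rbind, elig)
  .stage_log("cosinor", sum(elig$eligible), " eligible series analysed, ",
             sum(!elig$eligible), " excluded (< 7 valid samples)")
  ptab <- cosinor_parameter_table(fits)
  summ <- summarize_cohort(fits)

  .stage_log("associate", "Spearman grid and bootstrap uncertainty check")
  ## merged per-patient table: rest-activity indices + per-nucleoside
  ## relative amplitudes
  merged <- ra[, c("patient_id", "i_lt_o", "r24", "p11", "median_ha",
                   "rest_duration_a", "rhythm_index")]
  for (nuc in unique(ptab$nucleoside)) {
    v <- ptab$relative_amplitude[ptab$nucleoside == nuc]
    names(v) <- ptab$patient_id[ptab$nucleoside == nuc]
    merged[[paste0("relamp.", nuc)]] <- unname(v[merged$patient_id])
  }
  correlations <- spearman_matrix(merged[, -1, drop = FALSE])

  boot <- NULL
  if (config$bootstrap_B > 0) {
    boot <- lapply(setNames(nm = unique(ptab$nucleoside)), function(nuc) {
      fl <- fits[vapply(fits, function(f) identical(f$nucleoside, nuc), TRUE)]
      ord <- match(vapply(fl, function(f) f$patient_id, character(1)),
                   merged$patient_id)
      bootstrap_correlation_check(
        fl, param = "relative_amplitude",
        other = merged$rest_duration_a[ord], B = config$bootstrap_B,
        seed = config$seed, alpha = config$alpha_rhythm,
        quantile_level = config$bootstrap_quantile)
    })
  }

  .stage_log("chemo", "trend classification and CEA association")
  ## the survival contrast needs >= 2 patients per trend class; small or
  ## homogeneous cohorts simply report it as unavailable
  surv <- tryCatch(survival_by_trend(cohort$courses,
                                     alpha_trend = config$alpha_trend),
                   error = function(e) {
                     .stage_log("chemo", "survival contrast unavailable: ",
                                conditionMessage(e))
                     NULL
                   })
  chemo <- list(association = trend_cea_association(
                  cohort$courses, alpha_trend = config$alpha_trend),
                survival = surv)

  manifest <- list(package = "circanuc",
                   version = as.character(utils::packageVersion("circanuc")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config = unclass(config)[setdiff(names(config), "out_dir")])

  report <- list(cohort = cohort, rest_activity = ra, cosinor_fits = fits,
                 parameter_table = ptab, cohort_summary = summ,
                 eligibility = elig, correlations = correlations,
                 bootstrap_checks = boot, chemo = chemo, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ra, file.path(config$out_dir, "rest_activity_indices.csv"),
              row.names = FALSE)
    write.csv(ptab, file.path(config$out_dir, "cosinor_parameters.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(config$out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    write.csv(correlations, file.path(config$out_dir, "correlation_grid.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(chemo$association$table),
              file.path(config$out_dir, "trend_cea_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
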