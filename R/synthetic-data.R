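## Synthetic cohort generators.
##
## These emulate the three data streams of a circadian-monitoring study in
## metastatic colorectal cancer: (i) 1-min wrist-actigraphy over several days
## with a sleep-diary bed window, (ii) timed urinary modified-nucleoside
## concentrations collected at five clock times per day over two days, and
## (iii) daily overnight excretion around a chemotherapy course together with
## plasma CEA and survival. Every generator is a deterministic function of
## (params, seed) and returns its latent ground truth for oracle testing.

#' Parameters for the actigraphy generator
#'
#' @param bed_start,bed_end nominal diary bed window, `"HH:MM"` or clock
#'   minutes; may wrap midnight. Must be non-degenerate.
#' @param bedtime_jitter_sd SD (minutes) of the night-to-night Gaussian jitter
#'   applied independently to both ends of the bed window.
#' @param emission_means,emission_sds per-state Gaussian emission parameters
#'   on the `log1p(counts)` scale, ordered IA < MA < HA. Means must be
#'   strictly increasing.
#' @param stay_probs per-state self-transition probabilities in (0,1); the MA
#'   value also sets the geometric dwell of nocturnal interruptions.
#' @param night_interruption_rate expected number (Poisson) of brief MA
#'   excursions per night inside the bed window.
#' @param n_days number of recorded days (>= 1).
#' @param epoch_minutes epoch length in minutes (default 1).
#' @return an `actigraphy_params` list.
#' @export
actigraphy_params <- function(bed_start = "23:00", bed_end = "07:00",
                              bedtime_jitter_sd = 15,
                              emission_means = c(0.4, 3.0, 5.0),
                              emission_sds = c(0.45, 0.8, 0.6),
                              stay_probs = c(0.99, 0.9, 0.9),
                              night_interruption_rate = 1,
                              n_days = 5L, epoch_minutes = 1L) {
  bed_start <- clock_to_minutes(bed_start)
  bed_end <- clock_to_minutes(bed_end)
  if ((bed_end - bed_start) %% MINUTES_PER_DAY == 0)
    stop_param("bed interval is degenerate")
  if (length(emission_means) != 3 || any(diff(emission_means) <= 0))
    stop_param("emission_means must be 3 strictly increasing values (IA < MA < HA)")
  if (length(emission_sds) != 3 || any(emission_sds <= 0))
    stop_param("emission_sds must be 3 positive values")
  check_prob(stay_probs, "stay_probs")
  if (night_interruption_rate < 0)
    stop_param("night_interruption_rate must be >= 0")
  if (bedtime_jitter_sd < 0) stop_param("bedtime_jitter_sd must be >= 0")
  n_days <- as.integer(n_days)
  if (n_days < 1L) stop_param("n_days must be >= 1")
  structure(list(bed_start = bed_start, bed_end = bed_end,
                 bedtime_jitter_sd = bedtime_jitter_sd,
                 emission_means = emission_means, emission_sds = emission_sds,
                 stay_probs = stay_probs,
                 night_interruption_rate = night_interruption_rate,
                 n_days = n_days, epoch_minutes = as.integer(epoch_minutes)),
            class = "actigraphy_params")
}

#' Simulate a wrist-actigraphy recording with known latent states
#'
#' Epochs inside the (jittered) nightly bed window are in the inactive/rest
#' state IA, apart from Poisson-count brief interruptions that excurse to MA
#' with a geometric dwell time. Epochs out of bed alternate between MA and HA
#' as a two-state Markov chain with the given self-transition probabilities.
#' Counts are emitted per state as `round(max(0, expm1(Normal)))` on the
#' `log1p` scale, i.e. truncated, integer-rounded lognormal-type counts.
#'
#' @param params an [actigraphy_params()] object.
#' @param seed integer RNG seed; same `(params, seed)` reproduces the output
#'   bitwise.
#' @return a list with `series` (an [actigraphy_series()] whose diary holds
#'   the jittered bed windows) and `states` (integer latent states, 1 = IA,
#'   2 = MA, 3 = HA).
#' @export
generate_actigraphy <- function(params, seed) {
  stopifnot(inherits(params, "actigraphy_params"))
  set.seed(as.integer(seed))
  ep <- params$epoch_minutes
  n <- params$n_days * MINUTES_PER_DAY %/% ep
  t0 <- (seq_len(n) - 1) * ep                 # absolute minutes from day-0 midnight
  dur <- (params$bed_end - params$bed_start) %% MINUTES_PER_DAY

  ## nights d = -1 .. n_days-1; night -1 covers a wake-up inside the recording
  nights <- seq.int(-1L, params$n_days - 1L)
  starts <- params$bed_start +
    rnorm(length(nights), 0, params$bedtime_jitter_sd)
  ends <- params$bed_start + dur +
    rnorm(length(nights), 0, params$bedtime_jitter_sd)
  abs_start <- nights * MINUTES_PER_DAY + starts
  abs_end <- nights * MINUTES_PER_DAY + ends

  states <- integer(n)
  inbed <- rep(FALSE, n)
  for (k in seq_along(nights)) {
    inbed <- inbed | (t0 >= abs_start[k] & t0 < abs_end[k])
  }
  states[inbed] <- 1L

  ## nocturnal interruptions: brief MA excursions with geometric dwell
  for (k in seq_along(nights)) {
    n_int <- rpois(1, params$night_interruption_rate)
    if (n_int == 0) next
    at <- runif(n_int, abs_start[k], abs_end[k])
    len <- 1L + rgeom(n_int, 1 - params$stay_probs[2])
    for (j in seq_len(n_int)) {
      idx <- which(t0 >= at[j] & t0 < at[j] + len[j] * ep & inbed)
      states[idx] <- 2L
    }
  }

  ## daytime MA/HA Markov chain
  day_idx <- which(!inbed)
  if (length(day_idx)) {
    u <- runif(length(day_idx))
    s <- 2L
    for (i in seq_along(day_idx)) {
      stay <- if (s == 2L) params$stay_probs[2] else params$stay_probs[3]
      if (u[i] > stay) s <- if (s == 2L) 3L else 2L
      states[day_idx[i]] <- s
    }
  }

  z <- rnorm(n, params$emission_means[states], params$emission_sds[states])
  counts <- round(pmax(0, expm1(z)))

  diary <- data.frame(day = nights,
                      bed_start = starts %% MINUTES_PER_DAY,
                      bed_end = ends %% MINUTES_PER_DAY)
  list(series = actigraphy_series(counts, epoch_minutes = ep, start_min = 0,
                                  diary = diary),
       states = states)
}

#' Parameters for the timed urinary excretion generator
#'
#' The simulated log-concentration is a two-component (12 h + 24 h) cosine
#' curve plus Gaussian noise; concentrations are its exponential.
#'
#' @param mesor_log rhythm-adjusted mean on the natural-log scale.
#' @param amp12_log,amp24_log non-negative component amplitudes (log scale).
#' @param phase12,phase24 component acrophase angles in radians (the model
#'   uses `+theta` inside the cosine, so a component peaks at clock time
#'   `-theta * T / (2 * pi) mod T`).
#' @param noise_sd_log residual SD on the log scale (>= 0).
#' @param sample_times sampling times in hours from midnight of collection
#'   day 1; the default is the study schedule of 10 samples at 07:00, 11:00,
#'   15:00, 19:00 and 23:00 on two consecutive days.
#' @return a `urine_sim_params` list.
#' @export
urine_sim_params <- function(mesor_log = log(10), amp12_log = 0.1,
                             amp24_log = 0.4, phase12 = 0,
                             phase24 = -2 * pi * 13 / 24,
                             noise_sd_log = 0.15,
                             sample_times = study_sample_times()) {
  if (amp12_log < 0 || amp24_log < 0) stop_param("amplitudes must be >= 0")
  if (noise_sd_log < 0) stop_param("noise_sd_log must be >= 0")
  structure(list(mesor_log = mesor_log, amp12_log = amp12_log,
                 amp24_log = amp24_log, phase12 = phase12, phase24 = phase24,
                 noise_sd_log = noise_sd_log,
                 sample_times = as.numeric(sample_times)),
            class = "urine_sim_params")
}

#' The study's 10 urine collection times (hours from day-1 midnight)
#' @export
study_sample_times <- function() {
  c(7, 11, 15, 19, 23, 7 + 24, 11 + 24, 15 + 24, 19 + 24, 23 + 24)
}

# Deterministic two-component log-cosine curve.
urine_curve_log <- function(t_h, p) {
  p$mesor_log +
    p$amp12_log * cos(2 * pi * t_h / 12 + p$phase12) +
    p$amp24_log * cos(2 * pi * t_h / 24 + p$phase24)
}

#' Simulate timed urinary concentrations for one nucleoside
#'
#' @param params a [urine_sim_params()] object.
#' @param seed integer RNG seed.
#' @return data.frame with `time_h` and `concentration` (strictly positive).
#' @export
generate_urine_series <- function(params, seed) {
  stopifnot(inherits(params, "urine_sim_params"))
  set.seed(as.integer(seed))
  mu <- urine_curve_log(params$sample_times, params)
  eps <- rnorm(length(mu), 0, params$noise_sd_log)
  data.frame(time_h = params$sample_times, concentration = exp(mu + eps))
}

#' Parameters for the treatment-course generator
#'
#' @param baseline_log log of the overnight excretion on the first monitored
#'   day.
#' @param daily_slope_log log-scale change per day.
#' @param noise_sd_log day-to-day residual SD on the log scale (>= 0).
#' @param n_pre_days,n_post_days monitored days before/after the course
#'   (defaults 3 and 14; their sum must be >= 5).
#' @param cea_category one of `"decrease"`, `"stable"`, `"increase"`; the
#'   simulated CEA follow-up/baseline ratio is drawn consistently with it
#'   (< 2/3, within [2/3, 1.5], or > 1.5).
#' @param survival_months overall survival (> 0).
#' @param baseline_cea baseline plasma CEA in mg/L.
#' @return a `course_sim_params` list.
#' @export
course_sim_params <- function(baseline_log = log(10), daily_slope_log = 0,
                              noise_sd_log = 0.1, n_pre_days = 3L,
                              n_post_days = 14L,
                              cea_category = c("stable", "decrease", "increase"),
                              survival_months = 12, baseline_cea = 10) {
  cea_category <- match.arg(cea_category)
  if (noise_sd_log < 0) stop_param("noise_sd_log must be >= 0")
  n_pre_days <- as.integer(n_pre_days); n_post_days <- as.integer(n_post_days)
  if (n_pre_days + n_post_days < 5L)
    stop_param("need at least 5 monitored days (n_pre_days + n_post_days >= 5)")
  if (survival_months <= 0) stop_param("survival_months must be > 0")
  structure(list(baseline_log = baseline_log,
                 daily_slope_log = daily_slope_log,
                 noise_sd_log = noise_sd_log, n_pre_days = n_pre_days,
                 n_post_days = n_post_days, cea_category = cea_category,
                 survival_months = survival_months,
                 baseline_cea = baseline_cea),
            class = "course_sim_params")
}

#' Simulate a chemotherapy treatment course
#'
#' Daily overnight excretions follow `exp(baseline_log + slope * day + noise)`
#' over `n_pre_days` days before and `n_post_days` days after the course
#' (day 0 = course start, pre-course days are negative). CEA is simulated as
#' a baseline draw one week before the course and one follow-up at day 45,
#' with a ratio drawn inside the band of the requested category.
#'
#' @param params a [course_sim_params()] object.
#' @param seed integer RNG seed.
#' @return a `treatment_course` list with `excretion` (day, concentration),
#'   `cea` (day, cea_mg_per_l), `survival_months`, `toxicity_grade`, and the
#'   generating parameters in `truth`.
#' @export
generate_treatment_course <- function(params, seed) {
  stopifnot(inherits(params, "course_sim_params"))
  set.seed(as.integer(seed))
  day <- c(seq.int(-params$n_pre_days, -1L), seq_len(params$n_post_days))
  rel <- day - day[1]
  conc <- exp(params$baseline_log + params$daily_slope_log * rel +
                rnorm(length(day), 0, params$noise_sd_log))
  ratio <- switch(params$cea_category,
                  increase = runif(1, 1.7, 3.0),
                  stable = runif(1, 0.85, 1.18),
                  decrease = runif(1, 0.30, 0.60))
  cea0 <- params$baseline_cea * exp(rnorm(1, 0, 0.05))
  cea <- data.frame(day = c(-7, 45), cea_mg_per_l = c(cea0, cea0 * ratio))
  structure(list(patient_id = NA_character_,
                 excretion = data.frame(day = day, concentration = conc),
                 cea = cea, survival_months = params$survival_months,
                 toxicity_grade = 0L, truth = params),
            class = "treatment_course")
}

## --- cohort-level presets -------------------------------------------------

# Typical median overnight mesors (ug/g creatinine) per nucleoside in
# metastatic colorectal cancer cohorts.
NUCLEOSIDES <- c("pseudouridine" = 64.3, "1-methylguanosine" = 7.22,
                 "1-methyladenosine" = 6.84, "N2-N2-dimethylguanosine" = 6.35,
                 "4-acetylcytidine" = 3.11, "1-methylinosine" = 2.32,
                 "adenosine" = 0.69, "cytidine" = 0.58)

# Per-profile generator settings. "robust" emulates a regular rest-activity
# and excretion rhythm, "disrupted" an eroded one.
.profile_settings <- function(profile) {
  switch(profile,
         robust = list(jitter = 5, interruptions = 0.5,
                       amp24 = c(0.30, 0.60), amp12 = c(0.05, 0.20),
                       noise = 0.15),
         intermediate = list(jitter = 30, interruptions = 3,
                             amp24 = c(0.10, 0.30), amp12 = c(0.02, 0.10),
                             noise = 0.20),
         disrupted = list(jitter = 75, interruptions = 8,
                          amp24 = c(0.00, 0.10), amp12 = c(0.00, 0.05),
                          noise = 0.25),
         stop_param("unknown profile: ", profile))
}

#' Simulate a full study cohort
#'
#' Draws per-patient covariates, a 5-day actigraphy recording, a 10-sample
#' two-day urine panel for eight modified nucleosides, and a treatment course
#' with CEA and survival. Scenario presets control the circadian phenotype
#' mix: `"robust-rhythm"` (all patients regular), `"disrupted"` (all eroded)
#' or `"mixed"` (a robust/intermediate/disrupted blend).
#'
#' @param n_patients number of patients (>= 1).
#' @param scenario preset name.
#' @param seed integer RNG seed.
#' @param n_samples urine samples per patient (default the 10 study times;
#'   smaller values truncate the schedule, for eligibility testing).
#' @return a `nucleoside_cohort` list: `covariates` (data.frame),
#'   `actigraphy` (per-patient list of `series` + latent `states`), `urine`
#'   (long data.frame patient_id/nucleoside/time_h/concentration),
#'   `urine_truth` (generating parameters), `courses` (list of
#'   `treatment_course`), plus `scenario` and `seed`.
#' @export
generate_cohort <- function(n_patients, scenario = c("mixed", "robust-rhythm",
                                                     "disrupted"),
                            seed, n_samples = 10L) {
  scenario <- match.arg(scenario)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L)
    stop_param("n_patients must be >= 1")
  set.seed(as.integer(seed))
  ids <- sprintf("P%03d", seq_len(n_patients))

  profiles <- switch(scenario,
    "robust-rhythm" = rep("robust", n_patients),
    "disrupted" = rep("disrupted", n_patients),
    "mixed" = sample(c("robust", "intermediate", "disrupted"), n_patients,
                     replace = TRUE, prob = c(0.40, 0.35, 0.25)))

  covariates <- data.frame(
    patient_id = ids,
    sex = sample(c("F", "M"), n_patients, TRUE, prob = c(0.4, 0.6)),
    age = pmin(pmax(round(rnorm(n_patients, 64, 10)), 30), 88),
    who_ps = sample(0:2, n_patients, TRUE, prob = c(0.50, 0.35, 0.15)),
    primary_site = sample(c("colon", "rectum"), n_patients, TRUE,
                          prob = c(0.65, 0.35)),
    comorbidities = sample(c("yes", "no"), n_patients, TRUE),
    prior_surgery = sample(c("yes", "no"), n_patients, TRUE,
                           prob = c(0.7, 0.3)),
    chemo_lines = sample(1:4, n_patients, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
    profile = profiles,
    stringsAsFactors = FALSE)

  child <- matrix(sample.int(.Machine$integer.max - 1L,
                             n_patients * (2L + length(NUCLEOSIDES))),
                  nrow = n_patients)
  times <- study_sample_times()[seq_len(min(n_samples, 10L))]

  actigraphy <- vector("list", n_patients); names(actigraphy) <- ids
  urine <- list(); urine_truth <- list()
  courses <- vector("list", n_patients); names(courses) <- ids

  for (i in seq_len(n_patients)) {
    cfg <- .profile_settings(profiles[i])
    apar <- actigraphy_params(bedtime_jitter_sd = cfg$jitter,
                              night_interruption_rate = cfg$interruptions)
    ## per-patient rhythm phase and amplitudes (shared acrophase tendency
    ## around early afternoon, as in the cohort summaries)
    phase24 <- -2 * pi * 13 / 24 + rnorm(1, 0, 0.5)
    for (nuc in names(NUCLEOSIDES)) {
      upar <- urine_sim_params(
        mesor_log = log(NUCLEOSIDES[[nuc]]) + rnorm(1, 0, 0.30),
        amp12_log = runif(1, cfg$amp12[1], cfg$amp12[2]),
        amp24_log = runif(1, cfg$amp24[1], cfg$amp24[2]),
        phase12 = runif(1, -pi, pi), phase24 = phase24,
        noise_sd_log = cfg$noise, sample_times = times)
      us <- generate_urine_series(upar, child[i, 2L + match(nuc, names(NUCLEOSIDES))])
      urine[[length(urine) + 1L]] <-
        data.frame(patient_id = ids[i], nucleoside = nuc, us,
                   stringsAsFactors = FALSE)
      urine_truth[[length(urine_truth) + 1L]] <-
        data.frame(patient_id = ids[i], nucleoside = nuc,
                   mesor_log = upar$mesor_log, amp12_log = upar$amp12_log,
                   amp24_log = upar$amp24_log, phase12 = upar$phase12,
                   phase24 = upar$phase24, stringsAsFactors = FALSE)
    }
    trend_type <- sample(c("none", "increase", "decrease"), 1,
                         prob = c(0.6, 0.2, 0.2))
    slope <- switch(trend_type, none = 0, increase = 0.08, decrease = -0.08)
    cea_cat <- if (trend_type == "none") {
      sample(c("stable", "increase", "decrease"), 1, prob = c(0.8, 0.1, 0.1))
    } else sample(c("increase", "stable", "decrease"), 1,
                  prob = c(0.6, 0.3, 0.1))
    surv <- exp(rnorm(1, log(if (trend_type == "none") 18 else 9), 0.35))
    cpar <- course_sim_params(
      baseline_log = log(NUCLEOSIDES[["1-methylguanosine"]]) + rnorm(1, 0, 0.3),
      daily_slope_log = slope, noise_sd_log = 0.1,
      cea_category = cea_cat, survival_months = surv)

    actigraphy[[i]] <- generate_actigraphy(apar, child[i, 1])
    courses[[i]] <- generate_treatment_course(cpar, child[i, 2])
    courses[[i]]$patient_id <- ids[i]
  }

  structure(list(covariates = covariates, actigraphy = actigraphy,
                 urine = do.call(rbind, urine),
                 urine_truth = do.call(rbind, urine_truth),
                 courses = courses, scenario = scenario,
                 seed = as.integer(seed)),
            class = "nucleoside_cohort")
}

#' @export
print.nucleoside_cohort <- function(x, ...) {
  cat(sprintf("<nucleoside_cohort> %d patients, scenario '%s', seed %d\n",
              nrow(x$covariates), x$scenario, x$seed))
  invisible(x)
}
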