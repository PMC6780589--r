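# Synthetic cohort generator ------------------------------------------------
#
# Emulates the structure of i2b2-style warehouse extracts for VOC stays:
# patients, hospital stays, and long-format irregular measurements with
# known ground-truth mean trajectories, so that cohort selection, trajectory
# estimation and threshold analyses can be validated end to end.

#' Piecewise-linear mean function
#'
#' Returns a vectorized function of time since admission (hours) that
#' linearly interpolates between the supplied anchor points and is constant
#' beyond them (flat extrapolation).
#'
#' @param t_hours numeric vector of anchor times in hours, strictly increasing.
#' @param values numeric vector of anchor values, same length.
#' @return a function `f(t)` defined for all `t >= 0`.
#' @export
#' @examples
#' hb <- piecewise_linear(c(0, 120), c(9.5, 8.5))
#' hb(c(0, 60, 120, 200))
piecewise_linear <- function(t_hours, values) {
  stopifnot(length(t_hours) == length(values), length(t_hours) >= 1,
            !is.unsorted(t_hours, strictly = TRUE))
  force(t_hours); force(values)
  function(t) approx(t_hours, values, xout = t, rule = 2)$y
}

#' Ground-truth trajectory for one simulated variable
#'
#' Bundles the population mean function with the variance components used by
#' [generate_cohort()]: a sinusoidal 24 h circadian term (amplitude 0 for
#' non-cyclic variables, peak at 18:00 clock time), an additive Gaussian
#' random intercept per (stay, variable), and iid Gaussian residual noise.
#'
#' @param variable variable label, e.g. `"hemoglobin"`.
#' @param mean_function vectorized function of hours since admission, defined
#'   on at least `[0, 240]`; see [piecewise_linear()].
#' @param unit measurement unit string carried into the measurements table.
#' @param circadian_amplitude amplitude of the 24 h cycle, in variable units
#'   (>= 0).
#' @param between_stay_sd standard deviation of the per-stay random
#'   intercept (>= 0).
#' @param residual_sd standard deviation of residual noise (>= 0).
#' @return an object of class `trajectory_truth`.
#' @export
trajectory_truth <- function(variable, mean_function, unit = "",
                             circadian_amplitude = 0,
                             between_stay_sd = 0, residual_sd = 0) {
  stopifnot(is.character(variable), length(variable) == 1L,
            is.function(mean_function))
  if (circadian_amplitude < 0 || between_stay_sd < 0 || residual_sd < 0)
    stop_cfg("trajectory_truth('%s'): amplitudes and sds must be >= 0", variable)
  structure(list(variable = variable, mean_function = mean_function,
                 unit = unit, circadian_amplitude = circadian_amplitude,
                 between_stay_sd = between_stay_sd, residual_sd = residual_sd),
            class = "trajectory_truth")
}

#' Default ground truths mirroring the described in-stay trends
#'
#' Five variables with the qualitative courses reported for non-complicated
#' VOC stays: hemoglobin drifting 9.5 to 8.5 g/dL over five days; a white
#' blood cell spike above 12e9/L around admission decaying to ~10e9/L by day
#' 2; eosinophils rising from 2 to 4e8/L by day 5; CRP climbing to a ~60 mg/L
#' plateau over the first two days then slowly declining; and temperature
#' stable around 37 degC with a day/night cycle.
#'
#' @return named list of [trajectory_truth()] objects.
#' @export
default_truths <- function() {
  list(
    hemoglobin = trajectory_truth(
      "hemoglobin", piecewise_linear(c(0, 120), c(9.5, 8.5)), unit = "g/dL",
      between_stay_sd = 1.5, residual_sd = 0.3),
    wbc = trajectory_truth(
      "wbc", piecewise_linear(c(0, 6, 48, 240), c(11.5, 12.5, 10, 10)),
      unit = "1e9/L", between_stay_sd = 3, residual_sd = 1),
    eosinophils = trajectory_truth(
      "eosinophils", piecewise_linear(c(0, 120), c(2, 4)), unit = "1e8/L",
      between_stay_sd = 1.5, residual_sd = 0.5),
    crp = trajectory_truth(
      "crp", piecewise_linear(c(0, 48, 96, 240), c(15, 60, 60, 45)),
      unit = "mg/L", between_stay_sd = 25, residual_sd = 10),
    temperature = trajectory_truth(
      "temperature", piecewise_linear(c(0, 240), c(37, 37)), unit = "degC",
      circadian_amplitude = 0.3, between_stay_sd = 0.2, residual_sd = 0.15)
  )
}

#' Measurement-time sampling intensity
#'
#' Piecewise-constant Poisson intensity: `early_per_day` expected
#' measurements per day before `changepoint_hours`, `late_per_day` after.
#' Setting `fixed_times` overrides the Poisson draw with a deterministic
#' schedule (clipped to the stay).
#'
#' @param early_per_day,late_per_day expected measurements per 24 h.
#' @param changepoint_hours boundary between the two rates (default 48 h).
#' @param fixed_times optional fixed schedule in hours since admission.
#' @return a `sampling_intensity` list.
#' @export
sampling_intensity <- function(early_per_day = 6, late_per_day = 2,
                               changepoint_hours = 48, fixed_times = NULL) {
  if (is.null(fixed_times) && (early_per_day <= 0 || late_per_day <= 0))
    stop_cfg("sampling_intensity: rates must be positive")
  structure(list(early_per_day = early_per_day, late_per_day = late_per_day,
                 changepoint_hours = changepoint_hours,
                 fixed_times = fixed_times),
            class = "sampling_intensity")
}

#' Simulation configuration
#'
#' The defaults state the cohort the generator emulates: 164 patients,
#' 1 to 10 stays per patient with median 2 (truncated geometric), stay
#' durations on 1..10 days with mean about 4.4 (shifted binomial), labs
#' denser in the first 48 h, and contaminant "complicated" stays planted at
#' the given per-rule rates.  `contamination["oud"]` is a per-patient
#' probability (opioid-use disorder excludes patients, not stays); the other
#' entries are per-stay probabilities among stays of non-OUD patients, drawn
#' as one categorical so each contaminant stay carries exactly one trigger.
#'
#' @param n_patients number of patients (>= 0).
#' @param stays_per_patient_prob probability vector over 1..10 stays.
#' @param stay_duration_prob probability vector over 1..10 whole days.
#' @param sampling a [sampling_intensity()].
#' @param contamination named rates for `non_voc`, `oud`, `icu`, `severity`,
#'   `transfusion`, `complication`; all in `[0,1]`, stay-level entries
#'   summing to at most 1.
#' @param truths named list of [trajectory_truth()] objects.
#' @param ar_coef optional within-stay AR(1) coefficient for residuals
#'   (default 0, i.e. independent residuals).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_patients = 164,
                              stays_per_patient_prob = stays_geometric(),
                              stay_duration_prob = duration_binomial(),
                              sampling = sampling_intensity(),
                              contamination = c(non_voc = 0.05, oud = 0.03,
                                                icu = 0.04, severity = 0.05,
                                                transfusion = 0.06,
                                                complication = 0.08),
                              truths = default_truths(),
                              ar_coef = 0,
                              seed = 1L) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0)
    stop_cfg("simulation_config: n_patients must be a non-negative count")
  stopifnot(length(stays_per_patient_prob) == 10L,
            length(stay_duration_prob) == 10L)
  if (any(stays_per_patient_prob < 0) || any(stay_duration_prob < 0))
    stop_cfg("simulation_config: probability vectors must be non-negative")
  need <- c("non_voc", "oud", "icu", "severity", "transfusion", "complication")
  if (!all(need %in% names(contamination)))
    stop_cfg("simulation_config: contamination must name %s",
             paste(need, collapse = ", "))
  if (any(contamination < 0) || any(contamination > 1))
    stop_cfg("simulation_config: contamination rates must lie in [0,1]")
  stay_lv <- setdiff(need, "oud")
  if (sum(contamination[stay_lv]) > 1)
    stop_cfg("simulation_config: stay-level contamination rates sum above 1")
  structure(list(n_patients = as.integer(n_patients),
                 stays_per_patient_prob = stays_per_patient_prob /
                   max(sum(stays_per_patient_prob), .Machine$double.eps),
                 stay_duration_prob = stay_duration_prob /
                   max(sum(stay_duration_prob), .Machine$double.eps),
                 sampling = sampling, contamination = contamination,
                 truths = truths, ar_coef = ar_coef,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
stays_geometric <- function(p = 0.45) {
  w <- p * (1 - p)^(0:9)
  w / sum(w)   # truncated geometric on 1..10, median 2 at p = 0.45
}

#' @rdname simulation_config
#' @export
duration_binomial <- function(mean_days = 4.4) {
  # duration = 1 + Binomial(9, p); mean 1 + 9p
  p <- (mean_days - 1) / 9
  stopifnot(p > 0, p < 1)
  stats::dbinom(0:9, 9, p)
}

# Vectorized piecewise-Poisson measurement times for many stays at once.
# Returns data.table(idx, t_h) where idx indexes `duration_hours`.
sample_times_bulk <- function(duration_hours, intensity) {
  stopifnot(inherits(intensity, "sampling_intensity"))
  if (any(duration_hours <= 0))
    stop_cfg("measurement-time sampling: stay duration must be positive")
  n <- length(duration_hours)
  if (!is.null(intensity$fixed_times)) {
    out <- data.table::rbindlist(lapply(seq_len(n), function(i) {
      tt <- intensity$fixed_times
      data.table::data.table(idx = i, t_h = tt[tt >= 0 & tt <= duration_hours[i]])
    }))
    return(out[order(out$idx, out$t_h)])
  }
  cp <- intensity$changepoint_hours
  early_len <- pmin(duration_hours, cp)
  late_len <- pmax(duration_hours - cp, 0)
  n_early <- rpois(n, intensity$early_per_day / 24 * early_len)
  n_late <- rpois(n, intensity$late_per_day / 24 * late_len)
  idx <- c(rep(seq_len(n), n_early), rep(seq_len(n), n_late))
  lo <- c(rep(0, sum(n_early)), rep(cp, sum(n_late)))
  span <- c(rep(early_len, n_early), rep(late_len, n_late))
  t_h <- lo + runif(length(idx)) * span
  out <- data.table::data.table(idx = idx, t_h = t_h)
  out <- out[order(out$idx, out$t_h)]
  # enforce strict increase within stay (ties have probability ~0)
  dup <- duplicated(out, by = c("idx", "t_h"))
  if (any(dup)) out <- out[!dup]
  out
}

#' Sample irregular measurement times for one stay
#'
#' Draws measurement times from a piecewise-constant Poisson process that is
#' denser early in the stay, mirroring real in-hospital sampling where labs
#' and vitals are checked most often right after admission.  Uses the
#' current RNG stream.
#'
#' @param duration_hours positive stay duration in hours.
#' @param intensity a [sampling_intensity()].
#' @return strictly increasing numeric vector of times in
#'   `[0, duration_hours]`.
#' @export
sample_measurement_times <- function(duration_hours,
                                     intensity = sampling_intensity()) {
  if (length(duration_hours) != 1L || is.na(duration_hours) ||
      duration_hours <= 0)
    stop_cfg("sample_measurement_times: duration must be a positive number")
  sample_times_bulk(duration_hours, intensity)$t_h
}

comorbidity_names <- function() {
  c("acute_chest_syndrome", "avascular_necrosis", "retinopathy",
    "leg_ulcer", "stroke", "dialysis", "pulmonary_hypertension", "priapism")
}

#' Generate a synthetic VOC cohort
#'
#' Produces the three long-format tables the pipeline consumes (patients,
#' stays, measurements) plus a truth log sufficient to score recovery of the
#' planted structure.  Fully reproducible from `config$seed`.
#'
#' Contaminant stays are planted so that each carries exactly the flags or
#' codes its exclusion rule tests: a non-VOC primary code (D57.1 instead of
#' D57.0), an ICU transfer flag, a coded severity of 3-4, a transfusion
#' flag, or an added complication diagnosis code.  Opioid-use disorder is
#' planted per patient (an F11 code or a methadone/buprenorphine
#' prescription on all of that patient's stays).
#'
#' @param config a [simulation_config()].
#' @return list of class `voc_cohort` with elements `patients`, `stays`,
#'   `measurements` (data.frames) and `truth_log` (list with `planted`
#'   per-stay rules and clock hours, `effects` per (stay, variable) random
#'   intercepts, and the `truths` used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  np <- config$n_patients
  empty <- function() {
    list(patients = empty_patients(), stays = empty_stays(),
         measurements = empty_measurements(),
         truth_log = list(planted = data.frame(stay_id = character(),
                                               rule = character(),
                                               clock_hour = numeric()),
                          effects = data.frame(stay_id = character(),
                                               variable = character(),
                                               intercept = numeric()),
                          truths = config$truths))
  }
  if (np == 0L) {
    out <- empty()
    class(out) <- "voc_cohort"
    return(out)
  }

  # patients ---------------------------------------------------------------
  pid <- sprintf("P%04d", seq_len(np))
  sex <- ifelse(runif(np) < 0.531, "female", "male")
  genotype <- ifelse(runif(np) < 0.738, "SS", "other")
  age <- round(rlnorm(np, log(27), 0.30), 1)
  hb <- round(ifelse(genotype == "SS", rnorm(np, 8.5, 0.8),
                     rnorm(np, 10.2, 0.8)), 1)
  hb <- pmin(pmax(hb, 4), 16)
  com_p <- c(acute_chest_syndrome = 0.677, avascular_necrosis = 0.226,
             retinopathy = 0.116, leg_ulcer = 0.061, stroke = 0.037,
             dialysis = 0.012, pulmonary_hypertension = 0.018,
             priapism = 0.169)
  patients <- data.frame(patient_id = pid, sex = sex, genotype = genotype,
                         age_at_first_admission = age, steady_state_hb = hb,
                         stringsAsFactors = FALSE)
  for (cm in comorbidity_names()) {
    v <- runif(np) < com_p[[cm]]
    if (cm == "priapism") v <- v & sex == "male"
    patients[[cm]] <- v
  }
  oud_patient <- runif(np) < config$contamination[["oud"]]
  oud_mech <- ifelse(runif(np) < 0.5, "code", "drug")

  # stays ------------------------------------------------------------------
  n_stays_pp <- sample.int(10L, np, replace = TRUE,
                           prob = config$stays_per_patient_prob)
  ns <- sum(n_stays_pp)
  stay_patient <- rep(seq_len(np), n_stays_pp)
  sid <- sprintf("S%05d", seq_len(ns))
  days <- sample.int(10L, ns, replace = TRUE, prob = config$stay_duration_prob)
  origin <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  adm <- origin + floor(runif(ns, 0, 2191)) * 86400 +  # 2010-2015
    floor(runif(ns, 0, 24)) * 3600 + floor(runif(ns, 0, 60)) * 60
  dis <- adm + days * 86400
  clock_hour <- as.numeric(format(adm, "%H", tz = "UTC")) +
    as.numeric(format(adm, "%M", tz = "UTC")) / 60

  rates <- config$contamination[c("non_voc", "icu", "severity",
                                  "transfusion", "complication")]
  rule <- sample(c(names(rates), "clean"), ns, replace = TRUE,
                 prob = c(rates, 1 - sum(rates)))
  rule[oud_patient[stay_patient]] <- "clean"  # OUD stays carry only the OUD trigger

  icd <- ifelse(rule == "non_voc", "D57.1", "D57.0")
  comp_codes <- c("J18.9", "A41.9", "I82.9")  # pneumonia, sepsis, thrombosis
  is_comp <- rule == "complication"
  icd[is_comp] <- paste(icd[is_comp],
                        sample(comp_codes, sum(is_comp), replace = TRUE),
                        sep = ";")
  severity <- ifelse(rule == "severity",
                     sample(3:4, ns, replace = TRUE),
                     sample(1:2, ns, replace = TRUE))
  drugs <- rep("", ns)
  is_oud_stay <- oud_patient[stay_patient]
  code_mech <- is_oud_stay & oud_mech[stay_patient] == "code"
  drug_mech <- is_oud_stay & !code_mech
  icd[code_mech] <- paste(icd[code_mech], "F11.2", sep = ";")
  drugs[drug_mech] <- sample(c("methadone", "buprenorphine"),
                             sum(drug_mech), replace = TRUE)
  rule[is_oud_stay] <- "oud"

  stays <- data.frame(stay_id = sid, patient_id = pid[stay_patient],
                      admission = adm, discharge = dis,
                      icu_flag = rule == "icu",
                      severity_level = as.integer(severity),
                      transfusion_flag = rule == "transfusion",
                      icd_codes = icd, drugs = drugs,
                      stringsAsFactors = FALSE)

  # measurements ------------------------------------------------------------
  dur_h <- days * 24
  meas <- vector("list", length(config$truths))
  eff <- vector("list", length(config$truths))
  for (k in seq_along(config$truths)) {
    tr <- config$truths[[k]]
    b <- rnorm(ns, 0, tr$between_stay_sd)
    tt <- sample_times_bulk(dur_h, config$sampling)
    i <- tt$idx
    mu <- tr$mean_function(tt$t_h) +
      tr$circadian_amplitude *
        cos(2 * pi * (clock_hour[i] + tt$t_h - 18) / 24) + b[i]
    if (config$ar_coef != 0 && tr$residual_sd > 0) {
      res <- ar1_by_group(i, config$ar_coef, tr$residual_sd)
    } else {
      res <- rnorm(nrow(tt), 0, tr$residual_sd)
    }
    meas[[k]] <- data.table::data.table(
      stay_id = sid[i], variable = tr$variable, time_hours = tt$t_h,
      value = mu + res, unit = tr$unit)
    eff[[k]] <- data.frame(stay_id = sid, variable = tr$variable,
                           intercept = b, stringsAsFactors = FALSE)
  }
  measurements <- as.data.frame(data.table::rbindlist(meas))
  measurements <- measurements[order(measurements$stay_id,
                                     measurements$variable,
                                     measurements$time_hours), ]
  rownames(measurements) <- NULL

  out <- list(patients = patients, stays = stays, measurements = measurements,
              truth_log = list(
                planted = data.frame(stay_id = sid, rule = rule,
                                     clock_hour = clock_hour,
                                     stringsAsFactors = FALSE),
                effects = do.call(rbind, eff),
                truths = config$truths))
  class(out) <- "voc_cohort"
  out
}

# stationary AR(1) residuals within each group (groups given by sorted idx)
ar1_by_group <- function(idx, phi, sd) {
  n <- length(idx)
  z <- rnorm(n, 0, sd)
  if (n == 0) return(z)
  res <- numeric(n)
  new_grp <- c(TRUE, idx[-1] != idx[-n])
  for (j in seq_len(n)) {
    res[j] <- if (new_grp[j]) z[j] else phi * res[j - 1] + sqrt(1 - phi^2) * z[j]
  }
  res
}

empty_patients <- function() {
  df <- data.frame(patient_id = character(), sex = character(),
                   genotype = character(), age_at_first_admission = numeric(),
                   steady_state_hb = numeric(), stringsAsFactors = FALSE)
  for (cm in comorbidity_names()) df[[cm]] <- logical()
  df
}

empty_stays <- function() {
  data.frame(stay_id = character(), patient_id = character(),
             admission = as.POSIXct(character(), tz = "UTC"),
             discharge = as.POSIXct(character(), tz = "UTC"),
             icu_flag = logical(), severity_level = integer(),
             transfusion_flag = logical(), icd_codes = character(),
             drugs = character(), stringsAsFactors = FALSE)
}

empty_measurements <- function() {
  data.frame(stay_id = character(), variable = character(),
             time_hours = numeric(), value = numeric(), unit = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.voc_cohort <- function(x, ...) {
  cat("Synthetic VOC cohort\n")
  cat(sprintf("  patients:     %d\n", nrow(x$patients)))
  cat(sprintf("  stays:        %d\n", nrow(x$stays)))
  cat(sprintf("  measurements: %d (%d variables)\n", nrow(x$measurements),
              length(unique(x$measurements$variable))))
  if (nrow(x$truth_log$planted)) {
    tb <- table(x$truth_log$planted$rule)
    cat("  planted rules:", paste(sprintf("%s=%d", names(tb), tb),
                                  collapse = ", "), "\n")
  }
  invisible(x)
}
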