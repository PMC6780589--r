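# Fixture builders used across test files.  All synthetic, built in code.

.t0 <- as.POSIXct("2012-03-01 10:00:00", tz = "UTC")

make_stays <- function(stay_id, duration_days, patient_id = NULL,
                       icd = "D57.0", icu = FALSE, severity = 1L,
                       transfusion = FALSE, drugs = "") {
  n <- length(stay_id)
  data.frame(stay_id = stay_id,
             patient_id = patient_id %||% paste0("pt_", stay_id),
             admission = rep(.t0, n),
             discharge = .t0 + rep_len(duration_days, n) * 86400,
             icu_flag = rep_len(icu, n),
             severity_level = as.integer(rep_len(severity, n)),
             transfusion_flag = rep_len(transfusion, n),
             icd_codes = rep_len(icd, n), drugs = rep_len(drugs, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_patients <- function(patient_id, sex = "female", genotype = "SS") {
  n <- length(patient_id)
  data.frame(patient_id = patient_id, sex = rep_len(sex, n),
             genotype = rep_len(genotype, n),
             age_at_first_admission = rep(30, n),
             steady_state_hb = rep(9, n), stringsAsFactors = FALSE)
}

make_measurements <- function(stay_id, variable, time_hours, value,
                              unit = "") {
  data.frame(stay_id = stay_id, variable = variable,
             time_hours = time_hours, value = value,
             unit = rep_len(unit, length(stay_id)), stringsAsFactors = FALSE)
}

# 8-stay fixture: one stay violating each of the 6 pre-percentile rules,
# plus two clean stays of equal duration (so the percentile step removes
# nothing).
fixture_eight_stays <- function() {
  st <- rbind(
    make_stays("S1", 4, icd = "D57.1"),                      # not VOC-coded
    make_stays("S2", 4, icd = "D57.0;F11.2"),                # OUD patient
    make_stays("S3", 4, icu = TRUE),                         # ICU
    make_stays("S4", 4, severity = 3L),                      # severity 3-4
    make_stays("S5", 4, transfusion = TRUE),                 # transfusion
    make_stays("S6", 4, icd = "D57.0;J18.9"),                # complication
    make_stays("S7", 4),                                     # clean
    make_stays("S8", 4))                                     # clean
  list(stays = st, patients = make_patients(st$patient_id))
}

# patient table reproducing the published baseline-characteristics counts:
# 121 SS (63 female) and 43 other-genotype (24 female) patients.
fixture_table_one_patients <- function() {
  n_ss <- 121; n_ot <- 43
  ss_female <- 63; ot_female <- 24
  p <- data.frame(
    patient_id = sprintf("T%03d", 1:(n_ss + n_ot)),
    genotype = c(rep("SS", n_ss), rep("other", n_ot)),
    sex = c(rep("female", ss_female), rep("male", n_ss - ss_female),
            rep("female", ot_female), rep("male", n_ot - ot_female)),
    age_at_first_admission = c(rnorm(n_ss, 26, 6), rnorm(n_ot, 33, 8)),
    steady_state_hb = c(rnorm(n_ss, 8.5, 0.8), rnorm(n_ot, 10.2, 0.8)),
    stringsAsFactors = FALSE)
  # plant k TRUE flags in each genotype group for a given comorbidity;
  # within-group order is irrelevant to 2x2 counts
  plant <- function(k_ss, k_ot) c(seq_len(n_ss) <= k_ss,
                                  seq_len(n_ot) <= k_ot)
  p$acute_chest_syndrome <- plant(93, 18)
  p$avascular_necrosis <- plant(23, 14)
  p$retinopathy <- plant(12, 7)
  p$leg_ulcer <- plant(9, 1)
  p$stroke <- plant(3, 3)
  p$dialysis <- plant(1, 1)
  p$pulmonary_hypertension <- plant(2, 1)
  # priapism among males: 13 of 58 SS, 0 of 19 other
  pria <- rep(FALSE, n_ss + n_ot)
  pria[p$sex == "male" & p$genotype == "SS"][1:13] <- TRUE
  p$priapism <- pria
  p
}

# single-variable simulation config used by trajectory recovery tests
recovery_config <- function(truth, n_patients = 120, seed = 1,
                            sampling = sampling_intensity()) {
  simulation_config(
    n_patients = n_patients,
    stays_per_patient_prob = c(1, rep(0, 9)),     # one stay per patient
    contamination = c(non_voc = 0, oud = 0, icu = 0, severity = 0,
                      transfusion = 0, complication = 0),
    truths = list(truth), sampling = sampling, seed = seed)
}
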