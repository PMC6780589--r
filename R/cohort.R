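# Cohort selection -----------------------------------------------------------
#
# The study's operational definition of a non-complicated VOC stay, applied
# as an ordered filter chain: include stays coded D57.0; exclude all stays
# of opioid-use-disorder patients (F11-prefix code or maintenance drug);
# then exclude, stay by stay, ICU transfers, high coded severity (3-4),
# transfused stays, and stays carrying a complication diagnosis code;
# finally drop stays longer than the 90th duration percentile of the
# survivors.  Isolated fever is deliberately NOT an exclusion.

#' Filter configuration for cohort selection
#'
#' @param inclusion_code primary diagnosis code selecting VOC stays
#'   (default `"D57.0"`).
#' @param oud_code_prefix ICD-10 prefix marking opioid-use disorder
#'   (default `"F11"`).
#' @param oud_drugs drug labels implying opioid-use disorder management
#'   (default methadone, buprenorphine).
#' @param complication_codes ICD-10 codes marking a complicated stay;
#'   injected rather than hard-coded because the full complication list is
#'   site-specific.
#' @param duration_percentile duration cutoff quantile in (0,1)
#'   (default 0.90).
#' @return a `filter_config` object.
#' @export
filter_config <- function(inclusion_code = "D57.0",
                          oud_code_prefix = "F11",
                          oud_drugs = c("methadone", "buprenorphine"),
                          complication_codes = c("J18.9", "A41.9", "I82.9"),
                          duration_percentile = 0.90) {
  if (duration_percentile <= 0 || duration_percentile >= 1)
    stop_cfg("filter_config: duration_percentile must lie in (0,1)")
  structure(list(inclusion_code = inclusion_code,
                 oud_code_prefix = oud_code_prefix,
                 oud_drugs = oud_drugs,
                 complication_codes = complication_codes,
                 duration_percentile = duration_percentile),
            class = "filter_config")
}

split_codes <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

stay_duration_days <- function(stays) {
  as.numeric(difftime(stays$discharge, stays$admission, units = "days"))
}

#' Duration-percentile filter
#'
#' Computes the given quantile of the input stays' durations (fractional
#' days, linear interpolation between order statistics) and removes stays
#' strictly longer than it.  Meant to be applied after all other exclusions,
#' so the cutoff reflects the non-complicated population.
#'
#' @param stays stay table (needs `admission`, `discharge`).
#' @param percentile quantile in (0,1), e.g. 0.90.
#' @return list with `kept` (stay table) and `cutoff` (days).
#' @export
duration_filter <- function(stays, percentile = 0.90) {
  if (nrow(stays) == 0L)
    stop_cfg("duration_filter: no stays to compute a percentile from")
  d <- stay_duration_days(stays)
  cutoff <- unname(quantile(d, percentile, type = 7))
  list(kept = stays[d <= cutoff, , drop = FALSE], cutoff = cutoff)
}

#' Select the non-complicated VOC cohort
#'
#' Applies the ordered inclusion/exclusion chain and reports a
#' flowchart-style account of stays removed at each step.  Removal is
#' attributed to the first rule (in protocol order) a stay violates, so the
#' report steps partition the removed stays.
#'
#' @param stays stay table (see [read_tables()] schema).
#' @param patients patient table; every `stays$patient_id` must appear.
#' @param cfg a [filter_config()].
#' @return list with `included` (stay table) and `report` (a
#'   `filter_report` data.frame with columns `step`, `removed`, `remaining`,
#'   and attributes `cutoff_days` and `assignment` mapping each input stay
#'   to `"included"` or its removal step).
#' @export
select_cohort <- function(stays, patients, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  bad <- setdiff(stays$patient_id, patients$patient_id)
  if (length(bad))
    stop_cfg("select_cohort: stays reference unknown patient_id(s): %s",
             paste(head(bad, 5), collapse = ", "))

  codes <- split_codes(stays$icd_codes)
  drugs <- split_codes(stays$drugs)

  # patient-level OUD status from the full stay set
  has_oud_code <- vapply(codes, function(cc)
    any(startsWith(cc, cfg$oud_code_prefix)), logical(1))
  has_oud_drug <- vapply(drugs, function(dd)
    any(dd %in% cfg$oud_drugs), logical(1))
  oud_patients <- unique(stays$patient_id[has_oud_code | has_oud_drug])

  fails <- list(
    not_voc_coded = !vapply(codes, function(cc)
      cfg$inclusion_code %in% cc, logical(1)),
    opioid_use_disorder = stays$patient_id %in% oud_patients,
    icu_stay = as.logical(stays$icu_flag),
    severity_3_4 = stays$severity_level %in% c(3L, 4L),
    transfusion = as.logical(stays$transfusion_flag),
    complication_code = vapply(codes, function(cc)
      any(cc %in% cfg$complication_codes), logical(1))
  )

  n0 <- nrow(stays)
  assignment <- rep(NA_character_, n0)
  steps <- data.frame(step = character(), removed = integer(),
                      remaining = integer(), stringsAsFactors = FALSE)
  alive <- rep(TRUE, n0)
  for (nm in names(fails)) {
    hit <- alive & fails[[nm]]
    assignment[hit] <- nm
    alive <- alive & !hit
    steps <- rbind(steps, data.frame(step = nm, removed = sum(hit),
                                     remaining = sum(alive),
                                     stringsAsFactors = FALSE))
  }

  cutoff <- NA_real_
  if (any(alive)) {
    df <- duration_filter(stays[alive, , drop = FALSE],
                          cfg$duration_percentile)
    cutoff <- df$cutoff
    kept_ids <- df$kept$stay_id
    hit <- alive & !(stays$stay_id %in% kept_ids)
    assignment[hit] <- "duration_above_percentile"
    alive <- alive & !hit
  }
  steps <- rbind(steps, data.frame(step = "duration_above_percentile",
                                   removed = sum(assignment ==
                                                   "duration_above_percentile",
                                                 na.rm = TRUE),
                                   remaining = sum(alive),
                                   stringsAsFactors = FALSE))
  assignment[alive] <- "included"

  report <- structure(steps, class = c("filter_report", "data.frame"),
                      n_input = n0, cutoff_days = cutoff,
                      assignment = setNames(assignment, stays$stay_id))
  list(included = stays[alive, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Cohort selection flowchart (%d stays in)\n",
              attr(x, "n_input")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-26s removed %4d -> %4d remaining\n",
                x$step[i], x$removed[i], x$remaining[i]))
  if (!is.na(attr(x, "cutoff_days")))
    cat(sprintf("  duration cutoff: %.2f days\n", attr(x, "cutoff_days")))
  invisible(x)
}
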