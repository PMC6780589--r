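# File interface --------------------------------------------------------------
#
# Long-format CSV schema, one measurement per row (the shape of an
# i2b2-style fact-table extract):
#   patients.csv:     patient_id, sex, genotype, age_at_first_admission,
#                     steady_state_hb, <one logical column per comorbidity>
#   stays.csv:        stay_id, patient_id, admission, discharge (ISO-8601),
#                     icu_flag, severity_level, transfusion_flag,
#                     icd_codes (";"-separated), drugs (";"-separated)
#   measurements.csv: stay_id, variable, time_hours (or timestamp), value,
#                     unit

required_cols <- list(
  patients = c("patient_id", "sex", "genotype"),
  stays = c("stay_id", "patient_id", "admission", "discharge", "icu_flag",
            "severity_level", "transfusion_flag", "icd_codes", "drugs"),
  measurements = c("stay_id", "variable", "value")
)

check_schema <- function(df, what) {
  miss <- setdiff(required_cols[[what]], names(df))
  if (length(miss))
    stop_cfg("%s table is missing required column(s): %s", what,
             paste(miss, collapse = ", "))
  if (what == "measurements" &&
      !any(c("time_hours", "timestamp") %in% names(df)))
    stop_cfg("measurements table needs a time_hours or timestamp column")
  invisible(df)
}

parse_iso <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d"))
  out
}

#' Read the three cohort tables
#'
#' Reads and validates the patients / stays / measurements CSVs.  Missing
#' required columns raise a schema error naming the column; rows violating
#' basic invariants (discharge not after admission, non-finite measurement
#' values, negative times) are rejected with row-numbered warnings rather
#' than silently kept.
#'
#' @param patients,stays,measurements file paths.
#' @return list with validated data.frames `patients`, `stays`,
#'   `measurements`.
#' @export
read_tables <- function(patients, stays, measurements) {
  for (f in c(patients, stays, measurements))
    if (!file.exists(f)) stop_cfg("input file not found: %s", f)
  pt <- setDF(fread(patients, colClasses = list(character = "patient_id")))
  st <- setDF(fread(stays, colClasses = list(
    character = c("stay_id", "patient_id", "icd_codes", "drugs"))))
  ms <- setDF(fread(measurements,
                    colClasses = list(character = c("stay_id", "variable"))))
  check_schema(pt, "patients"); check_schema(st, "stays")
  check_schema(ms, "measurements")

  st$admission <- parse_iso(st$admission)
  st$discharge <- parse_iso(st$discharge)
  st$icd_codes[is.na(st$icd_codes)] <- ""
  st$drugs[is.na(st$drugs)] <- ""
  bad <- which(is.na(st$admission) | is.na(st$discharge) |
                 st$discharge <= st$admission)
  if (length(bad)) {
    warning(sprintf("stays: rejected %d row(s) with missing/inverted timestamps (rows %s)",
                    length(bad), paste(head(bad, 10), collapse = ", ")))
    st <- st[-bad, , drop = FALSE]
  }
  if ("timestamp" %in% names(ms)) ms$timestamp <- parse_iso(ms$timestamp)
  bad <- which(!is.finite(ms$value) |
                 (if ("time_hours" %in% names(ms))
                    !is.finite(ms$time_hours) | ms$time_hours < 0
                  else is.na(ms$timestamp)))
  if (length(bad)) {
    warning(sprintf("measurements: rejected %d malformed row(s) (rows %s)",
                    length(bad), paste(head(bad, 10), collapse = ", ")))
    ms <- ms[-bad, , drop = FALSE]
  }
  list(patients = pt, stays = st, measurements = ms)
}

#' Write a cohort's three tables to CSV
#'
#' Inverse of [read_tables()]; timestamps are serialized as ISO-8601 UTC.
#'
#' @param cohort list with `patients`, `stays`, `measurements` (e.g. a
#'   [generate_cohort()] result).
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- cohort$stays
  st$admission <- format(st$admission, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  st$discharge <- format(st$discharge, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  paths <- c(patients = file.path(dir, "patients.csv"),
             stays = file.path(dir, "stays.csv"),
             measurements = file.path(dir, "measurements.csv"))
  fwrite(cohort$patients, paths[["patients"]])
  fwrite(st, paths[["stays"]])
  fwrite(cohort$measurements, paths[["measurements"]])
  invisible(paths)
}
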