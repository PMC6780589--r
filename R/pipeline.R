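# End-to-end pipeline ---------------------------------------------------------

#' Run configuration for the end-to-end analysis
#'
#' @param patients,stays,measurements input CSV paths; leave `NULL` with
#'   `simulate = TRUE` to generate inputs first.
#' @param simulate simulate a cohort (written under `outdir/input/`)
#'   instead of reading files.
#' @param sim_config [simulation_config()] used when simulating.
#' @param filter [filter_config()].
#' @param trajectory [trajectory_config()].
#' @param queries list of [threshold_query()] (default [standard_queries()]).
#' @param variables variables to estimate trajectories for (default: all
#'   present in the measurements).
#' @param outdir output directory.
#' @param seed master seed, propagated to simulation and bootstrap stages.
#' @param make_figures write one PNG per trajectory (default `TRUE`).
#' @return a `run_config` object.
#' @export
run_config <- function(patients = NULL, stays = NULL, measurements = NULL,
                       simulate = is.null(patients),
                       sim_config = NULL, filter = filter_config(),
                       trajectory = trajectory_config(),
                       queries = standard_queries(), variables = NULL,
                       outdir = "voctraj-output", seed = 1L,
                       make_figures = TRUE) {
  seed <- as.integer(seed)
  if (is.null(sim_config)) sim_config <- simulation_config(seed = seed)
  sim_config$seed <- seed
  trajectory$seed <- seed
  structure(list(patients = patients, stays = stays,
                 measurements = measurements, simulate = simulate,
                 sim_config = sim_config, filter = filter,
                 trajectory = trajectory, queries = queries,
                 variables = variables, outdir = outdir, seed = seed,
                 make_figures = make_figures),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate-or-read inputs, select the non-complicated VOC cohort, estimate
#' an averaged trajectory per variable, run the threshold queries, and
#' build the baseline table, writing every artifact under `cfg$outdir`
#' together with a checksummed manifest.  Deterministic given `cfg$seed`.
#' Variables with insufficient data are skipped with a logged reason;
#' an empty selected cohort skips the analysis stages and returns a status
#' of `"empty-cohort"`.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with `status`, `selection`, `trajectories`,
#'   `thresholds`, `table_one`, `skipped`, `manifest`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(path) { written <<- c(written, path); path }

  if (cfg$simulate) {
    cohort <- generate_cohort(cfg$sim_config)
    paths <- write_cohort(cohort, file.path(cfg$outdir, "input"))
    for (p in paths) put(p)
    tabs <- cohort[c("patients", "stays", "measurements")]
  } else {
    tabs <- read_tables(cfg$patients, cfg$stays, cfg$measurements)
  }

  sel <- select_cohort(tabs$stays, tabs$patients, cfg$filter)
  rep_df <- as.data.frame(sel$report)
  fwrite(rep_df, put(file.path(cfg$outdir, "filter_report.csv")))
  jsonlite::write_json(
    list(n_input = attr(sel$report, "n_input"),
         cutoff_days = attr(sel$report, "cutoff_days"),
         steps = rep_df),
    put(file.path(cfg$outdir, "filter_report.json")),
    auto_unbox = TRUE, digits = NA, na = "null")
  st <- sel$included
  st_out <- st
  if (nrow(st_out)) {
    st_out$admission <- format(st_out$admission, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    st_out$discharge <- format(st_out$discharge, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  fwrite(st_out, put(file.path(cfg$outdir, "included_stays.csv")))

  out <- list(status = "ok", selection = sel, trajectories = list(),
              thresholds = NULL, table_one = NULL, skipped = character())
  if (nrow(st) == 0L) {
    message("run_full_analysis: selected cohort is empty; analysis stages skipped")
    out$status <- "empty-cohort"
  } else {
    vars <- cfg$variables %||%
      sort(unique(tabs$measurements$variable[
        tabs$measurements$stay_id %in% st$stay_id]))
    for (v in vars) {
      est <- tryCatch(
        estimate_trajectory(tabs$measurements, st, v, cfg$trajectory),
        error = function(e) e)
      if (inherits(est, "error")) {
        message(sprintf("run_full_analysis: skipping '%s': %s", v,
                        conditionMessage(est)))
        out$skipped <- c(out$skipped, setNames(conditionMessage(est), v))
        next
      }
      out$trajectories[[v]] <- est
      fwrite(as.data.frame(est),
             put(file.path(cfg$outdir, sprintf("trajectory_%s.csv", v))))
      if (isTRUE(cfg$make_figures)) {
        fp <- put(file.path(cfg$outdir, sprintf("trajectory_%s.png", v)))
        grDevices::png(fp, width = 900, height = 600)
        plot(est)
        grDevices::dev.off()
      }
    }

    thr <- list()
    for (qn in names(cfg$queries)) {
      r <- tryCatch(proportion_crossing(tabs$measurements, st,
                                        cfg$queries[[qn]]),
                    error = function(e) e)
      if (inherits(r, "error")) {
        message(sprintf("run_full_analysis: threshold '%s' skipped: %s", qn,
                        conditionMessage(r)))
        next
      }
      thr[[qn]] <- r
    }
    if (length(thr)) {
      tt <- threshold_results_table(thr)
      fwrite(tt, put(file.path(cfg$outdir, "thresholds.csv")))
      jsonlite::write_json(tt, put(file.path(cfg$outdir, "thresholds.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    out$thresholds <- thr

    first_pat <- tabs$patients[tabs$patients$patient_id %in% st$patient_id, ,
                               drop = FALSE]
    out$table_one <- tryCatch(build_table_one(first_pat),
                              error = function(e) NULL)
    if (!is.null(out$table_one))
      fwrite(out$table_one, put(file.path(cfg$outdir, "table_one.csv")))
  }

  manifest <- data.frame(
    file = sub(paste0("^", cfg$outdir, "/?"), "", written),
    md5 = unname(tools::md5sum(written)), stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, status = out$status,
                            files = manifest),
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
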