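# Threshold-window proportion analysis ---------------------------------------
#
# The "over 95% of stays ..." style statements: for a variable, a clinical
# threshold, and a time window of the stay, what fraction of stays ever (or
# always) lie at-or-above / below the threshold within the window?

#' Define a threshold query
#'
#' @param variable measurement variable label.
#' @param threshold threshold in the variable's units; "reaching" a
#'   threshold is inclusive (`>=`), matching clinical convention for fever
#'   (38 degC) and the 100 mg/L CRP bound.
#' @param direction `"at_or_above"` or `"below"`.
#' @param window half-open interval `[t_start, t_end)` in hours since
#'   admission; `t_end = Inf` means through the end of the stay.
#' @param aggregation `"ever_in_window"` (any qualifying point) or
#'   `"always_in_window"` (all points in the window qualify).
#' @param label optional human-readable name.
#' @return a `threshold_query` object.
#' @export
threshold_query <- function(variable, threshold,
                            direction = c("at_or_above", "below"),
                            window = c(0, Inf),
                            aggregation = c("ever_in_window",
                                            "always_in_window"),
                            label = NULL) {
  direction <- match.arg(direction)
  aggregation <- match.arg(aggregation)
  if (!is.finite(threshold))
    stop_cfg("threshold_query: threshold must be finite")
  if (length(window) != 2L || !(window[1] < window[2]))
    stop_cfg("threshold_query: window must satisfy t_start < t_end")
  structure(list(variable = variable, threshold = threshold,
                 direction = direction, window = window,
                 aggregation = aggregation,
                 label = label %||%
                   sprintf("%s %s %g in [%g,%s) h", variable,
                           if (direction == "at_or_above") ">=" else "<",
                           threshold, window[1],
                           ifelse(is.finite(window[2]),
                                  format(window[2]), "stay end"))),
            class = "threshold_query")
}

#' The three preconfigured stay-monitoring queries
#'
#' CRP reaching 100 mg/L within the first 24 h; CRP back below the normal
#' laboratory limit at any point from 48 h onward; and temperature reaching
#' 38 degC at any point of the stay.  In non-complicated VOC stays each of
#' these events is expected in fewer than 5% of stays.
#'
#' @param normal_crp_limit laboratory upper reference limit for CRP in
#'   mg/L (default 5; site-configurable).
#' @return named list of three [threshold_query()] objects.
#' @export
standard_queries <- function(normal_crp_limit = 5) {
  list(
    crp_100_first_day = threshold_query(
      "crp", 100, "at_or_above", c(0, 24), "ever_in_window",
      label = "CRP >= 100 mg/L within first 24 h"),
    crp_normal_after_48h = threshold_query(
      "crp", normal_crp_limit, "below", c(48, Inf), "ever_in_window",
      label = sprintf("CRP < %g mg/L (normal) from 48 h on",
                      normal_crp_limit)),
    temp_38_any_time = threshold_query(
      "temperature", 38, "at_or_above", c(0, Inf), "ever_in_window",
      label = "temperature >= 38 degC at any time of the stay")
  )
}

#' Proportion of stays crossing a threshold within a window
#'
#' A stay enters the denominator if it has at least one measurement of the
#' query variable inside the window; stays without any such measurement are
#' excluded (not imputed) and counted in `n_excluded`.  The binomial 95%
#' interval is exact (Clopper-Pearson).
#'
#' @param measurements,stays input tables; pass the selected stays to
#'   restrict the analysis set.
#' @param query a [threshold_query()].
#' @return a `threshold_result` list: `query`, `numerator`, `denominator`,
#'   `proportion`, `conf_int`, `n_excluded`.
#' @export
proportion_crossing <- function(measurements, stays, query) {
  stopifnot(inherits(query, "threshold_query"))
  pooled <- suppressWarnings(
    align_measurements(measurements, stays, query$variable,
                       max_time = Inf))
  inwin <- pooled[pooled$t >= query$window[1] & pooled$t < query$window[2], ,
                  drop = FALSE]
  denom_ids <- unique(inwin$stay_id)
  n_excluded <- nrow(stays) - length(denom_ids)
  if (length(denom_ids) == 0L)
    stop_cfg("proportion_crossing: no stay has a '%s' measurement in [%g,%g)",
             query$variable, query$window[1], query$window[2])
  hit <- if (query$direction == "at_or_above") inwin$value >= query$threshold
         else inwin$value < query$threshold
  agg <- tapply(hit, inwin$stay_id,
                if (query$aggregation == "ever_in_window") any else all)
  num <- sum(agg)
  den <- length(denom_ids)
  alpha <- 0.05
  ci <- c(if (num == 0) 0 else qbeta(alpha / 2, num, den - num + 1),
          if (num == den) 1 else qbeta(1 - alpha / 2, num + 1, den - num))
  structure(list(query = query, numerator = num, denominator = den,
                 proportion = num / den, conf_int = ci,
                 n_excluded = n_excluded),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$query$label, x$query$aggregation))
  cat(sprintf("  %d / %d stays = %.1f%%  (95%% CI %.1f-%.1f%%), %d stays unmeasured in window\n",
              x$numerator, x$denominator, 100 * x$proportion,
              100 * x$conf_int[1], 100 * x$conf_int[2], x$n_excluded))
  invisible(x)
}

threshold_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(label = r$query$label, variable = r$query$variable,
               threshold = r$query$threshold, direction = r$query$direction,
               t_start = r$query$window[1], t_end = r$query$window[2],
               aggregation = r$query$aggregation,
               numerator = r$numerator, denominator = r$denominator,
               proportion = r$proportion,
               ci_lower = r$conf_int[1], ci_upper = r$conf_int[2],
               n_excluded = r$n_excluded, stringsAsFactors = FALSE)))
}
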