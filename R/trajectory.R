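# Averaged trajectory with cluster-bootstrap band ---------------------------

#' Pool one variable's measurements on the time-since-admission axis
#'
#' Extracts a variable's measurements for the given (typically
#' post-selection) stay set and expresses each observation as hours since
#' its stay's admission.  Measurement tables may carry either a
#' `time_hours` column (already relative) or an absolute ISO-8601
#' `timestamp` column, in which case the stay's admission is subtracted.
#' Points beyond `max_time` are dropped with a message.
#'
#' @param measurements measurement table (`stay_id`, `variable`,
#'   `time_hours` or `timestamp`, `value`).
#' @param stays stay table defining the analysis set.
#' @param variable variable label to extract.
#' @param max_time horizon in hours (default 240).
#' @return data.frame with columns `stay_id`, `t`, `value`.  An absent
#'   variable yields an empty result with a warning, not an error.
#' @export
align_measurements <- function(measurements, stays, variable,
                               max_time = 240) {
  m <- measurements[measurements$variable == variable, , drop = FALSE]
  if (nrow(m) == 0L) {
    warning(sprintf("no measurements found for variable '%s'", variable))
    return(data.frame(stay_id = character(), t = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  m <- m[m$stay_id %in% stays$stay_id, , drop = FALSE]
  if ("time_hours" %in% names(m)) {
    t <- as.numeric(m$time_hours)
  } else if ("timestamp" %in% names(m)) {
    adm <- setNames(stays$admission, stays$stay_id)
    t <- as.numeric(difftime(m$timestamp, adm[m$stay_id], units = "hours"))
  } else {
    stop_cfg("align_measurements: need a time_hours or timestamp column")
  }
  keep <- !is.na(t) & t >= 0 & is.finite(m$value)
  late <- keep & t > max_time
  if (any(late))
    message(sprintf("align_measurements: dropped %d '%s' points beyond %g h",
                    sum(late), variable, max_time))
  keep <- keep & !late
  out <- data.frame(stay_id = m$stay_id[keep], t = t[keep],
                    value = m$value[keep], stringsAsFactors = FALSE)
  out[order(out$stay_id, out$t), , drop = FALSE]
}

#' Pointwise confidence band by stay-level (cluster) bootstrap
#'
#' Resamples whole stays with replacement, refits the penalized spline with
#' the penalty weight fixed at the full-data choice, and takes pointwise
#' empirical quantiles across replicates.  Resampling stays rather than
#' points respects the within-stay dependence of repeated measurements.
#'
#' @param pooled data.frame (`stay_id`, `t`, `value`).
#' @param cfg a [trajectory_config()]; `cfg$seed` makes the band
#'   reproducible.
#' @param fit optional [fit_mean_trajectory()] result for the same pooled
#'   data (refitted if omitted).
#' @param grid evaluation times; default `seq(0, t_max, by = grid_step)`.
#' @return list with `grid`, `lower`, `upper`, and the replicate curve
#'   matrix `curves` (replicates in rows).
#' @export
bootstrap_band <- function(pooled, cfg = trajectory_config(), fit = NULL,
                           grid = NULL) {
  if (is.null(fit)) fit <- fit_mean_trajectory(pooled, cfg)
  bl <- fit$blocks
  S <- length(bl$ids)
  if (S < 2L)
    stop_cfg("bootstrap_band: at least 2 distinct stays are required")
  if (is.null(grid)) grid <- seq(0, fit$t_range[2], by = cfg$grid_step)
  Bg <- pspline_basis(grid, fit$knots, fit$degree)
  curves <- with_seed(cfg$seed, {
    out <- matrix(NA_real_, cfg$n_bootstrap, length(grid))
    for (b in seq_len(cfg$n_bootstrap)) {
      w <- tabulate(sample.int(S, S, replace = TRUE), nbins = S)
      co <- solve_pspline(bl$Gf %*% w, bl$gf %*% w, fit$penalty, fit$lambda)
      if (!is.null(co)) out[b, ] <- Bg %*% co
    }
    out
  })
  ok <- stats::complete.cases(curves)
  alpha <- (1 - cfg$ci_level) / 2
  qs <- apply(curves[ok, , drop = FALSE], 2, quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  list(grid = grid, lower = qs[1, ], upper = qs[2, ], curves = curves)
}

#' Estimate a variable's averaged trajectory with its confidence band
#'
#' The full per-variable procedure: align measurements to hours since
#' admission, fit the cross-validated penalized spline to the pooled
#' points, and attach a pointwise cluster-bootstrap band.  The evaluation
#' grid is truncated where fewer than `min_support` stays are still under
#' observation, since a late-time average over a handful of long stays is
#' not an averaged trajectory in any useful sense.
#'
#' @param measurements,stays input tables ([read_tables()] schema); pass
#'   the selected stays from [select_cohort()] to restrict the analysis set.
#' @param variable variable label.
#' @param cfg a [trajectory_config()].
#' @return object of class `trajectory_estimate` with fields `variable`,
#'   `grid` (hours), `mean`, `lower`, `upper`, `support`, `n_stays`,
#'   `n_points`, `lambda`.
#' @export
estimate_trajectory <- function(measurements, stays, variable,
                                cfg = trajectory_config()) {
  pooled <- align_measurements(measurements, stays, variable, cfg$max_time)
  fit <- fit_mean_trajectory(pooled, cfg, variable = variable)
  grid <- seq(0, fit$t_range[2], by = cfg$grid_step)

  # support: stays whose observation window still extends to the grid time
  last_t <- tapply(pooled$t, pooled$stay_id, max)
  support <- vapply(grid, function(g) sum(last_t >= g), integer(1))
  keep <- support >= cfg$min_support
  if (!any(keep))
    stop_cfg("estimate_trajectory: no grid point reaches min_support for '%s'",
             variable)
  grid <- grid[keep]
  support <- support[keep]

  band <- bootstrap_band(pooled, cfg, fit = fit, grid = grid)
  mu <- predict(fit, grid)
  structure(list(variable = variable, grid = grid, mean = mu,
                 lower = pmin(band$lower, mu), upper = pmax(band$upper, mu),
                 support = support, n_stays = fit$n_stays,
                 n_points = fit$n_points, lambda = fit$lambda,
                 ci_level = cfg$ci_level, fit = fit),
            class = "trajectory_estimate")
}

#' @export
as.data.frame.trajectory_estimate <- function(x, ...) {
  data.frame(variable = x$variable, time_hours = x$grid, mean = x$mean,
             lower = x$lower, upper = x$upper, support = x$support,
             stringsAsFactors = FALSE)
}

#' @export
print.trajectory_estimate <- function(x, ...) {
  cat(sprintf(paste0("Averaged trajectory of '%s': %d stays, %d points, ",
                     "grid 0-%g h (%d points), %g%% band\n"),
              x$variable, x$n_stays, x$n_points, max(x$grid),
              length(x$grid), 100 * x$ci_level))
  print(head(as.data.frame(x), 5))
  invisible(x)
}

#' Plot an averaged trajectory
#'
#' Mean curve with shaded pointwise band on a days-since-admission axis and
#' the per-point stay support on a secondary axis.
#'
#' @param x a `trajectory_estimate`.
#' @param ylab y-axis label (defaults to the variable name).
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_estimate <- function(x, ylab = x$variable, ...) {
  days <- x$grid / 24
  old <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(old))
  plot(days, x$mean, type = "n", ylim = range(x$lower, x$upper),
       xlab = "days since admission", ylab = ylab, ...)
  graphics::polygon(c(days, rev(days)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(days, x$mean, lwd = 2, col = "steelblue4")
  graphics::par(new = TRUE)
  plot(days, x$support, type = "s", col = "grey50", lty = 3, axes = FALSE,
       xlab = "", ylab = "", ylim = c(0, max(x$support) * 1.6))
  graphics::axis(4, col.axis = "grey40")
  graphics::mtext("stays under observation", side = 4, line = 2.5,
                  col = "grey40", cex = 0.8)
  invisible(x)
}
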