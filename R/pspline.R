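# Penalized B-spline smoother ------------------------------------------------
#
# The estimator behind the averaged trajectories: a cubic B-spline basis on
# an equally spaced knot grid with a difference penalty on adjacent
# coefficients (P-spline), fitted to the pooled (stay, time, value) points.
# The penalty weight is chosen by cross-validation over stays, so that the
# smoothness choice respects within-stay dependence.  All fitting reduces
# to per-stay Gram blocks, which makes the stay-level cluster bootstrap in
# bootstrap_band() a cheap re-solve rather than a re-scan of the data.

#' Trajectory estimation configuration
#'
#' @param grid_step evaluation grid spacing in hours (default 6).
#' @param max_time analysis horizon in hours since admission (default 240,
#'   i.e. 10 days); later measurements are dropped.
#' @param spline_degree B-spline degree (default 3, cubic).
#' @param knot_spacing spacing of the knot grid in hours (default 12).
#' @param penalty_order order of the difference penalty (default 2; its
#'   null space contains straight lines, so linear trends are never
#'   penalized away).
#' @param lambda_grid candidate penalty weights searched by stay-level
#'   cross-validation.
#' @param cv_folds number of cross-validation folds over stays (default 10;
#'   reduced automatically when fewer stays are available).
#' @param n_bootstrap cluster-bootstrap replicates for the band
#'   (default 500, minimum 100).
#' @param ci_level pointwise confidence level (default 0.95).
#' @param min_support minimum number of stays still under observation for a
#'   grid point to be reported (default 10).
#' @param seed integer seed driving the bootstrap resampling.
#' @return a `trajectory_config` object.
#' @export
trajectory_config <- function(grid_step = 6, max_time = 240,
                              spline_degree = 3, knot_spacing = 12,
                              penalty_order = 2,
                              lambda_grid = 10^seq(-2, 6, length.out = 9),
                              cv_folds = 10,
                              n_bootstrap = 500, ci_level = 0.95,
                              min_support = 10, seed = 1L) {
  if (grid_step <= 0) stop_cfg("trajectory_config: grid_step must be > 0")
  if (ci_level <= 0 || ci_level >= 1)
    stop_cfg("trajectory_config: ci_level must lie in (0,1)")
  if (n_bootstrap < 100)
    stop_cfg("trajectory_config: n_bootstrap must be at least 100")
  structure(list(grid_step = grid_step, max_time = max_time,
                 spline_degree = as.integer(spline_degree),
                 knot_spacing = knot_spacing,
                 penalty_order = as.integer(penalty_order),
                 lambda_grid = lambda_grid, cv_folds = as.integer(cv_folds),
                 n_bootstrap = as.integer(n_bootstrap), ci_level = ci_level,
                 min_support = as.integer(min_support),
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

# extended knot vector and basis evaluation on [0, t_max]
pspline_knots <- function(t_max, spacing, degree) {
  inner <- seq(0, t_max, by = spacing)
  if (tail(inner, 1) < t_max) inner <- c(inner, t_max)
  c(rep(0, degree), inner, rep(t_max, degree))
}

pspline_basis <- function(t, knots, degree) {
  t <- pmin(pmax(t, knots[1]), tail(knots, 1))
  splines::splineDesign(knots, t, ord = degree + 1, outer.ok = TRUE)
}

# per-stay Gram blocks: flattened for fast weighted recombination
stay_blocks <- function(B, y, stay) {
  ids <- sort(unique(stay))
  q <- ncol(B)
  Gf <- matrix(0, q * q, length(ids))
  gf <- matrix(0, q, length(ids))
  rows <- split(seq_along(stay), factor(stay, levels = ids))
  for (j in seq_along(ids)) {
    Bj <- B[rows[[j]], , drop = FALSE]
    Gf[, j] <- as.vector(crossprod(Bj))
    gf[, j] <- as.vector(crossprod(Bj, y[rows[[j]]]))
  }
  list(ids = ids, Gf = Gf, gf = gf, rows = rows, q = q)
}

solve_pspline <- function(Gsum, gsum, P, lambda) {
  A <- matrix(Gsum, nrow(P)) + lambda * P
  tryCatch(solve(A, gsum), error = function(e) NULL)
}

#' Fit the averaged-trajectory smoother to pooled measurements
#'
#' Fits a penalized B-spline to the pooled `(stay_id, t, value)` points of
#' one variable.  The penalty weight is selected by K-fold cross-validation
#' grouped by stay (fold assignment is deterministic over sorted stay ids);
#' with a single stay it falls back to generalized cross-validation over
#' points.
#'
#' @param pooled data.frame with columns `stay_id`, `t` (hours), `value`,
#'   e.g. from [align_measurements()].
#' @param cfg a [trajectory_config()].
#' @param variable label used in error messages.
#' @return object of class `pspline_fit`; evaluate with
#'   `predict(fit, t)` for any `t` in `[0, max_time]`.
#' @export
fit_mean_trajectory <- function(pooled, cfg = trajectory_config(),
                                variable = "variable") {
  stopifnot(all(c("stay_id", "t", "value") %in% names(pooled)))
  if (nrow(pooled) == 0L)
    stop_cfg("fit_mean_trajectory: no measurements for '%s'", variable)
  t_max <- min(cfg$max_time, max(pooled$t))
  knots <- pspline_knots(t_max, cfg$knot_spacing, cfg$spline_degree)
  q <- length(knots) - cfg$spline_degree - 1L
  if (nrow(pooled) < max(10L, q))
    stop_cfg(paste0("fit_mean_trajectory: insufficient data for '%s' ",
                    "(%d points, need at least %d)"),
             variable, nrow(pooled), max(10, q))

  B <- pspline_basis(pooled$t, knots, cfg$spline_degree)
  D <- diff(diag(q), differences = cfg$penalty_order)
  P <- crossprod(D)
  bl <- stay_blocks(B, pooled$value, pooled$stay_id)
  S <- length(bl$ids)
  Gsum <- rowSums(bl$Gf)
  gsum <- rowSums(bl$gf)

  lambdas <- sort(unique(cfg$lambda_grid))
  if (length(lambdas) > 1L) {
    if (S >= 2L) {
      K <- min(cfg$cv_folds, S)
      fold <- rep_len(seq_len(K), S)  # over sorted stay ids: deterministic
      score <- vapply(lambdas, function(lam) {
        err <- 0
        for (k in seq_len(K)) {
          inK <- fold == k
          co <- solve_pspline(Gsum - rowSums(bl$Gf[, inK, drop = FALSE]),
                              gsum - rowSums(bl$gf[, inK, drop = FALSE]),
                              P, lam)
          if (is.null(co)) return(Inf)
          rows <- unlist(bl$rows[inK], use.names = FALSE)
          err <- err + sum((B[rows, , drop = FALSE] %*% co -
                              pooled$value[rows])^2)
        }
        err
      }, numeric(1))
    } else {
      # single stay: GCV over points
      n <- nrow(pooled)
      G <- matrix(Gsum, q)
      score <- vapply(lambdas, function(lam) {
        A <- G + lam * P
        Ainv <- tryCatch(solve(A), error = function(e) NULL)
        if (is.null(Ainv)) return(Inf)
        co <- Ainv %*% gsum
        edf <- sum(diag(Ainv %*% G))
        rss <- sum((B %*% co - pooled$value)^2)
        n * rss / (n - edf)^2
      }, numeric(1))
    }
    lambda <- lambdas[which.min(score)]
  } else {
    lambda <- lambdas
  }

  coef <- solve_pspline(Gsum, gsum, P, lambda)
  if (is.null(coef))
    stop_cfg("fit_mean_trajectory: singular system for '%s'", variable)
  structure(list(variable = variable, knots = knots,
                 degree = cfg$spline_degree, coef = drop(coef),
                 lambda = lambda, penalty = P, blocks = bl,
                 t_range = c(0, t_max), n_points = nrow(pooled),
                 n_stays = S),
            class = "pspline_fit")
}

#' @export
predict.pspline_fit <- function(object, t, ...) {
  drop(pspline_basis(t, object$knots, object$degree) %*% object$coef)
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat(sprintf(paste0("P-spline fit for '%s': %d points, %d stays, ",
                     "%d basis functions, lambda = %g\n"),
              x$variable, x$n_points, x$n_stays, length(x$coef), x$lambda))
  invisible(x)
}
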