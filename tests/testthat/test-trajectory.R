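# trajectory estimation

fast_cfg <- function(...) trajectory_config(n_bootstrap = 100, seed = 1, ...)

test_that("alignment computes hours since admission and pools stays", {
  st <- make_stays(c("S1", "S2", "S3"), 5)
  ms <- rbind(
    make_measurements("S1", "hb", c(0, 10, 20, 30), 9),
    make_measurements("S2", "hb", c(5, 15, 25, 35), 9),
    make_measurements("S3", "hb", c(1, 2, 3, 4), 9))
  pooled <- align_measurements(ms, st, "hb")
  expect_equal(nrow(pooled), 12)
  expect_setequal(pooled$t[pooled$stay_id == "S2"], c(5, 15, 25, 35))
  # timestamp route: 2.5 days after admission is t = 60 h, admission is 0
  ms2 <- data.frame(stay_id = "S1", variable = "hb",
                    timestamp = .t0 + c(0, 2.5 * 86400), value = c(9, 8.5))
  pooled2 <- align_measurements(ms2, st, "hb")
  expect_equal(pooled2$t, c(0, 60))
  # absent variable: empty with warning, not an error
  expect_warning(out <- align_measurements(ms, st, "missing_var"),
                 "no measurements")
  expect_equal(nrow(out), 0)
  # beyond-horizon points are dropped with a message
  expect_message(
    out2 <- align_measurements(make_measurements("S1", "hb",
                                                 c(10, 300), c(9, 9)),
                               st, "hb", max_time = 240),
    "dropped 1")
  expect_equal(out2$t, 10)
})

test_that("constant data reproduce a constant curve", {
  set.seed(2)
  pooled <- data.frame(stay_id = rep(c("a", "b", "c"), each = 8),
                       t = runif(24, 0, 200), value = 7.25)
  fit <- fit_mean_trajectory(pooled, fast_cfg())
  expect_equal(predict(fit, seq(0, 200, by = 5)), rep(7.25, 41),
               tolerance = 1e-8)
})

test_that("too few points raise an informative error naming the variable", {
  pooled <- data.frame(stay_id = "a", t = c(1, 2, 3), value = 1:3)
  expect_error(fit_mean_trajectory(pooled, fast_cfg(), variable = "ldh"),
               "insufficient data for 'ldh'")
})

test_that("unpenalized single-span fit equals OLS cubic regression", {
  set.seed(31)
  n <- 80
  pooled <- data.frame(stay_id = rep(sprintf("s%d", 1:10), each = 8),
                       t = runif(n, 0, 120),
                       value = 5 + 0.05 * runif(n) + sin(runif(n)))
  cfg <- fast_cfg(knot_spacing = 120, max_time = 120, lambda_grid = 0)
  fit <- fit_mean_trajectory(pooled, cfg)
  ols <- lm(value ~ t + I(t^2) + I(t^3), data = pooled)
  tt <- seq(0, max(pooled$t), length.out = 41)  # the fit's domain
  expect_equal(predict(fit, tt),
               unname(predict(ols, data.frame(t = tt))), tolerance = 1e-6)
})

test_that("noiseless linear truth is recovered to < 0.01 g/dL", {
  truth <- trajectory_truth("hemoglobin",
                            piecewise_linear(c(0, 120), c(9.5, 8.5)),
                            unit = "g/dL")
  co <- generate_cohort(recovery_config(truth, n_patients = 120, seed = 5))
  pooled <- align_measurements(co$measurements, co$stays, "hemoglobin")
  fit <- fit_mean_trajectory(pooled, fast_cfg())
  grid <- seq(0, 120, by = 6)
  expect_lt(max(abs(predict(fit, grid) - truth$mean_function(grid))), 0.01)
})

test_that("a spike-shaped truth has its argmax located within 6 h", {
  truth <- trajectory_truth(
    "wbc", piecewise_linear(c(0, 6, 48, 240), c(11.5, 12.5, 10, 10)),
    unit = "1e9/L", residual_sd = 0.2)
  co <- generate_cohort(recovery_config(
    truth, n_patients = 150, seed = 6,
    sampling = sampling_intensity(10, 3, 48)))
  pooled <- align_measurements(co$measurements, co$stays, "wbc")
  fit <- fit_mean_trajectory(pooled, fast_cfg(knot_spacing = 6))
  tt <- seq(0, 48, by = 0.5)
  expect_lt(abs(tt[which.max(predict(fit, tt))] - 6), 6)
})

test_that("band is ordered, seeded, and collapses without noise", {
  truth <- trajectory_truth("hb", piecewise_linear(c(0, 240), c(9.5, 8.5)))
  co <- generate_cohort(recovery_config(truth, n_patients = 60, seed = 9))
  pooled <- align_measurements(co$measurements, co$stays, "hb")
  cfg <- fast_cfg()
  b1 <- bootstrap_band(pooled, cfg)
  b2 <- bootstrap_band(pooled, cfg)
  expect_identical(b1[c("lower", "upper")], b2[c("lower", "upper")])
  expect_true(all(b1$lower <= b1$upper))
  # zero residual and between-stay noise: interior band width -> 0
  # (not exactly 0: near-singular resample systems leave ~1e-4 jitter)
  interior <- b1$grid > 12 & b1$grid < max(b1$grid) - 12
  expect_lt(max(b1$upper[interior] - b1$lower[interior]), 5e-3)
  # a single stay cannot support a band
  one <- pooled[pooled$stay_id == pooled$stay_id[1], ]
  expect_error(bootstrap_band(one, cfg), "2 distinct stays")
})

test_that("estimate_trajectory composes, truncates, and is order-invariant", {
  truth <- trajectory_truth("hb", piecewise_linear(c(0, 120), c(9.5, 8.5)),
                            between_stay_sd = 0.5, residual_sd = 0.3)
  co <- generate_cohort(recovery_config(truth, n_patients = 80, seed = 12))
  est <- estimate_trajectory(co$measurements, co$stays, "hb", fast_cfg())
  expect_s3_class(est, "trajectory_estimate")
  expect_true(all(est$lower <= est$mean & est$mean <= est$upper))
  expect_true(all(diff(est$grid) > 0))
  expect_true(all(est$support >= fast_cfg()$min_support))
  # row-permutation invariance under the same seed
  perm <- co$measurements[sample(nrow(co$measurements)), ]
  est2 <- estimate_trajectory(perm, co$stays, "hb", fast_cfg())
  expect_equal(as.data.frame(est), as.data.frame(est2))
  # no stay lasting past 72 h: the grid must end at or before 72 h
  short <- co
  keep <- short$measurements$time_hours <= 72
  short$measurements <- short$measurements[keep, ]
  est3 <- estimate_trajectory(short$measurements, short$stays, "hb",
                              fast_cfg())
  expect_lte(max(est3$grid), 72)
})

test_that("integrated recovery error shrinks with cohort size", {
  truth <- trajectory_truth("eos", piecewise_linear(c(0, 120), c(2, 4)),
                            between_stay_sd = 0.8, residual_sd = 0.5)
  iae <- vapply(c(small = 40, large = 360), function(n) {
    co <- generate_cohort(recovery_config(truth, n_patients = n, seed = 77))
    pooled <- align_measurements(co$measurements, co$stays, "eos")
    fit <- fit_mean_trajectory(pooled, fast_cfg())
    grid <- seq(0, 120, by = 6)
    mean(abs(predict(fit, grid) - truth$mean_function(grid)))
  }, numeric(1))
  expect_lt(iae[["large"]], iae[["small"]])
  expect_lt(iae[["large"]], 0.15)
})

test_that("plot method draws without error", {
  truth <- trajectory_truth("hb", piecewise_linear(c(0, 120), c(9.5, 8.5)),
                            residual_sd = 0.3)
  co <- generate_cohort(recovery_config(truth, n_patients = 40, seed = 2))
  est <- estimate_trajectory(co$measurements, co$stays, "hb", fast_cfg())
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_no_error(plot(est))
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
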