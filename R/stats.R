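# Group-comparison statistics -------------------------------------------------
#
# The univariate tests behind the baseline-characteristics table,
# implemented from first principles: two-sided Fisher exact test under the
# probability-mass rule, Pearson chi-squared with optional Yates
# correction, and the Wilcoxon rank-sum test with midranks, exact small-
# sample enumeration and a tie-corrected normal approximation otherwise.

as_2x2 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(2L, 2L)))
    t
  } else {
    stopifnot(length(t) == 4L)
    matrix(t, 2L, 2L, byrow = TRUE)
  }
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table no more probable than the observed one (the probability-mass
#' rule, the convention of most statistical software).  Probabilities are
#' accumulated in log space; a small relative tolerance treats
#' numerically tied masses as ties.
#'
#' @param t 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise
#'   (rows = groups, columns = trait yes/no).
#' @return two-sided p-value.  A zero margin returns 1 by convention
#'   (with a message): with an empty row or column there is a single
#'   attainable table.
#' @export
#' @examples
#' fisher_exact_two_sided(c(1, 120, 1, 42))   # 0.457
fisher_exact_two_sided <- function(t) {
  t <- as_2x2(t)
  if (any(t < 0) || any(t != round(t)))
    stop_cfg("fisher_exact_two_sided: counts must be non-negative integers")
  a <- t[1, 1]
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); N <- sum(t)
  if (N == 0 || r1 == 0 || r1 == N || c1 == 0 || c1 == N) {
    message("fisher_exact_two_sided: degenerate margin, p = 1 by convention")
    return(1)
  }
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  x <- lo:hi
  lp <- dhyper(x, c1, N - c1, r1, log = TRUE)
  lp_obs <- lp[x == a]
  min(1, sum(exp(lp[lp <= lp_obs + 1e-7])))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' @param t 2x2 matrix or length-4 row-wise vector.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return list with `statistic` and `p_value` (1 df).
#' @export
chi_squared_2x2 <- function(t, correct = FALSE) {
  t <- as_2x2(t)
  E <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(E == 0))
    stop_cfg("chi_squared_2x2: zero expected cell; use fisher_exact_two_sided")
  dev <- abs(t - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test
#'
#' Midranks handle ties.  When `m + n <= exact_limit` the null distribution
#' of the first sample's rank sum is obtained by full enumeration of all
#' `choose(m+n, m)` group assignments of the pooled midranks, and the
#' two-sided p is twice the smaller tail (capped at 1).  Otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric samples, both non-empty.
#' @param exact_limit maximum total sample size for exact enumeration
#'   (default 12).
#' @return list with `statistic` (rank sum of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y))
    stop_cfg("wilcoxon_rank_sum: both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  if (all(c(x, y) == c(x, y)[1]))
    return(list(statistic = W, p_value = 1, method = "degenerate"))
  if (N <= exact_limit) {
    sums <- utils::combn(r, m, sum)
    eps <- 1e-9
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = W, p_value = p, method = "exact")
  } else {
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(statistic = W, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal")
  }
}

# formatting helpers ----------------------------------------------------------
fmt_p <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "<0.001",
                ifelse(p >= 0.9995, "1", sprintf("%.3f", p))))
}
fmt_count_pct <- function(k, n) {
  sprintf("%d (%.1f%%)", k, ifelse(n > 0, 100 * k / n, 0))
}
fmt_median_iqr <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%g [%g; %g]", round(q[2], 1), round(q[1], 1), round(q[3], 1))
}

#' Baseline-characteristics table with genotype-group comparisons
#'
#' Builds a "table one": patient counts, sex, age at first admission,
#' steady-state hemoglobin, and the comorbidity-history flags, overall and
#' by group, with univariate group-comparison tests.  Quantitative rows are
#' summarized as median \[IQR\] and tested with the Wilcoxon rank-sum test;
#' categorical rows as count (percent) and tested with the Fisher exact
#' test when any expected cell is below 5, with the (uncorrected) Pearson
#' chi-squared test otherwise.  Priapism is summarized among males only.
#'
#' @param patients patient table ([read_tables()] schema).
#' @param group column name defining the two groups (default
#'   `"genotype"`, i.e. SS vs other).
#' @return data.frame of class `table_one` with columns `label`, `overall`,
#'   one summary column per group, `test`, `p_value`, `p_formatted`.
#'   With a single (or empty) group, comparison columns are omitted with a
#'   warning.
#' @export
build_table_one <- function(patients, group = "genotype") {
  g <- patients[[group]]
  lev <- sort(unique(g), decreasing = TRUE)   # "SS" before "other"
  two <- length(lev) == 2L && all(table(g) > 0)
  if (!two)
    warning("build_table_one: need two non-empty groups for comparisons; ",
            "emitting summaries only")

  male <- patients$sex == "male"
  rows <- list()
  add <- function(label, overall, per_group, test = NA_character_,
                  p = NA_real_) {
    rows[[length(rows) + 1L]] <<- c(list(label = label, overall = overall),
                                    as.list(per_group),
                                    list(test = test, p_value = p))
  }

  n_all <- nrow(patients)
  counts <- if (two) vapply(lev, function(l) sum(g == l), integer(1))
  add("All included patients", sprintf("n = %d", n_all),
      if (two) setNames(sprintf("n = %d (%.1f%%)", counts,
                                100 * counts / n_all), lev))

  cat_row <- function(label, flag, subset = rep(TRUE, n_all)) {
    f <- flag[subset]; gg <- g[subset]
    overall <- fmt_count_pct(sum(f), length(f))
    pg <- NULL; test <- NA_character_; p <- NA_real_
    if (two) {
      pg <- vapply(lev, function(l)
        fmt_count_pct(sum(f[gg == l]), sum(gg == l)), character(1))
      tab <- rbind(c(sum(f & gg == lev[1]), sum(!f & gg == lev[1])),
                   c(sum(f & gg == lev[2]), sum(!f & gg == lev[2])))
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(E < 5)) {
        test <- "fisher"
        p <- suppressMessages(fisher_exact_two_sided(tab))
      } else {
        test <- "chi_squared"
        p <- chi_squared_2x2(tab)$p_value
      }
    }
    add(label, overall, pg, test, p)
  }
  num_row <- function(label, v) {
    overall <- fmt_median_iqr(v)
    pg <- NULL; test <- NA_character_; p <- NA_real_
    if (two) {
      pg <- vapply(lev, function(l) fmt_median_iqr(v[g == l]), character(1))
      test <- "wilcoxon"
      p <- wilcoxon_rank_sum(v[g == lev[1]], v[g == lev[2]])$p_value
    }
    add(label, overall, pg, test, p)
  }

  cat_row("Females", patients$sex == "female")
  num_row("Age at first hospital admission", patients$age_at_first_admission)
  num_row("Steady state hemoglobin (g/dL)", patients$steady_state_hb)
  pretty <- c(acute_chest_syndrome = "Acute chest syndrome",
              avascular_necrosis = "Avascular bone necrosis",
              retinopathy = "Retinopathy", leg_ulcer = "Leg skin ulceration",
              stroke = "Ischemic stroke", dialysis = "Dialysis",
              pulmonary_hypertension = "Pulmonary hypertension")
  for (cm in names(pretty))
    if (cm %in% names(patients)) cat_row(pretty[[cm]], patients[[cm]])
  if ("priapism" %in% names(patients) && any(male)) {
    add("Male patients only", sprintf("m = %d", sum(male)),
        if (two) vapply(lev, function(l)
          sprintf("m = %d", sum(male & g == l)), character(1)))
    cat_row("Priapism", patients$priapism, subset = male)
  }

  out <- data.table::rbindlist(lapply(rows, as.data.frame), fill = TRUE)
  data.table::setDF(out)
  if (two) names(out)[3:4] <- paste0("group_", lev)
  out$p_formatted <- fmt_p(out$p_value)
  class(out) <- c("table_one", "data.frame")
  out
}

#' @export
print.table_one <- function(x, ...) {
  y <- x
  y$p_value <- NULL
  print.data.frame(y, right = FALSE, row.names = FALSE)
  invisible(x)
}
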