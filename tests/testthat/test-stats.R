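# from-scratch group-comparison tests

test_that("Fisher reproduces the published 2x2 p-values at printed precision", {
  expect_equal(round(fisher_exact_two_sided(c(1, 120, 1, 42)), 3), 0.457)
  expect_equal(round(fisher_exact_two_sided(c(13, 45, 0, 19)), 3), 0.030)
  expect_equal(round(fisher_exact_two_sided(c(2, 119, 1, 42)), 3), 1)
  expect_equal(round(fisher_exact_two_sided(c(9, 112, 1, 42)), 3), 0.457)
  expect_equal(round(fisher_exact_two_sided(c(12, 109, 7, 36)), 3), 0.275)
  expect_equal(round(fisher_exact_two_sided(c(3, 118, 3, 40)), 3), 0.186)
  expect_lt(fisher_exact_two_sided(c(93, 28, 18, 25)), 0.001)
})

test_that("Fisher equals the exact big-integer enumeration oracle", {
  set.seed(101)
  for (i in 1:40) {
    N <- sample(8:60, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c <- sample(0:(N - a - b), 1); d <- N - a - b - c
    t <- c(a, b, c, d)
    r1 <- a + b; c1 <- a + c
    if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) next
    expect_equal(fisher_exact_two_sided(t), oracle_fisher(a, b, c, d),
                 tolerance = 1e-10, label = paste(t, collapse = ","))
    # and agreement with the reference implementation
    expect_equal(fisher_exact_two_sided(t),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("Fisher is invariant under joint row/column transposition and
           degenerate margins give p = 1", {
  t <- c(5, 9, 2, 14)
  expect_equal(fisher_exact_two_sided(t),
               fisher_exact_two_sided(c(14, 2, 9, 5)))
  expect_message(p <- fisher_exact_two_sided(c(0, 0, 3, 7)), "degenerate")
  expect_equal(p, 1)
})

test_that("chi-squared matches the Pearson formula and its identities", {
  h <- chi_squared_2x2(c(10, 10, 10, 10))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  r <- chi_squared_2x2(c(93, 28, 18, 25))
  expect_equal(r$statistic, 17.7669, tolerance = 1e-4)
  expect_equal(r$p_value, 2.497e-5, tolerance = 1e-3)
  # equals the squared two-proportion z statistic
  a <- 93; b <- 28; c <- 18; d <- 25
  p1 <- a / (a + b); p2 <- c / (c + d); pp <- (a + c) / (a + b + c + d)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (c + d)))
  expect_equal(r$statistic, z^2, tolerance = 1e-10)
  # invariant to row and column permutation
  expect_equal(chi_squared_2x2(c(28, 93, 25, 18))$statistic, r$statistic)
  expect_equal(chi_squared_2x2(c(18, 25, 93, 28))$statistic, r$statistic)
  # Yates correction shrinks the statistic
  expect_lt(chi_squared_2x2(c(9, 3, 4, 10), correct = TRUE)$statistic,
            chi_squared_2x2(c(9, 3, 4, 10))$statistic)
  expect_error(chi_squared_2x2(c(0, 0, 3, 7)), "fisher")
})

test_that("Wilcoxon exact branch: worked examples and degenerate inputs", {
  r <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 5, 9), c(2, 5, 9))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 5))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("Wilcoxon exact branch equals the pair-counting oracle", {
  set.seed(202)
  for (i in 1:25) {
    m <- sample(2:5, 1); n <- sample(2:7, 1)
    x <- round(rnorm(m), 1)                 # rounding induces ties
    y <- round(rnorm(n), 1)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_rank_sum(x, y),
                 tolerance = 1e-12,
                 label = sprintf("m=%d n=%d rep=%d", m, n, i))
  }
  # tie-free case also agrees with the reference implementation
  x <- c(0.3, 1.7, 2.2, 4.1, 5.3); y <- c(0.9, 1.1, 3.5, 3.9, 6.2, 7.7, 8)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Wilcoxon normal branch is calibrated under the null", {
  set.seed(303)
  p <- replicate(400, wilcoxon_rank_sum(rnorm(60), rnorm(60))$p_value)
  # occasional duplicated p-values trigger a harmless KS ties warning
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("table one reproduces the published Fisher column", {
  set.seed(7)
  t1 <- build_table_one(fixture_table_one_patients())
  p_of <- function(label) t1$p_formatted[t1$label == label]
  expect_equal(p_of("Dialysis"), "0.457")
  expect_equal(p_of("Pulmonary hypertension"), "1")
  expect_equal(p_of("Priapism"), "0.030")
  expect_equal(p_of("Leg skin ulceration"), "0.457")
  expect_equal(p_of("Retinopathy"), "0.275")
  expect_equal(p_of("Ischemic stroke"), "0.186")
  expect_equal(p_of("Acute chest syndrome"), "<0.001")
  expect_equal(t1$test[t1$label == "Dialysis"], "fisher")
  expect_equal(t1$test[t1$label == "Acute chest syndrome"], "chi_squared")
  # published overall percentages follow from the same counts
  expect_equal(t1$overall[t1$label == "Acute chest syndrome"], "111 (67.7%)")
  expect_equal(t1$overall[t1$label == "Priapism"], "13 (16.9%)")
})

test_that("table one degrades gracefully with a single group", {
  p <- fixture_table_one_patients()
  p <- p[p$genotype == "SS", ]
  expect_warning(t1 <- build_table_one(p), "two non-empty groups")
  expect_false("group_other" %in% names(t1))
  expect_true(all(is.na(t1$p_value)))
})

test_that("quantitative-row p-values are uniform for a null grouping", {
  # genotype-independent ages: the Wilcoxon p across replicate cohorts
  # should be uniform on (0,1)
  set.seed(404)
  p <- replicate(300, {
    g <- c(rep("SS", 80), rep("other", 40))
    age <- rnorm(120, 30, 7)
    wilcoxon_rank_sum(age[g == "SS"], age[g == "other"])$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})
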