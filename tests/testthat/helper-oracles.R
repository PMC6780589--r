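# Independent oracles.  Deliberately implemented along different routes
# than the package code: the Fisher oracle enumerates the hypergeometric
# support with exact integer arithmetic (prime-factorized binomials
# materialized as base-1e7 big integers, so tie decisions are exact); the
# Wilcoxon oracle enumerates group assignments and counts Mann-Whitney
# pairs directly, never computing ranks of the null distribution.

# --- minimal non-negative big integers, little-endian base 1e7 -------------
.BB <- 1e7
big_one <- function() 1
big_mul_small <- function(a, s) {  # s < .BB
  r <- a * s
  carry <- 0
  for (i in seq_along(r)) {
    v <- r[i] + carry
    r[i] <- v %% .BB
    carry <- v %/% .BB
  }
  while (carry > 0) {
    r <- c(r, carry %% .BB)
    carry <- carry %/% .BB
  }
  r
}
big_add <- function(a, b) {
  n <- max(length(a), length(b))
  r <- c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
  carry <- 0
  for (i in seq_len(n)) {
    v <- r[i] + carry
    r[i] <- v %% .BB
    carry <- v %/% .BB
  }
  if (carry > 0) r <- c(r, carry)
  r
}
big_cmp <- function(a, b) {  # sign of a - b
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  while (length(b) > 1 && b[length(b)] == 0) b <- b[-length(b)]
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a)))
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  0
}
big_to_double <- function(a) sum(a * .BB^(seq_along(a) - 1))

.primes60 <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59)
legendre <- function(n, p) {
  s <- 0; pk <- p
  while (pk <= n) { s <- s + n %/% pk; pk <- pk * p }
  s
}
choose_exponents <- function(n, k) {
  vapply(.primes60, function(p)
    legendre(n, p) - legendre(k, p) - legendre(n - k, p), numeric(1))
}
exponents_to_big <- function(e) {
  b <- big_one()
  for (j in seq_along(.primes60))
    for (r in seq_len(e[j])) b <- big_mul_small(b, .primes60[j])
  b
}

# two-sided Fisher p by the probability-mass rule, exact tie decisions
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  stopifnot(N <= 60)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  w <- lapply(lo:hi, function(x)
    exponents_to_big(choose_exponents(r1, x) + choose_exponents(r2, c1 - x)))
  w_obs <- w[[a - lo + 1]]
  tot <- Reduce(big_add, w)
  sel <- Reduce(big_add, w[vapply(w, function(wx)
    big_cmp(wx, w_obs) <= 0, logical(1))])
  big_to_double(sel) / big_to_double(tot)
}

# Wilcoxon/Mann-Whitney two-sided p by full enumeration of group labels,
# statistic = number of (x, y) pairs with x > y plus half the ties
oracle_rank_sum <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_stat(seq_len(m))
  us <- combn(N, m, u_stat)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= obs + eps), mean(us >= obs - eps)))
}
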