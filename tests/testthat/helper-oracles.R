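# Independent oracles used to check the implementation. These stay
# deliberately naive: direct textbook formulas, quadrature and bisection,
# never calls into the code paths they verify.

# product-moment correlation straight from the covariance/sd definition
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# two-sided p by numeric quadrature of the t density, df = n - 2
oracle_cor_pvalue <- function(r, n) {
  df <- n - 2
  tt <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tt, Inf, rel.tol = 1e-10)$value
}

# smallest |r| with p <= alpha, by bisection over the quadrature oracle
oracle_critical_r <- function(n, alpha, tol = 1e-9) {
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_cor_pvalue(mid, n) <= alpha) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# two-sided pooled-variance two-sample t-test from the textbook formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tt), df = na + nb - 2)
}

# permutation p-value for a correlation: shuffle y, count |r| as extreme
oracle_permutation_p <- function(x, y, B = 2000, seed = 7) {
  set.seed(seed)
  r0 <- abs(oracle_pearson(x, y))
  hits <- sum(vapply(seq_len(B), function(i)
    abs(oracle_pearson(x, sample(y))) >= r0, logical(1)))
  (hits + 1) / (B + 1)
}

# quick canonical-TSV fixture writer
write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
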