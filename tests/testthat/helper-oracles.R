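# Independent oracles used to check the estimators against brute force.

# exact binomial log-likelihood of a probit line on grouped quantal data
probit_loglik <- function(b0, b1, level, n, d) {
  p <- pnorm(b0 + b1 * log10(level))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dbinom(d, n, p, log = TRUE))
}

# grid-search maximiser of the exact likelihood (coarse-to-fine)
grid_probit <- function(level, n, d, b0_range, b1_range, steps = 3) {
  for (s in seq_len(steps)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = 41)
    b1s <- seq(b1_range[1], b1_range[2], length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(function(x, y)
      probit_loglik(x, y, level, n, d)))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    b0 <- b0s[ij[1]]; b1 <- b1s[ij[2]]
    w0 <- diff(b0_range) / 8; w1 <- diff(b1_range) / 8
    b0_range <- c(b0 - w0, b0 + w0); b1_range <- c(b1 - w1, b1 + w1)
  }
  c(b0 = b0, b1 = b1)
}

# closed-form least squares on ln-transformed axes (normal equations)
loglog_ls_oracle <- function(conc, lt) {
  X <- cbind(1, log(conc))
  as.numeric(solve(t(X) %*% X, t(X) %*% log(lt)))
}

# bisection root of probit(p) = b0 + b1*log10(x)
bisect_ed <- function(p, b0, b1, lo = 1e-12, hi = 1e12, tol = 1e-12) {
  f <- function(x) b0 + b1 * log10(x) - qnorm(p)
  for (i in 1:200) {
    mid <- sqrt(lo * hi) # geometric bisection on the log scale
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (log10(hi / lo) < tol) break
  }
  sqrt(lo * hi)
}

# case-study shortcuts used across test files
cs_prediction <- function(species, mixture, totals) {
  predict_mixture_lt50_curve(case_study_mixture(species, mixture),
                             case_study_coefficients(species), totals)
}
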