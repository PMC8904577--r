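# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting for the AUC, bisection
# on the CDF for quantiles, and plain Monte Carlo for distributional moments.

# AUC by enumerating every case-control pair (ties count half).
brute_force_auc <- function(case_scores, control_scores) {
  wins <- outer(case_scores, control_scores, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(wins)
}

# Invert an increasing CDF by bisection, independent of uniroot.
bisect_quantile <- function(cdf, q, lower = -20, upper = 20, iter = 80L) {
  for (i in seq_len(iter)) {
    mid <- (lower + upper) / 2
    if (cdf(mid) < q) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

# Monte Carlo draws from the case/control mixture implied by (K, d).
draw_mixture <- function(K, d, n, seed) {
  model <- build_binary_model(K, d)
  set.seed(seed)
  status <- rbinom(n, 1L, K)
  mu <- ifelse(status == 1L, model$mu_case, model$mu_control)
  list(status = status, score = rnorm(n, mu, model$sigma_within))
}

# Monte Carlo draws from the bivariate-normal (score, trait) model.
draw_bivariate <- function(mean, sd, r2, n, seed) {
  set.seed(seed)
  z <- rnorm(n)
  rho <- sqrt(r2)
  list(z = z, y = mean + sd * (rho * z + sqrt(1 - rho^2) * rnorm(n)))
}
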