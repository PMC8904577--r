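# Synthetic cohorts with exactly the statistical structure the conversions
# assume, so the whole tool can be validated without individual-level data.

#' Simulate a case/control cohort from the mixture model
#'
#' Draws case status with probability K, then the standardized polygenic score
#' from the corresponding mixture component of the model implied by (K, AUC).
#' This is equivalent to drawing a liability and thresholding it, but needs no
#' nuisance liability parameter; `liability_mode = TRUE` uses the explicit
#' liability route as a robustness check (status from a thresholded liability
#' correlated with the score at the level implied by d).
#'
#' @param K Population prevalence.
#' @param auc AUC of the polygenic score, in `[0.5, 1)`.
#' @param n Number of individuals.
#' @param seed Integer seed; cohorts are reproducible given the seed.
#' @param liability_mode Draw via an explicit liability threshold instead of
#'   component-wise (default `FALSE`).
#' @return An object of class `simulated_binary_cohort`: a list with
#'   `case_status` (0/1), `pgs_z`, `n`, `true_K`, `true_auc`, `true_d`, `seed`.
#' @export
simulate_binary_cohort <- function(K, auc, n, seed, liability_mode = FALSE) {
  check_prob_open(K, "K")
  d <- auc_to_d(auc)
  n <- check_count(n, "n", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  model <- build_binary_model(K, d)
  set.seed(seed)
  if (isTRUE(liability_mode)) {
    # Liability route: score and liability bivariate standard normal, status
    # from thresholding liability at qnorm(1 - K). The score-liability
    # correlation is chosen so the score-status point-biserial correlation
    # matches the one the mixture model implies at population sampling
    # (r = d sqrt(K(1-K)) / sqrt(1 + d^2 K(1-K))); the case/control score
    # distributions are then only approximately normal.
    r_pb <- d_to_r(d, K)
    rho_l <- r_pb * sqrt(K * (1 - K)) / dnorm(qnorm(1 - K))
    rho_l <- min(rho_l, 1)
    z <- rnorm(n)
    liab <- rho_l * z + sqrt(1 - rho_l^2) * rnorm(n)
    status <- as.integer(liab > qnorm(1 - K))
  } else {
    status <- rbinom(n, 1L, K)
    mu <- ifelse(status == 1L, model$mu_case, model$mu_control)
    z <- rnorm(n, mu, model$sigma_within)
  }
  structure(list(case_status = status, pgs_z = z, n = n,
                 true_K = K, true_auc = auc, true_d = d, seed = seed),
            class = "simulated_binary_cohort")
}

#' Simulate a continuous-trait cohort from the bivariate-normal model
#'
#' Draws (score, trait) pairs jointly bivariate normal: score X ~ N(0, 1),
#' trait `Y = mean + sd (rho X + sqrt(1 - rho^2) E)` with E ~ N(0, 1)
#' independent, so the squared score-trait correlation is r2.
#'
#' @param mean,sd Population trait mean and SD.
#' @param r2 Variance explained by the score, in `[0, 1)`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return An object of class `simulated_continuous_cohort`: a list with
#'   `trait_value`, `pgs_z`, `n`, `true_mean`, `true_sd`, `true_r2`, `seed`.
#' @export
simulate_continuous_cohort <- function(mean, sd, r2, n, seed) {
  model <- build_continuous_model(mean, sd, r2)
  n <- check_count(n, "n", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  z <- rnorm(n)
  y <- mean + sd * (model$rho * z + sqrt(1 - model$rho^2) * rnorm(n))
  structure(list(trait_value = y, pgs_z = z, n = n,
                 true_mean = mean, true_sd = sd, true_r2 = r2, seed = seed),
            class = "simulated_continuous_cohort")
}
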