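# Observed-vs-estimated comparison across score quantiles: the validation
# design used to check the absolute-scale conversion on cohorts where
# individual-level data are available (here, simulated ones).

#' Mann-Whitney AUC of a score against case status
#'
#' The probability that a randomly chosen case scores higher than a randomly
#' chosen control, estimated by the rank-based Mann-Whitney U statistic (ties
#' counted half).
#'
#' @param cohort A [simulate_binary_cohort()] object, or any list with
#'   `case_status` (0/1) and `pgs_z` elements.
#' @return AUC in (0, 1).
#' @export
observed_auc <- function(cohort) {
  status <- cohort$case_status
  score <- cohort$pgs_z
  n1 <- as.numeric(sum(status == 1L))
  n0 <- as.numeric(sum(status == 0L))
  if (n1 == 0L || n0 == 0L)
    abort_domain("AUC requires both cases and controls (got %d cases, %d controls)",
                 n1, n0)
  r <- rank(score)
  (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Squared score-trait correlation of a continuous cohort
#'
#' @param cohort A [simulate_continuous_cohort()] object.
#' @return Observed R-squared in `[0, 1]`.
#' @export
observed_r2 <- function(cohort) {
  cor(cohort$pgs_z, cohort$trait_value)^2
}

#' Moment skewness of a numeric vector
#'
#' Standardized third central moment, `m3 / m2^(3/2)`.
#'
#' @param x Numeric vector.
#' @return Skewness estimate.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# Equal-count quantile assignment by rank (ties broken by position), the
# empirical counterpart of the model's equal-mass partition.
empirical_quantile_index <- function(score, n_quantiles) {
  ceiling(rank(score, ties.method = "first") * n_quantiles / length(score))
}

#' Validate the binary conversion against a simulated cohort
#'
#' Splits the cohort into equal-count score quantiles, measures the observed
#' case proportion in each, and compares it to the model-estimated case
#' probability. The model is parameterized either from the cohort itself
#' (`input = "observed"`: empirical case fraction and Mann-Whitney AUC, as
#' when validating against real data) or from supplied values
#' (`input = "supplied"`: the generating parameters, or `auc_override` to
#' study misspecification).
#'
#' @param cohort A [simulate_binary_cohort()] object.
#' @param n_quantiles Number of quantiles (default 20).
#' @param input `"observed"` or `"supplied"` (see Details).
#' @param auc_override Optional AUC to use in place of the cohort's, e.g. an
#'   externally estimated value whose misspecification effect is of interest.
#' @return An object of class `validation_summary`: per-quantile observed and
#'   estimated case probabilities, `mean_abs_diff` (mean |observed -
#'   estimated| in percentage points), `mean_abs_diff_rel` (mean relative
#'   difference as a percent of the estimated value), `observed_auc`, and
#'   `top_quantile_ratio` (estimated / observed case proportion in the top
#'   quantile).
#' @export
validate_binary <- function(cohort, n_quantiles = 20L,
                            input = c("supplied", "observed"),
                            auc_override = NULL) {
  stopifnot(inherits(cohort, "simulated_binary_cohort"))
  input <- match.arg(input)
  n_quantiles <- check_count(n_quantiles, "n_quantiles", min = 2L)
  idx <- empirical_quantile_index(cohort$pgs_z, n_quantiles)
  counts <- tabulate(idx, nbins = n_quantiles)
  if (any(counts == 0L))
    abort_domain("quantile %d contains no individuals; reduce n_quantiles",
                 which(counts == 0L)[1])
  obs <- vapply(seq_len(n_quantiles),
                function(i) mean(cohort$case_status[idx == i]), numeric(1))
  auc_obs <- observed_auc(cohort)
  if (input == "observed") {
    K <- mean(cohort$case_status)
    auc <- auc_obs
  } else {
    K <- cohort$true_K
    auc <- auc_override %||% cohort$true_auc
  }
  est <- risk_by_quantile(build_binary_model(K, auc_to_d(auc)),
                          n_quantiles)$case_probability
  structure(list(mode = "binary",
                 n_quantiles = n_quantiles,
                 n = cohort$n,
                 table = data.frame(quantile = seq_len(n_quantiles),
                                    observed = obs, estimated = est),
                 mean_abs_diff = 100 * mean(abs(obs - est)),
                 mean_abs_diff_rel = 100 * mean(abs(obs - est) / est),
                 observed_auc = auc_obs,
                 input_auc = auc,
                 top_quantile_ratio = est[n_quantiles] / obs[n_quantiles]),
            class = "validation_summary")
}

#' Validate the continuous conversion against a simulated cohort
#'
#' Splits the cohort into equal-count score quantiles, measures the observed
#' trait mean and SD in each, and compares them with the model-estimated
#' values. Differences are summarized as mean absolute relative differences
#' (percent of the estimated per-quantile mean, respectively SD).
#'
#' @param cohort A [simulate_continuous_cohort()] object.
#' @param n_quantiles Number of quantiles (default 20).
#' @param input `"observed"` (empirical trait mean/SD and R-squared) or
#'   `"supplied"` (the generating parameters).
#' @param r2_override Optional R-squared used in place of the cohort's.
#' @return An object of class `validation_summary` with per-quantile observed
#'   and estimated means and SDs, `mean_abs_diff` (means, percent),
#'   `mean_abs_diff_sd` (SDs, percent), `observed_r2`, and the trait
#'   `skewness`.
#' @export
validate_continuous <- function(cohort, n_quantiles = 20L,
                                input = c("supplied", "observed"),
                                r2_override = NULL) {
  stopifnot(inherits(cohort, "simulated_continuous_cohort"))
  input <- match.arg(input)
  n_quantiles <- check_count(n_quantiles, "n_quantiles", min = 2L)
  idx <- empirical_quantile_index(cohort$pgs_z, n_quantiles)
  counts <- tabulate(idx, nbins = n_quantiles)
  if (any(counts < 2L))
    abort_domain("quantile %d contains fewer than 2 individuals; reduce n_quantiles",
                 which(counts < 2L)[1])
  obs_mean <- vapply(seq_len(n_quantiles),
                     function(i) mean(cohort$trait_value[idx == i]), numeric(1))
  obs_sd <- vapply(seq_len(n_quantiles),
                   function(i) sd(cohort$trait_value[idx == i]), numeric(1))
  r2_obs <- observed_r2(cohort)
  if (input == "observed") {
    model <- build_continuous_model(mean(cohort$trait_value),
                                    sd(cohort$trait_value), r2_obs)
  } else {
    model <- build_continuous_model(cohort$true_mean, cohort$true_sd,
                                    r2_override %||% cohort$true_r2)
  }
  est <- trait_by_quantile(model, n_quantiles)
  structure(list(mode = "continuous",
                 n_quantiles = n_quantiles,
                 n = cohort$n,
                 table = data.frame(quantile = seq_len(n_quantiles),
                                    observed_mean = obs_mean,
                                    estimated_mean = est$trait_mean,
                                    observed_sd = obs_sd,
                                    estimated_sd = est$trait_sd),
                 mean_abs_diff = 100 * mean(abs(obs_mean - est$trait_mean) /
                                              abs(est$trait_mean)),
                 mean_abs_diff_sd = 100 * mean(abs(obs_sd - est$trait_sd) /
                                                 est$trait_sd),
                 observed_r2 = r2_obs,
                 skewness = skewness(cohort$trait_value)),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Observed vs estimated absolute values (%s, %d quantiles, n = %d)\n",
              x$mode, x$n_quantiles, x$n))
  if (x$mode == "binary") {
    cat(sprintf("  mean abs. diff. of case probability : %.2f points (%.1f%% relative)\n",
                x$mean_abs_diff, x$mean_abs_diff_rel))
    cat(sprintf("  observed AUC                        : %.3f (input %.3f)\n",
                x$observed_auc, x$input_auc))
    cat(sprintf("  top-quantile estimated/observed     : %.2f\n", x$top_quantile_ratio))
  } else {
    cat(sprintf("  mean abs. diff. of trait mean : %.2f%%\n", x$mean_abs_diff))
    cat(sprintf("  mean abs. diff. of trait SD   : %.2f%%\n", x$mean_abs_diff_sd))
    cat(sprintf("  observed R2 / skewness        : %.4f / %.3f\n",
                x$observed_r2, x$skewness))
  }
  invisible(x)
}
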