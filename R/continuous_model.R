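# Bivariate-normal model linking a standardized polygenic score to a normally
# distributed trait, and the conditional (per-quantile) moments built on it.

#' Build the bivariate-normal model for a continuous phenotype
#'
#' The standardized polygenic score X ~ N(0, 1) and the trait Y ~ N(mu,
#' sigma^2) are modelled as jointly bivariate normal with correlation
#' `rho = sqrt(r2)`, where r2 is the variance in the trait explained by the
#' score. The score is assumed oriented so a higher score implies a higher
#' trait value; set `negative_orientation = TRUE` to flip the sign of rho.
#'
#' @param mean Population trait mean (trait units).
#' @param sd Population trait SD (trait units), positive.
#' @param r2 Variance explained by the polygenic score, in `[0, 1)`.
#' @param negative_orientation If `TRUE`, higher scores predict lower trait
#'   values (rho = -sqrt(r2)).
#' @return An object of class `continuous_trait_model` with fields `mean`,
#'   `sd`, `r2`, `rho`.
#' @examples
#' build_continuous_model(mean = 100, sd = 15, r2 = 0.10)
#' @export
build_continuous_model <- function(mean, sd, r2, negative_orientation = FALSE) {
  check_finite(mean, "mean")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    abort_domain("`sd` must be a single positive number (got %s)", format(sd))
  check_finite(r2, "r2")
  if (r2 < 0 || r2 >= 1)
    abort_domain("`r2` must be in [0, 1); got %s", format(r2))
  rho <- sqrt(r2) * if (isTRUE(negative_orientation)) -1 else 1
  structure(list(mean = mean, sd = sd, r2 = r2, rho = rho),
            class = "continuous_trait_model")
}

#' @export
print.continuous_trait_model <- function(x, ...) {
  cat("Continuous-trait polygenic score model (bivariate normal)\n")
  cat(sprintf("  trait mean / SD : %g / %g\n", x$mean, x$sd))
  cat(sprintf("  R2 (rho)        : %g (%.4f)\n", x$r2, x$rho))
  invisible(x)
}

#' Moments of a truncated standard normal
#'
#' Closed-form mean and variance of Z ~ N(0, 1) conditional on Z in (a, b):
#' with Zm = Phi(b) - Phi(a), `mean = (phi(a) - phi(b)) / Zm` and
#' `variance = 1 + (a phi(a) - b phi(b)) / Zm - mean^2`, where terms with
#' infinite bounds vanish.
#'
#' @param a,b Truncation bounds, `a < b`; `-Inf` / `Inf` allowed.
#' @return A list with `mean` and `variance`.
#' @examples
#' truncated_std_normal_moments(-Inf, qnorm(0.05))
#' @export
truncated_std_normal_moments <- function(a, b) {
  if (is.na(a) || is.na(b) || !(a < b))
    abort_domain("truncation requires a < b (got a = %s, b = %s)",
                 format(a), format(b))
  mass <- pnorm(b) - pnorm(a)
  if (mass < 1e-300)
    abort_domain("interval (%s, %s) carries no normal mass", format(a), format(b))
  # x * phi(x) -> 0 as |x| -> Inf; code the limit explicitly
  phi_a <- if (is.finite(a)) dnorm(a) else 0
  phi_b <- if (is.finite(b)) dnorm(b) else 0
  aphi_a <- if (is.finite(a)) a * phi_a else 0
  bphi_b <- if (is.finite(b)) b * phi_b else 0
  m <- (phi_a - phi_b) / mass
  v <- 1 + (aphi_a - bphi_b) / mass - m^2
  list(mean = m, variance = v)
}

#' Trait mean and SD given a polygenic score interval
#'
#' Conditional on the standardized score falling in (a, b), the trait moments
#' follow from the bivariate-normal decomposition
#' `E[Y | X in (a,b)] = mu + rho sigma E[X | X in (a,b)]` and
#' `Var[Y | X in (a,b)] = sigma^2 (1 - rho^2) + rho^2 sigma^2 Var[X | X in (a,b)]`,
#' with the truncated-normal moments of X computed in closed form.
#'
#' @param model A [build_continuous_model()] object.
#' @param a,b Score interval bounds, `a < b`; infinite bounds allowed.
#' @return A list with `mean` and `sd` in trait units.
#' @export
trait_moments_interval <- function(model, a, b) {
  stopifnot(inherits(model, "continuous_trait_model"))
  tm <- truncated_std_normal_moments(a, b)
  m <- model$mean + model$rho * model$sd * tm$mean
  v <- model$sd^2 * (1 - model$rho^2) + model$rho^2 * model$sd^2 * tm$variance
  list(mean = m, sd = sqrt(v))
}

#' Trait mean and SD across polygenic score quantiles
#'
#' Splits the (standard normal) score distribution into equal-mass quantiles
#' and computes the conditional trait mean and SD within each.
#'
#' @param model A [build_continuous_model()] object.
#' @param n_quantiles Number of quantiles, at least 2.
#' @return A data frame of class `absolute_trait_table` with columns
#'   `quantile`, `lower`, `upper`, `trait_mean`, `trait_sd`; the model and
#'   partition are attached as attributes.
#' @export
trait_by_quantile <- function(model, n_quantiles = 20L) {
  stopifnot(inherits(model, "continuous_trait_model"))
  part <- quantile_partition(model, n_quantiles)
  b <- part$boundaries
  n <- part$n_quantiles
  mom <- lapply(seq_len(n), function(i) trait_moments_interval(model, b[i], b[i + 1]))
  out <- data.frame(quantile = seq_len(n),
                    lower = b[-length(b)],
                    upper = b[-1],
                    trait_mean = vapply(mom, `[[`, numeric(1), "mean"),
                    trait_sd = vapply(mom, `[[`, numeric(1), "sd"))
  structure(out, class = c("absolute_trait_table", "data.frame"),
            model = model, partition = part)
}

#' Absolute trait prediction for one individual's polygenic Z-score
#'
#' Places the Z-score in its quantile of the standard-normal score
#' distribution (1000 quantiles by default) and reports the conditional trait
#' mean together with a prediction interval,
#' `mean +/- qnorm((1 + level)/2) * sd`. By default the SD is the within-cell
#' conditional SD at the stated resolution; `sd_method = "point"` instead uses
#' the point-conditional values `mu + rho sigma z` and `sigma sqrt(1 - rho^2)`,
#' which differ negligibly at 1000 cells.
#'
#' @param model A [build_continuous_model()] object.
#' @param z The individual's standardized polygenic score.
#' @param level Prediction-interval coverage, in (0, 1); default 0.95.
#' @param n_quantiles Partition resolution; 1000 by default.
#' @param sd_method `"within_cell"` (default) or `"point"`.
#' @return An object of class `individual_trait_result` with fields `z`,
#'   `percentile`, `quantile_index`, `predicted_mean`, `predicted_sd`,
#'   `interval_lower`, `interval_upper`, `level`.
#' @examples
#' m <- build_continuous_model(mean = 100, sd = 15, r2 = 0.10)
#' individual_trait(m, z = -1.96)
#' @export
individual_trait <- function(model, z, level = 0.95, n_quantiles = 1000L,
                             sd_method = c("within_cell", "point")) {
  stopifnot(inherits(model, "continuous_trait_model"))
  check_finite(z, "z")
  check_prob_open(level, "level")
  sd_method <- match.arg(sd_method)
  part <- quantile_partition(model, n_quantiles)
  idx <- partition_index(part, z)
  if (sd_method == "within_cell") {
    mom <- trait_moments_interval(model, part$boundaries[idx],
                                  part$boundaries[idx + 1])
    m <- mom$mean; s <- mom$sd
  } else {
    m <- model$mean + model$rho * model$sd * z
    s <- model$sd * sqrt(1 - model$rho^2)
  }
  half <- qnorm((1 + level) / 2) * s
  structure(list(z = z,
                 percentile = 100 * pnorm(z),
                 quantile_index = idx,
                 n_quantiles = as.integer(n_quantiles),
                 predicted_mean = m,
                 predicted_sd = s,
                 interval_lower = m - half,
                 interval_upper = m + half,
                 level = level),
            class = "individual_trait_result")
}

#' @export
print.individual_trait_result <- function(x, ...) {
  cat(sprintf("Polygenic Z-score %.3f: percentile %.1f\n", x$z, x$percentile))
  cat(sprintf("Predicted trait value (quantile %d of %d): %.1f\n",
              x$quantile_index, x$n_quantiles, x$predicted_mean))
  cat(sprintf("%.0f%% prediction interval: %.1f to %.1f\n",
              100 * x$level, x$interval_lower, x$interval_upper))
  invisible(x)
}
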