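# Two-component normal mixture model for the standardized polygenic score of
# a binary phenotype, and the absolute-risk computations built on it.

#' Build the case/control mixture model for a binary phenotype
#'
#' In the population, the standardized polygenic score of a binary phenotype
#' is modelled as a mixture of two equal-variance normal components: cases
#' (weight K, the prevalence) and controls (weight 1 - K), separated by
#' Cohen's d within-group SD units. The component parameters are fixed in
#' closed form so the mixture has mean 0 and variance 1, matching a score
#' standardized against a reference population:
#' `sigma_within = 1 / sqrt(1 + K (1 - K) d^2)`,
#' `mu_control = -K d sigma_within`, `mu_case = (1 - K) d sigma_within`.
#'
#' @param K Population prevalence, in (0, 1).
#' @param d Cohen's d of the polygenic score (standardized case-control mean
#'   difference), non-negative. Use the `effect_metrics` converters (e.g.
#'   [auc_to_d()]) if the predictive utility is known on another scale.
#' @return An object of class `binary_trait_model` with fields `K`, `d`,
#'   `mu_case`, `mu_control`, `sigma_within`.
#' @examples
#' build_binary_model(K = 0.01, d = auc_to_d(0.67))
#' @export
build_binary_model <- function(K, d) {
  check_prob_open(K, "K")
  check_nonneg(d, "d")
  sigma <- 1 / sqrt(1 + K * (1 - K) * d^2)
  structure(list(K = K, d = d,
                 mu_case = (1 - K) * d * sigma,
                 mu_control = -K * d * sigma,
                 sigma_within = sigma),
            class = "binary_trait_model")
}

#' @export
print.binary_trait_model <- function(x, ...) {
  cat("Binary-trait polygenic score model (two-component normal mixture)\n")
  cat(sprintf("  prevalence K      : %g\n", x$K))
  cat(sprintf("  Cohen's d         : %.4f  (AUC %.3f)\n", x$d, d_to_auc(x$d)))
  cat(sprintf("  case component    : N(%.5f, %.5f^2)\n", x$mu_case, x$sigma_within))
  cat(sprintf("  control component : N(%.5f, %.5f^2)\n", x$mu_control, x$sigma_within))
  invisible(x)
}

#' Mixture CDF of the standardized polygenic score
#'
#' `K * Phi((x - mu_case)/sigma) + (1 - K) * Phi((x - mu_control)/sigma)`:
#' the marginal distribution function of the score in the population.
#'
#' @param model A [build_binary_model()] object.
#' @param x Score value(s); vectorized.
#' @return CDF value(s) in (0, 1).
#' @export
mixture_cdf <- function(model, x) {
  stopifnot(inherits(model, "binary_trait_model"))
  model$K * pnorm(x, model$mu_case, model$sigma_within) +
    (1 - model$K) * pnorm(x, model$mu_control, model$sigma_within)
}

#' Mixture quantile by root-finding
#'
#' The mixture CDF has no closed-form inverse; quantiles are located with a
#' bracketed root-finder (`uniroot`, Brent-type) on
#' `[mu_control - 10, mu_case + 10]`, absolute tolerance 1e-12.
#'
#' @param model A [build_binary_model()] object.
#' @param q Probability / probabilities in (0, 1); vectorized.
#' @return Score value(s) x with `mixture_cdf(model, x) = q`.
#' @export
mixture_quantile <- function(model, q) {
  stopifnot(inherits(model, "binary_trait_model"))
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    abort_domain("quantile probabilities must lie strictly between 0 and 1")
  lower <- model$mu_control - 10
  upper <- model$mu_case + 10
  vapply(q, function(qi) {
    f <- function(x) mixture_cdf(model, x) - qi
    out <- tryCatch(
      uniroot(f, c(lower, upper), tol = 1e-12, maxiter = 200L),
      error = function(e) abort_domain(
        "quantile solver failed for q = %g on bracket [%g, %g]: %s",
        qi, lower, upper, conditionMessage(e)))
    out$root
  }, numeric(1))
}

#' Partition a score distribution into equal-mass quantiles
#'
#' Returns the ordered interval boundaries `b_0 = -Inf < b_1 < ... < b_n = Inf`
#' such that each interval carries mass 1/n under the model's score
#' distribution (the mixture for a binary model, the standard normal for a
#' continuous model).
#'
#' @param model A `binary_trait_model` or `continuous_trait_model`.
#' @param n_quantiles Number of equal-mass intervals, at least 2.
#' @return An object of class `quantile_partition`: a list with `n_quantiles`
#'   and a boundary vector of length `n_quantiles + 1`.
#' @export
quantile_partition <- function(model, n_quantiles) {
  n_quantiles <- check_count(n_quantiles, "n_quantiles", min = 2L)
  probs <- seq_len(n_quantiles - 1L) / n_quantiles
  interior <- if (inherits(model, "binary_trait_model")) {
    mixture_quantile(model, probs)
  } else if (inherits(model, "continuous_trait_model")) {
    qnorm(probs)
  } else {
    abort_domain("`model` must be a binary or continuous trait model")
  }
  structure(list(n_quantiles = n_quantiles,
                 boundaries = c(-Inf, interior, Inf)),
            class = "quantile_partition")
}

#' @export
print.quantile_partition <- function(x, ...) {
  cat(sprintf("Equal-mass partition into %d quantiles\n", x$n_quantiles))
  cat("  interior boundaries: ",
      paste(format(utils::head(x$boundaries[-c(1, length(x$boundaries))], 6),
                   digits = 4), collapse = ", "),
      if (x$n_quantiles > 7) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Index of the half-open cell (b_{i-1}, b_i] containing z; values exactly on
# a boundary fall in the lower cell.
partition_index <- function(partition, z) {
  interior <- partition$boundaries[-c(1, length(partition$boundaries))]
  as.integer(sum(interior < z) + 1L)
}

#' Probability of being a case within a score interval
#'
#' Bayes' rule on the mixture: the case probability given a score in (a, b] is
#' the case-component mass of the interval divided by the total mixture mass,
#' `K (Phi_case(b) - Phi_case(a)) / (F(b) - F(a))`. Over the whole line this
#' is the prevalence K.
#'
#' @param model A [build_binary_model()] object.
#' @param a,b Interval endpoints, `a < b`; infinite bounds allowed.
#' @return Case probability in (0, 1).
#' @export
case_probability_interval <- function(model, a, b) {
  stopifnot(inherits(model, "binary_trait_model"))
  if (!(a < b)) abort_domain("interval requires a < b (got a = %g, b = %g)", a, b)
  mass <- mixture_cdf(model, b) - mixture_cdf(model, a)
  if (mass <= 0)
    abort_domain("interval (%g, %g] carries no mixture mass", a, b)
  case_mass <- model$K * (pnorm(b, model$mu_case, model$sigma_within) -
                            pnorm(a, model$mu_case, model$sigma_within))
  case_mass / mass
}

#' Absolute risk across polygenic score quantiles
#'
#' Splits the mixture into equal-mass quantiles and computes the case
#' probability within each, i.e. the proportion of individuals in each score
#' quantile expected to be affected.
#'
#' @param model A [build_binary_model()] object.
#' @param n_quantiles Number of quantiles (20 suits plots; 1000 gives the
#'   resolution used for individual look-ups).
#' @return A data frame of class `absolute_risk_table` with columns `quantile`,
#'   `lower`, `upper`, `case_probability`; the model and partition are attached
#'   as attributes.
#' @export
risk_by_quantile <- function(model, n_quantiles = 20L) {
  stopifnot(inherits(model, "binary_trait_model"))
  part <- quantile_partition(model, n_quantiles)
  b <- part$boundaries
  n <- part$n_quantiles
  # each cell has exact mass 1/n; case mass from the case component
  case_cdf <- pnorm(b, model$mu_case, model$sigma_within)
  prob <- model$K * diff(case_cdf) * n
  out <- data.frame(quantile = seq_len(n),
                    lower = b[-length(b)],
                    upper = b[-1],
                    case_probability = prob)
  structure(out, class = c("absolute_risk_table", "data.frame"),
            model = model, partition = part)
}

#' Absolute risk for one individual's polygenic Z-score
#'
#' Places the Z-score in its quantile of the mixture (1000 quantiles by
#' default) and reports that quantile's case probability along with the
#' individual's population percentile, `100 * F(z)` under the mixture CDF.
#'
#' @param model A [build_binary_model()] object.
#' @param z The individual's standardized polygenic score.
#' @param n_quantiles Partition resolution; 1000 by default.
#' @return An object of class `individual_risk_result` with fields `z`,
#'   `percentile`, `quantile_index`, `case_probability`.
#' @examples
#' m <- build_binary_model(K = 0.01, d = auc_to_d(0.67))
#' individual_risk(m, z = 1.96)
#' @export
individual_risk <- function(model, z, n_quantiles = 1000L) {
  stopifnot(inherits(model, "binary_trait_model"))
  check_finite(z, "z")
  tab <- risk_by_quantile(model, n_quantiles)
  idx <- partition_index(attr(tab, "partition"), z)
  structure(list(z = z,
                 percentile = 100 * mixture_cdf(model, z),
                 quantile_index = idx,
                 n_quantiles = as.integer(n_quantiles),
                 case_probability = tab$case_probability[idx]),
            class = "individual_risk_result")
}

#' @export
print.individual_risk_result <- function(x, ...) {
  cat(sprintf("Polygenic Z-score %.3f: percentile %.1f\n", x$z, x$percentile))
  cat(sprintf("Absolute risk (quantile %d of %d): %.1f%%\n",
              x$quantile_index, x$n_quantiles, 100 * x$case_probability))
  invisible(x)
}
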