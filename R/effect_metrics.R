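# Conversions among polygenic score effect-size metrics under the
# equal-variance binormal / liability-threshold model. All converters are pure
# scalar functions; Cohen's d is the hub metric every other metric converts
# through.

#' Convert AUC to Cohen's d
#'
#' Under the equal-variance binormal model, the area under the ROC curve of a
#' score that separates cases from controls relates to the standardized mean
#' difference d by AUC = Phi(d / sqrt(2)). This function inverts that relation.
#'
#' @param auc Area under the ROC curve, in `[0.5, 1)`. Scores must be oriented
#'   so that a higher score implies higher risk; an AUC below 0.5 indicates the
#'   opposite orientation and is rejected rather than silently reflected.
#' @return Cohen's d (non-negative).
#' @examples
#' auc_to_d(0.67)
#' d_to_auc(auc_to_d(0.67))
#' @seealso [d_to_auc()]
#' @export
auc_to_d <- function(auc) {
  check_finite(auc, "auc")
  if (auc < 0.5 || auc >= 1)
    abort_domain(paste0("`auc` must be in [0.5, 1); got %s. If your score is ",
                        "protective (AUC < 0.5), flip its orientation first."),
                 format(auc))
  sqrt(2) * qnorm(auc)
}

#' Convert Cohen's d to AUC
#'
#' AUC = Phi(d / sqrt(2)) under the equal-variance binormal model; exact
#' inverse of [auc_to_d()].
#'
#' @param d Cohen's d, non-negative.
#' @return AUC in `[0.5, 1)`.
#' @export
d_to_auc <- function(d) {
  check_nonneg(d, "d")
  pnorm(d / sqrt(2))
}

#' Convert a point-biserial correlation to Cohen's d
#'
#' GWAS-derived correlations between a polygenic score and a binary phenotype
#' depend on the case/control sampling ratio of the sample they were estimated
#' in. With case fraction P, the point-biserial correlation r and Cohen's d are
#' linked by `d = r / sqrt(P (1 - P) (1 - r^2))`.
#'
#' @param r Point-biserial correlation, in `[0, 1)`.
#' @param case_fraction Proportion of cases P in the sample the correlation was
#'   estimated in, strictly between 0 and 1.
#' @return Cohen's d.
#' @seealso [d_to_r()]
#' @export
r_to_d <- function(r, case_fraction) {
  check_finite(r, "r")
  if (r < 0 || r >= 1)
    abort_domain("`r` must be in [0, 1); got %s", format(r))
  check_prob_open(case_fraction, "case_fraction")
  pq <- case_fraction * (1 - case_fraction)
  r / sqrt(pq * (1 - r^2))
}

#' Convert Cohen's d to a point-biserial correlation
#'
#' Inverse of [r_to_d()]: `r = d sqrt(P (1 - P)) / sqrt(1 + d^2 P (1 - P))`.
#'
#' @inheritParams r_to_d
#' @param d Cohen's d, non-negative.
#' @return Point-biserial correlation in `[0, 1)`.
#' @export
d_to_r <- function(d, case_fraction) {
  check_nonneg(d, "d")
  check_prob_open(case_fraction, "case_fraction")
  pq <- case_fraction * (1 - case_fraction)
  d * sqrt(pq) / sqrt(1 + d^2 * pq)
}

#' Convert an odds ratio per standard deviation to Cohen's d
#'
#' Uses the logistic-scale relation `d = ln(OR) * sqrt(3) / pi`, which treats
#' the log odds ratio per SD of the score as a standardized effect on a
#' logistic latent variable with variance pi^2 / 3.
#'
#' @param or_per_sd Odds ratio per standard deviation of the polygenic score,
#'   at least 1 (flip the score orientation if your OR is below 1).
#' @return Cohen's d.
#' @seealso [d_to_or_per_sd()]
#' @export
or_per_sd_to_d <- function(or_per_sd) {
  check_finite(or_per_sd, "or_per_sd")
  if (or_per_sd < 1)
    abort_domain(paste0("`or_per_sd` must be >= 1; got %s. If your score is ",
                        "protective (OR < 1), flip its orientation first."),
                 format(or_per_sd))
  log(or_per_sd) * sqrt(3) / pi
}

#' Convert Cohen's d to an odds ratio per standard deviation
#'
#' Inverse of [or_per_sd_to_d()]: `OR = exp(d * pi / sqrt(3))`.
#'
#' @param d Cohen's d, non-negative.
#' @return Odds ratio per SD, at least 1.
#' @export
d_to_or_per_sd <- function(d) {
  check_nonneg(d, "d")
  exp(d * pi / sqrt(3))
}

# Lee et al. (2012, Genet Epidemiol 36:214-224) constants for the
# observed/liability-scale R2 transformation under case-control ascertainment:
# threshold t = qnorm(1 - K), z = dnorm(t), mean case liability m = z / K.
lee_constants <- function(K, P) {
  t <- qnorm(1 - K)
  z <- dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  u <- m * (P - K) / (1 - K)
  theta <- u * (u - t)
  list(C = C, theta = theta)
}

#' Convert observed-scale R-squared to liability-scale R-squared
#'
#' Applies the Lee et al. transformation for a binary phenotype analysed as
#' 0/1 in a (possibly case-enriched) sample: with C and theta computed from the
#' population prevalence K and the sample case fraction P,
#' `R2_liab = C R2_obs / (1 + C theta R2_obs)`. When P = K (a representative
#' cohort) theta is 0 and the transformation reduces to the familiar
#' `R2_liab = R2_obs K(1-K) / phi(t)^2` with t the liability threshold
#' `qnorm(1 - K)`.
#'
#' @param r2_obs R-squared on the observed (0/1) scale, in `[0, 1)`.
#' @param K Population prevalence, in (0, 1).
#' @param P Case fraction of the sample the R-squared was estimated in, in
#'   (0, 1).
#' @return R-squared on the liability scale, in `[0, 1)`.
#' @references Lee SH, Goddard ME, Wray NR, Visscher PM (2012). A better
#'   coefficient of determination for genetic profile analysis. Genetic
#'   Epidemiology 36(3):214-224.
#' @export
r2_observed_to_liability <- function(r2_obs, K, P) {
  check_finite(r2_obs, "r2_obs")
  if (r2_obs < 0 || r2_obs >= 1)
    abort_domain("`r2_obs` must be in [0, 1); got %s", format(r2_obs))
  check_prob_open(K, "K")
  check_prob_open(P, "P")
  cc <- lee_constants(K, P)
  cc$C * r2_obs / (1 + cc$C * cc$theta * r2_obs)
}

#' Convert liability-scale R-squared to observed-scale R-squared
#'
#' Exact inverse of [r2_observed_to_liability()].
#'
#' @param r2_liab R-squared on the liability scale, in `[0, 1)`.
#' @inheritParams r2_observed_to_liability
#' @return R-squared on the observed (0/1) scale.
#' @export
r2_liability_to_observed <- function(r2_liab, K, P) {
  check_finite(r2_liab, "r2_liab")
  if (r2_liab < 0 || r2_liab >= 1)
    abort_domain("`r2_liab` must be in [0, 1); got %s", format(r2_liab))
  check_prob_open(K, "K")
  check_prob_open(P, "P")
  cc <- lee_constants(K, P)
  denom <- cc$C * (1 - cc$theta * r2_liab)
  if (denom <= 0)
    abort_domain("liability R2 %s is not attainable at K = %s, P = %s",
                 format(r2_liab), format(K), format(P))
  r2_liab / denom
}

#' Bundle a predictive-utility metric with its context
#'
#' A `metric_value` records one of the effect-size metrics accepted for binary
#' phenotypes, plus the prevalence / sampling-fraction context some
#' conversions need.
#'
#' @param metric One of `"auc"`, `"cohens_d"`, `"correlation"`, `"or_per_sd"`,
#'   `"r2_observed"`, `"r2_liability"`.
#' @param value The metric's numeric value.
#' @param prevalence Optional population prevalence K.
#' @param case_fraction Optional sampling case fraction P.
#' @return An object of class `metric_value`.
#' @export
metric_value <- function(metric, value, prevalence = NULL, case_fraction = NULL) {
  metrics <- c("auc", "cohens_d", "correlation", "or_per_sd",
               "r2_observed", "r2_liability")
  if (!is.character(metric) || length(metric) != 1L || !metric %in% metrics)
    abort_domain("`metric` must be one of: %s", paste(metrics, collapse = ", "))
  check_finite(value, "value")
  if (!is.null(prevalence)) check_prob_open(prevalence, "prevalence")
  if (!is.null(case_fraction)) check_prob_open(case_fraction, "case_fraction")
  structure(list(metric = metric, value = value,
                 prevalence = prevalence, case_fraction = case_fraction),
            class = "metric_value")
}

#' Convert any accepted binary-phenotype metric to Cohen's d
#'
#' Dispatches to the metric-specific converter. Correlations and observed- or
#' liability-scale R-squared require the sampling case fraction (and, for the
#' liability scale, the prevalence); a missing context is an error rather than
#' a silent default.
#'
#' @param m A [metric_value()].
#' @return Cohen's d.
#' @examples
#' any_metric_to_d(metric_value("auc", 0.67))
#' any_metric_to_d(metric_value("or_per_sd", 2))
#' @export
any_metric_to_d <- function(m) {
  if (!inherits(m, "metric_value"))
    abort_domain("`m` must be a metric_value object")
  need <- function(field, name) {
    if (is.null(m[[field]]))
      abort_domain("metric '%s' requires `%s` to convert to Cohen's d",
                   m$metric, name)
    m[[field]]
  }
  switch(m$metric,
    cohens_d = check_nonneg(m$value, "cohens_d"),
    auc = auc_to_d(m$value),
    or_per_sd = or_per_sd_to_d(m$value),
    correlation = r_to_d(m$value, need("case_fraction", "case_fraction")),
    r2_observed = {
      if (m$value < 0 || m$value >= 1)
        abort_domain("`r2_observed` must be in [0, 1)")
      r_to_d(sqrt(m$value), need("case_fraction", "case_fraction"))
    },
    r2_liability = {
      K <- need("prevalence", "prevalence")
      P <- need("case_fraction", "case_fraction")
      r2o <- r2_liability_to_observed(m$value, K, P)
      r_to_d(sqrt(r2o), P)
    }
  )
}
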