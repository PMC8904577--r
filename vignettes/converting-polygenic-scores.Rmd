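---
title: "Converting polygenic scores to the absolute scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting polygenic scores to the absolute scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsabs)
```

## The problem

A polygenic score summarizes an individual's burden of trait-associated
alleles. After standardization against an ancestry-matched reference (the
"polygenic Z-score"), it places the individual on a relative scale: a Z-score
of 1.96 means "higher than 97.5% of the reference population". That relative
statement is easy to compute and easy to misread, because it says nothing
about how likely the phenotype actually is. Absolute statements — "about 2.7%
of people with this score develop the disorder", "the expected IQ at this
score is 90.7, with a 95% prediction interval of 62.8–118.6" — are what
non-experts interpret correctly, and producing them normally requires
individual-level data with phenotype and score on the same people.

`pgsabs` produces them from summary statistics alone. The price is a pair of
parametric assumptions, stated below, which are also exactly the assumptions
under which the package's simulation module generates data — so the validation
machinery tests the implementation, not the assumptions.

## Binary phenotypes: the two-component mixture

Scores are approximately normal within any homogeneous group (they are sums
of many small allelic contributions), so the population score distribution
for a disease decomposes into a case component and a control component:

$$X \sim K\, N(\mu_{cas}, \sigma_w^2) + (1-K)\, N(\mu_{con}, \sigma_w^2),$$

with prevalence $K$ and standardized separation $d = (\mu_{cas} -
\mu_{con})/\sigma_w$ (Cohen's d). Requiring the mixture to have mean 0 and
variance 1 — which is what reference standardization enforces — pins every
parameter:

$$\sigma_w = \frac{1}{\sqrt{1 + K(1-K)d^2}}, \qquad
  \mu_{con} = -K d \sigma_w, \qquad \mu_{cas} = (1-K) d \sigma_w.$$

`build_binary_model()` applies these closed forms; the constructor's
invariants (mixture mean 0, variance 1, separation d) are tested exactly and
against Monte Carlo draws.

Absolute risk within a score interval $(a, b]$ is a Bayes update of the
prevalence:

$$P(\text{case} \mid X \in (a,b]) =
  \frac{K\,[\Phi_{cas}(b) - \Phi_{cas}(a)]}{F(b) - F(a)},$$

where $F$ is the mixture CDF. Equal-mass quantile boundaries of $F$ have no
closed form; `mixture_quantile()` brackets each root with `uniroot` on
$[\mu_{con} - 10, \mu_{cas} + 10]$ at absolute tolerance $10^{-12}$, which
keeps the CDF/quantile round-trip below $10^{-9}$ everywhere we test it and
cannot escape the bracket for any probability with $|\Phi^{-1}(q)| \le 8$.

Two assumptions deserve emphasis. First, *equal within-group variances*: a
single d parameter implies cases and controls differ only in location. Second,
the risk is a *lifetime* risk given the supplied prevalence; it does not
condition on age or on the risk period already survived.

## Continuous phenotypes: bivariate-normal conditioning

For a normally distributed trait the score and trait are taken jointly
normal with correlation $\rho = \sqrt{R^2}$ (the score explains $R^2$ of the
trait variance). Conditioning on a score quantile uses the closed-form
truncated standard-normal moments

$$E[X \mid a < X < b] = \frac{\varphi(a) - \varphi(b)}{\Phi(b) - \Phi(a)},
\qquad
\mathrm{Var}[X \mid a < X < b] = 1 +
  \frac{a\varphi(a) - b\varphi(b)}{\Phi(b) - \Phi(a)} - E^2,$$

with the infinite-bound terms dropping out in the tail cells (no clipping of
$\pm\infty$ is performed), and then the linear-conditional decomposition

$$E[Y \mid X \in (a,b)] = \mu + \rho\sigma\, E[X \mid \cdot], \qquad
\mathrm{Var}[Y \mid X \in (a,b)] = \sigma^2(1-\rho^2) +
  \rho^2\sigma^2 \mathrm{Var}[X \mid \cdot].$$

We compute these directly rather than through a multivariate truncated-moment
routine: the univariate closed form is exact, fast, and testable against
rejection sampling, which the suite does.

The score orientation is assumed positive (higher score, higher trait);
`build_continuous_model(..., negative_orientation = TRUE)` flips $\rho$. The
sex-stratified use case is pure re-parameterization — supply the
stratum's $(\mu, \sigma, R^2)$ — and a test asserts the code path is
identical.

## Effect-size metric conversions

Published score performance comes in several currencies. All are mapped to
Cohen's d:

* **AUC**: $d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$ (equal-variance binormal).
* **Point-biserial correlation** at sample case fraction $P$:
  $d = r / \sqrt{P(1-P)(1-r^2)}$. This is where the GWAS sampling ratio
  enters; a correlation estimated in a 50/50 case-control sample and one
  estimated in a population cohort imply different d.
* **Odds ratio per SD**: $d = \ln(\mathrm{OR})\sqrt{3}/\pi$, the standard
  logistic-latent-scale conversion.
* **Observed/liability-scale $R^2$**: the Lee et al. (2012) transformation
  with the full ascertainment correction; at $P = K$ it reduces to
  $R^2_{liab} = R^2_{obs}\,K(1-K)/\varphi(t)^2$ with threshold
  $t = \Phi^{-1}(1-K)$.

Each pair closes its round trip to $10^{-9}$ over a grid, each map is
strictly monotone, and the AUC↔d relation is checked against the empirical
Mann–Whitney AUC of simulated two-group data. AUC below 0.5 and OR below 1
are rejected with an instruction to flip the score orientation, rather than
silently reflected: a silent reflection can hide a miscoded allele.

## Tunable parameters

* `n_quantiles` — resolution of the equal-mass partition. Default 1000 for
  individual look-ups (fine enough that the within-cell mean is within 0.1%
  of σ of the point-conditional value across the central range, |z| ≲ 2.6)
  and 20 for tables and plots, where the eye cannot use more.
* `level` — prediction-interval coverage, default 0.95.
* `sd_method` in `individual_trait()` — the prediction interval uses the
  within-cell conditional SD by default; `"point"` gives the point-conditional
  SD $\sigma\sqrt{1-\rho^2}$. At 1000 cells the two differ negligibly (both
  reproduce the same worked-example interval to the printed precision); the
  within-cell form is the default because it is exactly consistent with the
  quantile partition being reported.
* Percentiles: for the binary model the percentile is taken from the mixture
  CDF, which is exact under the model; for the continuous model the marginal
  score distribution is exactly standard normal, so $\Phi(z)$ is used. For
  realistic d the two agree to one decimal (1.96 ↦ 97.5 either way).
* Boundary ties: an individual exactly on a quantile boundary is assigned to
  the lower cell (half-open cells $(b_{i-1}, b_i]$).

## The synthetic-data generator and what validation shows

`simulate_binary_cohort(K, auc, n, seed)` draws case status Bernoulli(K) and
then the score from the corresponding mixture component;
`simulate_continuous_cohort(mean, sd, r2, n, seed)` draws (score, trait)
bivariate normal. These are *exactly* the model's assumptions, which is the
point: `validate_binary()` / `validate_continuous()` then split the cohort
into equal-count score quantiles and compare observed case proportions (or
trait means and SDs) with the model's estimates, so any discrepancy beyond
sampling noise is an implementation defect. The binary generator also offers
`liability_mode = TRUE`, drawing status by thresholding a latent liability
correlated with the score so that the score–status correlation matches the
mixture-implied point-biserial value; its case/control score distributions
are then only approximately normal, which makes it a useful robustness probe.

What passing validation does **not** show: that real phenotypes satisfy the
assumptions. Real scores can be non-normal (few-variant scores built at
stringent p-value thresholds), real traits can be skewed (BMI-like traits
show inflated SD discrepancies for exactly this reason — the validation
summary reports the trait skewness so this is visible), case and control
score variances can differ, and the supplied prevalence or AUC can simply be
wrong for the target population. The misspecification direction is itself
tested: feeding the validator an inflated AUC inflates the estimated
top-quantile risk relative to the simulated truth.

Discrepancy summaries follow the validation-table conventions: for binary
phenotypes the mean absolute difference between observed and estimated
per-quantile case probability is reported both in percentage points
(`mean_abs_diff`) and relative to the estimate (`mean_abs_diff_rel`) — rare
phenotypes make the relative figure the informative one; for continuous
phenotypes both the mean and the SD discrepancies are relative percentages.
Skewness is the standardized third central moment.

## Problem sizes

The test suite uses cohorts of $10^4$–$4\times10^5$ for convergence checks,
$5\times10^4$ with 20 quantiles for the matched-parameter accuracy check, and
$10^7$-draw Monte Carlo oracles (fixed seeds) for the per-quantile agreement
checks at 3 standard errors. Root-finding at 1000 quantiles costs well under
a second.

## Known limitations

* Binary risks are lifetime risks at the supplied prevalence; no
  age-conditional or competing-risk adjustment.
* Continuous conversion assumes normality of the trait; transform skewed
  traits before use, or expect the per-quantile SDs to disagree.
* All outputs inherit the representativeness of the inputs: a prevalence or
  AUC estimated in one ancestry or demographic does not transfer to another.
* The r↔d and OR↔d conversions use the standard point-biserial and
  logistic-scale forms; both are isolated in single functions so an
  alternative convention can be swapped in without touching the models.
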