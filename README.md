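# pgsabs

Translate standardized polygenic scores onto the absolute scale using summary
statistics only.

A polygenic Z-score tells an individual where they sit on the score
distribution (e.g. "97.5th percentile"), but not what that means for their
phenotype. `pgsabs` converts that relative position into an absolute
statement — the probability of being affected for a binary phenotype, or the
expected trait value with a prediction interval for a normally distributed
phenotype — using nothing but population summary statistics: the phenotype
prevalence `K` and the predictive utility of the score (AUC or an equivalent
metric) for binary traits; the population mean, SD and the variance explained
`R²` for continuous traits. It is aimed at researchers, genetic counsellors
and curious score recipients who have a Z-score and published performance
metrics, but no individual-level validation data.

## The model

**Binary phenotypes.** The standardized score is modelled as a two-component
normal mixture: cases (weight `K`) and controls (weight `1 − K`), separated by
Cohen's `d` within-group SDs. Component parameters are fixed in closed form so
the mixture has mean 0 and variance 1:

    σ_w = 1 / √(1 + K(1−K)d²),  μ_con = −K·d·σ_w,  μ_cas = (1−K)·d·σ_w

Mixture quantiles are located by bracketed root-finding on the mixture CDF
`F(x) = K·Φ((x−μ_cas)/σ_w) + (1−K)·Φ((x−μ_con)/σ_w)`, and the case
probability within a score interval `(a, b]` follows from Bayes' rule:
`P(case | X ∈ (a,b]) = K·(Φ_cas(b) − Φ_cas(a)) / (F(b) − F(a))`.

**Continuous phenotypes.** The score `X ~ N(0,1)` and trait
`Y ~ N(μ, σ²)` are bivariate normal with correlation `ρ = √R²`, so within a
score quantile `(a, b)`:

    E[Y | X ∈ (a,b)] = μ + ρσ·E[X | X ∈ (a,b)]
    Var[Y | X ∈ (a,b)] = σ²(1−ρ²) + ρ²σ²·Var[X | X ∈ (a,b)]

with the truncated standard-normal moments computed in closed form.

**Metric conversions.** Cohen's `d` is the hub: `AUC = Φ(d/√2)`,
`d = r / √(P(1−P)(1−r²))` for a point-biserial correlation estimated at case
fraction `P`, `d = ln(OR_SD)·√3/π` for an odds ratio per SD, and the
Lee et al. transformation links observed- and liability-scale `R²`.

## Worked example

Schizophrenia-like binary phenotype: prevalence 1%, polygenic score AUC 0.67,
individual Z-score 1.96:

```r
library(pgsabs)
model <- build_binary_model(K = 0.01, d = auc_to_d(0.67))
individual_risk(model, z = 1.96)
#> Polygenic Z-score 1.960: percentile 97.5
#> Absolute risk (quantile 975 of 1000): 2.7%
```

Being in the top 2.5% of scores raises the lifetime risk from the 1%
population baseline to only about 2.7% — the absolute scale makes the modest
discriminative power of the score explicit.

IQ-like continuous phenotype: mean 100, SD 15, score `R²` = 10%, Z-score
−1.96:

```r
model <- build_continuous_model(mean = 100, sd = 15, r2 = 0.10)
individual_trait(model, z = -1.96)
#> Polygenic Z-score -1.960: percentile 2.5
#> Predicted trait value (quantile 25 of 1000): 90.7
#> 95% prediction interval: 62.8 to 118.6
```

The same computations are available from a shell via the bundled CLI
(installed at `inst/cli/pgsabs`):

```sh
Rscript inst/cli/pgsabs binary --prevalence 0.01 --auc 0.67 --z 1.96
Rscript inst/cli/pgsabs continuous --mean 100 --sd 15 --r2 0.10 --z -1.96
Rscript inst/cli/pgsabs convert --from or_per_sd --to auc --value 2
Rscript inst/cli/pgsabs validate --mode binary --prevalence 0.1 --auc 0.6 \
    --n 50000 --seed 1
```

Validation without external data: `simulate_binary_cohort()` /
`simulate_continuous_cohort()` generate cohorts with exactly the assumed
statistical structure, and `validate_binary()` / `validate_continuous()`
compare observed per-quantile case proportions (or trait means and SDs)
against the model's estimates.

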