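# iepfit

Likelihood and Bayes inference for the two-parameter **Inverse Exponential
Power (IEP)** distribution, a heavy-tailed lifetime model for strictly
positive data.  If `X` follows the exponential power law, `1/X` is IEP;
the distribution function is

    F(x; α, λ) = exp{ 1 − exp[(λ/x)^α] },   x > 0,  α, λ > 0,

with density
`f(x) = (α/λ)(λ/x)^(α+1) exp[(λ/x)^α] exp{1 − exp[(λ/x)^α]}` and an
inverted-bathtub or J-shaped hazard.  The package is aimed at
biostatisticians and reliability analysts who want to fit this family to
positive right-skewed rates — the worked application is modelling the
cumulative COVID-19 case fatality rate (CFR, in percent, one value per
country) across WHO regions and the OECD, samples of which are bundled.

## What it provides

* **Distribution core** — `diep`, `piep`, `qiep`, `riep`, `hiep`, all
  routed through log/`expm1`-stable forms (the naive density overflows for
  `x ≪ λ`), with a closed-form quantile
  `λ [log(1 − log u)]^(−1/α)` used for inverse-transform sampling.
* **Maximum likelihood** — `iep_mle`: safeguarded Newton–Raphson on the
  analytic score in `(log α, log λ)`, with a Nelder–Mead rescue path;
  observed Fisher information (`iep_observed_info`), Wald intervals
  (`confint`) and parametric percentile-bootstrap intervals
  (`iep_boot_ci`).  All second- and third-order log-likelihood partials
  are available in closed form via `iep_derivs`.
* **Bayes estimators under squared-error loss**, with independent gamma
  priors (`iep_prior`): Lindley's approximation (`iep_lindley`), the
  Tierney–Kadane Laplace approximation (`iep_tk`), random-walk
  Metropolis–Hastings on the log scale (`iep_mh` / `iep_sel_estimate`),
  and a 2-D Gauss–Legendre quadrature posterior mean
  (`iep_posterior_mean_quad`) serving as the numerical gold standard.
* **Monte Carlo harness** — `iep_bias_mse_study` (average, mean absolute
  error, signed bias, MSE per estimator × sample size) and
  `iep_coverage_study` (Wald and percentile-bootstrap coverage and
  lengths), both bit-reproducible from a master seed.
* **Goodness of fit** — `iep_ks_test` (asymptotic Kolmogorov series by
  default; exact finite-`n` Marsaglia matrix-power distribution via
  `exact = TRUE`), plus `iep_ecdf_curve`/`iep_cdf_curve` for
  empirical-vs-fitted CDF overlays.
* **Data** — `iep_region("AFR" | "EMR" | "EUR" | "AMR" | "SEAR" | "WPR" |
  "OECD")` returns the bundled CFR samples; `read_sample` reads
  single-column files (comma-decimal input supported).
* **CLI** — a thin `Rscript` front end in `exec/iepfit`
  (`fit`, `gof`, `simulate`, `data` subcommands).

## Worked example

```r
library(iepfit)

x <- iep_region("AFR")$cfr          # 42 country-level CFR values, percent
fit <- iep_mle(x)
fit
#> Inverse Exponential Power fit (n = 42 )
#>   alpha  = 0.9993  (se 0.1157)
#>   lambda = 0.6609  (se 0.0645)
#>   log-likelihood = -62.9804  [newton, 6 iterations]

iep_ks_test(x, coef(fit)[1], coef(fit)[2])
#> One-sample Kolmogorov-Smirnov vs fitted IEP: D = 0.1810, p = 0.1274 (n = 42, asymptotic)

iep_lindley(x)                       # Bayes, Lindley approximation
#>     alpha    lambda
#> 0.9634924 0.6692081
iep_tk(x)                            # Bayes, Tierney-Kadane
#>     alpha    lambda
#> 0.9645094 0.6694869
iep_posterior_mean_quad(x)           # quadrature gold standard
#>     alpha    lambda
#> 0.9645809 0.6696214
```

The MLE says the African-region CFR sample is compatible with an IEP law
with exponent essentially 1 and scale 0.66%; the K-S test does not reject
the fit (p ≈ 0.13).  Under the default informative priors
(`alpha ~ Gamma(1, 2)`, `lambda ~ Gamma(2, 1)`, prior means 0.5 and 2) the
posterior mean pulls `alpha` down and `lambda` up, and the Tierney–Kadane
value agrees with the exact (quadrature) posterior mean to four decimals,
as its `O(n⁻²)` error predicts; Lindley's `O(n⁻¹)` approximation is
slightly farther off.

A small simulation comparison:

```r
iep_bias_mse_study(c(2, 2), n_grid = 50, n_reps = 200,
                   methods = c("mle", "tk"), seed = 1)[, 1:8]
#>   method  n parameter truth  average       bias  signed_bias         mse
#> 1    mle 50     alpha     2 2.052016 0.19498980  0.052015530 0.061555586
#> 2    mle 50    lambda     2 2.007289 0.06695967  0.007288804 0.007090922
#> 3     tk 50     alpha     2 1.930898 0.18372997 -0.069102435 0.051167784
#> 4     tk 50    lambda     2 2.003700 0.06653546  0.003700130 0.006943056
```

Bias here is the mean *absolute* error; the Bayes estimator trades a
little shrinkage bias for a lower MSE at small `n`.

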