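---
title: "The paired t-test as a latent change score model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The paired t-test as a latent change score model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedlcs)
```

## The model family

Two repeated continuous measurements per subject — a baseline $Y_1$ and a
follow-up $Y_2$ in the same units (the motivating setting is glycated
haemoglobin, HgA1c %, measured before and after a care intervention) — carry
five sample moments: two means, two variances and one covariance. Every model
in this package is a structural model for exactly those five moments.

The change score is inserted as a latent variable rather than a computed
column: the structural equation

$$Y_2 = 0 + 1 \cdot Y_1 + 1 \cdot \mathrm{LCS}_{21} + 0$$

fixes both loadings to unity, the $Y_2$ intercept to zero and the $Y_2$
residual (mean and variance) to zero, so the latent variable *is*
$Y_2 - Y_1$, the true change. The family then differs only in how change
relates to the baseline level:

* **Correlated specification** (`fit_lcs_correlated()`): $Y_1$ and
  $\mathrm{LCS}_{21}$ covary freely. Five free parameters
  $(\mu_1, \mu_\Delta, \sigma_1^2, \sigma_\Delta^2, \sigma_{1\Delta})$,
  zero degrees of freedom. The ML estimate of the change mean is the sample
  mean difference $\bar d$ and its standard error is $s_D/\sqrt{n}$ — the
  classical paired t-test quantities exactly. Only the reference distribution
  differs: the critical ratio $\bar d / SE$ is referred to the standard
  normal (the SEM convention), where the classical test uses $t_{n-1}$.
* **Self-feedback specification** (`fit_lcs_sfm()`): a directed path
  $\gamma$ regresses the change on the baseline,
  $\mathrm{LCS}_{21} = \alpha + \gamma Y_1 + \zeta$. Still saturated, but the
  intercept test now conditions on baseline: with the waves centered on the
  wave-1 mean, $\hat\alpha = \bar d$ while
  $SE(\hat\alpha) = \sqrt{\hat\psi/n}$ with
  $\hat\psi = s_D^2 (1 - r^2_{Y_1 D})$, so the SE shrinks by
  $\sqrt{1 - r^2}$, where $r_{Y_1 D}$ is the baseline–difference
  correlation. The closed forms are $\hat\gamma = \mathrm{cov}(Y_1, D)/
  \mathrm{var}(Y_1)$ (the regression-to-the-mean slope) and, uncentred,
  $\hat\alpha = \bar d - \hat\gamma \bar y_1$.
* **No-self-feedback constraint** (`fit_lcs_no_sfm()`): $\gamma = 0$, one
  degree of freedom. Its chi-square is the likelihood-ratio statistic of
  "change is unrelated to where one started", with closed form
  $-(n-1)\log(1 - r^2_{Y_1 D})$ under the default scale. Against the
  saturated model the difference test (`chisq_diff_test()`) on 1 df equals
  this chi-square.
* **Lagged autoregressive model** (`fit_ar_lagged()`):
  $Y_2 = c + \beta Y_1 + e$. The same model as the self-feedback form in
  different coordinates, with $\beta = 1 + \gamma$ identically; the package
  asserts this reparameterization identity numerically to $10^{-10}$. The
  standardized stability $\beta \, sd_1/sd_2$ is reported separately: the
  textbook statement that $|\gamma|$ is the complement $1-\rho$ of the
  stability holds exactly only in unstandardized form, or when the two wave
  SDs are equal, so the package never claims it in general.

## Estimation

All fitting is maximum likelihood on the mean-and-covariance structure. The
discrepancy between sample moments $(\bar m, S)$ and implied moments
$(\mu(\theta), \Sigma(\theta))$ is

$$F(\theta) = \log|\Sigma| - \log|S| + \operatorname{tr}(S\Sigma^{-1}) - 2 +
  (\bar m - \mu)^\top \Sigma^{-1} (\bar m - \mu),$$

minimized by BFGS with variance parameters log-transformed to stay positive,
convergence tolerance $10^{-10}$ on $F$, and up to five deterministically
jittered restarts. Starting values are moment-based and are in fact the
analytic ML solutions for every model in this family; the optimizer verifies
them and is kept only when it genuinely improves the fit, so reported
estimates carry no search round-off. Standard errors are square roots of the
diagonal of the inverse observed information of the ML log-likelihood
(multiplier $n$), computed with a central-difference Hessian (relative step
$10^{-5}$) at the optimum.

### Conventions

Three conventions are configurable and always serialized with results:

* **Moment denominator** — default $n-1$ (unbiased); $n$ behind a flag. The
  default is what makes the latent-change SE of the mean change equal the
  classical paired-test SE exactly.
* **Chi-square scale** — default $(n-1) F_{\min}$; $n F_{\min}$ behind a
  flag. The default pairs with the denominator convention above and is the
  convention of the commercial SEM software whose output these models
  replicate.
* **Reference distribution** — critical ratios are always referred to the
  standard normal, two-sided. This is deliberate and is the entire source of
  the p-value difference between the classical test ($p_t$) and its SEM twin
  ($p_z < p_t$ for any nonzero statistic): same estimate, same SE, heavier
  t tails.

Degenerate inputs are refused with specific errors: fewer than 3 complete
pairs (the change regression then has no residual df), a zero-variance wave,
a zero-variance difference score (uniform change), and exactly collinear
waves (singular sample covariance). Incomplete rows are dropped listwise with
a warning and a count in the report; full-information ML for missing data is
out of scope.

## Summary-statistics sensitivity analysis

Published pre–post comparisons often report only per-wave means and SDs.
The paired correlation $\rho$, which determines the difference-score
variance $\sigma_D^2 = \sigma_1^2 + \sigma_2^2 - 2\rho\sigma_1\sigma_2$ and
hence every SE, must then be assumed. `rho_sweep()` rebuilds the moment
summary for each $\rho$ on a grid (default 0.00–0.95 in steps of 0.05, a
deliberately coarse sweep of plausible test–retest correlations) and records
the p-values of both the classical test and the self-feedback intercept test.
The threshold $\rho^*$ where each curve first crosses the significance level
is then refined by bisection between the bracketing grid points to
$|\Delta\rho| < 10^{-4}$. For the worked synthetic design shipped with the
package ($n = 24$, means 0 and $-0.3$, unit SDs, $\alpha = 0.05$) the
classical threshold has the closed form
$\rho^* = 1 - n(\bar d/t_{crit})^2 / (2\sigma^2) = 0.7476$, which the
bisection reproduces to $10^{-3}$; the self-feedback test flips earlier
(near $\rho = 0.66$) because its SE is smaller at every $\rho$. The external
study that motivated this design reports no variances, so its exact threshold
is not a reproducible quantity; the package treats the behaviour
qualitatively and ships no third-party numbers.

Because every fit depends on the data only through $(n, \bar m, S)$, the
sweep's p-values are identical to those from any raw dataset possessing
exactly those moments; `paired_from_moments()` constructs such datasets
(empirically whitened and recoloured normal draws) and the test suite
asserts the sufficiency property to $10^{-10}$.

## The synthetic-data generator

`sim_design()` + `generate_paired()` draw bivariate-normal paired samples by
applying the Cholesky factor of the $2\times 2$ covariance to independent
standard normals. Defaults emulate the HgA1c regime of the worked example:
wave SDs 1.3, correlation 0.57, and (for alternative-hypothesis designs) a
small negative mean change of a few tenths of a unit. Reproducibility is by
derived substreams: replication $k$ under master seed $s$ seeds R's
Mersenne–Twister with a fixed integer function of $(s, k)$ kept below
$2^{31}$, so replications are bit-reproducible individually, in any order,
and without disturbing the caller's RNG state.

What the generator deliberately does *not* emulate: non-normal (skewed or
heavy-tailed) outcomes, floor/ceiling effects of bounded clinical scales,
measurement error distinct from occasion-specific variance, and more than
two waves. Passing Monte-Carlo calibration here therefore demonstrates
correctness of the estimators and their equivalences under bivariate
normality, not robustness of the paired t-test family to real-data
pathologies.

### Study sizes

The packaged studies use sizes chosen to give comfortable Monte-Carlo
resolution while keeping the default suite quick to run: the
equivalence suite spans 200 datasets with $n \in [5, 500]$ and
$\rho \in (-0.9, 0.9)$ (the estimator identity is algebraic, so any
discrepancy above $10^{-8}$ would indicate a coding error, not noise);
type-I calibration uses 5000 null replications at $n = 100$, giving a
three-sigma binomial band of $\pm 0.0092$ around the nominal 0.05; parameter
recovery uses 1000 replications at $n = 500$. The observed behaviour: the
classical test sits inside its band, while the self-feedback intercept test
rejects somewhat more often under the null — the price of its pointwise
smaller p-values ($p_{sfm} \le p_t$ always, by SE shrinkage plus the normal
reference), which the package reports rather than hides.

## Design choices that were genuinely open

* **Monte-Carlo fast path.** `run_error_rate_study()` evaluates the test
  statistics from the sample moments via the closed-form ML estimators
  instead of calling the numerical optimizer thousands of times. The test
  suite separately asserts engine/closed-form agreement across hundreds of
  datasets, so the fast path is the same estimator, merely cheaper.
* **Significance machinery for the self-feedback test** is the intercept
  Wald test (CR against the normal), matching how SEM software reports it; a
  likelihood-ratio test of $\alpha = 0$ would be asymptotically equivalent
  but would not reproduce the printed critical ratios.
* **Thresholds that never cross** are reported as absent (`NA`/JSON null),
  never as zero — a zero threshold would mean "significant at $\rho = 0$",
  which is a different claim.
* **Verdicts are advisory.** The chi-square difference verdict string uses a
  configurable $\alpha$ (default 0.05) but never gates any computation.

## Known limitations

Two waves only; single group; no covariates or predictors of change beyond
the baseline itself; no mixture/latent-class extensions; listwise deletion
rather than FIML; normal-theory ML only (no robust or weighted least
squares). These mirror the boundary of what the two-wave moment structure
identifies and keep the package a faithful, minimal account of the paired
t-test's SEM reformulation.
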