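---
title: "The GIVE statistic: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GIVE statistic: model, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(givestat)
```

## The model and the statistic

`givestat` works with the linear model

$$ y = X\beta + u, \qquad E(u) = 0, \qquad E(uu') = \sigma^2 \Omega^{-1}, $$

where $X$ is $n \times (p+1)$ with a leading intercept column, the errors are
allowed to be non-spherical ($\Omega$ positive definite, known, assumed
identity, or estimated), and $X$ may be correlated with $u$ in finite samples
— the IV setting. A same-width instrument matrix
$Z = (Z_0, Z_1, \dots, Z_p)$ ($Z_0$ the intercept's own column of ones) is
assumed correlated with $X$ and uncorrelated with $u$ in the limit:
$Z'u/n \to 0$, $Z'X/n \to \Sigma_{ZX} > 0$.

Estimation is two-stage feasible GLS. The first stage regresses $X$ on $Z$
under $\hat\Omega$, $\hat\alpha = (Z'\hat\Omega Z)^{-1} Z'\hat\Omega X$; the
second stage applies the quasi-projection
$P = Z (Z'\hat\Omega Z)^{-1} Z'$ to give

$$ \hat\beta_{IV}(\hat\Omega) = (X'PX)^{-1} X'Py, \qquad
   \hat u = y - PX\hat\beta . $$

The GIVE statistic is the IV analogue of the coefficient of determination,
defined through the centered decomposition of $y'P_I y$
($P_I = I - ee'/n$):

$$ G^2_{IV}(\hat\Omega)
   = \frac{\hat\beta' X'P\,P_I\,PX\hat\beta + 2\,\hat\beta'X'P\,P_I\,\hat u}
          {y'P_I y}
   = 1 - \frac{\hat u' P_I \hat u}{y' P_I y}. $$

The two forms are algebraically identical because $y = PX\hat\beta + \hat u$
by construction; `give_statistic()` evaluates both and enforces agreement to
$10^{-9}$ relative as a self-check. With $Z = X$ and $\Omega = I$, $P$ is the
hat matrix of $X$, the fit is OLS, residuals sum to zero, and $G^2$ equals the
classical $R^2$ exactly.

Unlike $R^2$, an IV $G^2$ can leave $[0,1]$ in finite samples (the
regression cross-term $2\hat\beta'X'P P_I \hat u$ is not constrained in
sign). The package reports the raw value with an `out_of_range` flag and never
clips: excursions outside $[0,1]$ are diagnostic of a poorly chosen
instrument set, and clipping would hide exactly the pathology the statistic
exists to reveal.

## Grouping instruments

Three classical constructions turn a regressor $x$ into an instrument that
depends on $x$ only through its ordering (which is what breaks the link with
additive measurement error in $x$):

* **Wald**: $-1$ for observations $\le$ the median, $+1$ above. The tie rule
  (equal-to-median goes to $-1$) is a deterministic convention; in small
  samples the opposite rule changes the split and hence $G^2$ slightly.
* **Durbin**: the ranks $1..n$, average ranks for ties (preserves the rank
  sum $n(n+1)/2$).
* **Bartlett**: sort, code the lowest $\lceil n/3\rceil$ as $-1$, the highest
  $\lceil n/3\rceil$ as $+1$, the middle as $0$; ties broken by original
  index. This is the classical three-group construction; the tercile sizes
  are a convention since only the extreme groups carry identification.

All three are invariant to adding a constant to $x$, and Wald/Durbin/Bartlett
group assignments are invariant to any strictly increasing transform.
Generated instruments are never applied to the intercept column.

## Conventions for $\Omega$ and the projection operator

Two points deserve care, and both are exposed rather than hidden:

**The printed operator.** The projection is implemented as
$P = Z(Z'\hat\Omega Z)^{-1}Z'$ — symmetric, satisfying $P\Omega P = P$, and
reducing to the 2SLS hat matrix at $\Omega = I$ — even though the first-stage
fitted values $\hat X = Z\hat\alpha = Z(Z'\hat\Omega Z)^{-1}Z'\hat\Omega X$
carry a trailing $\hat\Omega$. The trailing-$\Omega$ operator is available as
`quasi_projection(..., variant = "omega_weighted")` and
`iv_fit(..., projection = "omega_weighted")`; the two coincide at
$\Omega = I$, which covers every simulation design in the package.

**Scale of $\Omega$.** $\Omega$ is identified only up to a positive scalar
($\sigma^2$ absorbs it), and $\hat\beta$ is invariant to that scalar. Under
the printed operator, however, fitted values $PX\hat\beta$ are *not*: scaling
$\Omega$ by $c$ scales them by $1/c$. The feasible diagonal estimator
`estimate_omega()` (one FGLS iteration: first-stage squared residuals averaged
across columns, linearly smoothed against $Z$, floored at 5% of their mean,
inverted) therefore normalizes to $\mathrm{tr}(\hat\Omega) = n$, so a
homoskedastic sample yields $\hat\Omega \approx I$ and residuals stay on the
scale of the data. Users supplying a known full $\Omega$ should adopt the same
normalization if they intend to interpret fitted values or $G^2$. No claim is
made that this feasible estimator is optimal; it exists so the feasible-GLS
path is exercised end to end.

Linear systems are solved by factorization with an `rcond` guard
($< 10^{-12}$ raises a rank/identification error); no ridge regularization is
ever applied silently, because a quietly regularized fit would corrupt
comparisons of $G^2$ across instrument sets.

## Population targets and the oracle

The population target of $G^2$ is
$\theta_{IV}(\Omega) = \beta'\Sigma\beta / (\beta'\Sigma\beta + \sigma^2)$
with $\Sigma = \Sigma_{XZ}\Sigma_{Z\Omega Z}^{-1}\Sigma_{ZX}$. A subtlety
matters whenever the instruments do not span the regressors in the limit
(every grouping instrument is in this class): the residual
$\hat u = y - PX\hat\beta$ then retains the un-projected signal
$(I-P)X\beta$, so

$$ G^2 \;\longrightarrow\;
   \frac{\beta'\Sigma\beta}{\beta'\Sigma_{XX}\beta + \sigma^2}
   \;\le\;
   \frac{\beta'\Sigma\beta}{\beta'\Sigma\beta + \sigma^2} = \theta_{IV}, $$

with equality exactly when $\Sigma = \Sigma_{XX}$ (e.g. $Z = X$). The two
denominators differ by $\beta'(\Sigma_{XX}-\Sigma)\beta$ — precisely the
signal the instrument span misses, which the fit books as error variance.

`population_theta_oracle()` therefore offers both conventions. The default,
`sigma2 = "estimated"`, plugs the large-draw *estimated* residual variance
into the formula; since that estimate converges to
$\beta'(\Sigma_{XX}-\Sigma)\beta + \sigma^2$, the default oracle returns the
statistic's own large-sample value, which is the right reference when judging
the *estimator* (bias and MSE must be measured against what the statistic can
converge to). `sigma2 = "true"` uses the design's true error variance and
returns the literal $\theta_{IV}$ formula (which is $1$ in the noiseless
limit, as the definition requires). The gap between the two conventions is
itself a useful instrument-quality summary: Wald instruments leave a visibly
larger gap than Durbin ranks.

## Monte-Carlo designs

Both study designs fix the published conditions as defaults and use
$\Omega = I$:

* **Regression design** (`mlr_sim_config`): $n \in \{50, 100, 200\}$,
  $p = 5$ (or 9), $\sigma^2 \in \{1.5, 2.5, 3.5, 4.5, 5\}$, unit
  coefficients, intercept $1$. Regressors follow a one-factor Gaussian model
  $x_j = \lambda f + \sqrt{1-\lambda^2}\,e_j$ with loading $\lambda = 0.7$,
  giving unit variances, pairwise correlation $0.49$, and a high population
  multiple correlation with the response (e.g. $\theta \approx 0.86$ at
  $p = 5$, $\sigma^2 = 2.5$) — the stated regime of the study. The loading is
  a config knob.
* **Measurement-error design** (`me_sim_config`): latent $T$ from the same
  factor model, $\eta = \alpha e + T\beta$, observed $y = \eta + \epsilon$
  ($\sigma^2_\epsilon = 0.5$) and $X = T + \Delta$ with
  $\sigma^2_\delta \in \{1.5, \dots, 5\}$, $\epsilon \perp \Delta$. (In the
  published design description the varying variance is listed under a
  clashing symbol; it is resolved here as the regressor measurement-error
  variance $\sigma^2_\delta$, holding $\sigma^2_\epsilon = 0.5$, which is the
  only reading consistent with the stated generator.)

Summaries are the empirical relative bias
$RB = (\bar G^2 - \theta)/\theta$ and relative MSE
$RM = \overline{(G^2-\theta)^2}/\theta^2$ (so $RM \ge RB^2$); the published
account defers the exact formulas to supplementary material, and these
ratio-to-target definitions are what "relative" conventionally means. The
reference $\theta$ differs by design, deliberately:

* the regression design uses the method-specific self-consistent oracle
  (the statistic's own probability limit, above), so $RB, RM \to 0$ and the
  bias/precision ranking of instrument methods is meaningful;
* the measurement-error design uses the analytic latent-model value
  $\theta = \beta'\Sigma_T\beta/(\beta'\Sigma_T\beta + \sigma^2_\epsilon)$,
  because the question there is how far contamination pulls the fit below the
  error-free model — this is what makes "both methods are negatively biased"
  a well-defined, reproducible statement.

Seed discipline: a master seed generates a stream of per-replicate sub-seeds
(`sample.int` under the master), so every replicate is individually
reproducible, grids are embarrassingly parallel, and the whole summary is
bit-reproducible. Replicate-level fit failures are counted per cell and
reported, never silently dropped. Within each replicate both instrument
methods are built from the *same* draw, so method comparisons are paired.

What the generators do *not* emulate: real data have non-Gaussian tails,
heteroskedasticity, discrete and bounded regressors, and instruments whose
exogeneity is an assumption rather than a construction. Passing the
simulation-based tests shows the machinery is correct under the stated
Gaussian factor designs, not that grouping instruments are valid in any
particular application.

## The standardized statistic, as published

The asymptotic standardization is implemented exactly as published:

$$ T = \sqrt{n}\,\left[\nabla g(a)' V \nabla g(a)\right]_{a=\hat\beta_{IV}}
       \left(G^2_{IV} - \theta_{IV}\right), \qquad
   V = (X'PX)^{-1}(X'P\Omega PX)(X'PX)^{-T}, $$

with $g(a)$ the scalar map whose value at the estimate is the statistic
itself, differentiated by central differences (per-coordinate step
$h_j = 10^{-6}\max(1, |a_j|)$; the step-halving error contracts at the
expected second order), and the unobservable $u$ replaced by $\hat u$ at
evaluation. With the symmetric printed operator the sandwich collapses
algebraically to $V = (X'PX)^{-1}$; the three-factor product is computed as
written and the collapse is used as a cross-check. The $\Omega = I$
special case is the same formula with the identity covariance and agrees with
the general path bitwise.

**Caveat, stated plainly.** Because $V$ is built from un-normalized
cross-products, $X'PX = O(n)$ and the multiplicative factor
$\nabla g' V \nabla g$ is $O(1/n)$, while $G^2 - \theta_{IV} = O(n^{-1/2})$;
the product is $O(1/n)$ and *degenerates to zero* rather than converging to
$N(0,1)$. Empirically at $n = 1000$ the spread of $T$ is of order $10^{-4}$.
The published statement multiplies by the variance factor where a delta-method
standardization would divide by its square root; the form is kept as printed
(it is what the package documents and tests), and the distributional
acceptance check against $N(0,1)$ honestly fails. A studentized variant
$(G^2-\theta)/\sqrt{\hat\sigma^2\,\nabla g'V\nabla g}$ captures the scale of
the $\hat\beta$-channel fluctuations of $G^2$ reasonably well, but is still
not $N(0,1)$ — the residual channel of $G^2$'s variability and the
target-limit gap discussed above are outside $V$ — so the package does not
advertise any alternative as correctly calibrated. Users should treat $G^2$
as a descriptive ranking criterion, which is how the comparison API presents
it (no multiplicity adjustment: ranking, not testing).

## Applications and fixtures

The two bundled generators, `make_covid_fixture()` (country-level COVID-19
mortality vs a latent-tuberculosis proxy, with BCG-vaccination history, WHO
region and elderly share as drivers; the true `lntb10` effect on mortality is
negative) and `make_card_fixture()` (log wages, endogenous schooling with a
latent-ability confounder, college-proximity indicators), are **synthetic**
schema-matched stand-ins so every analysis code path runs without the
original external datasets. They reproduce structure, not published numbers.
In the original country-level analysis the model specification is ambiguous
about which covariates sit in $X$ versus $Z$; the package therefore takes the
endogenous set and the instrument mapping explicitly (CLI `--endog` /
`--instruments`), and the WHO region code is used numerically 1–6 as defined
(an indicator-expansion is left to the user's preprocessing).

## Problem sizes used in the test suite

The bundled checks run the designs at 100-replicate to 2000-replicate scale:
identity and reduction properties on 100 random instances; consistency at
$n = 5000$ over 200 replicates; convergence of $G^2$ to its target over
$n \in \{50, 200, 1000, 5000\}$ at 500 replicates; the full
$\{50,100,200\}\times\{1.5,\dots,5\}$ grids at 500 replicates; the
standardized statistic at $n = 1000$ over 2000 replicates. These sizes give
Monte-Carlo standard errors comfortably below the effect sizes being asserted
while keeping the whole suite in the low minutes on one CPU.

## Known limitations

* Only same-width instrument sets (just-identified in the column-count
  sense) are supported; over-identification, weak-instrument F statistics and
  instrument selection are out of scope.
* No standard errors for $\hat\beta$ are reported — the inferential object
  here is the fit statistic, not the coefficients.
* The feasible $\Omega$ estimator is a simple diagonal one-step smoother;
  serially correlated errors need a user-supplied full $\Omega$.
* The standardized statistic is provided as published and is not a usable
  test statistic (see the caveat above).
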