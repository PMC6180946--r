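---
title: "Single-model mediation analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-model mediation analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcmed)
```

## The model and the estimator

For a continuous outcome $Y$, exposures $X$ (entering through a basis
$h(X)$), mediators $M$, and confounders $C$, the package works with the
pair of linear models

$$
\mathrm{E}[Y \mid X, M, C] = \beta_0 + h(X)\beta_X + M\beta_M + C\beta_C,
\qquad
\mathrm{E}[Y \mid X, C] = \beta_0^* + h(X)\beta_X^* + C\beta_C^*,
$$

and the inferential target is the vector of changes in the
exposure-pathway coefficients, $\Delta = \beta_X^* - \beta_X$ (the
essential mediation components). Only the **full** model is ever fit.
With $\hat\beta$ asymptotically multivariate normal with covariance
$\Sigma$, partition the coefficients and $\Sigma$ into the
exposure-pathway block and the mediator block; conditioning the
exposure-block estimate on $\hat\beta_M = 0$ yields the closed forms

$$
\hat\Delta = -V_{XM} V_M^{-1} \hat\beta_M,
\qquad
\widehat{\mathrm{Cov}}(\hat\Delta \mid X, M) = V_{XM} V_M^{-1} V_{MX}.
$$

Algebraically, $-V_{XM}V_M^{-1}$ equals the matrix of regression
coefficients of the (residualized) mediator columns on the
(residualized) exposure columns, so $\hat\Delta$ coincides *exactly*,
in every finite sample, with the coefficient difference obtained by
also fitting the marginal model — the Frisch–Waugh–Lovell partitioned
regression identity. The test suite exercises this identity across
simple, polynomial, multi-mediator, and interaction designs at
tolerance $10^{-8}$; it is the package's core oracle.

Mediation effects are linear functionals of $\Delta$. For a contrast
$(x, x^*)$,

$$
\mathrm{PE}(x, x^*) = [h(x) - h(x^*)]\,\Delta,
\qquad
\widehat{\mathrm{Var}} = [h(x)-h(x^*)]\,V_{XM}V_M^{-1}V_{MX}\,[h(x)-h(x^*)]',
$$

with a symmetric two-sided $t$ interval on $n - k$ degrees of freedom
($k$ the number of full-model columns). Without an exposure–mediator
interaction the portion eliminated equals the natural indirect effect;
the decomposition reported by `decompose_effects()` is

* TE from the *fitted* marginal model (exposure-pathway and confounder
  columns only) — not as NDE + NIE. When an exposure–mediator
  interaction is present the two can differ; the report carries the
  discrepancy $|\mathrm{TE}_{\text{fitted}} - (\mathrm{NDE} +
  \mathrm{NIE}_{\text{mediation formula}})|$ as a diagnostic.
* $\mathrm{CDE}(m) = [h(x)-h(x^*)]\hat\beta_X + m\,\hat\beta_{XM}(x-x^*)$,
  with $m$ defaulting to the sample mean of the interacting mediator.
* $\mathrm{NDE}$: the same expression with $m$ replaced by
  $\hat{\mathrm{E}}[M \mid x^*]$ from an internally fitted linear
  mediator model.
* $\mathrm{PE} = \mathrm{TE} - \mathrm{CDE}(m)$ and
  $\mathrm{NIE} = \mathrm{TE} - \mathrm{NDE}$, both computed from the
  full fit as $[h(x)-h(x^*)]\Delta - m\,\hat\beta_{XM}(x-x^*)$ (the two
  routes agree exactly by the partitioned-regression identity, which
  makes the additivity identities hold to machine precision rather
  than approximately).

### Roles and interactions

Design columns carry role tags. The rule that makes the coefficient
partition work is: any column whose product involves a mediator
(including exposure × mediator products) belongs to the mediator
block; any mediator-free column involving an exposure (including
exposure × confounder and exposure × exposure products) belongs to the
exposure pathway; the intercept and confounder main effects belong to
neither. With exposure × confounder interactions, the indirect effect
marginalized over the confounder is obtained by evaluating the
contrast with the confounder at its mean:
$\Delta_1(x-x^*) + \Delta_2(x-x^*)\bar C$, whose variance expands into
the familiar three-term quadratic form. This reproduces, to machine
precision, the mediation-formula comparator
$\hat\beta_M(\hat\alpha_X + \hat\alpha_{XC}\bar C)(x-x^*)$ because the
mediator model is fit on exactly the mediator-free columns of the full
design (see below).

### The nestedness requirement

Marginalizing a linear mediator model out of a full model with a
*continuous* exposure × mediator interaction induces an $X^2$ term in
the marginal model. The single-model framework requires that implied
term to be present in the full model; otherwise the marginal model is
not nested and the framework does not apply.
`implied_submodel_check()` reports the implied terms, and all
downstream estimators refuse non-nested specifications with a classed
error rather than silently estimating something else. A binary
exposure is exempt ($X^2$ carries no new information). Declaring the
exposure with `exposure_terms = list(x = c("identity", "power:2"))`
restores nestedness and can be read as relaxing the assumption that
all nonlinear exposure effects act through the mediator.

## Variances: conditional, marginal, and approximations

The closed form above is the **fully conditional** variance — $X$ and
$M$ fixed, $Y$ random — which is the classical regression convention.
Treating the mediator as random instead gives, by the law of total
variance, the **marginal** variance implemented in
`marginal_variance()` for the simple model:

$$
\mathrm{Var}(\hat\Delta \mid X) =
\frac{n^2 r_{XM}^2 \hat\sigma_M^2 \hat\sigma^2_{Y|X,M}}{|D'D|}
+ \hat\beta_M^2 \frac{\hat\sigma^2_{M|X}}{n \hat\sigma_X^2},
$$

evaluated by plug-in: the sample correlation, maximum-likelihood
(divide-by-$n$) variances of $X$ and $M$, the full-model mean squared
error, and the mediator-model residual variance. The first term is
algebraically identical to the conditional variance for the simple
model (asserted in the tests), so the second term *is* the
random-mediator premium; it is $O(1/n)$ but, with a large mediator
coefficient, far from negligible at moderate $n$ — under the default
simulation design below it is roughly seven times the conditional
variance at $n = 200$.

This distinction matters for calibration, and the simulation harness
makes it visible. With the design held fixed across replicates, the
conditional variance is unbiased for the empirical variance of
$\hat\Delta$ and the conditional $t$ interval attains its nominal
level against the estimator's conditional target. Across fresh
replicates (mediator random), the empirical variance of $\hat\Delta$
is the marginal one; there the marginal-variance $t$ interval is the
calibrated one, and the conditional interval — unchanged in width —
covers the true effect well below nominal. Neither behavior is a
defect; they answer different questions, and `run_variance_study()`
reports coverage for every requested method so the user can see both.

The approximations:

* `sobel_variance()` — first-order delta method for the product
  $\hat\alpha_X\hat\beta_M$: $\hat\alpha_X^2 s^2_{\beta_M} +
  \hat\beta_M^2 s^2_{\alpha_X}$. Targets the unconditional spread.
* `bootstrap_variance()` — case mode resamples $(y, X, M, C)$ rows
  jointly (approximates the fully unconditional variance); residual
  mode resamples full-model residuals on the fixed design
  (approximates the conditional variance). Percentile 2.5/97.5
  intervals are reported; no bias correction or acceleration is
  applied. Rank-deficient case resamples are skipped and counted.
* `monte_carlo_variance()` — draws $(\alpha_X, \beta_M)$
  *independently* from normals centered at the estimates. Independence
  is a deliberate choice: the two coefficients come from different
  fits, and the exact limiting value
  $a^2 s_b^2 + b^2 s_a^2 + s_a^2 s_b^2$ (the variance of a product of
  independent normals) serves as the convergence oracle in the tests.
* `interaction_pe_variance()` — the moderated-mediation
  $\mathrm{PE}(m)$ variance, computed as the exact quadratic form of
  the mediator-block coefficient combination $\Delta - m\beta_{XM}$,
  which expands to
  $V_{XM}V_M^{-1}V_{MX} + m^2\mathrm{Var}(\hat\beta_{XM})
  - 2m\,V_{XM}V_M^{-1}\mathrm{Cov}(\hat\beta_M, \hat\beta_{XM})$
  scaled by $(x-x^*)^2$.

Bootstrap replicate and Monte Carlo draw defaults are 10000 each.

## Multiple mediators

`total_indirect()` and `specific_indirect()` come from the same single
fit: the total uses the whole mediator block, the specific effect for
$M_i$ uses the scalar diagonal block
$-\hat V_{XM_i}\hat V_{M_i}^{-1}\hat\beta_{M_i}(x-x^*)$. Because
correlated mediators share explanatory overlap, specific effects
behave like partial sums of squares: they need not (and generally do
not) sum to the total, and opposite signs produce inconsistent
mediation. The comparators assume more: `parallel_model()` adds one
mediator regression per mediator and estimates each path as
$\hat\alpha_{Xi}\hat\beta_{M_i}$ (Sobel standard errors);
`serial_model()` assumes a causal order between exactly two mediators
and splits the total into three path products, with the printed
three-way-product variance
$\hat\alpha_1^2\hat\delta_{21}^2 s^2_{\beta_2} +
\hat\alpha_1^2\hat\beta_2^2 s^2_{\delta_{21}} +
\hat\delta_{21}^2\hat\beta_2^2 s^2_{\alpha_1}$. Both comparator
decompositions sum to the single-model total exactly (OLS algebra, not
approximation), for either serial order — a property the tests assert
on correlated-mediator data. More than two serial mediators would
require variance formulas we do not have in closed form, so that is a
scope error rather than a guess. Confounders, when present, enter
every fitted equation; confounder–mediator interactions in the
comparators are not supported.

## Omitted covariates and estimator bias

If the outcome truly depends on a covariate $W$ omitted from the full
model, the indirect-effect estimate acquires expected bias
$(r_{XW} - r_{XW.M})(\sigma_W/\sigma_X)\gamma_W$
(`omitted_covariate_bias()`); it vanishes when $W$ is orthogonal to
$X$ or to $M$, and the invariance is exact in-sample when $W$ is
orthogonal to the span of the intercept, $X$, and $M$ — the
construction used in the corresponding test. Note the causal caveat:
a $W$ correlated with both $X$ and $M$ is an unmeasured
exposure–mediator confounder, and natural effects are then not
identifiable regardless of the algebra.

Even correctly specified, $\hat\Delta$ is a small-sample-biased
(though consistent) estimate: in correlation form it is a nonlinear
function of the sample correlation, which is itself biased —
approximately $\mathrm{E}[r] = \rho - \rho(1-\rho^2)/2N$
(`cochran_expected_r()`). `run_bias_study()` shows the conditioning-set
consequence: with $X$ and $M$ fixed across replicates the mean of
$\hat\Delta$ equals the fixed sample's projection coefficient times
$\beta_M$ (inheriting the fixed $r_{XM}$'s deviation), while letting
$M$ vary re-centers the estimate exactly at $\alpha_X\beta_M$.

## The synthetic-data generator

`sim_design()` encodes the generative model
$X \sim N(0, \sigma_X^2)$, $M = \alpha_0 + \alpha_X X + \varepsilon_M$,
$Y = \beta_0 + \beta_X X + \beta_M M + \varepsilon_Y$ with Gaussian
errors. Defaults: $n = 200$, $\alpha_X = 0.75$, $\beta_M = 2$ (true
indirect effect $1.5$), $\beta_X = 1$, intercepts $0$, all standard
deviations $1$. The product $1.5$ and the mediator-coefficient
magnitude are the conditions the simulation studies are stated for;
the remaining values are package defaults chosen as a plain unit-scale
design, all overridable. Three conditioning modes control what is
redrawn per replicate (`fixed-XM`, `fixed-X-random-M`, `random-XM`).
Reproducibility is by construction: one master seed spawns an
independent L'Ecuyer-CMRG stream per replicate (stream 0 is reserved
for the fixed-design draws), so replicate $i$ is bit-identical
regardless of how many replicates are run or in what order, and any
resampling method invoked inside a replicate continues that
replicate's stream.

What the generator emulates is deliberately minimal: linear
structural equations, homoscedastic Gaussian errors, a single
continuous exposure and mediator, no confounding, no missingness.
Passing simulation checks therefore demonstrates the estimator's
algebraic and distributional properties under the model's own
assumptions — not robustness to nonlinearity, heteroscedasticity,
non-Gaussian errors, measurement error in the mediator, or violated
identification assumptions, none of which the generator produces.

Study sizes used by the test suite and acceptance script: 1000
replicates at $n = 200$ for the recovery and conditional-variance
checks, 2000 replicates for the marginal-variance check, 10000
bootstrap replicates and $10^6$ Monte Carlo draws for the
resampling-agreement checks, $10^5$ draws for the sample-correlation
bias check. These sizes put Monte Carlo error well inside the asserted
tolerances.

## Numerical choices

* OLS is solved by QR; the coefficient covariance is
  $\hat\sigma^2 (D'D)^{-1}$ with the unbiased divisor $n - k$,
  matching the $t(n-k)$ intervals.
* $\hat\Delta$ is computed from the *unscaled* $(D'D)^{-1}$ blocks —
  $\hat\sigma^2$ cancels in $V_{XM}V_M^{-1}$ — so the components
  remain defined for saturated fits with zero residual variance
  (which are flagged with a warning, and all variances are then 0).
* Rank is checked by SVD with tolerance $10^{-10}$ times the largest
  singular value; rank-deficient designs are an error, not a silent
  pivot.
* A zero-residual fit warns (`degenerate_residuals`); a numerically
  singular mediator block errors (`singular_mediator_block`).
* `cov_delta` is symmetrized as $(A + A')/2$ to remove round-off
  asymmetry before quadratic forms.
* The full model always includes an intercept (excluded from both
  coefficient blocks). The intercept-shift components of the
  coefficient change are not part of any reported effect and are not
  exposed.
* Missing data: listwise deletion at frame construction with the
  dropped-row count logged and carried into the report. Imputation is
  a user-side tool upstream of the frame.
* Confounder and mediator reference values default to sample means.
* Mediator models condition on exactly the mediator-free columns of
  the full design. This is what makes the mediation-formula
  comparators match the single-model estimates to machine precision
  instead of approximately.

## Limitations

Linear models with continuous outcomes only: no GLM/binary-outcome
support, no weighted, robust, or mixed models. Identification (the
no-unmeasured-confounding assumptions for CDE/NDE/NIE) is assumed, not
tested — the package estimates regression functionals, and their
causal reading is the analyst's responsibility. Non-nested
exposure–mediator interaction models are rejected rather than
estimated via the general mediation formula. The serial comparator is
limited to two mediators, and inverse-probability-weighting approaches
to interdependent mediators are out of scope.
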