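---
title: "Mixed logit severity models with heterogeneity in means and variances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed logit severity models with heterogeneity in means and variances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(severomix)
```

## The model

Crash injury severity is coded on three levels — minor (including
property-damage-only), severe (hospitalised more than three weeks), fatal —
and modelled through a latent severity propensity for crash $i$ and level
$n$:

$$Y_{in} = \alpha_n + \beta_i' X_{in} + \varepsilon_{in},$$

with i.i.d. Gumbel errors, so that conditional on $\beta_i$ the outcome
probabilities are multinomial logit. One alternative-specific constant is
fixed at zero (the base alternative, minor injury by default): only utility
*differences* are identified. The defining feature of the mixed
(random-parameters) logit is that coefficients vary across crashes:

$$\beta_i = \beta + \Theta' M_i + |\sigma|\,e^{\omega' SD_i}\,\nu_i .$$

Covariates in $M_i$ shift the coefficient's mean ("heterogeneity in
means"); covariates in $SD_i$ scale its standard deviation through the
exponential ("heterogeneity in variances"), around a baseline dispersion
$\sigma$; and $\nu_i$ is a standardised disturbance from an
analyst-chosen mixing distribution. Unconditional choice probabilities
integrate the logit kernel over $\nu$:

$$P_i(n) = \int \frac{e^{\alpha_n + \beta_i' X_{in}}}
 {\sum_m e^{\alpha_m + \beta_i' X_{im}}} f(\nu)\, d\nu .$$

## Simulated maximum likelihood and Halton draws

The mixing integral has no closed form; it is approximated by averaging the
kernel over $K$ quasi-random draws per observation,

$$\hat P_i(n) = \frac1K \sum_{k=1}^K
 \mathrm{logit}_n\!\big(\beta_{i,k}\big),$$

and $\sum_i \log \hat P_i(y_i)$ is maximised. Draws come from Halton
radical-inverse sequences — deterministic low-discrepancy sequences in prime
bases (base 2 for the first random parameter, 3 for the second, …) that
cover the unit interval far more evenly than pseudo-random numbers, so the
simulated likelihood stabilises with hundreds rather than tens of thousands
of draws. Design choices:

* **`k = 1000` by default** (the stable-estimation convention in this
  literature); `k` between 100 and 250 is adequate for exploration, and this
  vignette's and the test suite's experiments use 25–250 to keep problem
  sizes desk-scale (recovery experiments use N = 5000, K = 250; size/power
  experiments N = 500–1600, K = 60–100).
* **`discard = 100` initial points per base**: the early part of a Halton
  sequence is serially correlated; dropping a fixed prefix is the
  conventional remedy. No scrambling, so every run is bit-reproducible.
* **Per-observation blocks**: observation $i$ consumes sequence elements
  $(i-1)K+1, \dots, iK$, keeping observations independent.
* Uniforms map to variates by inverse CDF: standard normal, symmetric
  triangular or uniform on $[-1, 1]$, or $\mathrm{sign}\cdot
  e^{\text{loc} + \text{scale}\,z}$ for the lognormal (sign-definite
  coefficients such as strictly positive effects).

## Estimation choices

* **Optimiser.** BFGS on the negative simulated log-likelihood with
  *analytic* gradients (the score of the simulated likelihood has a closed
  form involving the same per-draw probabilities as the likelihood itself,
  so one engine pass returns both). Central finite differences remain
  available (`gradient = "numeric"`) and are cross-checked against the
  analytic path in the test suite; analytic is the default because it is
  exact and roughly an order of magnitude faster, which is what makes
  replicate experiments tractable.
* **Starting values** are zeros with baseline dispersions at 0.1;
  convergence is declared when the per-observation score satisfies
  $\max_p |g_p| / N < 10^{-5}$ at the optimiser's final iterate. If the
  iteration budget is the only stopping reason the optimiser restarts from
  its last iterate (twice by default). Non-convergence is always reported
  through the `converged` flag, never silently.
* **Dispersions are unconstrained**, entering the likelihood as $|\sigma|$:
  the sign of $\sigma$ is not identified, and unconstrained storage avoids
  boundary problems at $\sigma = 0$. Reported standard deviations are
  magnitudes.
* **Standard errors** come from the inverse numerical Hessian of the
  negative log-likelihood at the optimum (finite differences of the
  analytic gradient). A singular Hessian flags standard errors unavailable
  rather than failing.
* **`LL(0)` is the equal-shares null** $-N\ln J$, the null-model convention
  used for the McFadden pseudo $R^2 = 1 - LL(\beta)/LL(0)$ in this
  literature (e.g. $N = 773$ gives $-849.227$).
* **Reporting convention**: parameters with two-sided $p \le 0.1$ are
  starred; variable selection itself is left to the analyst, with
  `test_random_candidates()` implementing the usual one-at-a-time loop that
  keeps a coefficient random only while its dispersion's t-statistic is
  significant.

## Identification of dispersions

A point worth knowing before specifying models: with binary covariates the
dispersion of a random coefficient is identified only through *cell
variety*. If the random covariate is the model's only covariate, the
severe/fatal odds ratio is constant across the mixture and the handful of
observable cell probabilities can be matched exactly by a plain multinomial
logit — the fitted dispersion collapses to zero regardless of the truth.
Identification returns once other covariates enter other utilities, so that
different covariate cells probe the mixing distribution at different
points. The package's own test fixtures for dispersion recovery therefore
carry several fixed covariates besides the random one, and applied
specifications should too.

Relatedly, at small samples with few draws the simulated likelihood can
drift along near-flat ridges where the dispersion inflates while per-draw
kernels saturate. The optimiser reports these runs as non-converged (the
restart logic does not mask them); the practical remedies are more draws,
more data, or a simpler random-parameters structure.

## Average marginal effects

For a binary covariate, the effect on each severity probability is the
sample average of switching it 0 → 1 for every observation with everything
else fixed:

$$ME = \frac1m \sum_{j=1}^m
 \big[\hat P_j(n)\,|\,X_j = 1 - \hat P_j(n)\,|\,X_j = 0\big].$$

Two implementation decisions matter. First, both counterfactuals use the
*same* draw matrix, so quasi-random noise cancels exactly in the difference
and each row of a marginal-effects table sums to zero to machine precision
(probability can only be reallocated between severities). Second, when the
toggled covariate also appears as a mean or variance shifter of a random
coefficient, the toggle propagates through those channels too — both the
direct utility term and the shifted coefficient switch together. The
average runs over all observations, not only those observed at zero.

## Transferability and temporal-instability tests

Whether model $B$'s parameters describe dataset $A$ is tested with

$$\chi^2 = -2\big[LL(\beta_{BA}) - LL(\beta_A)\big],$$

where $LL(\beta_{BA})$ evaluates $B$'s converged parameters on $A$'s data
with no re-estimation (fresh Halton draws built for $A$ with the same
settings) and $LL(\beta_A)$ is a free refit of the same specification on
$A$. The refit is initialised at the transferred values — which makes
$\chi^2 \ge 0$ structural up to optimiser tolerance — and optionally
cross-checked from a cold start, keeping the better optimum. Degrees of
freedom equal the number of estimated parameters in the transferred
specification (constants and dispersion terms included; where "variables"
versus "parameters" is ambiguous in this literature, parameters is the
count used here). Confidence is the $\chi^2$ CDF in percent, rendered as
`chi2 (dof) [confidence%]` with two-decimal truncation and `>99.99` above
that.

One statistical property deserves emphasis. When the reference parameters
$\hat\beta_B$ are themselves estimates from a finite sample, the statistic's
null mean is approximately $k(1 + n_A/n_B)$, not $k$: the transfer deficit
includes the estimation noise of $\hat\beta_B$. With comparable subgroup
sizes the test therefore rejects a true null well above its nominal rate —
a property of the method as defined, not of this implementation. The
package's size-control experiment accordingly evaluates the machinery in
the large-reference-sample limit (reference fixed at the generating
parameters), where the statistic is $\chi^2_k$ and the empirical rejection
rate matches the nominal size; the power experiment uses fitted reference
models at realistic subgroup sizes, where distinct truths are rejected with
near-certainty. Applied conclusions drawn from very high confidence values
(as is typical with real crash data) are unaffected.

## Out-of-sample prediction simulation

To compare two fitted models on one dataset, both are evaluated on that
dataset's covariates — rebuilding each random coefficient from the *target*
data's own mean- and variance-shifter values, so means and variances of the
random parameters are fully accounted for — and the per-severity mean
probabilities are differenced (out-of-sample minus within-sample). The
differences sum to zero by construction; swapping the two models negates
them. The temporal version runs each earlier-period model against each
later period's data within a seatbelt group.

## The synthetic-data generator

Because real crash registers are typically restricted, the package ships a
generator whose output has exactly the structure the estimator assumes:

* covariates are independent Bernoulli draws at stated frequencies
  (defaults follow observed crash-data shares, e.g. male 0.857, four-lane
  0.645, sloped road 0.107), with an optional shared-latent dependence hook
  for exercising the multicollinearity screen;
* outcomes are sampled by drawing one realisation of each random
  coefficient per record, forming the three utilities, and sampling from
  the closed-form logit probabilities — equivalent to adding independent
  Gumbel errors to the utilities;
* `study_config()` describes a six-subgroup study (two seatbelt states by
  three biennial periods; default sizes 773/999/842 restrained and
  1228/1608/1387 unrestrained) with either one shared truth (for size
  control) or per-subgroup truths separated by gaps of 0.3–1.6 (for power),
  with round-number true values following the sign patterns typical of
  severity models.

What passing tests on this data do and do not show: the generator matches
the model, so recovery experiments validate the estimator and the
surrounding machinery, not the model's adequacy for any real register. Real
crash data have correlated covariates, misclassified outcomes, and
unmodelled dependence (e.g. multiple crashes at one site); none of that is
emulated beyond the optional covariate-dependence hook.

## Numerical details and limitations

* Softmax is computed with max-utility subtraction; finite output is
  guaranteed for utilities up to ±700. Simulated probabilities below
  1e-300 are floored with a counter.
* Everything is deterministic given (data, spec, `k`, `discard`); generator
  determinism is per `(config, seed)`.
* Not implemented, by design: correlated random parameters, panel/grouped
  draws, nested or ordered-response structures, Bayesian estimation,
  standard errors for marginal effects, and pooled (non-pairwise) stability
  tests. Missing values are rejected, not imputed. Continuous covariates
  pass through the estimator but the marginal-effects machinery assumes
  binary indicators.

## A compact end-to-end run

```{r example, eval = FALSE}
study <- generate_study_like(study_config("distinct"), seed = 1)
spec <- study$truth[[1]]$spec
res <- run_severity_study(study, spec, k = 100, se = FALSE)
res$transferability[, c("model", "data", "cell")]
res$predictions
```
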