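---
title: "Detecting selective reporting with mixture selection models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective reporting with mixture selection models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selmix)
```

## The problem

Archives of behavioural-policy trials ("nudge units") are unusual in that
the record of *trials* is comprehensive: no whole study can quietly
disappear. That rules out classical publication bias, but not selective
reporting — the choice of which outcome, specification, or covariate set
becomes the headline effect estimate. Funnel-plot asymmetry tests lose
power against such bias when true effects are heterogeneous, which they
demonstrably are across intervention types. `selmix` takes the
model-based route: fit the effect-size distribution with and without an
explicit reporting-bias component and let model comparison decide which
description the data prefer.

## Model

Each record is an estimate $y_i$ (percentage points) with known sampling
SD $\sigma_i$. The base model is a $K$-component normal-mixture
random-effects meta-analysis:

$$m(y_i) = \sum_{k=1}^K \pi_k\, \varphi\!\left(y_i;\ \mu_k,\ \tau_k^2 + \sigma_i^2\right),$$

$K \in \{1,2,3\}$. One component is the standard random-effects model; two
or three components accommodate qualitatively different intervention
classes (e.g. default changes versus reminder letters) without forcing a
single Gaussian through a heavy-tailed effect distribution.

Selective reporting is a step weight function on the *reported estimate*:

$$w(y_i) = \begin{cases} 1 & y_i \text{ in the selected region} \\ \omega & \text{otherwise,} \end{cases} \qquad \omega \in (0, 1],$$

with three mechanisms for the suppressed region: negative estimates
(sign), or estimates non-significant at $\alpha = 0.10$ or $0.05$. The
observed-data density is the weighted marginal renormalized by the
expected weight,

$$f(y_i) = \frac{w(y_i)\, m(y_i)}{A_i}, \qquad
A_i = \sum_k \pi_k \left[ P_k(\text{selected}) + \omega\,(1 - P_k(\text{selected})) \right],$$

where $P_k$ is a normal-CDF probability with mean $\mu_k$ and SD
$\sqrt{\tau_k^2 + \sigma_i^2}$. $\omega = 1$ recovers the plain mixture
exactly. Effects are treated as independent across rows — the estimate is
the unit of analysis; trial labels are carried for extensions (e.g.
cluster bootstrap) but deliberately do not enter the likelihood.

Two modelling choices were genuinely open and are worth stating:

* **Weight after mixing.** The selection weight applies to the mixture
  *marginal*, not per component: reporting decisions observe the estimate,
  not the latent component membership. The per-component alternative
  would multiply each component by its own normalizing constant; it is a
  different model, and the marginal formulation is the one implemented.
* **Two-sided significance by default.** For the $\alpha$ mechanisms,
  "significant" means $|y_i|/\sigma_i > z_{1-\alpha/2}$ regardless of
  sign, so the $\alpha$ mechanisms are genuinely distinct hypotheses from
  the sign mechanism rather than a near-duplicate of it. A
  `sidedness = "one_sided"` switch ($y_i/\sigma_i > z_{1-\alpha}$) is
  provided for sensitivity analysis.

A moderated variant adds a common per-domain offset to all component
means (reference level: first domain), costing one parameter per
non-reference domain; it lets study-level covariates absorb heterogeneity
that would otherwise masquerade as extra mixture components.

## Estimation

All models are fit by maximum likelihood with `stats::optim` (BFGS) on an
unconstrained scale: means untouched, $\log \tau_k$ with a floor of
$10^{-8}$ (estimates below $10^{-4}$ are reported as exact zeros),
multinomial-logit mixture weights, and a logistic map of $\omega$ onto
$[10^{-4}, 1]$ — the lower bound keeps the likelihood finite, and an
estimate at the upper boundary reads "no detectable selection". The
gradient is supplied analytically (responsibilities for the mixture part,
normal-CDF derivatives for the normalizing constant) and is verified
against central differences in the test suite.

Mixtures have multimodal likelihoods, so every fit is multi-start
(default 20): component means drawn from data quantiles, $\tau$'s from
$(0.25, 0.5, 1, 2)\times$ sample SD, weights from a flat Dirichlet,
$\omega$ from $\{0.1, 0.5, 0.9\}$, all seed-controlled, so a fit is a
deterministic function of (data, model, config). Two refinements matter
in practice:

* **Polish and boundary passes.** The best start is re-run until the
  objective stops improving; then, because $\tau \to 0$ is only reachable
  asymptotically on the log scale, any component with a small fitted
  $\tau$ is re-optimized with $\tau$ pinned at the floor and the better
  of the two optima kept. Without this, $\hat\tau$ can stall around
  $10^{-3}$ with a visibly worse likelihood than the boundary.
* **Nested warm starts.** In the class comparison, the $K$-mixture starts
  from the $(K-1)$-mixture optimum with a split component, and every
  selection model starts from its no-selection counterpart with $\omega$
  essentially at 1. This guarantees the fitted log-likelihoods respect
  model nesting (a property the test suite enforces to $10^{-6}$).

Label switching is resolved by a canonical ordering: components sorted by
mean, ties broken by $\tau$ then weight.

## Model comparison

Fits are scored by $\mathrm{BIC} = p \ln n - 2\hat\ell$ with $n$ the
number of effect estimates — the likelihood's units — and $p$ the free
parameter count ($3K - 1$ mixture parameters, 2 when $K = 1$, plus 1 for
$\omega$). The three mechanisms within a selection class are combined
with equal prior mass $1/3$ into a class evidence
$E = \tfrac13 \sum_t e^{-\mathrm{BIC}_t/2}$, carried as a pseudo-BIC
$-2 \ln E$ (always within $[\min_t \mathrm{BIC}_t,\ \min_t \mathrm{BIC}_t
+ 2\ln 3]$); class BIC weights are then
$w_m \propto e^{-\mathrm{BIC}_m/2}$. An alternative convention — equal
prior mass per individual model, weights summed within class — is exposed
as `class_weight_method = "sum_within"`; the two differ only in prior
allocation and agree to displayed precision whenever one mechanism
dominates. All of this runs through log-sum-exp, so it is shift-invariant
and safe for BICs in the hundreds.

## What the generator emulates — and what it does not

`simulate_dataset()` produces archives with the structure the models
assume: component membership from $\pi$, true effects
$\theta \sim N(\mu_k, \tau_k^2)$, standard errors from a log-normal
(default median 1.0 pp, log-SD 0.5 — central 95% of $\sigma_i$ spanning
roughly a factor of seven, the order-of-magnitude spread typical of
archived trials), observed $y \sim N(\theta, \sigma^2)$, and suppression
by rejection: a draw in the suppressed region is kept with probability
$\omega$ and regenerated otherwise, so retained data follow *exactly* the
selection model's observed density. Defaults describe a realistic
archive: 241 effects at ~1.9 effects per trial (trial sizes
$1 + \mathrm{Poisson}(0.9)$), a dominant modest component and a smaller
high-mean, high-heterogeneity component ($\pi = 0.7/0.3$,
$\mu = 0.5/3.0$, $\tau = 0.6/2.5$ pp).

The generator deliberately does not emulate: within-trial correlation of
effects (trial labels are grouping only, matching the likelihood's
independence assumption); non-normal sampling error; dependence of
$\sigma_i$ on the true effect (no small-study confounding); or
outcome-level selection inside a trial. Passing recovery tests therefore
demonstrate that the inference machinery is correct *under the model's own
assumptions* — they do not certify behaviour under correlated effects or
misspecified error distributions, which is exactly the caveat that applies
to the method on real data.

## Numerical choices and degenerate inputs

* $\tau_k = 0$ is admissible (a fixed-effect spike); densities then use
  $\sigma_i$ alone.
* $\omega$ is floored at $10^{-4}$ during optimization; the generator cap
  (`max_draw_factor`, default 1000$\times$ the target) aborts cleanly
  when a truth places essentially all mass in the suppressed region.
* Log-likelihoods are computed by log-sum-exp across components; a zero
  density returns $-\infty$ rather than an error.
* Convergence: `reltol` $10^{-10}$, at most 2000 iterations per start;
  the returned gradient norm at the optimum is recorded per fit.
* Exact BIC ties in mechanism ranking are reported as ties rather than
  broken arbitrarily.

## Problem sizes

The shipped experiments use synthetic archives of 241–500 effects, 10–20
recovery replicates, and 2–10 optimizer starts with warm starts — sizes at
which every stage is exercised end to end and the whole suite runs on a
laptop in minutes. The same code paths scale unchanged to more starts and
replicates for production analyses.

## Known limitations

* The step selection function has a single $\omega$; graded or continuous
  (e.g. logistic) weight functions are out of scope by design — the
  one-parameter step is the minimal model of "suppressed results are
  reported less often".
* No parameter standard errors or profile intervals are reported; the
  comparison is BIC-based, and BIC weights are the inferential output.
* ML estimates of weakly separated mixture components are right-skewed in
  the upper mean at archive-scale $n$; recovery experiments quantify this
  (bias/RMSE tables) rather than hide it.
* BIC's $n$ is the effect count; with strong within-trial dependence the
  effective sample size is smaller and BIC differences overstated — one
  more reason trial labels are retained for future clustered extensions.
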