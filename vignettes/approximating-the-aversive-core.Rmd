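---
title: "Approximating the common core of aversive personality from trait subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating the common core of aversive personality from trait subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Aversive ("dark") personality traits — Machiavellianism, Psychopathy,
Sadism, Spitefulness, Greed, and so on — correlate substantially with one
another. One influential account attributes this to a single common
disposition, the Dark Factor of Personality (D), of which every aversive
trait is a flavored manifestation. Researchers who want an aversive trait's
*unique* variance routinely partial out the variance it shares with a small
set of other aversive traits (most often the Dark Triad or Dark Tetrad),
implicitly assuming that whatever those few traits share is an adequate
stand-in for the common core of *all* aversive traits. `darkcore` implements
the machinery needed to interrogate that assumption: how closely does the
general factor extracted from a *subset* of traits approximate the general
factor extracted from a full battery?

The measurement model throughout is an orthogonal bifactor model. For item
$i$ belonging to trait scale $t$,

$$ y_i = \lambda_{g,i}\, F_D + \lambda_{s,i}\, F_t + \varepsilon_i, $$

with all factors mutually orthogonal. $F_D$ (the general factor) carries the
variance shared by *all* items — the common core — while each $F_t$ carries
the variance shared only within scale $t$ beyond the core. The workflow is:

1. fit the full bifactor model over all $T$ scales by maximum likelihood;
2. extract regression-method factor scores for $F_D$ (the criterion);
3. for every subset of $k$ traits, refit the reduced bifactor model on the
   subset's items, score its general factor, and correlate it with the
   full-model scores;
4. summarize the correlation distributions by subset size, by included
   trait, and for conventional named sets.

## Estimation

Fitting minimizes the normal-theory ML discrepancy between the sample
covariance $S$ (denominator $N$) and the model-implied covariance
$\Sigma(\theta) = \Lambda \Psi \Lambda^\top + \Theta$:

$$ F_{ML} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p . $$

Identification is by marker variables: the loading of the first item overall
is fixed to 1 on the general factor, and the first item of each scale is
fixed to 1 on its specific factor; factor variances are free and factor
covariances are fixed to zero. For $p$ items over $T$ scales this leaves
$(p-1) + (p-T) + p + (T+1)$ free parameters, hence
$df = p(p+1)/2 - (3p + 1 - T + 1)$; the full 151-item, 16-scale battery
gives $df = 11{,}023$.

Numerical choices, all tunable via `engine_options()`:

* **Optimizer.** L-BFGS-B with the analytic gradient
  ($\partial F / \partial \Sigma = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$,
  chained through the bifactor pattern). Default function tolerance
  `factr = 1e6` (about `2e-10` in $F_{ML}$), iteration cap 5,000.
* **Start values.** General loadings from a one-component principal-axis
  pass on the correlation matrix, rescaled to the marker metric; flat 0.3
  specific loadings; half the item variance as residual variance; marker
  communalities for the factor variances.
* **Heywood guard.** Residual and factor variances are bounded below at
  `1e-4` times the (marker) item variance, keeping $\Sigma$ invertible
  through tens of thousands of unsupervised refits. A solution sitting on
  that bound is flagged (`heywood`) and treated as a restart trigger,
  because boundary optima are often spurious local solutions: the engine
  jitters the start values (multiplicative lognormal, sd 0.2, seeded) and
  retries, keeping the best discrepancy seen. Up to 5 restarts are also
  used when an attempt fails outright.
* **Convergence.** A fit counts as converged if the optimizer terminated
  regularly *or* the analytic gradient at the returned point is below
  `grad_tol` (default `1e-3`). The second clause matters for reduced models
  with only two group factors: a bifactor model with two specific factors is
  empirically under-identified, so $k = 2$ refits sit on a ridge of
  equivalent minima. Such fits are stationary points, and their factor
  scores are perfectly well defined given the returned parameters; they are
  reported, not discarded. Fits that truly fail are returned with
  `converged = FALSE`, counted, and excluded from summaries.
* **$\chi^2$ convention.** $\chi^2 = N \cdot F_{ML}$, matching the biased
  (divide-by-$N$) sample covariance; an $N-1$ variant is available via
  `n_convention`. RMSEA is $\sqrt{\max(0, (\chi^2 - df)/(df\,N))}$ with the
  90% CI endpoints from the noncentral-$\chi^2$ inversion (tail
  probabilities 0.95 and 0.05, zero when no solution exists). SRMR is the
  root mean square of correlation-metric residuals over the unique elements
  including the diagonal.

## Factor scores and ECV

D scores are regression-method (Thurstone) scores,
$\hat F = \hat\Psi \hat\Lambda^\top \hat\Sigma^{-1}(x - \bar x)$, with the
general-factor row retained. The method is closed-form, deterministic and
(with loadings of this size) highly determinate. Because the marker-metric
solution is sign-unidentified, scores are aligned so that the sum of general
loadings is positive; alignment is idempotent and all reported correlations
are signed, not absolute.

Per scale, the explained common variance
$ECV_t = \sum_{i \in t} \ell_{g,i}^2 \big/ \left(\sum_{i \in t} \ell_{g,i}^2
+ \sum_{i \in t} \ell_{s,i}^2\right)$ uses completely standardized loadings
$\ell = \lambda \sqrt{\psi} / \mathrm{sd}(y)$; it measures each trait's D
saturation and is invariant to item rescaling.

## The subset pipeline

`enumerate_subsets()` lists all $\binom{T}{k}$ subsets per size
(deterministic lexicographic order; $\sum_{k=2}^{11}\binom{16}{k} =
63{,}002$ for the full battery). `run_all()` fits the full model once,
scores it, then maps the reduced refits over the enumeration; each subset's
jitter seed derives from the global seed and the subset's identity, so the
result table is identical under any worker count. Summaries report per-size
medians and 1st/5th/10th percentiles (linear interpolation between order
statistics — the convention is recorded in the output metadata),
distributions conditional on an included trait, tail compositions (which
traits populate the worst/best 1% of subsets, ties at the cutoff included),
and named-set comparisons (a set's $r$ against the median of its size class
and of same-size subsets containing each member).

## What the synthetic data emulate — and what they do not

The package ships a generator rather than respondent data. The default
population (`make_default_population()`) emulates a 16-scale battery of 151
five-point Likert items answered by respondents of a large online panel:

* item counts per scale exactly 13, 12, 9, 6, 14, 7, 9, 8, 9, 6, 8, 9, 10,
  4, 17, 10 ($p = 151$);
* one standard-normal general factor plus 16 orthogonal specific factors;
* heterogeneous D saturation: the Frustralia-, Machiavellianism- and
  Crudelia-like scales carry general loadings around 0.6-0.75 with weak
  specific loadings, while the SD3-Narcissism-, Entitlement- and Greed-like
  scales are dominated by specific variance (general loadings 0.25-0.40);
  within each scale, loadings are spread evenly over the scale's band;
* responses formed as latent normal variables
  $y^* = \lambda_g F_D + \lambda_s F_t + \varepsilon$ discretized at four
  per-item cut-points. Cut-points are the symmetric base
  $(-1.8, -0.6, 0.6, 1.8)$ shifted per scale so the expected observed item
  means spread over roughly 1.9-2.9 — matching the range real aversive
  scales occupy — with the Sadism-like scale shifted hard right so its
  expected mean sits near 1.44, reproducing the floor effect that attenuates
  its correlations.

Exact loading values are configuration, not contract: tests assert ranges
and orderings (e.g. the Frustralia-like ECV exceeds the SD3-Narcissism-like
ECV), never the stylized numbers themselves. The analysis stages treat the
Likert responses as continuous in ML estimation — the estimator the original
analysis used — so the generator's discretization deliberately stresses the
estimator the same way real Likert data would.

The generator does **not** emulate careless responding, attention-check
failures, missing data, acquiescence or other response styles, non-normal
latent distributions, or correlated specific factors. Passing tests
therefore show that the pipeline recovers known structure under clean
conditions; they cannot certify behavior under messy real-world response
processes.

## Problem sizes

The test suite and the acceptance script exercise three scales of problem:

* closed-form and oracle checks (enumeration counts, $df$, RMSEA from the
  published full-battery statistics $\chi^2 = 35{,}211$, $df = 11{,}023$,
  $N = 1{,}676$) at negligible cost;
* one full-size replica — 151 Likert items, $N = 1{,}676$ — fitted once to
  confirm the complete specification estimates cleanly at the real study's
  dimensions;
* the exhaustive subset study scaled down to 8 traits of 4 items
  ($n = 800$, $k = 2..6$, 238 refits). Eight traits preserve everything the
  full enumeration is used for — a planted high-saturation trait, a planted
  low-saturation trait, a floor-effect scale, and enough subsets per size
  for stable percentiles — while an exhaustive 16-trait run (63,002 refits)
  adds nothing qualitative. The scaled study reproduces, as properties: the
  median correlation rising with subset size; the dispersion shrinking; the
  low-saturation trait dominating the bottom 1% of three-trait subsets and
  the high-saturation trait the top 1%; triad/tetrad-like named sets
  underperforming their size class; and diminishing median gains at the
  largest sizes.

## Known limitations

* No standard errors, robust corrections, mean structure, or missing-data
  ML; covariance-only estimation.
* Likert items are treated as continuous; no polychoric pathway.
* Bifactor models with two group factors are empirically under-identified;
  $k = 2$ results are reported (the distributions are still informative) but
  their parameter estimates should not be interpreted individually.
* The default population is stylized. Its ECV profile is qualitatively, not
  numerically, faithful to published trait batteries, so data-bound
  quantities (exact medians, exact percentile tables) are not expected to
  match any particular empirical study.
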