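---
title: "Detecting tipping points and classifying stressor interactions along a gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tipping points and classifying stressor interactions along a gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipstress)
```

## The problem

Ecological responses to a press stressor often change abruptly at a
threshold — a tipping point — rather than smoothly. When a second, pulsed
stressor overlaps the first, the threshold can shift and the two stressors
can interact non-additively. `tipstress` implements the complete analysis
chain for a two-stressor factorial gradient experiment of the kind run in
mesocosm studies of freshwater mussels: a gradient of nutrient enrichment
(13 fertilizer masses, 0–120 g) crossed with a salinity regime (stable
water vs. a weekly saltwater intrusion), with tank-level mortality as the
response.

The package answers three questions:

1. **Is there a threshold?** Broken-line regression locates breakpoints in
   mortality along the gradient; a Davies-type test decides whether a slope
   change exists at all.
2. **Does the threshold look like a tipping point?** Rising variance as the
   gradient approaches the threshold (an early-warning signal) and
   multimodality of the mortality distribution (alternative states) are
   checked with a variance profile and Hartigan's dip test.
3. **How do the stressors interact?** Relative survival responses are
   combined on the Bliss-independence scale; the rescaled deviation from
   additivity classifies each gradient level as synergy, additive,
   antagonistic buffering, or suppression.

## Broken-line regression

The mean response is continuous piecewise linear,

$$E[y] = \alpha + \beta_0 x + \sum_j \beta_{U_j} (x - \psi_j)_+,$$

with unknown breakpoints $\psi_j$. `fit_segmented()` estimates them by
iterative linearization: the working model adds, for each breakpoint, the
indicator column $V_j = -1[x > \psi_j]$; the fitted coefficient
$\hat\gamma_j$ on $V_j$ measures the gap left in the fitted line at
$\psi_j$, and the update $\psi_j \leftarrow \psi_j + \hat\gamma_j /
\hat\beta_{U_j}$ is a first-order step towards the zero-gap solution.

Numerical choices:

* **Convergence**: stop when $\max_j |\hat\gamma_j| < 10^{-4}$ (response
  units) or after 50 iterations. Non-convergence flags the fit, it does not
  raise an error.
* **Damping**: a step is halved until the residual sum of squares does not
  increase, so accepted iterations are monotone in RSS; updates leaving the
  observed range are pulled back to the nearest interior midpoint of the
  distinct `x` values.
* **Multi-start**: breakpoint likelihoods have local optima, so the
  iteration is restarted from quantile-spread initial values and from the
  best candidate of a coarse exact grid search over interior midpoints
  (the same candidate set the brute-force oracle
  `brute_force_breakpoints()` enumerates exhaustively). The lowest-RSS
  solution wins.
* **Uncertainty**: $SE(\hat\psi_j) = SE(\hat\gamma_j)/|\hat\beta_{U_j}|$
  (delta method), with a t-based 95% interval.

The package deliberately fits 0, 1 and 2 breakpoints per treatment in the
pipeline and selects among them with an explicit rule: the Davies test
gates existence (p < 0.05), then BIC chooses between the 1- and
2-breakpoint fits. Automating the selection makes reanalysis reproducible
where a manual choice would not be.

## The Davies test

Under the no-breakpoint null the location $\psi$ does not exist, so the
slope-change t statistic at the best location is not t-distributed.
`davies_test()` evaluates the t statistic for the added ramp $(x-\psi_k)_+$
on a grid of K = 10 interior quantiles of `x` and refers the maximum
$M = \max_k |t_k|$ to the upper bound

$$p = P(|T| > M) + V \exp(-M^2/2)/\sqrt{8\pi},$$

where $V$ is the total variation of the signed statistics along the grid
and $T$ carries the residual degrees of freedom (a finite-sample refinement
of the Gaussian reference; with tank-level binomial mortality data the
realized null rejection rate is close to, and slightly above, the nominal
0.05 — about 0.055 in the package's own calibration simulations). K and the
grid placement are configuration, not constants.

## Outlier screening

Breakpoint estimates are sensitive to single extreme tanks, so the pipeline
screens each treatment cell (nutrient level × salinity, n = 5) with
Dixon's ratio test before fitting. The ratio family follows standard
practice for the cell size (r10 up to n = 7, then r11, r21, r22), the
critical values are the two-tailed Rorabacher (1991) tables for
α = 0.05/0.01, and at most one tank per cell can be flagged. Screening per
cell (rather than per treatment arm) keeps a genuine threshold jump from
being mistaken for an outlier.

## Tipping-point corroboration

**Variance profile.** `variance_profile()` computes the unbiased sample
variance of mortality per level and smooths it with a local-linear,
tricube-weighted smoother (span 0.75 of the levels, at least 3 levels per
window). The smoother reproduces constants exactly, so a flat variance
field stays flat; a rising bump near the breakpoint is the early-warning
signature.

**Dip test.** `dip_statistic()` implements Hartigan's dip — the smallest
sup-distance between the empirical cdf and any unimodal cdf — via the
greatest-convex-minorant / least-concave-majorant construction on the
sorted sample, iteratively narrowing the modal interval (compiled code;
the implementation was validated against an independent definitional
oracle that bisects the feasibility of a unimodal cdf within a sup-norm
band, solved as a quadratic program over mode splits). `dip_test()`
calibrates the statistic against Uniform(0,1) samples of the same size
(B = 999 by default), the canonical null, which is conservative for
lighter-tailed unimodal data. Two caveats follow from that calibration and
are visible in the package's own simulations: the test essentially never
rejects for Normal samples of the experiment's size (n = 65), and its
power against a balanced two-component Normal mixture separated by 4
standard deviations is only moderate (about 0.65 at n = 65) — multimodality
evidence at this sample size is corroborative, not decisive.

## Interaction classification

Survival percentages $W$ (100 − mortality) are expressed relative to
control, $w = W/W_0$. Bliss independence predicts the combined relative
survival $w_X w_Y$; the deviation from additivity is

$$DA = w_{XY} - w_X w_Y.$$

The rescaled DA maps interaction strength onto $[-1, 2]$: negative DA is
divided by the expected response $E = w_X w_Y$ (so $-1$ means the
combination kills everything), positive DA by the headroom
$\min(w_X, w_Y) - E$ to the strongest single stressor (so $+1$ means the
combination does exactly what the worse stressor alone does, and values
beyond 1 mean one stressor reverses the other). Values are clipped to
$[-1, 2]$; near-zero denominators return the clip boundary and set a
degenerate flag (with `eps = 1e-9` guarding both comparisons). Bins are
closed on the left: $[-1,-0.5)$ synergy, $[-0.5,0.5)$ additive,
$[0.5,1.3)$ buffering, $[1.3,2]$ suppression; the boundary convention is
explicit because the interval endpoints overlap in common usage.

The multiplicative null model works on mortality-effect proportions,
$(N + SV) - N \cdot SV$, which caps combined mortality at 100% — the cap
logic only works multiplicatively on proportions, not percentages. On the
survival scale the same null is $W_0\, w_X\, w_Y$, and the sign of DA
agrees exactly with the observed-vs-null mortality comparison; the package
keeps both representations and the identity is asserted in the tests.

`interaction_table()` uses raw cell means by default;
`use = "bath_adjusted"` averages the predictions of an additive
cell-plus-bath linear model instead, for designs where the blocking
structure leaks into the cell means.

**Two-way test.** The conventional check is a two-way
(13 nutrient levels × 2 salinity regimes) fixed-effects model with
interaction, fitted by weighted least squares. Cell variances estimated
from 5 replicates are far too noisy to use as weights directly (doing so
inflates the interaction F test's type-I error to about 0.07), so the
one-step weights shrink each cell variance towards the pooled variance
with 24 prior degrees of freedom — chosen so the test holds its nominal
0.05 level under an additive truth (realized ~0.054 in the calibration
simulations) while still down-weighting genuinely noisy cells. The
water-bath random intercept is tested by a likelihood-ratio statistic
against the 50:50 mixture of a point mass at zero and $\chi^2_1$ (the
boundary null for a variance component), with `lme4` fitting the mixed
model.

## The synthetic generator

No raw data ships with the package; `make_design()` and
`simulate_experiment()` regenerate the full study design — 13 nutrient
levels (0–120 g in 10 g steps; the levels are a constructor argument so
measured values can be substituted), 2 salinity regimes, 5 replicates, 130
tanks in 6 water baths, 15 individuals per tank — with known
piecewise-linear truth:

* `stable_single_threshold`: background mortality 5%, flat to a breakpoint
  at 70 g, then rising at 1.2 percentage points per gram (≈65% at 120 g) —
  a mortality range typical of a severe die-off at high enrichment.
* `intrusion_double_threshold`: rise–fall–rise with breakpoints at 26.91 g
  and 84.13 g (8% at 0 g, ≈48% at the first breakpoint, ≈23% at the
  second, ≈66% at 120 g).
* `null_flat`: constant 15% mortality, no breakpoint.

Tank counts are Binomial(15, p) with a Normal(0, 0.02) bath effect on the
probability scale (small, matching a blocking factor that matters but does
not dominate). Optional near-threshold variance inflation adds logit-normal
jitter to p whose sd ramps linearly from 0 at 25 g away from a breakpoint
to 1.5 at the breakpoint. The magnitude is chosen so that the induced
spread in mortality (roughly ±12 percentage points near the threshold) is
on the scale of the between-state separation of the piecewise truth —
emulating the flickering between alternative states that makes variance
rise and the mortality distribution bimodal near a tipping point. Because
p(1−p)/15 itself grows with mean mortality, the binomial part of the
variance also rises beyond the breakpoint; in simulations the smoothed
variance inside the ±25 g window exceeds the outside mean in roughly 9 of
10 data sets, not always.

What the generator does **not** emulate: water chemistry and
nutrient-release kinetics, replacement of dead individuals during the
experiment (end-of-experiment counts suffice when mortality concentrates
at the end), temporal autocorrelation, and overdispersion away from
thresholds. Passing recovery tests on these simulations therefore show
that the estimators work under binomial noise with the stated mean
structures — not that any particular field data set satisfies those
assumptions.

## Problem sizes used in the validation studies

The packaged tests run: 500 simulated experiments for single-breakpoint
recovery (median bias and CI coverage), 200 for double-breakpoint
recovery, 1,000 replicates each for the Davies and interaction-F
calibrations, 500 each for the dip test's conservativeness and power, 200
random small instances for the exhaustive-search equivalence of the
breakpoint fitter, and a 438,976-point grid for the interaction-metric
contract. These sizes keep Monte-Carlo error near or below the margins
being asserted.

## Limitations

* Breakpoint confidence intervals are pointwise delta-method intervals;
  no simultaneous bands.
* The segmented model is Gaussian least squares on percentages; a binomial
  GLM variant is out of scope.
* The dip test at n = 65 has limited power against moderately separated
  mixtures (see above). Conversely, tank-level mortality with 15
  individuals per tank can only take 16 values, and the resulting ties
  inflate the dip relative to the continuous uniform null — dip p-values
  on tank-level data overstate multimodality evidence and should be read
  together with the histogram they summarize.
* The heterogeneous-variance mixed model is approximated by moderated WLS
  plus a random-intercept LRT, not a full heterogeneous-covariance fit.
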