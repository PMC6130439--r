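---
title: "Modelling default-mode to task-positive negative connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling default-mode to task-positive negative connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negconn)
```

## The scientific problem

The default-mode network (DMN) supports internally directed
processing and deactivates during external tasks; the task-positive
networks (cingulo-opercular, salience, dorsal-attention,
ventral-attention, fronto-parietal) do the opposite. In resting-state
fMRI the two systems' spontaneous BOLD fluctuations are negatively
correlated, and the strength of this segregation is a plausible
substrate of attentional control: weaker anticorrelation has been
repeatedly associated with ADHD. Testing that association in a
longitudinal child cohort requires a chain of decisions — how to
censor motion, which edges define "the" anticorrelation, how to
summarize them, and how to model repeated scans — each of which this
package implements as an explicit, testable operation.

## The measurement model

**Framewise displacement and censoring.** FD at frame $t$ is the sum
of absolute backward differences of the six realignment parameters,
rotations converted to arc length on a 50 mm sphere (configurable via
`head_radius_mm`). The first frame is assigned FD = 0. Censoring at
0.2 mm is *strict*: a frame exactly at the threshold is kept, because
the criterion is stated as "exceeding". To equate data quantity
across scans, exactly `ceiling(4 * 60 / TR)` clean frames are sampled
uniformly without replacement; eligibility requires *strictly more*
than 4 minutes of clean data. Censored frames are simply dropped and
the survivors concatenated — no interpolation — which is the standard
scrubbing contract for correlation estimation.

**Connectivity.** Pearson correlation over the selected frames for
all ROI pairs, Fisher transformed ($z = \mathrm{atanh}\, r$). One
frame set serves all pairs: frame selection is a scan-level decision,
never pair-level. The diagonal is undefined after the transform and
stored as `NA`. A perfect $|r| = 1$ (practically impossible on real
data, easy to provoke in toy examples) is capped at
$\mathrm{atanh}(1 - 10^{-7}) \approx 8.4$ with a warning rather than
propagating infinities.

**The anticorrelated mask.** Not every DMN-to-task-positive edge is
negative, so the mask is defined on an *independent reference
sample*: per candidate edge, average across reference scans, then
retain either edges below a stated correlation cut (−0.3 / −0.35 /
−0.375 are first-class choices) or the most-negative fixed fraction
(density rule, ceiling count, lexicographic tie-break for
determinism). Averaging is done on the z scale by default — the
variance-stabilized convention — and converted back with `tanh` so
that cuts are stated in r units, where they are conventionally
printed; `average = "r"` is available because the choice is genuinely
open, and on realistic references the two differ negligibly (the
test suite checks this). The packaged 333-region assignment table is
a *synthetic stand-in* with the published per-network region counts
(41 DMN, 123 task-positive), block-ordered: every computation here
depends only on network membership, not on anatomical identity, and
users with the real assignment table can supply it as a two-column
TSV.

**The averaged metric.** `avg_neg_conn` is the arithmetic mean of
Fisher-z values over mask edges — one number per scan, more negative
meaning stronger segregation. Averaging first and testing once avoids
the multiple-comparisons burden of edgewise inference; the edgewise
module then localizes, rather than establishes, effects.

## The inference model

Scans nest within subjects, so all group-level analyses are linear
mixed-effects models with a subject random intercept, fitted by
maximum likelihood (not REML: ML likelihoods are comparable across
fixed-effect structures, which AIC selection requires). Tests use
Satterthwaite denominator degrees of freedom via `lmerTest`. Model 1
is main effects (`group + age + sex + mean_fd`), Model 2 adds
group×age, Model 3 the full three-way factorial; counting the two
variance components these carry 7, 8 and 11 parameters. Age is
mean-centred before interaction models so main effects stay
interpretable; centring never changes the highest-order interaction
test, and `center_age = FALSE` is available. Mean FD stays in every
model as the standard motion covariate.

When no subject has a repeat scan the random-intercept variance is
unidentifiable; `fit_lmm` then returns the ordinary-least-squares
fit, flagged `method = "ols"` — which is exactly the right estimator
for that degenerate design, and what the test suite's closed-form
normal-equations oracle checks against.

Edgewise fits reuse Model 1 per edge with Benjamini–Hochberg
correction applied per term across edges (not pooled across terms);
summed-t maps then aggregate significant (uncorrected $p < 0.05$)
edge t scores by region and direction. The secondary scan-level QC —
removing scans until the across-scan association between mean FD and
the averaged metric is non-significant — is implemented as
leave-one-out influence-ranked removal with a configurable cap and
alpha; the stopping criterion is the package's own documented choice,
since published pipelines state the outcome of such filters more
often than their algorithm.

The gender-balanced permutation repeatedly thins the ADHD scans to a
chosen male/female composition (controls always fully retained),
refits, and *averages the p values* over iterations. Averaged p
values are a descriptive robustness summary, not a formal test — they
answer "does the effect survive when the sex imbalance is removed",
and they reproduce the single full-sample fit exactly in the
degenerate full-selection case, which the tests exploit.

**CPT scoring.** The identical-pairs continuous performance task
yields, per scan, hits on targets and false alarms on easy ("stim")
and difficult ("catch") nontargets (design 60/180/60 of 300 trials).
Sensitivity is $d' = \Phi^{-1}(H) - \Phi^{-1}(F)$ per difficulty.
Degenerate rates (0 or 1) are corrected by the conditional half-count
rule — add 0.5 to the count and 1 to the denominator only when the
raw rate is degenerate — with log-linear and clamp alternatives
tagged in the result, because the field's references describe several
conventions without mandating one. Results that depend on the
correction at all involve near-ceiling performance and should be read
with that flag in mind.

## What the synthetic generator emulates

`generate_cohort()` plants the statistical structure the analysis
assumes, at the latent level where the statistics operate:

$$\zeta_s = z_0 + \delta_g [\mathrm{ADHD}] + \delta_x [\mathrm{F}]
  + \beta_a (\mathrm{age} - \mathrm{age}_{ref}) + u_i + \varepsilon_s,
  \qquad \rho_s = \tanh \zeta_s$$

with $u_i \sim N(0, \tau^2)$ subject intercepts and scan noise
$\varepsilon_s \sim N(0, \sigma_s^2)$. Each frame draws a DMN factor
and a task-positive factor as bivariate normal with correlation
$\rho_s$ (unassigned ROIs get an independent factor), and ROI signals
load on their network factor ($\lambda$) plus ROI noise
($\sigma_{roi}$). Injecting the anticorrelation at the two-factor
level rather than edgewise means *every* DMN-to-task-positive edge
inherits the effect — mirroring the averaged-metric logic — and gives
the closed-form oracle
$E[r_{edge}] = \rho_s \lambda^2 / (\lambda^2 + \sigma_{roi}^2)$
(`expected_edge_r`), which Monte-Carlo tests verify.

Defaults were chosen once to sit near the study conditions this
design emulates and are all configurable: baseline ages uniform on
7–11 years with ~1.5-year lags (1–3 waves, so ages span 7–15);
male proportions 0.51 (control) and 0.71 (ADHD); $z_0 = -0.60$ so
that with $\lambda = \sigma_{roi} = 1$ the expected averaged metric
is $\mathrm{atanh}(0.5 \tanh z_0) \approx -0.28$, in the reported
range for such metrics; $\delta_g = +0.06$ giving a marginal group
gap of $\approx 0.024$ measured z-units; $\delta_x = -0.05$ (females
more negative); $\beta_a = -0.010$/year; $\tau = 0.08$,
$\sigma_s = 0.05$. Motion is a random-walk on the six parameters
tuned to a 0.10 mm mean FD, with 0.5 mm transient spikes at rate
0.05 per frame; at spike frames a *global* artifact
(`artifact_gain` × spike size) is added to all ROI signals, because
FD-correlated global artifacts are precisely the failure mode frame
censoring exists to remove — censoring therefore measurably improves
estimates on this generator. CPT truth couples $d'$ to the expected
metric with slope `b_conn = 2.8` per z-unit (intercepts 2.0 easy /
0.57 difficult, SDT criterion 0.5, trial noise via binomial draws
whose hit rate follows the easy $d'$ and whose catch false-alarm rate
is set so scoring recovers the difficult $d'$ exactly in
expectation).

What it does **not** emulate: hemodynamic autocorrelation and
spectra, spatial smoothness and parcel size heterogeneity,
physiological noise, distance-dependent artifact structure,
site/scanner effects, and any direct (non-connectivity-mediated)
group effect on $d'$. Passing tests therefore certify the
*pipeline's* statistical behaviour — calibration, recovery,
determinism — under a clean factor model, not performance on real
BOLD data.

## Numerical choices and degenerate inputs

* Frame selection, permutation draws and the generator all take
  explicit integer seeds and restore the caller's RNG state; the
  pipeline fans a single seed into per-stage substreams so stage
  reruns reproduce in isolation, and an unchanged config reproduces
  `report.json` byte for byte.
* Correlations of constant ROIs are undefined: flagged per scan,
  stored `NA`, and an error names the offending edges if they reach
  the averaged metric.
* Matrices require at least 3 retained frames; fewer is an error,
  not a silent small-sample estimate.
* The density rule uses `ceiling(fraction × candidates)` and breaks
  boundary ties lexicographically, so masks are deterministic.
* An empty mask (no candidate edge below the cut) is an error
  reporting the observed minimum — on references that are not
  actually anticorrelated this should fail loudly, not return an
  empty average.
* TR is never defaulted when reading real data; it is a required
  argument (the generator's own config carries its TR explicitly).
* Rotations on disk default to radians with a degrees switch, since
  both realignment dialects are common.

## Problem sizes in the test suite

The suite exercises recovery at 150 subjects per group (20
replicates) and type-I calibration at 40 per group (200 replicates)
on a 24-ROI toy parcellation with 200-frame scans — sizes chosen so
the full suite completes in a few minutes while leaving the
statistical checks well-powered; the same code paths scale unchanged
to 333 ROIs, where only the matrix sizes grow. The permutation
module's reproducibility is checked at 500 iterations; production
analyses would use the conventional 10,000.

## Known limitations

* The averaged-p permutation summary inherits the caveats above; a
  max-statistic or sign-flip permutation would give formal FWER
  control and is out of scope here.
* The secondary FD QC criterion is one defensible operationalization
  of "remove scans whose connectivity tracks motion"; alternatives
  (correlation magnitude cut, robust regression influence) would
  remove slightly different sets.
* The packaged parcellation stand-in supports every network-level
  statistic but cannot support anatomical claims about *which*
  regions drive effects; supply the real assignment table for that.
* Satterthwaite p values are approximate in small samples with few
  repeat scans; the OLS fallback is exact but forfeits the
  longitudinal variance decomposition.
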