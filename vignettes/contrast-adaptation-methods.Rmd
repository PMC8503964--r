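---
title: "Simulating and analysing contrast-adaptation matching experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing contrast-adaptation matching experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastfade)
```

## The paradigm

Prolonged viewing of a high-contrast pattern desensitises the cortical
neurons tuned to it, and the pattern's apparent contrast fades. The
method-of-adjustment paradigm implemented here measures that fading
directly: on each trial the observer adjusts the Michelson contrast of a
grating below fixation until it appears identical to a reference grating
above fixation. In the *control* condition nothing is shown between trials;
in the *adaptation* condition the session opens with 180 s of exposure to a
0.7-contrast grating at the upper location, topped up for 10 s between
trials. Matched contrast plotted against reference contrast in log-log
coordinates is the paradigm's standard summary: control matches fall on a
line of slope ~1 (veridical matching), adaptation matches on a steeper line
— apparent contrast is reduced most at low contrasts and approaches
veridical near the adapting contrast.

This package is headless by design. Stimuli can be rendered for figures and
demos, but sessions run against a generative simulated observer and the
timing constants are carried as metadata, never slept. That makes the whole
pipeline — protocol, slider mechanics, observer, statistics — testable and
usable for power analysis and teaching without a display.

## Stimuli

`render_grating()` evaluates, on a pixel grid covering the patch,

$$L(x,y) = L_b\left(1 + c\, e^{-(x^2+y^2)/2\sigma^2} \sin(2\pi f x + \phi)\right)$$

with background luminance $L_b = 0.5$ (mid-gray, normalised $[0,1]$ units —
no monitor gamma is modelled), Michelson contrast $c$, spatial frequency
$f = 3$ cycles per degree of visual angle (DVA), and a 3 × 3 DVA patch. Two
choices were genuinely open and are parameters:

* **Envelope width.** The Gaussian mask's SD is not dictated by the patch
  size alone; we default to $\sigma = \mathrm{size}/6$, the common
  convention that lets ±3σ of the mask fill the patch, and allow
  $\sigma = \infty$ to disable the envelope (used by the contrast-
  verification tests, since the envelope attenuates measured Michelson
  contrast below the nominal $c$).
* **Phase.** Defaults to $\phi = 0$; it only matters for pixel-exact
  comparisons.

`compose_frame()` places optional upper/lower patches 3 DVA above and below
a 0.5 DVA fixation cross and refuses layouts where the patches would
overlap.

## The slider scales

Both protocols drive the match through a 1000-step slider whose positions
map to a geometric ("log-spaced") contrast list built by `log_spaced()`:
$v_i = \mathrm{lo}\,(\mathrm{hi}/\mathrm{lo})^{i/(n-1)}$, endpoints exact.

* **Replication scale** (`replication_scale()`): 1000 steps on
  $[0.01, 1.0]$ with a literal 0 prepended at position 0, so the lower
  grating can be switched off. It is never rotated.
* **Exercise scale** (`exercise_scale()`): 1000 steps on $[0.05, 1.0]$, no
  zero. On *every* exercise trial the scale is cut at a random position
  (`rotate_scale()`): the contrast at the cut becomes position 0 and the
  contrasts below the cut are appended at the far end. This forces an
  untrained observer to search the scale anew on each trial instead of
  reusing remembered slider positions. The cut is drawn uniformly over all
  positions — no other distribution is suggested by the design — and
  practice trials are rotated like main trials, since they mirror the main
  trials' structure.

Quantisation of an intended match onto the slider uses the nearest value in
*log* distance (`nearest_position()`): the scale is geometric, so log
distance is its natural metric. Positions are 0-based throughout.

## Protocols

`make_trial_plan()` implements "10 matches per level" as a balanced
shuffled deck — each level appears exactly `reps` times in a uniformly
random order — rather than independent draws, because the per-level counts
are exact in the design. The replication protocol runs 11 levels × 10 in
the control session (110 trials) and 6 levels × 10 under adaptation (60
trials). The exercise protocol is one seamless session: 6 unrecorded
practice trials, 60 control trials, then 60 adaptation trials, all on the
same 6 levels. One seeded RNG per session governs trial order, cut indices
and observer noise; the seed is recorded in every CSV row, and sessions
restore the caller's RNG state. In the replication design the slider is
unrotated and its initial position is not part of the record; we document
position 0 as the nominal start.

## The simulated observer

The observer is generative, not mechanistic: it implements the statistical
structure the analysis fits, $\ln m = (\beta_0 + u) + \beta_1 \ln c +
(\beta_2 + \beta_3 \ln c)A + \varepsilon$, with lognormal trial noise
($\varepsilon$ Gaussian on the log scale) and a Gaussian per-observer
intercept $u$. No contrast-gain-control front end (e.g. Naka–Rushton) or
adaptation dynamics over the 180 s induction are modelled; real observers'
generative process is unknown, and this choice makes parameter recovery
well-defined. Defaults are the reference mixed-model estimates
($\beta_0 = -0.084$, $\beta_1 = 0.982$, $\beta_2 = 0.052$,
$\beta_3 = 0.443$, $\sigma_\varepsilon = 0.2875$, $\sigma_{id} = 0.0424$),
so simulation followed by analysis targets those same numbers. Intended
matches below the smallest positive scale value clamp to it — the log-scale
model cannot produce 0 — and every recorded match is, by construction, a
value the active scale contains.

What passing tests therefore show: the pipeline recovers the parameters of
*this* observer under *these* protocols. They do not show that human data
obey the lognormal noise model, that matching noise is contrast-independent
on the log scale, or anything about induction time courses.

## Statistical analysis

Means are taken on the raw contrast scale per (observer, condition, level)
— `summarize_matches()`, sample SD with the $n-1$ denominator — and the
*means* are then log-transformed and fitted, matching the analysis order of
the reference study. Natural logarithms are used throughout; the reported
residual SD of the reference fit is consistent with the trial-level
variation only on the natural-log scale. `fit_loglog()` is invariant to the
base applied to both axes except that the intercept rescales by
$\ln(\mathrm{base})$, which the suite checks to 1e-10.

`fit_lmm()` fits the random-intercept model by **maximum likelihood** (not
REML — ML is what the reference AIC/logLik reporting implies, and it makes
the deviance/AIC identities exact). Writing
$\lambda = \sigma_{id}^2/\sigma_\varepsilon^2$, the marginal covariance is
block compound-symmetric and, for fixed $\lambda$, both the GLS fixed
effects and the profiled $\hat\sigma_\varepsilon^2$ have closed forms using
$(I + \lambda J)^{-1} = I - \tfrac{\lambda}{1+\lambda n_i}J$ per observer
block. The scalar profile likelihood is maximised by a bounded 1-D search
on $\sqrt\lambda$ (interval $[0, 50]$, tolerance 1e-9); the boundary
$\sigma_{id} = 0$ is admissible and flagged, and every likelihood
evaluation is kept as a trace for diagnosing non-convergence. Numerical
choices:

* fixed-effect covariance is the ML plug-in
  $\hat\sigma^2 (X^\top V^{-1} X)^{-1}$;
* all fixed effects use the residual df convention $n - 4$, with two-sided
  t tests and t-based 95% CIs;
* variance-component CIs are Wald intervals on the log-SD scale, from the
  numerical curvature (central differences, step 1e-4) of the profile
  likelihood in $(\log\sigma_{id}, \log\sigma_\varepsilon)$ — profile CIs
  were the open alternative; Wald-on-log is cheap, positive by
  construction, and matches the reference intervals' shape;
* AIC/BIC count $k + 2 = 6$ parameters; deviance is $-2\,\ell$;
* records with a zero matched contrast (possible on the replication
  slider) cannot enter a log-scale fit and are dropped with a counted
  warning; practice trials are always dropped;
* no multiple-testing correction is applied (none is applied in the
  reference analysis).

The suite cross-checks `fit_lmm()` against an independent ML fitter (lme4)
on simulated data and against OLS in the degenerate zero-between-variance
case, and `fit_loglog()` against an explicit normal-equations solver.

## Problem sizes and reproducibility

The Monte-Carlo recovery study simulates the reference design — 2 observers
× (110 control + 60 adaptation) = 340 records per replicate — for 200
replicates, checking that the mean interaction estimate sits within
Monte-Carlo error of the generating $\beta_3$ and that t-based 95% CI
coverage lands in [90%, 99%]. Two hundred replicates put the Monte-Carlo
SE of the mean near 0.003, small enough to detect meaningful bias while
keeping the study quick on a single CPU. All simulations are seeded; every
CSV and manifest records its seed.

## Known limitations

* No interactive data collection: mouse/keyboard handling, frame timing and
  monitor calibration are out of scope, as is the 180 s induction dynamics.
* The observer model is an assumption (see above); recovery results
  quantify the *analysis*, not human behaviour.
* With only two observers the random-intercept SD is weakly identified; its
  Wald CI is wide and the boundary estimate $\sigma_{id}=0$ occurs in a
  non-trivial fraction of simulated replicates. Fixed-effect inference is
  unaffected in the balanced designs used here.
* The packaged reference match table stores means to 4 decimals; desk
  replication of the pooled fits is exact only to that rounding.
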