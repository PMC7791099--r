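---
title: "Measuring fMRI habituation with novelty-normalized slopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fMRI habituation with novelty-normalized slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habslope)
```

## The measurement problem

Repetition-suppression paradigms present the same stimulus at a fast,
regular rate (here: 1 Hz for two minutes) and track the decline of the BOLD
response. Two features of that decline are easy to conflate: how *large*
the initial (novelty) response is, and how *fast* the signal falls away
from it. A region that starts higher has more room to fall, so a raw slope
mixes the two. `habslope` separates them: the **novelty amplitude** `a` is
the residual signal at the start of the habituation window, the **raw
slope** `b` is the OLS slope of signal on time (seconds) across the window,
and the **normalized habituation slope** is

> b′ = b / a  (per second),

which is unchanged when the residual series is rescaled by any positive
constant. More negative b′ means faster habituation; b′ near zero means the
response is sustained (failed habituation).

Division by a noisy amplitude is the pivotal modeling choice and its main
hazard: when `|a|` is small the ratio explodes. A guard flags b′ as
unreliable (and sets it to `NA`) when `|a|` falls below 5% of the run SD;
the raw slope is always reported alongside, so analyses "uncorrected for
novelty response" remain possible. An alternative correction — entering the
novelty amplitude as a covariate at the group level instead of dividing —
is compatible with the slope table this package produces
(`raw_slope_b` and `novelty_a` are both emitted per cell).

## The habituation window

The window is *data-driven but fixed*: it is detected once, on the
baseline-visit control-group mean series, and then applied unchanged to
every group and visit, so that group differences cannot leak into the
window definition. Its start is the time of peak signal after stimulus
onset (earliest volume on ties); its end is the first post-peak time at
which the signal is back at baseline, which for residual series is 0.
An exact zero-crossing is noise-fragile, so "returned" means at or below
5% of the peak amplitude (`baseline_tol_frac`, configurable). Detection
errors out rather than guessing when the peak sits at the first or last
volume, when no return occurs before the configurable cap, or when a
small-image target onset falls inside the window (the design keeps the
first 10 s target-free precisely so the window stays uncontaminated).

On clean simulated data with the default timing — peak 8 s, return 18 s —
detection reproduces the 10 s window exactly (volumes 4..9 at TR 2 s). On
cohorts simulated at the default slope means, the *control-group mean*
decays faster than the slowest individual, so the detected return can fall
earlier than 18 s (commonly 14 s); both windows lie inside the linear decay
segment of every simulated participant, so slope recovery is unaffected.

## What the simulator emulates, and what it does not

`simulate_cohort()` generates the full study: 68 controls and 70 patients
by default, two visits, three regions, one analyzed repetition run per
visit. The mean ROI signal is piecewise linear — rise from 0 to the novelty
amplitude over [0, 8 s], linear decay at rate `b′ · a` per second over
[8 s, 18 s] — and afterwards relaxes exponentially back to baseline (time
constant 4 s). The relaxation, rather than a flat plateau at the
end-of-window value, keeps the run mean near zero; this matters because
first-level residualization includes an intercept, and a large run mean
would otherwise shift every amplitude measurement. A convolved HRF train is
deliberately not simulated: the analysis only reads the window, and the
piecewise shape keeps ground truth exact.

Noise is stationary AR(1) (default marginal SD 1, coefficient 0.3),
reflecting the temporal autocorrelation of unfiltered fMRI residuals; no
temporal filter is applied anywhere, since slow signal change *is* the
quantity of interest. Left and right hemispheres share a common noise
component giving correlation ≈ `hemi_correlation` (default 0.8); the
pipeline averages hemispheres after checking that correlation. Spike
artifacts hit a volume with probability `outlier_rate`, perturbing both the
global-intensity series (by 25 SD of its noise, so the 5-SD change rule can
find them) and every ROI series (by 10 × `noise_sd`), which is what makes
the one-hot outlier regressors in the nuisance design do real work. Motion
is small mean-zero AR(1) jitter around the reference position — the
compliant-participant regime; the QC thresholds (3 mm) are essentially
never tripped by it, only by construction in tests.

Per-participant true slopes are drawn around group × visit × region cell
means (defaults: controls −0.16 / −0.12 / −0.48 at baseline and
−0.11 / −0.09 / −0.37 at follow-up for hippocampus / occipital pole / FFA;
patients −0.06 / 0.06 / −0.29 and 0.00 / 0.02 / −0.23) with total cell SD
0.3. Half of that variance (`slope_icc = 0.5`) is a stable participant ×
region component shared across visits: habituation rate is treated as an
individual trait, which is also what makes the participant random
intercept in the inference model a correct description of the generated
data — with independent draws per visit the random-intercept test would be
conservative. Novelty amplitudes are truncated normal (mean 10, SD 2,
floor 0.5); clinical and demographic variables are truncated normals and
categorical draws at the configured cell means/proportions and exist to
exercise the demographics tables and the correlation screen, not to model
psychopathology.

What the simulator does *not* reproduce: convolved hemodynamics,
physiological noise, voxel-level spatial structure (the NIfTI fixture
writer adds only iid voxel noise), motion-correlated signal bleed, face
runs, or any dependence of clinical scores on habituation (all screen
correlations are null by construction). Passing tests therefore demonstrate
that the estimators and tests are correct and calibrated on data with known
structure — not that the pipeline is robust to every pathology of real
fMRI.

One realism limit deserves emphasis. The slope SD of 0.3 per second,
combined with a 10 s window, generates some participants with strongly
positive b′ — signal *rising* throughout the window to several times the
novelty amplitude. Such shapes dominate the run variance, and
intercept-inclusive residualization then shifts their measured novelty
amplitude enough to destabilize the ratio b/a. The direct estimation path
(simulate → average hemispheres → slope) is unbiased — mean estimation
error is indistinguishable from zero at 500 participants per group — but
the full pipeline path (with nuisance regression) has heavy-tailed
estimates for those extreme draws. Real residual series do not take such
shapes; in simulation the unreliable-amplitude guard absorbs part of the
problem, and the raw slope is always available.

## QC and exclusion

Outlier volumes are defined on the *changes* of the global-intensity
series: a volume is flagged when its volume-to-volume change deviates from
the mean change by more than 5 SD of the change distribution (so the rule
is invariant to constant intensity offsets), or when motion exceeds 3 mm in
absolute translation on any axis or in frame-to-frame relative
displacement. Relative displacement is the Euclidean norm of the
translation deltas plus the arc length of the rotation deltas at a 65 mm
head radius (configurable). Note one consequence of the change-based rule:
a single-volume spike corrupts both adjacent transitions and flags two
volumes, whereas a step change flags one. The SD is taken over the whole
run rather than robustly; with a 60-volume run and the default 5× multiplier
this costs a little sensitivity when multiple spikes co-occur, and the
multiplier is exposed for anyone preferring a robust variant.

A run is excluded when ≥ 2 outlier volumes fall inside the habituation
window; outliers elsewhere never exclude (they are instead regressed out as
one-hot spike columns). Exclusion is deliberately window-scoped and
monotone — adding in-window outliers can only move a run toward exclusion —
and both properties are under test.

## Inference

Per region, `fit_group_time_model()` fits `b′ ~ group + visit +
(1 | participant)` by REML (lme4), keeping participants with a single
visit. The group effect is summarized by β (patient − control), its Wald
F = t², a denominator df, p, Cohen's d, and `100 β` as "percent slower".
The default df method is **between-within**: the between-subject (group)
effect gets `n_subjects − 2` df and within-subject effects get
`n_obs − n_subjects − p_within` — the containment-style accounting used by
mixed-model software in repeated-measures designs, and the one consistent
with a two-group longitudinal cohort reporting F(1, N − 2). Satterthwaite
df (lmerTest) are available via `ddf = "satterthwaite"`. Cohen's d defaults
to `2t/√df`; because several variants of this formula circulate for mixed
designs, the formula is a pluggable function argument rather than a
constant choice.

Within-group habituation is tested with one-sample t-tests, one-sided
toward negative means (H0: mean b′ = 0, no habituation). The clinical
correlation screen uses Spearman's rho (average ranks on ties; exact null
distribution when tie-free and small-n, AS89/t approximation otherwise)
with Holm step-down FWE correction across measures within each group ×
visit × region family — Holm rather than Bonferroni because it is uniformly
more powerful and, like Bonferroni, valid under arbitrary dependence.
Constant columns yield an explicitly undefined result rather than being
dropped. Demographic contrasts use Pearson chi-square without continuity
correction, which reproduces published two- and three-level contingency
statistics computed from percentages and group sizes; power calculations
use the noncentral t distribution for a two-sided two-sample test.

## Numerical and procedural choices

* Time is measured in seconds, not volumes, so b′ is TR-independent.
* Window indices are 0-based volume numbers (`start_index = floor(t_peak /
  TR)`), matching acquisition conventions; R-level code converts at the
  boundary.
* Peak ties break to the earliest time; the return is the *first*
  qualifying volume.
* OLS slopes and residualization use closed-form/QR linear algebra and are
  tested against brute-force normal-equations oracles at 1e-10.
* `simulate_roi_run()` refuses (by default) parameter combinations whose
  mean decay exceeds one novelty amplitude over the window
  (`|b′| · duration > 1`), which would drive the mean signal below
  −a; the cohort generator disables this check because unbounded Gaussian
  slope draws at the default dispersion legitimately exceed it, and the
  estimators remain well-defined on such series.
* Replicate-level simulation studies (e.g. the type-I-error calibration)
  draw from one continuous RNG stream (`simulate_slope_table(seed =
  NULL)` after a single `set.seed`). Reseeding the generator for every
  replicate from arbitrary integers produced measurable cross-replicate
  dependence — enough to move an exact t-test's empirical size by ±2
  percentage points — so per-replicate reseeding is not used anywhere a
  rate is being estimated.
* Problem sizes in the shipped checks: slope recovery uses 500 participants
  per group (one region, two visits); calibration uses 1000 replicates of
  30 + 30 participants at the slope-draw stage, where the quantity under
  test — the mixed model's size — lives. Both run in well under five
  minutes on a single core.

## Known limitations

* The simulator's linear-decay signal model cannot represent exponential
  habituation; fitting nonlinear decays is out of scope.
* The normalized slope is undefined when the novelty amplitude is near
  zero; such cells are flagged, not imputed.
* The between-within df method is an approximation in unbalanced designs;
  Satterthwaite is provided for sensitivity analyses.
* Voxelwise slope maps are not implemented; the unit of analysis is the
  ROI-mean series (with a small volumetric path — NIfTI image + mask —
  for extraction testing).
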