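---
title: "From heartbeat variability to hippocampal connectivity: the vagalfc pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From heartbeat variability to hippocampal connectivity: the vagalfc pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagalfc)
```

## What the package computes

`vagalfc` implements the computational chain of a classic exercise-neuroimaging
design: a 2x2 cohort (exercise vs. control group, scanned before and after an
intervention) in which vagally mediated heart rate variability and seed-based
resting-state functional connectivity of the anterior hippocampus (aHC) are
measured and related. The chain has five analysis stages plus a synthetic-data
stage that makes every other stage testable with known ground truth:

1. **Pulse-to-RR conversion** — band-pass a finger photoplethysmogram
   (0.5-5 Hz at 500 Hz sampling), detect pulse maxima, and post-process the
   resulting RR series with an adaptive artifact filter; summarize with mean
   heart rate (`60000 / mean(RR)`) and RMSSD, the root mean square of
   successive RR differences.
2. **Vagal threshold during incremental exercise** — RMSSD in a sliding
   window of 256 RR intervals with 192 intervals of overlap; the deflection
   point (DP) is the first window whose RMSSD drops strictly below
   `mean + 3 SD` of the track over the last 30% of the exercise time, and the
   vagal threshold is the stepped-protocol power active at the DP.
3. **Fitness metrics** — VO2max as the best mean of three consecutive 10-s
   bins of breath-by-breath VO2; Pmax with linear partial-stage interpolation
   on the 50 W / 3 min protocol; the aerobic threshold as the first lactate
   rise above the resting value.
4. **Seed connectivity maps** — discard the first 5 volumes, remove linear
   and quadratic trends, band-pass 0.01-0.08 Hz, regress confounds, smooth
   (6 mm FWHM whole-brain convention, 4 mm for brainstem work), extract the
   mean course of a 5-mm seed sphere (right aHC at MNI (28, -12, -20)),
   and correlate it with every voxel; maps are stored as Fisher z = atanh(r).
5. **Group inference** — voxelwise Group x Time interaction as a pooled
   two-sample t on per-subject `z(T1) - z(T0)` difference maps (identical to
   the 2x2 mixed ANOVA interaction, F = t^2); clusters formed at voxel
   p < 0.001 and tested at cluster-level FWE p < 0.05 by permutation of the
   maximum cluster size; post-hoc t-tests; a Wilks-Lambda MANOVA on the
   autonomic scalars; and the Pearson correlation between per-subject
   connectivity change over a cluster and RMSSD change.

## The generative model of the synthetic data

All inputs can be simulated with planted effects, so every downstream claim in
the test suite is a recovery of known truth rather than a comparison with an
opaque reference.

**Exercise RR series** (`gen_rr_exercise`). RR intervals are drawn as
`trend(t) + e`, with independent Gaussian deviations of SD
`local_rmssd(t) / sqrt(2)`. Because successive differences of independent
deviations have SD `sqrt(2) * sigma`, the local expected RMSSD follows the
profile exactly: a linear decline from `rmssd_start_ms` to `rmssd_floor_ms`
over `[0, dp_true_s]` and the floor afterwards. The mean-RR trend declines
linearly from `rr_rest_ms` to `rr_end_ms` over the same span and then stays
flat; saturating both trend and variability at `dp_true_s` keeps the
post-deflection tail exactly frozen when the floor is zero, which gives the
suite a sharp degenerate case. Independent Gaussian increments are the
simplest model with a closed-form RMSSD; real RR series have autocorrelation
and respiratory modulation that this generator deliberately omits, so passing
recovery tests demonstrate correctness of the estimator chain, not robustness
to physiological nuisance structure.

**PPG traces** (`gen_ppg`). One stereotyped asymmetric bump (gamma-like rise
over 150 ms, slower decay, unit amplitude, maximum exactly at the beat time)
per beat plus white Gaussian noise. Only peak timing matters downstream; no
dicrotic notch or baseline wander is modeled.

**BOLD phantoms** (`phantom_spec`, `gen_session_volume`). A small 4D grid
(default 20x20x12 voxels of 2.5 mm, 240 volumes at TR 2.52 s) of white noise
with two disjoint 8-voxel cubes: seed voxels share a latent course `u` (plus
small per-voxel noise), target voxels are `r*u + sqrt(1-r^2)*noise`, so the
planted seed-target correlation is `r`. There is no hemodynamic response
model, no physiological noise, no motion, and by default no spatial
autocorrelation (an optional Gaussian pre-smoothing flag exists because
cluster inference behaves differently on smooth fields). Normalization to a
template is out of scope: phantoms are born in a common space.

**Cohorts** (`cohort_spec`, `gen_bold_cohort`). Coupling is manipulated on the
Fisher-z scale - the scale of the downstream statistics - as
`atanh(r0) + subject trait + session noise`, with exercise-group T1 sessions
additionally shifted by `interaction_delta_z` plus subject-level
heterogeneity, then mapped back through `tanh`. In the exercise group the
per-subject coupling change is drawn jointly with the RMSSD change at
correlation `rho_fc_rmssd` (default -0.7: connectivity decreases as vagal
tone increases). Defaults plant the study's design: 17 subjects per group,
and noise scales (`delta_z_sd = 0.35`, `session_sd_z = 0.03`,
`subject_sd_z = 0.2`) chosen so that stable between-subject heterogeneity
dominates session and measurement noise - the regime in which a strong
across-subject correlation between measured connectivity change and RMSSD
change is observable at all. Volumes are materialized lazily from per-session
seeds, so a full cohort never needs to be held in memory.

## Numerical and statistical choices

**Window bookkeeping.** A track with `n` intervals, window `w` and overlap
`o` has exactly `floor((n - w) / (w - o)) + 1` windows; each window is
timestamped with the mean beat time of the beats it spans (the alternatives -
last or central beat - move the DP by at most half a window and are not
exposed). Per-window RMSSD uses the n-1 sample convention through cumulative
sums, and is tested for exact equality against the direct estimator.

**Deflection-point rule.** "Drops below" is read as strict `<` on the first
forward scan, with an optional `sustain_windows` argument for requiring
consecutive sub-threshold windows (default 1: the rule as stated). The last
30% of exercise time is measured on the clock-time axis of window centers,
the tail SD uses the n-1 denominator, and a track that never crosses raises a
typed not-found condition rather than clamping to the end of exercise. The
vagal threshold reports the stepped stage power active at the DP
(piecewise-constant, not interpolated), mirroring the protocol's stepped
nature; the first exercise stage carries the 50 W start power, so stage `k`
(0-based, 180 s each) maps to `50 + 50k` W.

**Filters.** The pulse band-pass is a 4-pole Butterworth applied forward and
backward (`signal::filtfilt`), i.e. zero-phase with squared magnitude; at
500 Hz and 0.5-5 Hz this is numerically stable and passes a 2 Hz tone within
5% while suppressing 0.05 Hz drift by more than 20 dB. The BOLD band-pass is
instead an FFT projection (zero the DC and all out-of-band bins): at a
sampling rate of only ~0.4 Hz and ~235 samples, IIR edge transients are long
relative to the series, whereas the spectral projection is exactly zero-phase
with unit in-band gain, and it is the convention of the resting-state tools
this stage mirrors. Temporal preprocessing order is detrend, band-pass, then
confound regression; if confounds are regressed after filtering they should
be filtered identically (the package leaves confound preparation to the
caller, which the tests exercise by constructing confounds on the filtered
scale).

**Seed geometry and Fisher z.** Sphere membership is decided by voxel centers
in world space with an inclusive radius; a 5-mm sphere centered on a voxel
center of a 2.5-mm grid therefore contains exactly the 33 offsets with
`i^2 + j^2 + k^2 <= 4`. Correlations with `|r| >= 1 - 1e-12` are clipped
before `atanh` and counted; zero-variance voxels get `z = 0` and are masked
out instead of propagating NaN.

**Cluster-level inference.** The original analysis used parametric
random-field-theory FWE correction; this package substitutes subject-level
permutation of the maximum cluster size - a standard, assumption-light
equivalent that needs no smoothness estimation. Difference maps are
recomputed under random group relabelings (vectorized over all permutations),
clusters are formed at `|t| > qt(1 - 0.001, df)` with 26-connectivity (the
SPM convention; 6 and 18 available), positive and negative clusters are kept
separate, and `p_fwe = (1 + #{max >= observed}) / (n_perm + 1)` so that the
observed labeling is counted and p is never zero. When fewer distinct
labelings exist than requested permutations (e.g. 2+2 subjects: C(4,2) = 6)
they are enumerated exactly. The MANOVA uses Wilks' Lambda with Rao's F - the
SPSS default - computed on T1-T0 difference vectors, which reduces exactly to
the univariate ANOVA with one variable.

**Degenerate inputs.** Flat difference maps yield t = 0 (not NaN); paired
tests on constant differences yield an infinite or NaN statistic with a
`degenerate` flag; the adaptive RR filter warns and flags when more than 20%
of intervals are replaced; `aerobic_threshold` with `delta = 0` is documented
as noise-sensitive.

## Problem sizes used by the test suite and acceptance script

Recovery claims are simulation-based, and the suite fixes its own scales:
deflection-point recovery uses 700-s profiles (so the last-30% tail holds at
least three sliding windows, enough for a stable mean + 3 SD threshold) with
floors at 3 ms and true deflections at 300/360/420 s; coupling recovery uses
50 phantoms of 240 volumes; FWER validity uses 20x20x12 phantoms with 80
analyzed volumes per session - the false-positive rate of a null cohort does
not depend on the series length, so the shorter series buys many more
cohorts - at 17+17 subjects and 500 permutations, on the 6-mm-smoothed
stream: on unsmoothed white noise the max-cluster-size statistic is so
discrete (null sizes 0-3) that the attainable significance levels skip the
nominal 0.05 entirely and the test is degenerately conservative, whereas on
the pipeline's smoothed maps the null size distribution is rich and the
attained rate sits near nominal; the end-to-end power runs
use 16x16x10 phantoms with 150 analyzed volumes, a planted 8-voxel
interaction of standardized size d = 1.5 (translated to a Fisher-z shift
analytically from the generator's change-SD, never tuned), and a planted
DeltaFC-DeltaRMSSD correlation of -0.7.

## What passing tests do and do not show

The synthetic generators are intentionally minimal. Recovery of planted
couplings, deflection points and correlations demonstrates that the
estimators, bookkeeping and inference machinery are correct and that the
permutation test controls its error rate on exchangeable data. It does not
demonstrate robustness to head motion, physiological aliasing, spatial
nonstationarity, non-Gaussian HRV dynamics, or registration error - none of
which are modeled. The MANOVA and post-hoc procedures are implemented and
verified against matrix oracles, but published cohort-specific statistics
cannot be reproduced without the original subject data.

## A worked example

```{r, eval = FALSE}
set.seed(1)
# 1) an incremental test: detect the vagal threshold
prof <- rr_profile(duration_s = 700, dp_true_s = 420, seed = 1)
beats <- gen_rr_exercise(prof)
track <- sliding_rmssd(beats)
vt <- deflection_point(track, exercise_start_s = 0, exercise_end_s = 700)
vt <- vt_at_dp(vt, stage_ramp(n_stages = 6))
vt

# 2) a small imaging cohort with planted effects
ph <- phantom_spec(shape = c(16, 16, 10), n_volumes = 155, coupling_r = 0.5,
                   seed = 7)
cs <- cohort_spec(n_per_group = 17, interaction_delta_z = -0.55,
                  rho_fc_rmssd = -0.7, seed = 8)
co <- gen_bold_cohort(ph, cs)
fc <- cohort_zmaps(co)
clusters <- permutation_cluster_fwe(fc, n_perm = 500, seed = 9)
head(as.data.frame(clusters))

# 3) relate connectivity change to RMSSD change in the exercise group
tab <- co$table
ex <- tab$group == "exercise"
drmssd <- tab$rmssd_ms[ex & tab$session == "T1"] -
  tab$rmssd_ms[ex & tab$session == "T0"]
delta_correlation(fc, attr(clusters, "voxels")[[1]], drmssd)
```

## Known limitations

* The adaptive RR filter is a running-median/MAD rule reproducing the purpose
  of the published adaptive filters (artifact replacement) rather than any
  specific published recursion; window and threshold are configurable.
* Motion correction, slice timing, segmentation and template normalization
  are out of scope; volumes are assumed spatially aligned.
* Only time-domain HRV is provided; frequency-domain indices are not used by
  this analysis chain.
* The lactate-based anaerobic threshold (maximal lactate steady state) is an
  external input, not computed; the aerobic threshold's "first rise" needs a
  numeric delta (default 0.5 mmol/l, typical assay noise).
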