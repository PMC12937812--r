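---
title: "Simulating closed-loop motor-imagery neurofeedback: models, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop motor-imagery neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfsim)
```

# The paradigm being simulated

`nfsim` simulates a classifier-based real-time fMRI neurofeedback session
and its full analysis chain. A session has six runs: two paced finger-tapping
runs used to train a tapping-vs-rest decoder, two motor-imagery
neurofeedback runs in which the decoder's volume-by-volume output drives a
visual display (a cross that flashes when motor circuits appear engaged),
and two final tapping runs that serve as a held-out positive control for the
decoder and as the post-training behavioral measurement. Tapping runs
alternate six 28–32 s tapping blocks (three at 1 Hz, three at 4 Hz) with six
rest blocks, starting at rest; imagery runs open with two practice blocks
(one per condition, displaying ideal feedback) followed by six alternating
"imagine tapping" (ITAP) and "do not imagine tapping" (noITAP) blocks. Runs
are 210 volumes at TR 2 s; block time fills the front of the run and the
remainder is unlabelled scan time.

Because no public data exist for this paradigm, the package generates its
own sessions with known ground truth, which turns every downstream claim
into a testable recovery problem.

# The synthetic BOLD model

Each voxel time course is

\[
y_v(t) = \beta_0 + a_{c(t)}\,[u_c \ast h](t)\,\mathbf{1}[v \in M]
 + b_v t + \mathbf{m}(t)^\top \boldsymbol{\gamma}_v + \varepsilon_v(t),
\]

where \(h\) is the canonical double-gamma HRF (delays 6 s and 16 s,
dispersions 1, peak:undershoot 6:1, 32 s support, peak-normalized against
the continuous maximum so sampling at any dt gives consistent values),
\(u_c\) is the condition boxcar, \(M\) is the planted motor network (three
blobs standing in for M1, SMA and cerebellum, ~115 voxels of a ~940-voxel
analysis mask on the default 16×16×10 grid), \(b_v\) a per-voxel linear
drift, \(\mathbf{m}\) six random-walk motion series with weak spatial
coupling \(\boldsymbol{\gamma}_v\), and \(\varepsilon\) white Gaussian noise
(an AR(1) option exists, off by default). Tapping amplitude defaults to
CNR 1.0 (amplitude equal to the noise SD on a baseline of 100); the
contrast-to-noise of block designs is high after spatial smoothing, so this
is a realistic, not a generous, setting. Imagery amplitude is 0.6× the
tapping amplitude, scaled per subject — the study design does not constrain
overt-vs-imagined amplitude, so it is an explicit parameter.

The analysis mask is the brain mask minus a visual-cortex exclusion region.
The exclusion region is defined on a finer grid and resampled with the rule
that a functional voxel is retained when at least 20% of its volume is
covered — the resampling convention real masking pipelines use, exercised
directly by the tests.

## Cohorts and the behavior coupling

A cohort draws, per subject, a lognormal imagery-amplitude factor
(sdlog 0.5, mean 1: imagery ability varies a lot across people, consistent
with the large spread of neurofeedback performance), and a tapping
improvement latent correlated with that amplitude at exactly the configured
`coupling_strength`. The improvement is expressed in behavior: tap-timing
jitter is set per run so that expected RMSE matches run-level targets
(0.038/0.024/0.023/0.033 Hz at 1 Hz; 0.056/0.062/0.061/0.065 Hz at 4 Hz,
with a multiplicative between-subject spread of sdlog 0.35), and the run-5
target is the run-2 target minus the subject's planted improvement
(latent SD 0.010 Hz at 1 Hz, 0.020 Hz at 4 Hz, mean 0.001 Hz). Taps are
nominal-interval events with Gaussian timing jitter and a 1% independent
miss probability. An ICARS-like clinical covariate (N(40,15), clipped to
0–100) is drawn independently as the control covariate.

# Behavioral scoring

The instantaneous rate of each tap is the reciprocal of the time since the
previous tap. The RMSE score pools, over the same-speed blocks of a run,
the deviations of instantaneous rates from the instructed rate — but
intervals flagged by the missed-tap rule are excluded. The two metrics
partition the behavior: a gap of duration \(\Delta t\) contributes
\(\max(0, \mathrm{round}(\Delta t \cdot r) - 1)\) missed taps (edge gaps at
block start and end included; an empty block contributes its full ideal
count), and only gaps below that threshold contribute rate errors. The
separation matters quantitatively: at 1 Hz a single skipped tap produces a
−0.5 Hz rate error whose square dwarfs the timing jitter, so an RMSE that
included inactivity gaps could not sit at millihertz scale while missed
taps are at the percent level — yet that is exactly the regime the
behavioral literature reports. Improvement is `rmse(run2) − rmse(run5)`,
positive when error decreased after neurofeedback.

# Decoder training

Training volumes from runs 1–2 are preprocessed offline: per voxel,
intercept, linear trend and the six motion series are regressed out over
the whole run, then volumes are smoothed at 1.5 voxels FWHM (the 6 mm
equivalent). Per-TR labels come from the schedule (either tapping speed →
"tap"), shifted by `label_shift_trs` volumes to respect hemodynamic delay.
The default shift is 3 TRs (6 s): the canonical HRF's block response
crosses half its plateau 5.2 s after block onset, so at TR 2 s a 3-volume
shift aligns the label flip with the sign change of the response. Two
volumes on each side of every label change are additionally censored from
training (`censor_trs = 2`): transition volumes sit mid-ramp, their shifted
labels are unreliable, and a separable classifier forced to fit them does
so through noise voxels, destroying the interpretability of the weight map.

The decision rule is a linear soft-margin SVM over analysis-mask voxels
(visual-exclusion voxels therefore carry exactly zero weight). The default
penalty is deliberately small (`cost = 0.001`). For this data the problem
is separable, so any cost above ~0.01 returns the hard-margin solution,
whose weights are dominated by the noise components of a handful of support
vectors — decoding survives, but the weight map does not resemble the
planted network at any CNR. In the strongly regularized regime the
discriminant approaches the class-mean difference, which stabilizes both
the map (top-decile weights recover the planted network at Dice ≈ 0.9) and
held-out accuracy. LIBSVM orients decision values toward whichever class
appears first in the data; the trainer re-orients so positive always means
"tap".

# The online pathway

Real-time decoding cannot use the whole run: the package mirrors the
incremental contract in `online_preprocess()` — nuisance coefficients are
estimated only on the volumes acquired before the current one, then used to
residualize the current volume at its own time point. Three conventions
make this numerically faithful to the offline pathway:

* **Task protection.** The known task structure (HRF-convolved condition
  boxcars from the schedule) is included in the estimation design so the
  intercept and trend do not absorb task variance; without it, the
  extrapolated trend tracks the block structure and noiseless online
  decoding drops from ~92% to ~73%. Only the task regressor's own
  [intercept, trend] projection is subtracted from the volume, which is
  exactly the component offline detrending removes, so online residuals
  converge to offline residuals as the history grows.
* **Graduated model.** The model grows with the history — intercept and
  task from 4 volumes, linear trend from 16, motion from 40 — because a
  10-parameter fit on a dozen volumes amplifies noise. A task regressor
  enters only once its variance beyond the current nuisance subspace
  exceeds a tolerance (SD > 0.05); before that its coefficient is not
  identifiable and near-collinear fits produce arbitrarily large
  coefficients.
* **Cold start.** Until the history contains both conditions, baseline and
  task level are not separately identifiable, and decodes reflect the cold
  start rather than the classifier. Imagery runs solve this by design: the
  two practice blocks exist precisely to kick-start the online analysis,
  and scoring begins after them. The held-out tapping runs have no practice
  blocks, so `evaluate_held_out()` excludes a 32-TR warm-up (one rest +
  tapping cycle at the longest block length) from scoring; the exclusion
  length is a parameter.

Feedback replay (`run_feedback()`) drives the display at TR *t* from the
decode of volume *t − latency*, with a 2-TR (4 s) acquisition-to-display
latency by default. Practice TRs always show the ideal pattern and are
unscored. Each non-practice imagery TR is scored by what the display did on
that TR: ITAP and flashing is a true positive, noITAP and static a true
negative, and the accuracies are tp/(tp+fn), tn/(tn+fp) and
(tp+tn)/all — with equal class TR counts the overall accuracy is exactly
the mean of the class accuracies. No hemodynamic shift is applied to
scoring labels; the display-vs-block agreement is the quantity of interest.

# GLM and group analysis

First-level designs convolve condition boxcars (tapping runs) or 1-TR stick
functions (imagery events: "true ITAP" TRs vs all other imagery TRs) with
the canonical HRF, plus intercept and polynomial drift; rank-deficient
designs are rejected naming the offending column. Fits are ordinary least
squares per voxel; analysis smoothing defaults to 2 voxels FWHM (8 mm
equivalent). Group maps are voxelwise one-sample t (df n−1; zero-variance
voxels yield NA, not infinity) and the improvement-covariate t from
[intercept, ΔRMSE, control] regression (df n−3; a constant control reduces
to the two-column fit). The covariate defaults to the mean of the 1 Hz
improvement and half the 4 Hz improvement: both speeds index the same
latent ability on different scales, and averaging halves measurement noise.

Cluster-extent thresholding keeps voxels below the voxelwise p (one-sided
positive by default, configurable two-sided) and discards face-connected
components smaller than k. Face (6-neighbor) connectivity is the default
for determinism and simplicity; 18-connectivity is available. The extent
thresholds are inputs — 17/16/15 voxels for tapping/imagery/covariate maps
as reference presets — because the "expected voxels per cluster" quantity
depends on search volume and smoothness and is not re-derived here.

## Calibration and a power ceiling

Under null coupling the covariate map's voxelwise false-positive rate at
p < 0.001 sits inside the binomial band (checked over 20 cohorts with
unsmoothed first levels, which keeps voxels independent so the binomial
reference is exact; smoothing leaves the marginal rate unchanged but
correlates voxels).

Recovery of a planted coupling has a hard ceiling that users should know
about: with n = 16 subjects and one control covariate, the one-sided
p < 0.001 threshold (t = 3.85 at df 13) corresponds to a sample partial
correlation of 0.73. At a true coupling of 0.8 the chance that a cohort's
realized correlation clears that bar is only ≈ 0.72 — per-cohort detection
is a coin weighted by sampling variability in the cohort itself, not by
implementation quality. In our seeded calibration runs, 6–7 of 10 coupled
cohorts produce a suprathreshold covariate cluster overlapping the planted
network; the failing cohorts have realized correlations of 0.60–0.73,
undetectable at that threshold in principle. This is a faithful property of
small-sample covariate mapping at strict uncorrected thresholds.

# Behavioral statistics conventions

* `one_sample_t()` accepts raw samples or (mean, sd, n) with identical
  results, so published group results can be recomputed from summary
  statistics alone.
* `rm_anova()` implements one- and two-factor fully within-subject ANOVA
  through orthonormal effect contrasts. Mauchly's sphericity test uses the
  Box two-term series (via `stats::mauchly.test` on the contrast space; a
  one-term approximation differs in the third decimal), and the
  Greenhouse–Geisser epsilon is applied to the dfs only when Mauchly
  rejects at 0.05 — with two-level factors sphericity is vacuous and no
  correction applies. F, epsilon and corrected dfs agree with `car::Anova`
  to 1e-8 (an independent cross-check in the test suite).
* `wilcoxon_signed_rank()` reports the tie- and continuity-corrected normal
  Z (the SPSS/`wilcox.test` convention). Against full enumeration its
  worst-case two-sided-p error is ≈0.036 at n = 6, shrinking below 0.02 by
  n = 9 — an inherent property of the approximation, documented rather than
  patched.
* `spearman_rho()` rank-averages ties and uses the t approximation with
  n − 2 df.

# What the simulation does and does not emulate

The generator reproduces the statistical structure the analysis depends on:
block timing, HRF dynamics, drift and motion nuisance, white (optionally
AR(1)) noise, behavioral precision at published magnitudes, and a
cohort-level coupling between imagery ability and motor improvement. It
does not emulate anatomical geometry, physiological (cardiac/respiratory)
noise, strategy failure or non-compliance, imperfect motion correction
(motion enters as known regressors, matching a pipeline where realignment
is solved upstream), or slice-timing offsets (the correction hook is a
no-op on synthetic data). Passing tests therefore demonstrate that the
analysis chain is correct and calibrated for data with this structure — not
that decoding accuracy on real patients would reach the simulated ~97%;
with real noise sources the study-scale accuracies (~58% imagery, ~68%
held-out) are the realistic regime.

# Problem sizes in the test suite

The shipped tests run the full study conditions where a claim depends on
them — 16×16×10 grids, 210 volumes, 16-subject cohorts, 10-seed decoder
recovery, 20 null cohorts, 1000-replicate behavioral oracles and ANOVA
nulls — and drop to small crafted fixtures (tiny grids, hand-built tap
streams, function-valued decoders) wherever the property is structural
rather than statistical. A full `run_study()` at default scale takes about
a minute on one core.
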