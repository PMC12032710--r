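---
title: "Muscle synergy analysis for assisted sitting-standing transitions: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Standing up from a chair and sitting down are balance-critical transitions.
Rollators (four-wheeled walkers) are prescribed to make them safer, yet they
are also associated with falls, and it is poorly understood how handle
support reorganizes movement coordination. One productive lens is muscle
synergy analysis: multi-muscle surface EMG is factorized into a small number
of modules, each combining an activation time course with a vector of
relative muscle contributions, and changes in coordination appear as changes
in module structure, timing or weighting.

`synergykit` implements a complete analysis chain for this setting: a
30-channel EMG montage (14 bilateral muscles plus erector spinae and rectus
abdominis) recorded while participants stand up (sit-to-stand) or sit down
(stand-to-sit) under three support conditions — unassisted (UA), light touch
(LT, palm on the handles for a haptic cue), and full support (FS, power grip
with load transfer) — on a normal or compliant (balance-pad) floor, using
one of several kinematically defined movement strategies (e.g. forward
leaning, hybrid, vertical rise). Strategy labels are inputs to this package,
not outputs: kinematic classification is out of scope.

Because no public recordings accompany this problem setting, the package
ships a synthetic-data generator that emulates the full study structure with
known ground truth, so every downstream stage is testable without downloads.

# The two synergy models

Let $M^s \in \mathbb{R}_{\ge 0}^{101 \times 30}$ be the time-normalized,
amplitude-normalized envelope matrix of trial $s$ (101 time samples, 30
muscles). All trials of one movement × floor × strategy group are
concatenated column-wise.

**Temporal synergies.** The trial-independent part is a set of $N$
activation profiles $C_n \in \mathbb{R}_{\ge 0}^{101}$, shared by all trials
of the strategy; the trial-dependent part is a weighting vector per synergy
and trial:

$$M^s \approx \sum_{n=1}^{N} C_n \, w^s_n, \qquad w^s_n \in
\mathbb{R}_{\ge 0}^{1 \times 30}.$$

The NMF input is the $101 \times 30\,\mathrm{tr}$ matrix of trials side by
side.

**Spatial (synchronous) synergies.** The roles are swapped: fixed
muscle-weighting vectors $W_n \in \mathbb{R}_{\ge 0}^{30}$ combine with
trial-dependent activation profiles; the input matrix is
$30 \times 101\,\mathrm{tr}$.

Both are fitted with non-negative matrix factorization under Frobenius loss
using standard multiplicative updates. The protocol defaults are 50 random
restarts and a 3000-iteration cap per restart; the restart with the lowest
final objective is kept. We stop a restart early when the relative objective
decrease over 10 iterations falls below $10^{-6}$; the objective is
non-increasing by construction, which the test suite asserts on the traces.
Initial factors are uniform random, scaled to the data magnitude, and every
restart draws from its own seeded stream.

**Scale convention.** NMF factors are only determined up to a per-component
scale. We store trial-independent factors at unit maximum and fold the scale
into the trial-dependent counterpart. This changes no reconstruction
(asserted to $10^{-10}$) and makes profiles comparable for timing analysis
and weightings comparable across synergies for the statistics stage.

**Identifiability.** With strictly positive weightings, overlapping profiles
admit a continuum of equivalent factorizations (additive mixing). Realistic
muscle weightings are sparse — each synergy engages a subset of muscles —
which bounds the mixing and makes recovery well posed. The generator's
default weightings are therefore sparse (each synergy activates each channel
with probability 0.6, with guards so no channel or synergy is empty), and
parameter-recovery tests confirm cosine similarity > 0.99 between recovered
and planted profiles on noiseless data.

# Model-order selection

A fivefold cross-validation over whole trials (80:20 train/test; trials are
never split across folds, and folds are stratified by support condition when
metadata is available) guards against overfitting single trials: synergies
are extracted from the training trials, the trial-independent factors are
frozen, the trial-dependent factors for the held-out trials are obtained by
non-negative least squares (one NNLS solve per held-out column), and the
held-out reconstruction quality is

$$R^2 = 1 - \mathrm{SSE}/\mathrm{SST},$$

where SST sums squared deviations from the mean vector. "Mean vector" is
read as the per-row mean (each time sample, or each muscle, keeps its own
mean); a grand-mean variant is available behind the `center` argument of
`compute_r_squared()`, defaulting to per-row.

Two selection criteria operate on the across-fold mean of the $R^2$ curve:

* **Knee criterion.** Straight lines are fitted to the curve over
  $[N_k, N_{30}]$ for $k = 1, 2, \dots$, iteratively removing the smallest
  candidate; the selected order is the first left endpoint whose regression
  mean squared residual drops below $10^{-4}$ — the point beyond which the
  curve is approximately straight. Constructed piecewise-linear curves are
  recovered exactly in the tests.
* **Global/local criterion** ($N^*$). The smallest $n$ with mean
  $R^2 \ge 0.9$ and increment $R^2_n - R^2_{n-1} < 0.05$. We define
  $R^2_0 = 0$, so a curve that is already above 0.9 at $n = 1$ fails the
  local criterion there (the jump from 0 exceeds 0.05) and selects $n = 2$.

**Compactness.** For a representation with $n_t$ temporal and $n_s$ spatial
synergies over $T = 101$ samples and $M = 30$ muscles, the temporal model
stores $T n_t$ trial-independent plus $n_t M$ per-trial values, the spatial
model $n_s M$ plus $T n_s$. `compactness_summary()` tabulates these counts
and `compare_model_counts()` summarizes the spatial-minus-temporal order
difference as mean ± sample SD across datasets.

# Matching activation profiles across movement strategies

Within one movement × floor task, the unit-maximum temporal profiles of all
strategies (taken from the knee-selected models) are pooled and clustered
with k-means (k-means++ seeding, Euclidean metric on the 101 samples, best
of 50 restarts by within-cluster sum of squares, 1000-iteration cap). The
number of clusters is increased from one until two constraints hold:

1. every profile correlates (Pearson) at least 0.9 with its cluster
   centroid, and
2. no cluster contains two profiles from the same strategy.

A cluster holding one profile is a strategy-specific synergy. The
all-singleton partition is always valid, so the search terminates. Euclidean
distance drives the clustering and the correlation is only a validity check,
keeping the two roles separate; clustering operates on unit-max profiles
because NMF scale is arbitrary. Cluster identity across repeated runs (10 by
default) is compared by a label-invariant canonical signature; the agreement
fraction over run pairs is reported, and disagreement warns rather than
fails. Clusters are finally ordered chronologically by centroid peak index,
ties broken by the earlier ascending half-maximum crossing.

# Activation timing: FWHM

The duration of a temporal synergy is the full width at half maximum of its
main peak (global maximum, ties to the earliest sample). Half-height
crossings are searched contiguously outward from the peak, so secondary
bumps never extend the width, and are localized with sub-sample precision by
linear interpolation. One inter-sample step equals 1% of the normalized
movement duration. Since the movements are sequential, boundary synergies
(no crossing before sample 0 or after sample 100) are measured one-sidedly
from the movement start or to the movement end and flagged. A
constant-positive profile yields width 100 with both flags and a warning.

# Statistics: support effects on muscle weightings

For each synergy of a strategy, the 30-channel trial weightings are reduced
to 16 muscles (left/right averaged for the 14 bilateral muscles; ES and RA
kept single, RA last) and stacked into one response column per trial — the
stacked-response realization of a multivariate mixed model with a single
residual variance and a participant random intercept:

$$\mathrm{Weightings}_{tp} = \beta_{0p} + \beta_1 \mathrm{LT}_{tp}
 + \beta_2 \mathrm{FS}_{tp} + \epsilon_{tp}, \qquad
 \beta_{0p} = \gamma_{00} + u_{0p}.$$

Support enters by reference (dummy) coding; the model is fitted twice, with
UA and with LT as the reference group, so all three pairwise contrasts are
tested. Estimation is maximum likelihood (`lme4::lmer`, `REML = FALSE`);
fixed effects are tested two-sidedly with t statistics on residual degrees
of freedom. The reparameterization identity
$\beta_{FS}^{(LT)} = \beta_{FS}^{(UA)} - \beta_{LT}^{(UA)}$ is asserted in
the tests. Within a strategy the significance level is Bonferroni-corrected
for $2 \times$ (number of synergies) stage-1 tests.

If stage 1 is significant, a second model adds the muscle factor and its
interaction with support, `response ~ (LT + FS) * muscle + (1 | participant)`,
with effect (sum-to-zero) coding of the 16 muscles and RA as the implied
reference level; at most three follow-up tests are corrected accordingly.
The interaction t-tests localize which muscles change with support relative
to the grand mean. Residual diagnostics (skewness, Shapiro-Wilk on at most
5000 residuals, a Spearman association between fitted values and absolute
residuals) are advisory only and never gate the analysis. A heteroscedastic
per-muscle residual extension would be a natural refinement; the stacked
single-variance reading follows the printed model formula and is the
default.

# The synthetic-data generator

The generator is first-class, tested code. Its defaults emulate the study
design: 20 participants × 2 movements × 2 floors × 3 supports × 3
repetitions (18 trials per participant and movement; 720 in total), with a
strategy inventory per movement × floor task of (7, 6, 6), (10, 8),
(8, 8, 8) and (7, 7) synergies and a fixed strategy per participant × task
(optionally re-drawn per support condition to emulate support-induced
strategy switching).

* **Profiles** are truncated Gaussians on the 0–100% grid at unit maximum,
  so FWHM is analytically known. Default peak times are evenly spaced and
  default widths grow from $\sigma = 4$ at mid-movement to $\sigma = 11$ at
  the boundaries, reproducing the empirical pattern of narrow activation
  near seat-off/seat-on and broad activation at movement start and end.
  The mid-movement width also respects the measurement chain: a 10 Hz
  envelope low-pass smears bumps much narrower than ~100 ms.
* **Weightings** per trial are the sparse baselines times muscle-group
  support factors times lognormal jitter with unit mean
  (meanlog $= -\sigma^2/2$), so non-negativity is structural and planted
  support ratios are recovered in expectation (verified by Monte Carlo
  against the closed form).
* **Support effects** default to UA (1, 1, 1), LT (1.3, 0.95, 1), FS
  (2.2, 0.75, 1) for (upper body, lower limb, trunk). Full support shifts
  load into the arms, so upper-body weightings rise steeply while lower-limb
  weightings drop moderately; the asymmetry means full support changes the
  overall weighting magnitude, not merely its distribution, which is what
  makes a stacked mean-shift test (stage 1) sensitive to it. No published
  per-muscle magnitudes exist for this setting; these are free parameters
  chosen once as plausible, not calibrated to any recording.
* **Envelope noise** is additive zero-mean Gaussian, clipped at zero, with
  SD defaulting to 3% of each channel's own activity range — per-channel
  scaling keeps weak muscles from drowning in noise sourced from strong
  ones.
* **Raw recordings** modulate a zero-mean band-limited (20–450 Hz) noise
  carrier with the envelope mapped onto wall-clock time, add 50 Hz hum (2%
  of channel range) and, on ES/RA, periodic QRS-shaped ECG artifacts (30% of
  channel range at 1.2 Hz). Upper-body and trunk channels sample at 1500 Hz,
  lower-limb channels at 4000 Hz, mirroring a two-system acquisition setup.
  Kinetic traces are phenomenological: seat force unloads (or loads)
  smoothly between movement start and seat-off (seat-on), vertical GRF is
  its complement plus a transition bump, and the CoM follows a trapezoidal
  velocity profile (0.1 s ramps). There is no forward dynamics simulation
  and no kinematics beyond the vertical CoM.
* **Randomness** flows from one integer master seed through
  `split_seed(seed, key)`, a 31-bit string-keyed hash, so every trial,
  restart and stage has its own reproducible stream and all derived seeds
  stay below $2^{31}$.

What the generator does *not* emulate — electrode crosstalk, fatigue,
movement artifacts, non-stationary carrier spectra, inter-muscle noise
correlation, realistic strategy kinematics — bounds what passing tests
show: they validate the algorithms against a faithful model of the data
*structure*, not against the idiosyncrasies of real EMG.

# Preprocessing operationalization

Raw EMG is band-pass filtered 20–500 Hz and notch filtered at 50 Hz with
zero-lag 4th-order Butterworth responses (order-2 designs applied
forward-backward; the notch is a narrow 49–51 Hz band-stop). Our
forward-backward filter pads with odd reflection, with a pad long enough to
absorb the notch's ring-in. ECG artifacts on the trunk channels are removed
by template matching: QRS-like events are detected on a smoothed rectified
signal (threshold: median + 3.5 robust SDs, 0.4 s refractory period,
borderline detections pruned below 60% of the median beat prominence), a
muscle- and participant-specific template is the mean of beat-aligned ±60 ms
windows across all of the participant's trials, and each beat is subtracted
after least-squares scaling to its local window. Envelopes are full-wave
rectified and low-pass filtered at 10 Hz (zero-lag), with small negative
filter undershoots clipped at zero so the NMF input is well defined.

Movement events come from the kinetic traces: standardized vertical GRF,
seat force, CoM position and CoM velocity (on a common 100 Hz grid) are
clustered into three phases with k-means++; labels are median-smoothed; the
contiguous middle phase marks the movement. Because cluster boundaries are
biased towards the middle of a transition, the boundaries are refined
outward while the CoM velocity stays above a noise-aware threshold (5% of
the mid-phase peak, or 4 robust SDs of the resting velocity, whichever is
larger). The seat transition is the time the seat force crosses 2% of the
seated weight (configurable): reaching zero for seat-off, leaving zero for
seat-on. Windows run from 0.2 s before movement start (muscles activate
before visible movement) to movement end and are resampled to 101 points by
cubic spline on each channel's own time base, so the two acquisition rates
need no prior common-rate resampling. Finally, envelopes are
amplitude-normalized per muscle and participant to the maximum across all of
that participant's trials; identically zero muscles are left unscaled and
flagged. Trials with corrupt channels are an input-level exclusion, not
detected here.

# Problem sizes and numerical choices in the tests

The protocol constants above (order range 1–30, 5 folds, 50 restarts, 3000
iterations, correlation 0.9, 10 repeats, $\alpha = 0.05$) are package
defaults. The test suite and the acceptance script run the same code at
desk scale, chosen for fast feedback: 3–5 planted synergies, 8–10 trials per
strategy, order range 1–6, 2–5 restarts, a few hundred iterations, cohorts
of 4–8 participants; mixed-model calibration uses 500 null replicates and
200 effect replicates on 8-muscle stacked tables. These sizes are the
package's own choice of test scale; all conclusions they support (exact
recovery, calibration, determinism) are scale-free properties of the
algorithms.

Degenerate inputs are handled explicitly: all-zero NMF input, all-zero
profiles, constant data (undefined $R^2$), single participants (random
intercept unidentifiable), too few trials for the fold count, too few
detected heartbeats, still kinetic traces — each raises an informative
error naming the offending object.

# Known limitations

* The knee criterion depends on the order range: truncating at a small
  maximum order flattens the regression and can shift the knee.
* The stacked stage-1 model tests an overall weighting shift; a pure
  redistribution between muscle groups that preserves the stacked mean is
  only detectable in stage 2, and stage 2 is gated on stage 1.
* k-means matching with a hard correlation threshold is sensitive near the
  0.9 boundary; the robustness check reports, but does not resolve,
  ambiguous assignments.
* The event detector is designed for clean single-transition trials;
  hesitations or double seat contacts would need a more structured model.
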