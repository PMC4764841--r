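---
title: "Decoding attempted hand movements from slow MEG fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attempted hand movements from slow MEG fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfdecode)
```

## The problem

Severely paralysed patients — for example after brachial plexus root
avulsion — retain cortical motor representations even when the limb cannot
move. Magnetoencephalography (MEG) picks up the *movement-related cortical
field* (MRCF): a slow magnetic deflection that builds up from roughly a
second before a movement attempt, peaks shortly after it, and whose
amplitude and topography depend on the attempted movement type. `smfdecode`
implements a complete decoding pipeline around this signal: feature
extraction, movement-type and movement-intention classification, onset
detection for real-time use, a simulated closed-loop prosthetic-hand
session with exact evaluation statistics, and a simplified distributed
source-imaging stage. A forward-modelled synthetic generator stands in for
patient recordings, so every stage is testable end to end.

## The slow movement field

The decoding feature is deliberately simple. With 84 parietal sensors
sampled at 1000 Hz, the slow movement field (SMF) at time $t$ is

$$\mathrm{SMF}_c(t) \;=\; \frac{\bar{x}_c[t-500, t) - \mu_c}{\sigma_c},$$

the 500-ms time-average of each parietal channel, z-scored by the
per-channel mean $\mu_c$ and standard deviation $\sigma_c$ of the first
50 s of the session (a task-free head segment). Two conventions matter and
are fixed package-wide:

* **Causal labeling.** A feature labelled $t$ uses samples from
  $[t-500, t)$ ms only. The real-time path computes "the latest SMF" every
  200 ms; it must never read future samples, so the offline grid inherits
  the same convention and offline and online features agree bitwise on the
  same data (this is a tested invariant).
* **Band powers are normalized symmetrically.** Alpha (8–13 Hz), beta
  (13–30 Hz) and high-gamma (80–150 Hz) powers are computed by FFT over the
  same 500-ms window (half-open frequency intervals, no taper by default; a
  Hann option exists) and z-scored against the distribution of
  500-ms-window band powers over the same 50-s head segment (hop 100 ms).
  No notch filter is applied by default.

Degenerate channels (zero baseline SD) raise an error rather than silently
producing infinities.

## What the synthetic generator emulates

`simulate_open_loop()` reproduces the statistical structure the analysis
assumes, on a toy head:

* **Geometry.** 160 (or fewer) radial magnetometers on a Fibonacci cap
  above a 10-cm single-sphere conductor; the 84 sensors nearest a
  posterior-superior direction form the parietal decoding subset. Cortical
  sources are unit dipoles on a 7.5-cm shell, kept inside the instrumented
  cap (sources below the sensor rim are unobservable by construction).
  Dipole orientations are random with a guaranteed tangential component —
  a stand-in for cortical folding, since purely radial dipoles are silent
  in a spherical conductor.
* **Task.** 40 execution cues per movement type (grasp / open), one every
  5.5 s, in blocks of four same-type cues, after a task-free 50-s head
  segment. The closed-loop stream instead alternates 22 instructions every
  7 s.
* **MRCF.** A raised-cosine template rising from $-1000$ ms before the cue
  to a peak at $+300$ ms and decaying to zero by $+1000$ ms, projected
  through the Sarvas lead field from a type-specific dipole patch. The two
  types differ in amplitude (1.25 : 1) *and* by a small patch offset;
  trial-to-trial amplitude jitter (multiplicative SD 0.2) models
  attempt-to-attempt variability. These defaults were chosen so that, at
  the package's test scale, movement-type decoding lands in the 65–95 %
  band while intention decoding is the easier, near-ceiling task — the
  ordering characteristic of this paradigm.
* **Oscillations and ERD.** Narrow-band alpha and beta rhythms from a
  sensorimotor patch, multiplicatively suppressed to $\sqrt{1-d}$ of their
  amplitude during each movement epoch ($d$ = ERD depth, defaults 0.5 and
  0.4).
* **Noise.** Per-sensor $1/f$ background (SD 1.0) plus spatially white
  Gaussian noise (SD 0.5), in the same arbitrary units as the signal.

What it does **not** emulate: correlated brain noise, eye-blink or cardiac
artifacts, head movement, realistic conductor geometry, or inter-subject
variability in anatomy. Passing tests therefore demonstrate correctness of
the *analysis machinery* under the assumed signal model, not performance on
real recordings.

The $1/f$ background deserves a note: its low-frequency power makes 500-ms
window means drift on multi-second scales, which is exactly why baseline
z-scoring, cross-validated threshold calibration and session-start
recalibration (below) are necessary. It is the adversary the pipeline is
designed against.

## Nested cross-validated decoding

Movement type is classified by an RBF-kernel SVM. Candidate time windows
(ends 0–1000 ms after the cue, i.e. 500-ms windows starting at −500…+500)
and the hyperparameters $\gamma$ and $C$ are selected **inside** each
training fold by an inner cross-validation; the outer test trials only ever
score the already-selected model. Ties in inner accuracy break
deterministically toward smaller cost, then smaller $\gamma$, then the
earlier window. Feature standardization happens per fold from training
statistics (via the SVM's scaling). A leakage canary in the test suite
corrupts held-out trials and asserts the training-side selection is
unchanged.

Movement intention (rest vs intention) concatenates the eleven windows
covering −2500…−1000 ms (rest) and −500…1000 ms (intention) of each trial
into 924-dimensional examples; folds are formed over trials so a trial's
two examples never straddle a fold boundary. Chance is 50 % for both tasks.

Default grids are the conventional log-2 RBF grids
($\gamma \in 2^{-15..3}$, $C \in 2^{-5..15}$, step 2 in the exponent;
outer 10 folds, inner 5). The test suite and acceptance script use reduced
grids ($\gamma \in 2^{\{-13,-9,-5\}}$, $C \in 2^{\{-1,3,7\}}$, outer 4,
inner 3, six windows) and 12-trial-per-type sessions; these sizes are the
package's test-scale defaults and are reported alongside every result.

Feature kinds are compared across subjects with a one-way ANOVA
(observations = subjects, groups = kinds; a 9-subject × 4-kind table gives
$F(3,32)$), Tukey–Kramer post-hoc pairs, and a paired two-tailed t-test
between designated kinds.

## Onset detection

The real-time decoder tracks two confidences on each incoming SMF:

* $c_{\mathrm{svm}}$ — an RBF-SVM rest/intention classifier whose decision
  values are Platt-calibrated into $[0,1]$. The sigmoid is fit on
  **cross-validated** decision values; in-sample margins of a separating
  SVM would saturate the sigmoid and the stream would carry no information
  on new data.
* $c_{\mathrm{gpr}}$ — the posterior mean of a Gaussian process regression
  trained on a boxcar target (0 on rest windows, 1 on intention windows).
  The RBF bandwidth uses a deterministic median heuristic; the boxcar is
  the minimal target consistent with "confidence of intention", since the
  level the regression should track is otherwise unspecified.

An onset is declared when **both** confidences strictly exceed their
thresholds; ties do not trigger. After a detection, further onsets are
suppressed for 1500 ms (half-open: an onset exactly 1500 ms later is
allowed). Thresholds are calibrated by a joint quantile sweep: both are set
at the same quantile level of their rest-segment distributions, and the
smallest level whose rest false-detection rate meets the target (default
1/min) wins. Calibration uses cross-validated rest confidences — in-sample
ones are overfit low and the resulting thresholds fire constantly on
held-out data. A zero target is special-cased to thresholds strictly above
the rest maxima, since an observed zero rate certifies nothing.

The offline evaluation (`evaluate_first_onset()`) mirrors the real-time
path under ten-fold cross-validation: per fold the reference time $t^\*$ is
the window where type-classification accuracy peaks within the training
trials, and each test trial is scanned from $t^\*-2000$ to $t^\*+1000$ ms
in 200-ms steps. At the defaults, a 9-session synthetic cohort shows a
modal first-onset bin just before $t^\*$ and a within-±500-ms capture
fraction among detected trials around 60–75 %, against a uniform-scan
expectation of 31.25 % (5 of 16 scanned points). Both the
among-detected and among-all-trials fractions are reported, since either
reading of "percent of trials" is defensible.

A deliberately counterintuitive property of the negative control: with
label-shuffled training the Platt slope collapses and $c_{\mathrm{svm}}$
becomes nearly constant, so the calibrated detector goes *silent* rather
than firing uniformly — an uninformative decoder produces no detections.
The control therefore accepts either outcome: uniform timing among
detections, or a silent detector; both certify the absence of cue-locked
structure.

## Closed-loop simulation

`run_closed_loop()` replays the full real-time chain on a simulated
feedback session: every 200 ms the latest SMF (window ending one processing
delay, 70 ms, before wall time) updates the confidences; onsets flip a
two-state prosthetic hand to the type inferred by a third RBF SVM after the
150-ms hand-control delay. The delay model totals ≈830 ms (acquisition
0.02, processing 70, the 500-ms window itself, hand control 150, screen
projection 110). Logged onset times are corrected by subtracting the
70-ms processing delay.

Two training choices matter:

* The type classifier is trained on **all** intention-epoch windows, not
  only the peak-accuracy window: at a detected onset the MRCF is still
  ramping, and a classifier trained only at the peak is out of its
  training range there (it degenerates to a constant prediction).
* Thresholds are **recalibrated on the stream's task-free head segment**
  before control starts (`recalibrate = TRUE`). This is the automated
  counterpart of the experimenter adjusting thresholds at the beginning of
  a feedback session, and it absorbs the session-to-session drift of the
  $1/f$ background.

Scoring divides the session (from the first instruction) into sections at
every instruction change *and* every hand-state change — section counts can
therefore exceed the instruction count. Sections are half-open
$[start, end)$; an onset on a boundary belongs to the later section; a
section is TP/FP/FN/TN according to (different/same state) × (onset/no
onset). Movement-type accuracy counts only onsets inside different-state
sections and is `NA` (never 0) when there are none. Both tables are tested
with the exact one-tailed Fisher test below.

## Exact statistics

The one-tailed Fisher exact p is the hypergeometric tail
$p = \sum_{k \ge a} P(k \mid \text{margins})$ — the positive-association
direction (more detections in different-state sections; more correct
inferences on the diagonal). It is validated against brute-force
enumeration over *all* margin-compatible 2×2 tables with $N \le 60$
(635,375 tables, max |Δ| < 1e-9) and against `fisher.test(alternative =
"greater")`. Accuracy is $100(a+d)/N$ reported to one decimal.

## Simplified source imaging

The full hierarchical variational-Bayes source imaging used upstream of
this pipeline is prior art and out of scope; its hyperparameters
($m_0 = 100$, $\gamma_0 = 10$) are carried in `inverse_config()` as
provenance only. In its place: a Sarvas single-sphere forward model and a
Tikhonov minimum-norm inverse
$W = L^\top (L L^\top + \lambda C_n)^{-1}$ with the sensor noise covariance
$C_n$ estimated from the −1500…−500 ms pre-cue baseline, pooled over
trials.

Lead-field columns are depth-normalized before inversion (standard
depth weighting). Without it, noiseless single-dipole recovery mislocalizes
weak-column vertices; with it, recovery is exact on the package's meshes.
The per-vertex current scale becomes arbitrary, which downstream stages
never see: the estimated slow cortical potential (eSCP; per-vertex mean
current over 0–500 ms) is z-scored per vertex against its own
baseline-window distribution, and the per-vertex one-way ANOVA F-map
comparing the two movement types is invariant to per-vertex affine maps.
The p < 0.05 display mask is unadjusted, as is conventional for such maps
(an optional Benjamini–Hochberg flag exists, default off). Under the null
generator the mask rate sits in the binomial band around 5 %.

A known limitation, verified in the tests: a *linear* minimum-norm inverse
spreads the type contrast along correlated lead-field columns, so
significant vertices are spatially *enriched* around the true patches
(about twice chance, with the largest F-values at the patches) but not
focally concentrated the way a sparse Bayesian inverse would render them.

## Numerical and design choices

* All randomness flows from explicit integer seeds through a
  state-preserving wrapper; generators, model fits and the pipeline are
  bitwise reproducible (`run_pipeline()` embeds a configuration hash in
  its outputs).
* The head geometry (`mesh_seed`) is deliberately decoupled from the
  session seed, so a subject's open-loop and closed-loop sessions share
  spatial patterns while noise realizations differ.
* Session containers are a directory of Arrow Feather files (bitwise
  double round-trip for data and sensor geometry), an events CSV, and a
  JSON sidecar carrying the full generator configuration; damaged or
  out-of-order containers raise typed format/validation errors.
* `lambda = 0` with a rank-deficient gram matrix raises a conditioning
  error advising regularization rather than returning garbage.
* Fold assignment is stratified with seeded shuffling; a class missing
  from a fold raises a stratification error.

## Problem sizes used in the shipped checks

Simulations in the test suite and acceptance script use 84-sensor arrays,
200–300-vertex meshes, and sessions of 8–12 trials per movement type
(the generator's task defaults remain 160 sensors and 40 trials per type);
nested CV runs with the reduced grids listed above; the onset cohort is
9 sessions; the closed-loop stream carries 22 alternating instructions.
These sizes keep a full run on one CPU in the tens of minutes while leaving
every statistical property testable.
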