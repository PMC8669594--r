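---
title: "Source-space decoding and network analysis of reach-and-grasp EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space decoding and network analysis of reach-and-grasp EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspsource)
```

## The problem

Movement-related cortical potentials (MRCP) are slow (0.1–3 Hz) negative
EEG deflections that precede and accompany voluntary movement. Because
volume conduction smears cortical currents across the scalp, channel-space
MRCP mix contributions from many regions; projecting them onto cortical
sources (EEG source imaging, ESI) yields region-resolved signals (sMRCP)
that are physiologically interpretable and lower-dimensional. `graspsource`
implements a complete analysis chain for a six-condition reach-and-grasp
paradigm — five natural grasps (palmar, pinch, push, twist, plug) plus a
no-movement control — from raw multichannel recordings to decoding curves
and phase-locking brain networks, together with a synthetic-data generator
that makes every stage testable against known ground truth.

## The synthetic experiment

The generator reproduces the recording protocol the analysis expects: 8
sessions of 10 trials per task (480 trials), 40 EEG channels at 1000 Hz,
plus button and force auxiliary channels and a 10-s rest recording. Each
trial slot contains a beep, a task cue at +3 s, a "go" cue at +5 s, and a
movement executed within 5 s whose onset follows a truncated-normal
reaction time (mean 0.5 s, SD 0.1 s). Reach, grasp and return phases each
last 0.8–1.1 s, so grasping completes about two seconds after onset.

Source activity lives on the padded epoch grid $[-3, 3.5)$ s around
movement onset:

* **Motor/premotor templates** (BA4a, BA4p, BA6, with weaker copies in
  BA1–BA3b and Broca) are smooth negative deflections: a slow readiness
  negativity common to all movement conditions plus a sharp peri-grasp peak
  whose amplitude (6–10 source units) and latency (1.3–1.7 s) are
  condition-specific. The right hemisphere carries 0.4 times the left
  (right-handed movements), and the no-movement condition has identically
  zero motor templates.
* **Visual templates** (V1, V2, MT, both hemispheres, no lateralisation)
  carry a reaching-phase response with an opposite-polarity returning-phase
  rebound, identical across the five grasps; no-movement receives only a
  small cue response. This encodes the design choice that grasp *types*
  are distinguished by their motor peak alone, while movement versus
  no-movement is also visible in visual areas — so decoding accuracy should
  peak in the grasping phase rather than saturate early.
* **Phase-coupled oscillations** (1.5 Hz, diffusing random-walk phase,
  3 rad·s^-1/2^ diffusion) are planted per ROI and trial; the pairs
  (BA4a_L, BA6_L) and (V1_L, V2_L) share their phase trajectories with
  couplings 0.9 and 0.8, giving the connectivity stage a known target.

Sensor data are the leadfield projection of the sources plus temporally
coloured (AR(1), ~2 Hz knee), spatially mixed Gaussian noise, scaled in
microvolts so the ±100 µV rejection rule is meaningful. The `snr`
parameter is the ratio of the epoch-wide RMS of the noiseless template
projection to the noise SD; the default 3 gives single-trial sensor MRCP
that are visible but clearly noisy, which we consider realistic for
band-limited EEG. Inter-trial amplitude variability — not specified by any
protocol — is exposed as a log-normal scale (`amp_var`, default 0.2)
rather than fixed. The default leadfield is a random unit-column gain
matrix: it preserves everything the inverse method needs (known forward
model, ROI labelling) without head anatomy; `simulate_source_epochs()`
additionally bypasses the sensor chain when only downstream stages are
under study.

What the generator does *not* emulate: ocular/muscle artifacts (hence no
ICA stage), line noise, head anatomy, electrode drift, or behavioural
learning effects. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical model of the data, not robustness
to every pathology of real EEG.

## Event detection and trial validity

Movement onset and end are the rising and falling edges of the button
channel, grasp start/end the edges of the force channel. Edges are
detected at half the channel's dynamic range with a 10-ms debounce (the
protocol leaves thresholding unspecified; these are package choices).
No-movement trials receive a pseudo-onset: the "go" cue time plus the
subject's mean reaction time over valid movement trials. Four discard
rules flag trials exclusively, in priority order R1 (button released
before "go"), R2 (no return within 5 s of "go"), R3 (reaction time
> 1.5 s), R4 (wrong movement — decidable only against simulation truth,
a no-op on real data). Trials with valid button but unusable force edges
get the extra code `FORCE` and are excluded from phase analysis only.

## Preprocessing

The chain is: 0.1–40 Hz zero-phase band-pass → downsample to 100 Hz →
epoch $[-3, 3.5)$ s → amplitude/joint-probability/kurtosis rejection →
common average reference → 0.1–3 Hz MRCP band. Numerical choices:

* **Half-open intervals everywhere**: $[a, b)$ at rate $r$ holds
  `round((b - a) * r)` samples. This makes the 5.5-s tROI at 16 Hz exactly
  88 samples, reconciling the sliding-window model count with the grid.
* **Epoch padding**: epochs are cut 1 s wider than the $[-2, 3.5)$ s tROI
  so that a *causal* 1-s feature window exists for every tROI time point
  (the first model's window is exactly $[-3, -2)$).
* **"Zero-phase fourth-order"** means an order-4 design applied
  forward–backward (`filtfilt`), i.e. an effective order-8 magnitude
  response. Band-passes are realised as a high-pass/low-pass cascade after
  demeaning: the direct band-pass design with a 0.1 Hz edge at 1000 Hz has
  poles outside the unit circle in transfer-function form, while the
  cascade is stable and equivalent in the passband for edges this far
  apart.
* **Resampling** low-passes at 0.45 of the target rate (zero-phase) about
  the channel mean, then interpolates onto the half-open target grid, so
  durations are preserved to one sample and constants pass exactly.
* **Rejection statistics**: AMP flags any sample beyond ±100 µV (applied
  before re-referencing, since the threshold refers to recorded
  amplitudes); JP is the summed negative log-density of the trial under
  per-channel empirical Gaussians pooled across trials; KURT is the
  trial-mean per-channel kurtosis. JP/KURT flag deviations beyond 5 SD of
  the across-trial spread; a degenerate zero-spread statistic flags
  nothing. Flag precedence is AMP > JP > KURT; each trial carries one flag.
* Bad-channel handling by visual inspection has no analogue here; the
  synthetic data are generated without bad channels.

## Source imaging

The noise covariance is the sample covariance of the identically
preprocessed 10-s rest recording with relative diagonal loading $10^{-6}$.
The inverse operator is sLORETA for scalar (fixed-orientation) sources:
minimum-norm kernel $K = L^\top (L L^\top + \lambda C)^{-1}$ with
$\lambda = \mathrm{tr}(L L^\top) / (n_{ch}\, \mathrm{snr}^2)$ (snr = 3 by
default, the common ESI working assumption), standardised source-wise by
the diagonal of the resolution matrix $KL$. By the Cauchy–Schwarz
inequality in the $(LL^\top + \lambda C)^{-1}$ inner product, the
standardised power of a single noiseless point source is maximised exactly
at the true source for any positive-definite $C$ and $\lambda > 0$ — the
zero-localisation-error property the acceptance suite verifies over 100
random leadfields. Source estimates are averaged within each of the 24
Brodmann-subset ROIs as a *signed* mean (sMRCP keeps polarity, which is
informative), and no depth weighting is applied because the
standardisation already compensates.

## Decoding

sMRCP is resampled to 16 Hz. For each of the 88 tROI grid points a causal
window $[t-1, t)$ s supplies amplitudes every 125 ms — 8 values × 24 ROIs
= 192 features — to a six-class shrinkage LDA: one pooled within-class
covariance shrunk toward a scaled identity with the analytic Ledoit–Wolf
intensity, class means, and equal-prior linear scores. The shrunk
covariance is positive definite even with more features than trials, which
is the regime here. Cross-validation is stratified 5-fold, repeated 10
times with per-repeat reshuffling from one master seed; confusion matrices
are fold-summed counts averaged over repeats, precision is
diagonal/column-sum, and the peak is the earliest argmax of the
grand-average accuracy curve. Whether the original protocol stratified its
folds is unknowable from the description; stratification was chosen
because class-imbalanced folds are strictly worse for a balanced design.

The adjusted chance level is the exact binomial bound: the smallest $k/n$
with $P(\mathrm{Bin}(n, 1/6) \ge k) \le 0.05$, e.g. 19.79% at $n = 480$.
Published grand-average significance levels for comparable six-class
designs (17.75–17.95%) are averages of per-subject levels computed from
retained-trial counts that are not recoverable here, so they cannot be
reproduced exactly; the formula above is the defensible replacement.

The window-size experiment repeats the whole procedure for windows of one
sample, 0.5, 1 and 1.5 s. Windows that would reach before the padded
epoch start are skipped (the 1.5-s window therefore starts later in the
tROI), and the per-size peak accuracies feed a one-way repeated-measures
ANOVA (subjects × sizes, condition tested against the subject×condition
residual; no sphericity correction by default). The degenerate all-equal
table returns $F = 0$, $p = 1$ by convention.

## Connectivity and network metrics

Instantaneous phases come from the FFT analytic signal of each ROI's
band-limited sMRCP, computed on the whole padded epoch so that the 1-s
windows (slid in 0.1-s steps over the tROI; 46 windows) avoid the
transform's edge artifacts. The phase-locking value of a window is
$\mathrm{PLV} = |\tfrac1N \sum_n e^{j\Delta\varphi_n}|$ over its $N$
samples. PLV is computed per trial and averaged across a condition's
trials (the single-trial formula is the stated one; averaging the
trial-averaged signal instead is available via `average = FALSE` plus
manual averaging, but single-trial-then-average is the default because
trial-averaged signals inflate locking). Matrices are symmetric with unit
diagonal; thresholding at 0.65 keeps supra-threshold edges with their
weights and never creates self-loops.

Metrics on the thresholded graph: mean weighted degree (DE = mean node
strength), density (DS = edges/276 for 24 nodes), Onnela geometric-mean
weighted clustering (CC, weights rescaled by the maximum; degree-<2 nodes
contribute 0), characteristic path length on $1/w$ distances over
*connected* pairs only (CPL; an edgeless graph is flagged `NA`), and
Louvain modularity (M, resolution 1, seeded tie-breaking). Weighted
versions are the default throughout — degree is explicitly weighted in
the source method, and mixing weighted DE with binary CC/CPL would be
inconsistent — with `binary = TRUE` available where the alternative is
wanted. Disconnected pairs are excluded from CPL rather than harmonically
averaged, matching the way path length is conventionally reported for
thresholded brain graphs.

## Statistics and the pipeline

Movement versus no-movement sMRCP differences are tested per time point
with the two-sided Wilcoxon rank-sum test (exact null below a combined
n of 21, tie-corrected normal approximation above), masked at p < 0.05
without multiple-comparison correction — matching how such dot tracks are
conventionally displayed — with an optional Benjamini–Hochberg flag. Each
ROI track is tested separately per hemisphere.

`run_pipeline()` chains simulate → events → preprocess → source → decode →
connect → metrics → stats, logs per-stage timings, and writes the result
bundle (TSV/CSV plus a JSON manifest). All randomness descends from the
configuration's master seed through per-session and per-repeat child
seeds, so two runs with one seed write byte-identical result files.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run desk-scale versions of
the study design: two-session experiments with 2–4 trials per task for
pipeline-level checks, 60 planted source-space trials (10 per class, SNR
10) for decoder sanity, 100 random 40×48 leadfields for localisation, and
exhaustive graph enumeration up to 6 nodes plus 100 random 24-node graphs
for the metric oracles. These sizes were chosen as the smallest at which
each property is statistically unambiguous; the full 8-session, 480-trial
design is the generator default and runs the same code paths.

## Known limitations

* The random leadfield has no anatomy: localisation statements are about
  the operator algebra, not about spatial resolution on a head model.
* ICA-based artifact removal is out of scope; the threshold-based
  rejections are the only cleaning implemented.
* The JP statistic follows common practice (empirical-Gaussian joint log
  probability) but the original screening procedure is named, not
  specified; thresholds are matched (5 SD) rather than formulas.
* PLV on slow (0.1–3 Hz) signals has few independent phase samples per
  1-s window; planted-coupling recovery works, but absolute PLV levels
  depend on the phase-diffusion rate of the generator.
* Chance levels and significance masks are per-analysis, uncorrected
  unless requested.
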