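# graspsource

Decoding natural reach-and-grasp movements from low-frequency EEG in
source space, with phase-locking brain-network analysis — as a tested,
reproducible R pipeline.

## What it does, and for whom

Movement-related cortical potentials (MRCP) are slow (0.1–3 Hz) negative
EEG deflections around voluntary movement. Brain–computer interfaces for
motor rehabilitation want to read from them not just *whether* a user
moves, but *which* of several natural grasps is intended. Because volume
conduction smears cortical activity across the scalp, a source-space
analysis — projecting the MRCP onto cortical regions of interest via an
inverse solution — gives physiologically interpretable, lower-dimensional
signals (sMRCP).

`graspsource` implements the full chain for a six-condition paradigm
(palmar, pinch, push, twist, plug, no-movement):

1. **Synthetic experiments** (`simulate_experiment`) — 40-channel, 1000-Hz
   recordings with button/force channels, condition-specific MRCP source
   templates with left-hemisphere lateralisation, planted phase couplings,
   coloured sensor noise, a 10-s rest segment, and configurable fractions
   of invalid trials. Everything downstream is testable against this
   ground truth.
2. **Event detection** (`detect_edges`, `apply_discard_rules`,
   `assign_pseudo_onsets`, `segment_phases`) — movement onset/end from
   button edges, grasp phase from force edges, four discard rules
   (release before "go"; no return within 5 s; reaction time > 1.5 s;
   wrong movement), pseudo-onsets for no-movement trials.
3. **Preprocessing** (`preprocess_experiment`) — zero-phase order-4
   Butterworth 0.1–40 Hz, downsample to 100 Hz, epoch [−3, 3.5) s around
   onset, ±100 µV / joint-probability / kurtosis rejection at 5 SD,
   common average reference, 0.1–3 Hz MRCP band.
4. **Source imaging** (`estimate_noise_cov`, `sloreta_operator`,
   `apply_inverse`) — rest-based noise covariance and an sLORETA inverse
   (minimum-norm kernel `K = Lᵀ(LLᵀ + λC)⁻¹` standardised by the diagonal
   of the resolution matrix `KL`), averaged within 24 Brodmann-subset
   ROIs (BA1–BA45, V1, V2, MT × both hemispheres) to give sMRCP.
5. **Decoding** (`cross_validated_curves`, `window_size_experiment`,
   `chance_level`) — sMRCP at 16 Hz; per tROI grid point a causal 1-s
   window of amplitudes every 125 ms (24 ROIs × 8 = 192 features) feeds a
   six-class shrinkage LDA (Ledoit–Wolf analytic shrinkage); 88 models
   over the [−2, 3.5) s tROI; stratified 5-fold CV × 10 repeats;
   accuracy/precision curves, confusion matrices, exact-binomial adjusted
   chance level.
6. **Connectivity and graph metrics** (`plv_matrix`, `threshold_graph`,
   `metrics_timecourse`) — Hilbert-transform instantaneous phases,
   phase-locking value `PLV = |mean(exp(jΔφ))|` in 1-s windows slid by
   0.1 s, edges below 0.65 removed, and the five weighted metrics: mean
   degree (DE), density (DS), Louvain modularity (M), clustering
   coefficient (CC), characteristic path length (CPL).
7. **Statistics** (`ranksum_timecourse`, `rm_anova_window_sizes`) —
   per-time-point Wilcoxon rank-sum movement-vs-no-movement tracks and the
   repeated-measures ANOVA over feature-window sizes.

`run_pipeline()` chains all stages from one seeded configuration and
writes a TSV/CSV/JSON result bundle; identical seeds give byte-identical
result files.

## Worked example

```r
library(graspsource)

cfg <- sim_config(n_sessions = 1, trials_per_task_per_session = 4,
                  n_sources = 24, seed = 7)
rep <- run_pipeline(cfg, folds = 3, repeats = 2, verbose = FALSE)
rep$decoding
#> <decoding_result> 88 windows (1-s features), 24 trials, 3x2 CV
#>   peak accuracy 77.1% at 1.8750 s (chance level 33.33%)

rep$metrics[rep$metrics$condition == "palmar",
            c("condition", "time_s", "DE", "DS", "M", "CC", "CPL")]
#>  condition time_s       DE         DS          M        CC      CPL
#>     palmar   -1.0 1.257450 0.07608696 0.65442604 0.2247978 4.673581
#>     palmar    0.0 2.695375 0.15579710 0.20952974 0.3634390 2.710433
#>     palmar    1.4 5.946189 0.31159420 0.06365551 0.4788479 1.960958
```

Reading the output: decoding accuracy peaks at 1.875 s after movement
onset — inside the grasping phase, where the planted condition-specific
motor peaks (1.3–1.7 s) fall inside the causal 1-s feature window — and
far above the exact-binomial chance level for 24 trials. The network rows
show the planted dynamics resolving over time: as within-module phase
coupling strengthens around the movement, density and clustering rise and
the characteristic path length falls between the planning phase (−1 s),
movement onset (0 s) and the accuracy peak (1.4 s).

The default `sim_config()` is the full study design — 8 sessions × 10
trials × 6 tasks = 480 trials at 1000 Hz — and runs the same code path;
the small configuration above keeps the example fast.

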