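---
title: "EEG features and classification of tonic cold pain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG features and classification of tonic cold pain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`eegpain` implements an epoch-by-epoch classification pipeline for
discriminating a resting, no-pain state from tonic cold pain (a cold pressor
immersion) in multichannel scalp EEG. Recordings come from a 19-channel
10-20 montage sampled at 300 Hz, carrying subject, group (healthy vs.
chronic pain) and condition (baseline vs. CPT) labels. The pipeline turns
each 10-second, non-overlapping epoch into a named vector of 380 features in
seven classes, screens out feature classes corrupted by voluntary movement
at baseline, trains classifiers under leave-one-subject-out (LOSO)
cross-validation, and attaches permutation-test p values and bootstrap
confidence intervals to the resulting accuracies.

Because no public recording set accompanies this design, the package ships a
first-class synthetic-EEG generator with known ground truth. Every
downstream stage is validated end to end against cohorts whose condition
effects, movement artifacts and cross-channel phase structure are injected
by construction.

## The synthetic cohort model

Each recording is a sum over the four canonical bands — delta (1–4 Hz),
theta (4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz) — of:

* **Shared band oscillators.** Per band, `n_generators` (default 3)
  amplitude-modulated oscillators whose instantaneous frequency drifts
  slowly inside the band. Each channel receives each generator through a
  loading weight (Dirichlet-distributed across generators) and a fixed
  channel-specific phase lag. The first generator's lags grow
  anterior-to-posterior by `lag_gradient` (default 0.15 rad/channel), giving
  a known lead/lag direction for validating the directed phase lag index;
  the remaining generators use randomly ordered gradients. A single
  generator would make the cross-channel phase geometry one-dimensional, and
  thresholded connectivity graphs of such signals are almost triangle-free —
  unlike real scalp networks; three generators give the phase geometry
  enough dimensionality for realistic clustering (binary graph clustering
  coefficients around 0.2 ± 0.1 at the minimally spanning threshold).
* **Channel-specific independent activity**, split between a regular
  (band-centre, 8% of the band width) and an irregular (full-band noise)
  part, both derived from one noise field. Their mixing fraction
  (`base_noise_mix`, default 0.25) is the generator's handle on signal
  complexity: moving it toward 1 tilts the channel's own spectrum from
  centre-concentrated to flat, raising permutation entropy monotonically
  while leaving the shared fraction — and hence phase-lag connectivity —
  untouched.
* **1/f background noise** with exponent 1 and amplitude `noise_amp`
  (default 5 µV against band amplitudes of 20/10/15/5 µV for
  delta/theta/alpha/beta, eyes-open-like).

Subjects are not interchangeable: band amplitudes (log-normal, σ = 0.2),
coupling strength, baseline irregularity, and the whole per-band lag/loading
pattern are drawn once per subject and reused for both conditions. This
subject-stable structure is what makes LOSO validation meaningful (epochs
within a subject are correlated) and gives the movement screen realistic
between-subject variance.

**Condition effect.** An `effect_spec` applies to CPT recordings only:
`complexity_shift` adds to the irregularity mixing fraction on the affected
channels in the target band (raising their permutation entropy);
`phase_lag_shift` adds a fixed phase offset to the affected channels'
oscillator lags (shifting their dPLI lead/lag asymmetry). With both at zero,
baseline and CPT epochs are draws from the identical distribution — the
basis of all null-calibration checks. The demonstration effect
(`demo_effect()`) uses a theta-band shift over ten frontal/central/parietal
channels; a mixing shift of 0.75 produces a per-channel theta-PE shift on
the order of one pooled standard deviation across epochs.

**Movement artifact.** A configurable fraction of subjects is flagged as
"movers" at baseline. Their recordings receive ~2-s Hanning-enveloped bursts
(default 25/min, i.e. near-continuous) combining a large slow (0.5–3.5 Hz)
movement/electrode potential — shared with zero lag across the montage, so
it inflates spectral power while staying invisible to phase-lag indices —
and a milder EMG-band (13–50 Hz) component, mostly independent across
channels, which dilutes genuine beta-band phase coupling. This composition
was calibrated so that the movement screen reproduces the qualitative
pattern the paradigm expects: spectral power, wPLI and weighted graph
metrics load on movement; peak frequency, permutation entropy, dPLI and
binary graph metrics do not. The zero-lag/independent split is the physical
reason binary (rank-based) networks stay stable while weighted (value-based)
metrics shift.

What the generator does **not** emulate: eye blinks and cardiac artifacts,
volume-conduction geometry from a real head model, non-stationary state
changes within a recording, electrode impedance drift, and group differences
between healthy and pain cohorts at baseline (both groups are generated from
the same distribution). Passing tests therefore demonstrate the pipeline's
correctness and calibration on signals with the assumed statistical
structure, not clinical performance on real paediatric EEG.

## The 380-feature set

Per epoch: 76 spectral power (19 channels × 4 bands), 4 peak frequency
(channel-averaged, 1 × 4 bands), 76 permutation entropy, 76 wPLI row means,
76 dPLI row means, 36 binary-graph and 36 weighted-graph metrics
(9 metrics × 4 bands).

* **Spectra** use the multitaper method with K = 3 Slepian tapers and
  time-bandwidth product NW = 2 on a 0.1-Hz grid (native for 10-s epochs at
  300 Hz). Band power is the trapezoidal integral over the band's closed
  interval — shared edges contribute half to each side, so the four bands
  tile the 1–30 Hz total exactly. Peak frequency is the argmax of the
  channel-averaged spectrum inside the band; exact ties resolve to the
  lowest frequency. The Slepian tapers are computed from the classical
  symmetric tridiagonal formulation (Sturm bisection plus inverse
  iteration), cached per epoch length.
* **Permutation entropy** uses embedding dimension 5 and lag 4 on each
  band-filtered channel, ties broken by temporal order (the Bandt–Pompe
  convention), normalized by log(5!) to [0, 1].
* **Connectivity.** Instantaneous phase comes from the FFT-based analytic
  signal; the first and last 5% of samples are discarded before phase
  statistics to suppress Hilbert end effects. wPLI weights phase-difference
  signs by the imaginary cross-spectrum magnitude; the degenerate 0/0 case
  (identical channels) is defined as 0. dPLI is the fraction of samples
  where one channel's wrapped phase difference is positive, with exact
  simultaneity counted ½, so `dpli[i,j] + dpli[j,i] = 1` holds identically.
  Row means exclude the diagonal.
* **Graphs.** Binary graphs binarize each epoch's wPLI matrix at the
  participant's per-band threshold: the minimally spanning density of that
  participant's mean baseline wPLI matrix (edge ranking by weight, ties by
  row/column order, so binarization is deterministic and nested across
  densities). If an individual epoch's graph is disconnected at that
  density, the density is raised to that epoch's own spanning density.
  Weighted graphs use the raw wPLI matrix. The nine metrics per band are
  characteristic path length (edge length 1/weight), mean clustering
  coefficient (geometric-mean-of-triangle-weights form, which reduces to
  the usual binary coefficient on 0/1 graphs), modularity (best of 10
  Louvain restarts for observed graphs), mean node strength, their four
  random-network-normalized counterparts, and small-worldness (normalized
  clustering / normalized path length). Normalization divides by the mean
  over 100 surrogates obtained by degree-preserving double-edge swaps, with
  edge weights additionally permuted over the rewired topology for weighted
  graphs (2 Louvain restarts per surrogate; the ensemble mean is what
  matters). Disconnected surrogates are excluded from the path-length
  ensemble mean, and a 0/0 metric ratio counts as 1 (indistinguishable from
  the ensemble). Note that because the surrogates preserve the degree
  sequence and the edge-weight multiset exactly, the normalized *mean* node
  strength is identically 1 for both graph kinds; the two `strength_norm`
  entries are retained to keep the declared 9-metric layout but carry no
  information.

Band-specific signals are produced by zero-phase (forward–backward)
4th-order Butterworth filtering of the continuous recording, which is then
segmented — filtering the recording rather than each epoch avoids per-epoch
filter transients. The broadband 0.1–50 Hz pre-filter is applied as a
high-pass/low-pass cascade for numerical conditioning at the very low
normalized corner frequency.

## Movement screen

Baseline epochs of movers and non-movers are compared per feature class
with an independent-sample t test (pooled variance by default), Cohen's d
reported with the negligible/small/medium/large conventions at
0.2/0.5/0.8. Within a class, all channels and bands are pooled — each
epoch-feature cell is one observation — except for the two graph classes,
whose nine metrics live on incompatible scales with opposite artifact
responses (an artifact that dilutes connectivity raises path length while
lowering strength, cancelling in a pooled stream); those are tested per
metric with bands pooled, and the class is dropped when any metric reaches
the threshold. The threshold is the Bonferroni level α/7 = 0.05/7 ≈ 0.007.
Dropped classes are removed before classification. Constant streams (the
`strength_norm` entries) are untestable and skipped.

## Classification and inference

Features are standard-scaled per feature using training-partition
statistics only; constant features pass through centred. The model sweep
covers LDA (defaults), SVM with linear and RBF kernels over
C ∈ {0.1, …, 1.0, 2, 5, 10}, decision trees with gini/entropy criteria, and
L1-penalized logistic regression over the same C grid (penalty
λ = 1/(C·n), the usual inverse-regularization correspondence). All sweep
evaluations use LOSO: one fold per subject, fold accuracy is the proportion
of that subject's epochs classified correctly, overall accuracy the
unweighted mean across folds; the scaler is re-fit inside every fold.
Sweep ties break toward smaller C, then linear before RBF, then family
order — fully deterministic. The 80:20 train/validation split is
subject-level by default (an epoch-level split, available behind a flag,
would let epochs of one subject fall on both sides). Single-feature runs
(per-electrode theta-PE models) use a penalized-likelihood fit by BFGS,
since the coordinate-descent solver requires at least two columns.

Permutation tests shuffle condition labels within each subject (preserving
per-subject epoch counts; global shuffling available), re-run the full
scale-fit-score procedure per permutation, and use the add-one estimator
p = (1 + #{null ≥ observed})/(1 + n_perm), which can never be exactly
zero. Bootstrap CIs resample per-epoch prediction records with replacement
(subject-level resampling available) and take the 2.5/97.5 percentiles;
two accuracies are called different only when their CIs do not overlap.
Defaults are 10,000 permutations and resamples; the test-suite and
demonstration runs use hundreds, which is enough for the calibration
checks performed there. Feature importance ranks the L1 logistic weights
by magnitude (inputs were standard-scaled, so weights are comparable) and
reports the top 10%, `floor(0.10 · p)` entries — 19 for a 192-feature
retained set; positive weights predict the pain condition.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen as the smallest sizes at which
each property is statistically decidable: feature-structure checks on a
2-subjects-per-group, 2+2-epoch cohort; the movement screen on 10 subjects
(60% movers) with 6 baseline epochs each; null calibration on 200
independent 12-subject cohorts (one epoch per condition) with a
99-permutation test of the held-out validation accuracy at α = 0.01 and
300-resample CIs of that same validation accuracy (a single fit —
cross-validated fold accuracies are correlated through their shared
training data, which a resampling CI cannot see, so the held-out accuracy
is the quantity whose CI is honestly calibrated); effect recovery on ten (tests) or five (acceptance script)
cohorts of 20 subjects × 8 epochs with the full SVM and logistic sweeps;
graph-ensemble sizes of 10–20 surrogates in loops, 100 as the analysis
default. Oracles — brute-force motif enumeration, explicit
Dijkstra/triangle counting, exhaustive modularity over all partitions (≤ 8
nodes) or bipartitions, and an independent tridiagonal DPSS reference — are
kept separate from the implementation paths they check.

## Known limitations

* The identity of the nine graph metrics per band is a declared convention
  (five named metrics plus four normalized variants); `graph_metric_names()`
  is the single place it is defined.
* Louvain is a stochastic heuristic; modularity values are best-of-restarts
  under a fixed seed and can sit below the true maximum on adversarial
  graphs (they match exhaustive search on all small random graphs tested).
* wPLI on short narrowband epochs has a positive bias that shrinks with
  epoch length; comparisons are therefore always within-pipeline, never
  against an absolute coupling scale.
* The movement screen's per-metric treatment of graph classes, the
  subject-level split default, the within-subject permutation unit and the
  spanning-density fallback for disconnected epoch graphs are documented
  design choices where the underlying paradigm leaves the procedure open.
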