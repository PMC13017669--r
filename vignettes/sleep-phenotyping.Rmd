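---
title: "Computational sleep phenotyping from nocturnal polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational sleep phenotyping from nocturnal polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`somnphen` implements an end-to-end phenotyping analysis for central
disorders of hypersomnolence (narcolepsy types 1 and 2, idiopathic
hypersomnia, and sleepy clinical controls) built on a single night of
staged polysomnography: a hypnogram at 30-second epoch resolution, one
C3-referenced EEG channel, and optionally a *hypnodensity* — the per-epoch
stage-probability output of an automated sleep-staging model. This
vignette documents the models and procedures, the tunable parameters and
their defaults, the synthetic cohort the validation rests on, and the
numerical choices a maintainer should know about.

## The feature model

Six feature sets, 330 features in total, are derived per participant. The
analysis window runs from *persistent sleep onset* — the first epoch
opening a run of at least 20 consecutive non-wake epochs (10 minutes; the
common persistent-sleep convention, used because the clinical screening
context treats a night without persistent sleep as unusable) — to the
final non-wake epoch, and is split into quarters Q1–Q4 at epoch offsets
`floor(i * N / 4)` (half-open intervals, remainders accruing to later
quarters, so the partition is deterministic and near-equal).

1. **Whole-night hypnogram (8)** — total sleep time (minutes of non-wake
   epochs), REM sleep onset (minutes from persistent sleep onset to the
   first REM epoch, missing when no REM occurs), the stage shift index
   (adjacent-epoch stage changes per hour of *window duration*; the
   alternative per-hour-of-sleep denominator is not used, a choice made
   here once since conventions differ), and the five stage proportions.
2. **Whole-night spindle (10)** — described below.
3. **Quarter-night hypnogram (28)** — the whole-night set minus REM
   onset, per quarter.
4. **Stage-transition probabilities (100)** — per quarter, the 5×5 matrix
   of `P(next stage | current stage)` estimated from consecutive epoch
   pairs lying wholly inside the quarter (pairs straddling a boundary are
   not counted, keeping quarters independent). Rows with no observed
   departures are missing rather than zero.
5. **Quarter-night qEEG (120)** — normalized multitaper band power in six
   bands (delta 0.5–4, theta 4–8, alpha 8–12, sigma 12–16, beta 16–30,
   gamma 30–47 Hz) × five stages × four quarters.
6. **Quarter-night hypnodensity (64)** — per quarter, the mean stage
   probabilities (5), the mean pairwise mixture `min(p_a, p_b)` for the
   10 unordered stage pairs, and the mean Shannon entropy (natural log,
   maximum `ln 5`). `min(p_a, p_b)` is used for "a mix of two stages"
   because it is bounded by 0.5, zero as soon as either stage is
   excluded, and maximal when the two stages tie; the product
   `p_a * p_b` is a reasonable alternative with similar ordering
   behaviour.

The catalog (`feature_catalog()`) is the single source of truth for
names, order and set membership; the classifier's set partitions and the
clustering input are derived from it.

### qEEG details

The recording is band-passed once to 0.5–47 Hz with a zero-phase
linear-phase FIR filter (order 512; zero phase preserves event timing for
the spindle module). The night window is tiled with non-overlapping
2-second windows aligned to epoch starts (15 per epoch), so every window
inherits a unique stage and quarter. Each window is screened for
artifacts in a fixed order — flat line (peak-to-peak < 1 µV), saturation
(any |sample| ≥ 500 µV), high slew (any one-sample jump > 100 µV) — and
discarded unless clean. The thresholds are implementation defaults
exposed as arguments; the artifact classes are standard but no canonical
threshold values exist. Clean windows get a multitaper PSD (DPSS tapers,
time–bandwidth 2, 3 tapers — a conventional choice for 2-s windows;
tapers are computed from the symmetric tridiagonal eigenproblem and
cached), integrated over the six bands and normalized by total 0.5–47 Hz
power, so each window's band vector is a probability vector and the
features are invariant to channel gain. Features average clean windows
per (band, stage, quarter); empty cells are missing.

### Spindles and slow oscillations

Spindles are detected in N2 with a wavelet detector: complex Morlet
power at 13.5 Hz (7 cycles, so the ±2σ response spans roughly 11–16 Hz),
smoothed with a 0.1-s moving average. Thresholds are expressed as
multiples of the N2 sigma-power *noise floor*, estimated as the median
smoothed N2 power divided by ln 2 — the median-to-mean conversion for
exponentially distributed narrow-band noise power. The median-anchored
floor is deliberately robust: the raw mean is inflated by the spindles
themselves (at two 1-s spindles per minute they occupy ~3% of N2 at an
order of magnitude above background, biasing a mean-based threshold
upward and costing recall), while raw median multiples sit so low on the
smoothed-power distribution that background noise sustains them for
spurious half-second events. Candidate cores exceed 4.5× the floor, are
extended to flanking 2× crossings, merged across gaps shorter than
0.5 s, and kept when 0.5–3.0 s long. Event amplitude (largest
peak-to-peak), frequency and peak time come from the 11–16 Hz filtered
trace. Frequency is zero-crossings/(2 × duration): the raw
zero-crossing count divided by duration counts *half*-cycles and would
double the oscillation frequency, so the emitted value is the one in the
sigma range.

Slow oscillations are detected on 0.3–1.5 Hz filtered signal over all
non-wake sleep (configurable): negative-going zero-crossing pairs with a
negative phase of 0.3–1.5 s, negative peak ≤ −40 µV and peak-to-peak
≥ 75 µV — a conventional amplitude-criterion detector, since no single
standard exists.

The 10 spindle features are count, density per N2 minute, mean
frequency/amplitude/duration, SO-coupling proportion (any temporal
overlap between a spindle and an SO), coupling angle (circular mean of
the SO-band analytic-signal phase at spindle peaks, over coupled
spindles), phase-locking value (resultant length, 0–1), dispersion (the
Fano factor — variance/mean — of per-30-s-epoch N2 spindle counts; 0
when there are no spindles) and mean sigma-band isolation (the event's
sigma-power enrichment over a ±3-s local baseline divided by the mean
enrichment of the other five bands, delta included).

## The classifier evaluation framework

Binary diagnosis tasks are evaluated with a Monte-Carlo outer loop: R
stratified 70/30 splits (per-class training counts are
`round(0.7 × n_class)`), each followed by 10-fold cross-validated
hyperparameter tuning on the training split *with SMOTE balancing
applied only to the nine training folds* — validation folds never
contain synthetic points — and a final random forest trained on the full,
un-augmented training split. Test-set AUC (Mann–Whitney concordance with
ties counting one half) and F1 (threshold 0.5, smaller class positive —
a convention fixed here since none is standard) are averaged across
runs, the ROC by vertical averaging on a 101-point FPR grid, and
impurity importances are converted to per-run ranks and averaged.

The forest is `ranger` with 500 trees; the default tuning grid crosses
maximum depth {5, 10, unbounded} with per-split feature fractions
{√p/p, 0.25, 0.5}; the tuning criterion is mean validation AUC with ties
resolved toward the earliest grid row. The grid is a framework default —
the evaluation protocol, not any particular grid, is the contribution —
and every piece (trees, folds, k = 5 SMOTE neighbours, grid) is exposed
in `eval_config()`. SMOTE synthesizes minority points as
`x + u (x_nn − x)`, `u ~ U[0,1]`, between a minority point and one of
its k nearest minority neighbours, balancing classes to equality.
Missing feature cells are imputed with training-split means inside each
run, so no test information leaks into training.

Top-feature models take the 8 best mean-ranked features of each of the
six sets (48 in total); exclusion variants drop one or more sets and
refill round-robin from the retained sets' next ranks until 48 features
are restored. When a retained set runs dry (the whole-night hypnogram
set has only 8 features) the refill continues over the remaining sets
and logs the shortfall.

## The clustering framework

Preprocessing (mean imputation computed over *all* participants, as the
comparison families span groups; near-zero-variance removal;
z-standardization) is followed by PCA, retaining the smallest leading
subspace reaching 90% cumulative variance. k-means (k-means++ seeding,
50 restarts, best inertia, Lloyd iterations) runs within each diagnosis
group for k = 2–10, and k is chosen by the Calinski–Harabasz index. The
index is **maximized** by default: CH is a between/within dispersion
ratio whose standard semantics are larger-is-better. A `direction`
switch supports minimization for exact reproduction of protocols stated
that way. Clusters with fewer than 10 members are excluded from
comparison; the remaining two clusters are compared feature-by-feature
(original scales, not the standardized ones) with Welch t-tests,
Benjamini–Hochberg-corrected within the group's family. Demographics and
biomarker columns can be compared alongside but are never part of the
clustered matrix. For diagnosis-pair comparisons the BH family instead
pools all pairs, matching the overlapping-participants structure of that
family.

## The synthetic cohort

No clinical recordings ship with the package; every validation runs
against a generator with known ground truth:

* **Hypnogram** — a per-epoch Markov chain over (W, N1, N2, N3, R). The
  default kernel is sticky (diagonal 0.5–0.86) and starts awake;
  recordings default to 700–1100 epochs (≈6–9 h), the typical clinical
  night.
* **EEG (128 Hz default)** — per-epoch spectral synthesis: white noise
  shaped in the frequency domain by a stage-specific amplitude mask
  whose band plateaus realize the stage's relative band-power profile
  exactly in expectation; total background SD 12 µV. The N2 profile
  allocates 5% of variance to sigma (≈2.7 µV RMS), matching realistic
  non-spindle sigma activity and keeping injected spindles unambiguous
  against background, which the truth-based detector scoring requires.
  Spindles are injected into N2 as Hann-windowed 13 Hz sinusoids (1.0 s,
  30 µV peak-to-peak) at a Poisson rate of 2 per N2 minute; slow
  oscillations into N3 as single 0.8 Hz cycles (120 µV peak-to-peak) at
  5 per N3 minute. Every injected event is recorded in the truth object.
* **Hypnodensity** — each epoch's probability row is Dirichlet with
  weight `concentration` (default 50) on the true stage and 1 elsewhere;
  entropy decreases monotonically in the concentration.
* **Cohort** — per-participant seeds derive deterministically from one
  master seed; demographics are simulated placeholders; feature-cell
  missingness (default 1%, capped at the 2% the preprocessing contract
  allows) is injected after extraction.

`example_group_specs()` bundles the two validation scenarios: "null"
(two identical groups — exchangeable by construction) and "separated"
(fragmented transitions, doubled gamma share in N1/N2/REM, spindle
density 4/min at 12 Hz, flatter hypnodensity at concentration 8).

What the generator does *not* emulate: real EEG morphology beyond
band-power structure (no 1/f continuum, K-complexes, arousals, or
artifacts), apnea or limb movements, multi-channel montages, or
inter-night variability. Passing tests therefore demonstrate that the
pipeline measures what it claims on signals with known structure — not
clinical performance on real recordings.

## Validation design and problem sizes

The test suite checks every operation against independent oracles
(brute-force pair counting for AUC, the literal step-up construction for
BH, the two-loop formula for CH, hand counts for hypnogram features,
closed forms for degenerate hypnodensities, FFT periodograms for
spectra) and recovers generator parameters end to end: transition
kernels to ±0.05 from ≥5,000 pooled epochs, spindle recall and precision
≥0.9 at 2/min injected events, entropy monotone in concentration,
null-cohort AUC near chance and separated-cohort AUC ≥0.9, two-blob
cluster recovery with adjusted Rand index 1, and ~5% nominal false
positives on null cluster comparisons.

Cohort-level suites run at desk scale by design: 25 participants per
group and 240–320-epoch nights (the generator's clinical defaults remain
700–1100). Two behaviours of small null cohorts are worth knowing: the
R = 50 outer runs share one cohort, so their mean AUC carries
cohort-level variability of roughly ±0.06, and resampling-based null
evaluation sits slightly below 0.5 on average; individual null-cohort
draws can therefore land just outside [0.4, 0.6] without indicating a
defect.

## Numerical choices and degenerate inputs

* FFT-based filtering pads to 5-smooth lengths; the brick-wall
  band-analytic transform returns filter, envelope and phase in one
  pass. The FIR stage compensates its group delay exactly.
* Band edges assign a bin to the band whose `[low, high)` interval
  contains it; the topmost band includes 47 Hz.
* A constant 2-s window has undefined normalized band power and is an
  error if it reaches the PSD stage (screening catches it as flat
  first).
* Hypnodensity rows within 1e-3 of summing to 1 are renormalized;
  anything worse, or any negative entry, is rejected.
* `calinski_harabasz` reports `Inf` when the within-cluster scatter is
  exactly zero.
* k-means++ duplicate centers are dropped before Lloyd iterations, and a
  restart that fails (empty cluster) is discarded.
* CV folds that lose a class are redrawn with a derived sub-seed (and
  the refold logged); stratified splitting refuses classes with fewer
  than 4 members.
* Zero detected spindles yield count 0, density 0, dispersion 0 and
  missing averages; a group in which fewer than 5 N2 minutes exist gets
  no spindle features at all.
* An unusable recording (no persistent sleep onset) becomes an
  all-missing feature row with a warning during cohort extraction, so
  one bad night does not abort a cohort run.

## Known limitations

* Spindle detection has been validated against injected synthetic
  events, not against human scorers; threshold transfer to clinical EEG
  is untested here.
* The gamma band (30–47 Hz) is susceptible to EMG/ECG contamination
  that the three artifact screens only partially remove.
* The SMOTE implementation interpolates linearly and assumes Euclidean
  similarity, with the usual caveats in high dimensions.
* Only binary classification tasks are implemented; multiclass tasks
  and across-diagnosis pooled clustering are out of scope.
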