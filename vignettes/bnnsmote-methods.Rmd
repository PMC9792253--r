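---
title: "Methods: boundary-aware minority oversampling for seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-aware minority oversampling for seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long-term scalp EEG monitoring produces vastly more nonictal than ictal
signal: once a recording is cut into fixed-length windows, ictal windows are
outnumbered by roughly 1:30. A classifier trained on such data minimises its
loss by siding with the majority class, so recall on seizures collapses even
when accuracy looks excellent. The standard remedy is to resample the
*training* data towards balance before fitting. This package implements a
boundary-aware oversampler, BNNSMOTE, together with the four reference
resamplers it is usually compared against, an EEG preprocessing chain, a
lightweight one-dimensional convolutional classifier with analytic cost
accounting, and a leakage-safe evaluation protocol.

## BNNSMOTE

All resamplers operate on a `labeled_dataset` — a numeric feature matrix
with binary labels, label 1 being the seizure/minority class. Windows of raw
EEG become rows by flattening (`segments_to_dataset()`).

BNNSMOTE composes three stages, all built on one exact k-nearest-neighbour
backend (`compute_neighbors()`; Euclidean metric, ties broken by lower row
index so results are platform-independent):

1. **Noise filtering** (`filter_noise()`). A minority sample whose `k_noise`
   nearest neighbours in the full dataset are *all* majority is an isolated
   point inside the majority region. Interpolating from it would manufacture
   label noise, so it is flagged and excluded from synthesis. By default the
   flagged rows are also dropped from the output training set
   (`keep_noise = TRUE` retains them, for ablation).
2. **Boundary construction** (`boundary_majority()`, `danger_minority()`).
   Majority samples whose `k_boundary`-neighbourhoods (computed with noise
   excluded) contain at least one clean minority sample mark the class
   boundary from the majority side. The clean minority samples that appear
   among the `k_danger` nearest neighbours of at least one such boundary
   majority sample form the *hard-to-learn* set: the seizure windows a
   classifier actually struggles with.
3. **Synthesis** (`synthesize_samples()`). New minority rows are convex
   combinations `x_new = x_p + delta * (x_q - x_p)` with the parent `p`
   drawn uniformly from the hard-to-learn set, the partner `q` drawn
   uniformly from *all* clean minority samples, and `delta ~ U(0, 1)`.
   Synthesis continues until the minority/majority ratio reaches
   `target_ratio` (default 1: a balanced training set).

```{r}
library(bnnsmote)
gen <- make_clusters(cluster_config(n_major = 600, n_minor = 20,
                                    separation = 2, noise_frac = 0.1,
                                    seed = 1))
res <- bnnsmote(gen$dataset, resample_config(seed = 1))
res
res$provenance[1:3, ]   # parent, partner, delta per synthetic row
```

### Design choices that were genuinely open

* **Boundary majority samples are identified, not generated.** One reading
  of the method's description is that new *nonseizure* samples are created
  near the boundary. Creating majority samples would worsen the imbalance
  the algorithm exists to fix and contradicts its three-step summary
  (filter noise / construct the hard-to-learn set / synthesise seizure
  samples), so this package treats the step as identification of existing
  boundary majority samples, which then vote for the hard-to-learn set.
* **Partner choice is global.** The partner is drawn from all clean
  minority samples, not from the parent's k nearest minority neighbours;
  the method's own description says seizure samples are selected *at
  random* for synthesis. `partner_mode = "knn"` gives the SMOTE-style
  restriction for comparison.
* **Noise rows are removed from the output.** They are "filtered … to
  remove noise"; keeping them would reinsert exactly the points stage 1
  identified as harmful. `keep_noise` exposes the alternative.
* **Empty danger set.** On well-separated data no majority sample sees a
  minority neighbour and the hard-to-learn set is empty. The resampler then
  falls back to synthesising from all clean minority samples (with a
  warning) so the balance contract still holds; when the boundary-majority
  set is empty the danger rule falls back to the borderline criterion
  (minority samples with between `k_danger/2` and `k_danger - 1` majority
  neighbours).
* **Neighbourhood sizes.** `k_noise = k_boundary = k_danger = 5`, the
  SMOTE-family convention; all exposed in `resample_config()`.
* **Determinism.** Every resampler consumes a private seeded RNG stream in
  the documented order (parent, partner, delta per synthetic row), so a
  `(data, config, seed)` triple reproduces the result bit for bit.
* **No internal feature scaling.** Distances are computed on features as
  given; callers decide on standardisation. For flattened raw EEG windows
  the channels share a physical unit (microvolts), so the default is the
  identity.

### Reference resamplers

`ros()` duplicates minority rows uniformly with replacement
(provenance records `delta = 0`, partner = parent). `smote()` interpolates
from any minority parent towards one of its `k_danger` minority
neighbours. `blsmote()` restricts parents to the borderline DANGER set
(`k/2 <= m' < k` majority neighbours; `m' = k` is noise-like and never a
parent) and no-ops with a warning when the set is empty. `svmsmote()`
approximates the boundary with the minority support vectors of a
soft-margin linear SVM (fit via `e1071::svm`) and interpolates from them
towards minority neighbours (the interpolation-only variant; extrapolation
is out of scope). All five honour the same balance, provenance, and
determinism contracts.

## EEG preprocessing

* **Bandpass** (`bandpass()`): order-4 Butterworth, 0.5–50 Hz, applied
  forward-backward so the phase is zero and the effective order doubles
  (both order and band configurable). Each channel is demeaned and extended
  by odd reflection over about three periods of the low cutoff before
  filtering; without that, the zero-phase pass starts from zero initial
  conditions and leaves large edge transients (a constant channel, for
  instance, would not be annihilated).
* **Segmentation** (`segment()`): sliding windows of 4 s with a 2 s step
  (1024 samples per window at 256 Hz); `n = floor((T - w)/s) + 1` windows.
  A window is labelled ictal when at least half of it overlaps a seizure
  interval ("majority-overlap"; `any-overlap` and `full-containment` are
  available). The half-overlap rule keeps windows that straddle onset or
  offset without labelling near-misses; note that a window with *exactly*
  50% overlap is ictal, on both sides of an interval. All intervals are
  half-open `[start, end)` in seconds.
* **Channel screening** (`anova_select()`): each window is reduced to one
  scalar per channel — log signal energy by default (mean absolute
  amplitude and variance are alternatives) — and a one-way two-group
  analysis of variance compares ictal and nonictal groups per channel;
  channels with `p < alpha` are retained. For two groups the F statistic
  is exactly the squared pooled-variance t statistic, which the tests
  exploit as an independent oracle. Two caveats the tests make explicit:
  the screen assumes segments are independent, so it should be calibrated
  on *non-overlapping* windows (with a 50% overlap the segment energies
  correlate and the F statistic is anticonservative); and retaining
  "exactly the right channels" is a support-recovery claim that needs
  family-wise error control — at a per-channel `alpha = 0.05` across a
  montage of 23 channels, at least one false retention is expected about
  half the time, so the recovery tests use a Bonferroni-corrected level.
  Cross-patient aggregation of per-channel decisions is not reproducible
  from a single recording; a fixed `keep` list (`select_channels()`,
  `chbmit_selected_channels()`) stands in for it.

## The classifier

`default_spec()` declares the reference architecture as an ordered table:
a stride-2 initial convolution (1→32, kernel 3), seven inverted-residual
bottleneck stages with expansion factor, output channels, repetitions and
stride `(t, c, n, s)` = (1,16,1,1), (6,24,2,2), (6,32,3,2), (6,64,4,2),
(6,96,3,1), (6,160,3,2), (6,320,1,1), a pointwise convolution to 1280
channels, global average pooling, and a two-class linear head. The shape
flow for a 1024-sample window is 1024×1 → 512×32 → 512×16 → 256×24 →
128×32 → 64×64 → 64×96 → 32×160 → 32×320 → 32×1280 → 1×1280 → 2.

Decisions worth recording: the architecture table lists stride 1 for the
first convolution while its shape column halves 1024 to 512 — the shape
column wins, so the first convolution uses stride 2. The depthwise kernel
size is 3 (the MobileNet convention, and the only value consistent with
the published parameter and mult-add totals). Inside a bottleneck the
layout is pointwise expansion (omitted when `t = 1`) + batch
normalisation + clipped-linear activation (ReLU6), depthwise convolution
(stride `s` only in a stage's first repetition) + normalisation +
activation, then pointwise projection + normalisation with no activation;
a residual connection is added when the stride is 1 and input and output
channels match.

**Accounting** (`count_parameters()`, `count_mult_adds()`): convolutions
are bias-free (normalisation supplies the shift) and contribute
`kernel × in_channels/groups × out_channels` weights; batch normalisation
contributes `2 × channels`; the linear head has a bias. Multiply-adds
count convolutional and linear layers only —
`kernel × (in/groups) × out × out_length` per convolution — excluding
normalisation, activation and pooling, the dominant convention for
mult-add tables. Under these conventions the reference model has
2,182,850 parameters (2.2 M) and 92,500,480 MACs (92.5 M) for one
1024-sample window; both are recomputed by `scripts/acceptance.R`.

**Training** (`train_model()`): the instantiated graph is trained by
reverse-mode differentiation written in plain R (im2col convolutions,
per-tap depthwise accumulation, batch-norm backward in closed form),
minimising two-class cross-entropy with Adam (defaults: learning rate
1e-3, batch 64, 30 epochs — the source experiments do not state an
optimiser, so these are ordinary defaults, all configurable). Gradients
are verified against central finite differences in the test suite.
Training the full 2.2 M-parameter model in interpreted R is slow, so the
test suite trains a scaled-down spec of the same op vocabulary (input
length 64, ~1.3 k parameters, 200 windows, 20 epochs — a few seconds) and
checks it reaches ≥95% training accuracy on a separable fixture; the full
model is exercised analytically and by shape-flow simulation. A
dependency-free 1-nearest-neighbour classifier (`knn_classifier()`)
serves as the fast surrogate wherever resampler properties, not network
capacity, are under test.

## Evaluation protocol

`cross_validate()` runs `n_folds` rounds; each round splits the data into
80% train / 20% test by *stratified* random sampling (the protocol a
"5-fold, 8:2 ratio" description pins down is Monte-Carlo cross-validation;
classic partitioned k-fold is available with `mode = "kfold"`).
Stratification prevents test folds without positives. The resampler is
applied to the training portion only — the test portion is never
resampled — and every fold is audited: the original indices behind each
synthetic row's parent and partner must be disjoint from the test set.
Metrics are accuracy `(TP+TN)/N`, recall `TP/(TP+FN)`, precision
`TP/(TP+FP)` and F1 (their harmonic mean), with the convention that a
zero denominator yields 0 (so F1 = 0 whenever TP = 0). Fold metrics are
averaged arithmetically. `benchmark_resamplers()` tabulates the five
resamplers plus the no-resampling baseline in one table.

## Synthetic ground truth

Every fixture is generated, seeded, and returns its planted structure;
nothing is inferred from data.

* `make_clusters()` draws both classes from spherical normals whose
  deviations are truncated at radius 3 sd, the minority centre `separation`
  pooled-sd units away along the first axis. A `noise_frac` fraction of
  minority rows is relocated into the majority core with enforced pairwise
  spacing of at least 1 sd. Truncation and spacing are what make the
  planted truth *exact*: with unbounded tails a legitimate minority
  straggler can wander into the majority core and become indistinguishable
  from planted noise, and two adjacent planted points would shield each
  other from the all-majority-neighbourhood test. Exact-recovery tests
  therefore run at separation 8 sd; near the overlap regime (separation
  ~2, the default and the standard imbalanced fixture at 1:30) noise
  flagging is intentionally probabilistic, which is the regime the
  resampler comparison runs in.
* `make_eeg()` produces band-limited `1/f` background (30 µV RMS) per
  channel; inside annotated intervals the affected channels add a
  3 Hz spike-wave-like oscillation (fundamental plus weaker second
  harmonic under a raised-cosine onset/offset envelope) scaled to
  `burst_gain` times the background RMS. Three hertz spike-wave is the
  canonical generalized-seizure motif; the generator makes no claim to
  physiological realism (no artefacts, no inter-channel propagation, no
  evolving seizure morphology), so passing tests demonstrate algorithmic
  correctness on controlled signals, not clinical performance.
* `make_imbalanced_segments()` places one seizure interval on the
  segmentation grid so the ictal:nonictal window ratio approximates a
  target (default 1:30, the long-term-monitoring figure) and reports the
  achieved ratio.

## Numerical conventions and degenerate inputs

Distance ties break by lower reference index; `order()`'s stable sort
makes this deterministic. Synthetic rows reproduce
`parent + delta*(partner - parent)` to better than 1e-9 elementwise
(exactly, in IEEE terms — the tests allow 1e-9). Resampling a dataset
with more minority than majority, or one already at the target ratio, is
a warning/no-op; synthesis with fewer than two clean minority samples is
a refusal (error), as is an unknown channel name, a cutoff at or above
Nyquist, or a window longer than the record. Zero-phase filtering solves
edge conditions in floating point, so scaling commutes with filtering to
about 1e-9 of the signal scale rather than exactly.

## Known limitations

The trainer is pure R: fine for the scaled specs the tests use,
impractical for training the full model on days of EEG. The EDF codec
writes the fixed-rate 16-bit dialect only (identical rate on all
channels, one-second records) and stores annotations in a sidecar TSV
rather than EDF+ events. Event-based seizure metrics (detection latency,
false alarms per hour) and statistical comparison between resamplers are
out of scope, as are multi-class resampling, categorical features, and
undersampling or GAN-based augmentation.
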