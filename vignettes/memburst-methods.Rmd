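---
title: "Decoding verbal memory from iEEG burst time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding verbal memory from iEEG burst time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`memburst` implements a decoding pipeline for verbal memory built on a
simple physiological premise: transient high-gamma (HG, 80--200 Hz) and
beta (15--40 Hz) oscillatory bursts in posterior parietal intracranial EEG
carry information about memory state (whether the subject is encoding a
word or freely recalling) and memory performance (whether a studied word
will later be recalled).  Rather than feeding raw band-passed voltage to a
classifier, the pipeline detects discrete bursts, re-renders each one as a
Gaussian kernel whose amplitude encodes the burst's spectral power, and
stacks the resulting smooth, non-negative "convolved burst" traces --- one
HG row and one beta row per recording contact --- into 2-D trial tensors
for small 1-D convolutional networks.

The package is organized around the delayed verbal free-recall task: lists
of 12 words shown for 1.6 s each with 0.75--1.0 s blank inter-stimulus
intervals, a 20 s arithmetic distractor, and a 30 s free-recall window per
list.  A synthetic session generator reproduces this schedule and plants
bursts with class-dependent statistics, so the entire pipeline --- from
voltage traces to cross-validated AUROC --- is testable end to end with
known ground truth.

# The synthetic session generator

`simulate_session()` produces one experiment: bipolar-referenced channels
of 1/f background noise (log-log spectral slope $-2$, RMS 20 µV) plus a
60 Hz mains component (5 µV), sampled at 500 Hz by default (the study
rates 512--2000 Hz are supported and resampled to 500 Hz for analysis).
Into this background it plants Hann-windowed sinusoidal bursts:

* **Encoding regime.**  Within each word's planting window --- word onset
  to the next word onset, capped at 3 s, so windows partition the epoch
  and no region is double-planted --- bursts arrive as a Poisson process:
  HG at 0.6 bursts/s (duration $0.10 \pm 0.02$ s), beta at 0.4 bursts/s
  (duration $0.15 \pm 0.03$ s).  Words are independently labeled
  "subsequently recalled" with probability `recall_p` (default 0.25, a
  typical free-recall hit rate), and recalled words' windows receive the
  configured class multipliers on burst rate and/or amplitude --- this is
  the effect the performance decoder must find.
* **Recall regime.**  The 30 s free-recall windows receive their own burst
  rates (defaults: HG 1.5/s, beta 1.0/s), making memory *state* decodable.
  The real recall-epoch statistics are not characterized by the task
  description, so this regime is a modeling choice: elevated parietal
  burst rates during active retrieval, with no speech or muscle artifact.
* **Amplitudes** are drawn from $\mathcal N(100, 20^2)$ µV --- five times
  the background RMS, a deliberately suprathreshold regime.  The package
  targets the question "is the class information in detected bursts
  recoverable?", not "how faint can a burst be?"; detection sensitivity is
  characterized separately at 8× background in the regression tests.

Every planted burst (channel, band, onset, offset, centre frequency,
amplitude) and every label is recorded, and the whole session is
bit-reproducible from its seed.  `write_session_bids()` emits a
BIDS-iEEG-flavoured text layout (float32 binary + JSON sidecar, events /
channels / truth TSVs).

What the generator deliberately does **not** emulate: interictal
epileptiform discharges, muscle and speech artifact, electrode geometry or
volume conduction, non-stationary background, or any cross-regional
structure.  Tests passing on this generator therefore demonstrate that the
pipeline recovers the class signal it is pointed at under clean but
realistic spectral conditions --- not that it is robust to the
contamination that dominates clinical recordings (the low-voltage QC
screen addresses only one such failure mode).

# Preprocessing

`to_bipolar()` subtracts adjacent contacts within each strip / grid /
depth group ($n$ contacts → $n-1$ channels).  `notch_60()` removes mains
with a fourth-order Butterworth band-stop (59--61 Hz, i.e. a 2 Hz
stop-band) applied forward-backward; zero-phase filtering everywhere is a
deliberate choice because burst onset times feed the decoder.
`standardize_signal()` standardizes each contact over the full session
(not per epoch); constant channels are excluded with a warning.
`screen_low_voltage()` implements the automated part of quality control:
zero-phase FIR band-pass in each band, sliding 200 ms RMS with a 100 ms
hop, and flags for channels whose maximum windowed RMS stays below 5 µV
(HG) or 10 µV (beta) --- the signature of white-matter or high-impedance
contacts whose recordings cannot support burst decoding.

# Burst detection and the convolved representation

`wavelet_tfr()` computes a complex Morlet transform by frequency-domain
convolution.  Detection runs on grids wider than the strict bands ---
50--250 Hz in 4 Hz steps for HG (7-cycle wavelets), 5--50 Hz in 1 Hz steps
for beta (5 cycles) --- so contours of band-edge events are not truncated;
events whose peak frequency falls outside 80--200 / 15--40 Hz are then
discarded.  The beta map's analytic transform is evaluated at a quarter of
the sampling rate (its spectral support permits this exactly), which
speeds long-session detection about fourfold.

`detect_bursts()` realizes the topographical analysis of the wavelet map
with the following concrete choices, each of which the underlying method
leaves open:

* **Baseline.**  Each frequency row is normalized by the mean and SD of
  its cells at or below the row's 75th percentile (`baseline_q`).  A
  baseline computed from all cells lets dense burst activity inflate its
  own reference --- in task sessions bursts can occupy a third of the
  recording --- which both masks detection and hands the seed ranking to
  spectral leakage in quiet rows.
* **Seeds.**  2-D local maxima of the z-map with $z \ge 2$.
* **Contours.**  Each seed is flood-filled (4-connectivity, strongest
  seeds claim cells first) to its half-maximum contour measured on the
  *baseline-relative power excess* $(P-\mu)/\mu$.  The excess is
  comparable across 1/f-scaled rows; a z-relative contour is degenerate
  for strong bursts (z is variance-normalized and unbounded, so "half the
  seed" can exceed every neighbouring cell).
* **Events.**  Onset/offset are the contour's temporal extent, peak
  frequency is the seed's row, and power is the contour's summed
  magnitude².  Overlapping events are merged only when their peak
  frequencies lie within the wavelet's spectral resolution
  ($2f/n_{\text{cycles}}$): such pairs are fragments of one burst, whereas
  distinct co-occurring bursts at separated frequencies must stay
  distinct or burst counts saturate exactly when rates are high.

At the z = 2 default, noise alone produces a non-trivial event floor
(order 1 event/s per channel per band on pure 1/f noise); these events
carry near-baseline power and are strongly down-weighted by the
power-scaled representation below.  The false-event rate on fixed-seed 1/f
noise is pinned by a regression test so that drift across releases is
caught.

`convolve_bursts()` renders events as
$f(t) = \sum_i A_i \exp\!\big(-(t-p_i)^2 / (2 w_i^2)\big)$ with $p$ the
onset/offset midpoint and $w$ the event duration times `w_scale`
(default 1).  $A$ defaults to the burst's power *density* --- contour
power divided by duration --- normalized by the median density of that
channel/band/session, so a typical event peaks near 1 and strong bursts
dominate.  The density is used rather than the raw contour sum because
$w$ already encodes duration: scaling $A$ by the duration-summed power
would count duration twice, hand the series a heavy tail dominated by a
few long merged events, and let the block-level realization noise of that
tail masquerade as class signal (the state-decoding null only sits at
chance with the density scaling; `amplitude = "power"` retains the
summed-power variant).  Kernels are evaluated on ±5 w support and summed;
the series is non-negative, zero wherever no kernel has support, and
integrates to $\sum_i A_i w_i \sqrt{2\pi}$.

`burst_snr()` is the separate signal-to-noise estimator used only for the
explanatory model, never for decoding: a zero-phase symmetric FIR
band-pass (order 500 for HG, 100 for beta), noise = RMS of the filtered
trace, candidate peaks = local maxima of its absolute value with
$z \ge 2$, signal = the 95th percentile of those peak amplitudes, and
SNR = signal / noise.  Degenerate rule: when no peak reaches the z
threshold --- a pure sinusoid is the canonical case, where every peak is
typical of the trace --- all local maxima are used, which reproduces the
analytic $\sqrt 2$ for a pure tone.

# Trial tensors

Burst tensors stack rows contact-major, HG before beta, so a session with
$C$ contacts yields $2C$-row tensors; the broadband variant keeps the raw
standardized iEEG ($C$ rows).  Epochs:

* **Encoding** (`extract_encoding_epochs()`): one 3 s tensor per word,
  starting at word onset (covering the 1.6 s presentation, the ISI, and a
  margin), labeled by subsequent recall.
* **State** (`extract_recall_segments()` + `build_state_dataset()`):
  encoding tensors (label 1) pooled with randomly placed 3 s segments of
  the recall windows (label 0) and shuffled; the multiset of tensors is
  seed-independent, only the order varies.
* **Recall performance** (`extract_recall_epochs()`): one 30 s tensor per
  list, labeled good iff that list's recall count *strictly exceeds* the
  mode of the counts across lists; modal ties break toward the smaller
  value, so "good" always means above the typical session.

Tensors are decimated to 50 Hz by default (`decimate = 10`): the convolved
series is a sum of Gaussians with $w \ge 50$ ms, which 50 Hz represents
essentially losslessly, and fixed small inputs keep repeated
cross-validated training tractable.  The examples in this vignette and the
acceptance analyses use `decimate = 20` (25 Hz) with 12--15-list,
1--2-channel sessions --- problem sizes chosen so a full cross-validated
experiment runs in tens of seconds on one core while leaving the class
signal intact.

# The CNN decoders

All four decoders share one architecture: three 1-D convolution blocks
(64, 128, 64 filters; kernel 3; "same" padding; ReLU; batch normalization
after each block), global average pooling over time, and a single sigmoid
unit, trained with Adam (step size $10^{-3}$) on binary cross-entropy.
Glorot-uniform initialization, zero biases, batch-norm momentum 0.99 and
$\varepsilon = 10^{-3}$ follow the framework defaults the architecture was
specified with.  Model-specific schedules: CNN1 (state) 100 epochs / batch
128; CNN2a (broadband encoding) and CNN2b (burst encoding) 150 / 128; CNN3
(recall performance) 100 / 32.

Two implementation notes that matter numerically:

* **Batch-norm recalibration.**  After the configured epochs the
  batch-norm running statistics are replaced by one full pass over the
  training set.  With momentum 0.99 and few gradient steps (30-epoch
  full-batch training takes 30 steps) the exponentially averaged
  statistics are still dominated by their initialization, and
  inference-mode normalization would be badly wrong; recalibration makes
  evaluation reflect the trained network at any epoch budget.
* **Determinism.**  Weights are drawn from R's RNG under the
  configuration seed, the per-epoch batch order is a pre-drawn permutation
  table, and training runs single-threaded in float32, so a fixed seed
  gives bit-identical models and predictions.

`crossvalidate()` assigns folds by *list* whenever the dataset carries
list structure (default $k = 5$; leave-one-out via $k = n$ on ungrouped
data).  Grouping matters because trials cut from one list share signal:
adjacent 3 s encoding epochs overlap by up to half a second, and twelve
random 3 s segments of a 30 s recall window overlap massively.  With
trial-level folds that shared content sits on both sides of the
train/test split and the network scores well by recognizing memorized
waveforms --- on identical-regime synthetic data (no class signal at all)
trial-level folds yield AUROC near 0.7, while list-grouped folds sit at
chance.  Within the grouping, assignment keeps both classes on every
training side; class-blind splits of small imbalanced datasets routinely
produce single-class training folds.  The model is retrained from scratch
per fold and test-fold probabilities are pooled into one ROC per
experiment.  There is no early stopping, no inner validation split,
and no resampling-based class rebalancing; optional inverse-frequency loss
weights exist but default off.  `train_test_distinct()` trains on one
experiment and scores another, quantifying the optimism of
cross-validation.  `ablate_beta()` drops the beta rows to measure what
they contribute.

# Evaluation

`auroc()` is the rank (Mann--Whitney) statistic, ties counting one half;
`youden_point()` scans every ROC threshold for the maximum of
$J = \text{sensitivity} + \text{specificity} - 1$, breaking J ties toward
higher sensitivity, and reports the full confusion metrics there.  PPV and
F1 are reported as 0 when no positive predictions are made.
`compare_aurocs()` wraps the two-sided paired / unpaired t-test; for
identical paired lists (zero-variance differences) it reports $t = 0$,
$p = 1$ rather than NaN.

# The explanatory GLM

`fit_auroc_glm()` models per-experiment AUROC with ordinary least squares
(normal family, identity link, fixed intercept, no random effects) on six
covariates --- electrode type (depth 0 / subdural 1), contact count, mean
HG burst SNR, mean beta burst SNR, recall probability, word-trial count
--- through a *curated* set of 41 interaction terms
(`glm_terms_default()`), headlined by the four-way
`e_num:hg:beta:recall_p` interaction.  The curated set is not
hierarchically closed, so centering covariates changes the fitted model;
the complete $2^6$-style factorial is available behind
`full_factorial = TRUE` and carries the usual invariances.  Covariates
enter raw (unstandardized).  The whole-model F statistic tests against the
intercept-only model; with 62 experiments the design leaves 20 residual
degrees of freedom.  Rank-deficient designs fail loudly, naming the
collinear terms.

# Time-series LIME

`lime_explain()` adapts LIME to multichannel time series: each tensor row
is tiled into 10 equal segments (default), perturbed copies zero a random
subset of (row, segment) cells --- zero is the natural "no burst" baseline
of the non-negative convolved series --- and an ordinary least-squares
surrogate of the model probabilities on the binary masks ranks cells by
coefficient magnitude.  The top 20% (ceiling) are flagged influential, and
`lime_aggregate()` counts flags across trials.  The surrogate needs at
least twice as many perturbed copies as cells (default 4×); plain least
squares, with no kernel weighting or adaptive segmentation, keeps the
explanation exactly reproducible and oracle-checkable.

# Numerical and degenerate-input policy

* Zero or constant channels: standardization excludes them with a
  warning; the SNR estimator raises an error (SNR undefined).
* Single-class datasets are rejected before any training.
* Epochs that would run past the recording end are dropped with a
  warning; whole recall epochs past the end are an error.
* AUROC/Youden on single-class labels: error, not NaN.
* The wavelet grid is clipped below Nyquist; requesting frequencies at or
  above Nyquist is an error.
* All tolerances asserted in the test suite are stated there explicitly;
  kernel evaluation is exact to float64 rounding on ±5 w support.

# Known limitations

The detector's z = 2 seed threshold admits a noise-event floor that the
power-scaled representation down-weights but does not remove; burst
*counts* alone are therefore a poor readout at this threshold.  Contour
half-maximum extents systematically under-cover the true burst extent
(roughly a third of the duration inward per boundary, partly offset by
wavelet smoothing), so boundary errors scale with burst duration.  The
GLM's curated term set is reported exactly as specified even though a
hierarchically closed design would be statistically cleaner.  CNN training
at very small epoch budgets depends on the batch-norm recalibration
described above; without it, reported probabilities are not meaningful.
The synthetic generator's recall regime is a modeling construct --- state
decoding results on synthetic data validate the pipeline's mechanics, not
the neuroscience claim itself.
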