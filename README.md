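# memburst

Decoding verbal memory state and performance from intracranial EEG
high-gamma and beta burst time series.

## The problem

During delayed verbal free recall — study a list of 12 words, solve
arithmetic for 20 s, then recall freely for 30 s — posterior parietal
cortex shows transient band-limited power bursts: high-gamma (HG,
80–200 Hz) events tracking local population firing and beta (15–40 Hz)
events linked to information gating. `memburst` asks whether the *timing
and power of these discrete bursts alone* can classify, within an
experiment:

* **memory state** — is this 3-s window word encoding or free recall?
* **encoding performance** — will this studied word later be recalled?
* **recall performance** — is this a good or a poor recall session?

The package is aimed at researchers who work with task iEEG and want a
fully testable reference implementation of burst-based decoding: every
stage runs on synthetic sessions with known ground truth, so each claim
the pipeline makes is checkable against planted bursts and labels.

## The method

1. **Preprocess** — bipolar montage, zero-phase 60 Hz Butterworth notch
   (4th order, 2 Hz stop-band), per-session standardization, and an
   automated low-voltage screen (sliding 200 ms RMS; flags channels whose
   band RMS never reaches 5 µV in HG or 10 µV in beta).
2. **Detect bursts** — topographical analysis of the complex Morlet
   wavelet transform: per-frequency robust z-scoring, local maxima with
   z ≥ 2 as seeds, flood-fill expansion to the half-maximum contour on
   the baseline-relative power excess, strict band filtering, and
   resolution-aware merging. Each event gets an onset, offset, peak
   frequency and power.
3. **Convolve** — each burst becomes a Gaussian kernel

   `f(t) = A · exp(−(t − p)² / (2 w²))`

   with `A` the burst's power density (contour power / duration,
   median-normalized per channel/band), `p` the onset–offset midpoint,
   and `w` the burst duration; kernels sum into one non-negative trace
   per contact per band.
4. **Tensorize** — 2-D trial tensors stack the traces contact-major (HG
   row then beta row per contact): 3-s stimulus-locked encoding epochs,
   random 3-s recall segments, or whole 30-s recall epochs labeled
   good/poor against the modal recall count.
5. **Decode** — small 1-D CNNs (Conv1D 64–128–64, kernel 3, batch norm,
   global average pooling, sigmoid; Adam), trained with list-grouped
   k-fold cross-validation (overlapping epochs never span a train/test
   split) or on fully distinct train/test experiments, with a
   beta-ablation variant to isolate what the beta rows contribute.
6. **Evaluate & explain** — pooled ROC/AUROC, confusion metrics at the
   maximum of Youden's J, a normal-identity GLM relating per-experiment
   AUROC to electrode type/count, band burst SNRs, recall probability and
   trial count (41 curated interaction terms), and a time-series LIME
   that ranks (electrode × band, time-segment) cells by influence.

## Worked example

```r
library(memburst)

# one synthetic experiment: recalled words get 3x the HG burst rate
cfg <- default_config(seed = 5)
res <- run_pipeline(cfg, out_dir = "run1")
res$result
#> Decode result: n = 72, AUROC = 0.819, Youden J = 0.521 (sens 0.833, spec 0.688, acc 0.736)
res$session
#> Synthetic iEEG session: 1 channel(s) x 498 s @ 500 Hz, 6 lists, 24/72 words recalled, 669 planted bursts
head(res$bursts, 3)
#>       channel band onset_s offset_s duration_s peak_freq_hz      power
#> 1 LSMG1-LSMG2   HG   0.014    0.328      0.314          130 1.6743e-03
#> 2 LSMG1-LSMG2   HG   0.306    0.356      0.050          186 7.9775e-05
#> 3 LSMG1-LSMG2   HG   0.314    0.348      0.034          122 1.0167e-04
```

Reading this output: the generator planted 669 bursts across the task
schedule of a 6-list session; the burst table is what detection recovered
from the noisy voltage traces (times in seconds, power in wavelet
magnitude² units — the first rows here are weak background events from
the lead-in; planted bursts carry powers orders of magnitude larger), and
the decode result says the burst-tensor CNN, cross-validated over the 72
word trials with list-grouped folds, separated subsequently recalled from
forgotten words with AUROC 0.82. At the Youden-optimal threshold it
catches 83% of recalled words while correctly rejecting 69% of forgotten
ones. A null session (class effect 1.0) yields AUROC ≈ 0.5 by the same
path. `run1/` contains the QC report, burst table, fold predictions,
metrics report and a manifest; rerunning with the same config reproduces
them byte for byte.

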