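---
title: "Hybrid convolutional-recurrent units for EEG seizure detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid convolutional-recurrent units for EEG seizure detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Epileptic seizures appear in single-channel EEG as high-amplitude rhythmic
discharges that differ sharply from healthy background activity and from
interictal (between-seizure) epileptiform transients. `seizunit` implements
a deep classifier for the five-set Bonn corpus layout: sets A and B are
scalp recordings from healthy subjects (eyes open / closed), C and D are
intracranial interictal recordings (contralateral hippocampus /
epileptogenic zone), and E contains ictal (seizure) waveforms. Each record
is 23.6 s of a single channel sampled at 173.61 Hz (4,097 samples).

The network is a stack of one to four feature-extraction *units*, each

> Conv1D (ReLU, stride 1, valid padding) → bidirectional LSTM or GRU
> (full sequence output, directions concatenated) → average pooling,

with a dropout stage between consecutive units, followed by Flatten, a
stack of ReLU dense layers and a softmax output trained with categorical
cross-entropy and Adam. The convolution extracts local waveform motifs,
the bidirectional recurrent layer integrates them over time in both
directions, and pooling halves the temporal axis so that successive units
operate at coarser scales. Thirty published configurations cover six input
regimes (full-length, 11.8 s and 1 s segments, each raw or band-pass
filtered) times five classification tasks (A–E, B–E, AB–CD–E, AB–C–D–E,
A–B–C–D–E); each is available with either recurrent cell type, giving 60
study × task × cell combinations resolved by `get_config()` from a YAML
registry.

## Evaluation protocol

Records are segmented *before* splitting: studies 1–2 use whole records,
3–4 use non-overlapping 2,048-sample halves, 5–6 use 178-sample (1 s)
windows with the 3-sample remainder discarded. Five-fold cross-validation
partitions segments with class stratification; each fold trains a fresh
model and is evaluated by argmax prediction on its held-out fold. With the
full corpus this reproduces the published arithmetic: 1,000 half-length
segments split 800/200, 200 full-length binary records split 160/40, 500
multiclass records split 400/100.

Four metrics are computed from each fold's confusion matrix and averaged
over folds. For two classes the seizure set E is the positive class, so
sensitivity is seizure recall:

$$\mathrm{Acc} = \frac{TP+TN}{TP+TN+FP+FN},\quad
\mathrm{Sens} = \frac{TP}{TP+FN},\quad
\mathrm{Spec} = \frac{TN}{TN+FP},\quad
F_1 = \frac{2TP}{2TP+FP+FN}.$$

For more than two classes the published tables report single values
without defining the reduction; `seizunit` uses the unweighted one-vs-rest
macro average (and the ordinary multi-class accuracy), the symmetric
default. Per-class metrics with empty denominators are defined as 0 with a
warning. Splits are stratified at segment level, matching the 800/200
arithmetic; this lets segments of one record appear in both train and test
folds for studies 3–6, which mirrors the protocol being implemented rather
than a leakage-free design — `make_folds()` operates on labels only, and a
group-aware split can be built from `group_ids` if leakage-free evaluation
is wanted.

## Preprocessing

Even-numbered studies band-pass the raw signal to 0.5–50 Hz with an
order-2 Butterworth design applied forward and then backward (zero net
phase, no time delay; the effective magnitude response is the squared
one-pass response, so the −3 dB design points become −6 dB). Filter
coefficients come from `signal::butter()`; the forward–backward pass uses
odd-reflection edge padding of `3 × 2·order` samples per side, an
implementation constant chosen to match common practice; residual edge
transients from the 0.5 Hz corner are visible within roughly 2 s of the
record ends, which is why the filter-response tests measure amplitudes on
the central part of a tone. No amplitude normalization is applied anywhere
in the pipeline (none is part of the published method); a per-segment
z-score helper exists for experimentation but is never applied by default.

The choice of 178 samples for the "1 s" studies is taken as printed even
though 173.61 Hz × 1 s ≈ 174 samples; the numeric inconsistency is in the
source and is reproduced, not resolved.

## The surrogate EEG generator

Testing a seizure-detection pipeline requires data with the right class
structure, not physiologically realistic EEG. `generate_record()` builds
each record as 1/f^α colored noise (unit standard deviation) plus
narrow-band random-phase sinusoids, class-specific transients and white
noise (sd 0.3). Defaults, chosen once to caricature the five sets:

| class | background α | band peak (Hz, rel. power) | transients |
|---|---|---|---|
| A | 1.0 | 10 ± 1, 0.5 | — |
| B | 1.0 | 10 ± 1, 1.5 | — |
| C | 1.3 | 6 ± 1, 0.6 | spikes 0.3/s, amp 3 |
| D | 1.5 | 5 ± 1, 0.6 | spikes 0.7/s, amp 4 |
| E | 1.0 | — | 3–12 Hz bursts, gain 5 |

Interictal spikes are biphasic derivative-of-Gaussian templates (σ = 20 ms)
at Poisson times; ictal bursts are Hann-windowed sinusoids of 1.5–3 s with
uniform 3–12 Hz carriers and ~0.75 duty cycle at five times the background
sd, which concentrates well over 60% of total spectral power in the burst
band and makes ictal records separable from all other classes by a simple
variance threshold — the oracle the end-to-end tests rely on. Amplitudes
are unit-free: the Bonn corpus stores integer ADC counts whose absolute
scale carries no information, and since the pipeline applies no
normalization, a unit-scale background is the neutral choice. Everything
is seeded (per-record seeds derived from one master seed), so datasets are
bit-reproducible.

What the surrogate deliberately omits: real artifact structure
(EMG/EOG/electrode pops), inter-subject variability, non-stationary
background drift, and realistic spike morphology. A test passing on
surrogate data therefore demonstrates that the implementation learns and
evaluates correctly under the published protocol, not that the
architecture reaches any particular accuracy on clinical EEG; published
Bonn accuracies can be checked by pointing `run_study()` at a downloaded
Bonn directory.

## The training engine

No deep-learning framework is involved: the package carries a compact
sequence-model engine (RcppArmadillo) implementing exactly the layers the
architecture needs — Conv1D via im2col, bidirectional LSTM/GRU with
standard cell equations, average pooling, inverted dropout, dense layers,
softmax — trained by backpropagation through time with Adam
(β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷). Analytic gradients are verified against
central finite differences in the test suite for both cell types through
the full stack. Training and prediction run in float32 with a polynomial
`exp` (relative error < 2×10⁻⁷); the float64 instantiation of the same
templated code backs the gradient checks. On a single core a Study-1
binary fold (160 full-length records, 10 epochs) trains in roughly half a
minute.

Weights are initialized with uniform Glorot draws for all kernels
(recurrent kernels included) and zero biases except the LSTM forget gate,
which starts at 1 — a standard stabilization for long sequences. Data are
reshuffled each epoch; the last batch of an epoch may be smaller than 64.
Runs are deterministic given the seed on a fixed platform (weight draws,
shuffling and dropout masks all derive from it); bit-identical results
across BLAS implementations are not promised.

## Choices where the published description is silent

* **Pooling size/stride**: 2/2 in every unit — the smallest non-trivial
  downsampling, standard practice.
* **Conv activation**: ReLU, consistent with the dense stages.
* **Bidirectional merge**: concatenation (doubles the channel count).
* **Recurrent stages emit full sequences** — required for a following conv
  or pooling stage to have a time axis.
* **Adam learning rate**: 0.001 (exposed in the train configuration).
* **Dropout placement**: one stage after each unit except the last.
* **Missing registry values** (the Study-1 dropout rate, several dense
  widths, Study-4/5 epoch counts): documented fallbacks — dropout 0.1
  (the rate every other study states), dense width 100 (the most common
  published width), 150 epochs (the count stated for every non-binary
  model in studies 1–3). Such entries are flagged `incomplete` and
  `get_config()` warns when resolving them.
* **Prediction ties** break toward the lowest class index.
* **Failed folds** (non-finite loss) are excluded from averages and the
  report is marked partial, never silently averaged.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the full published
arithmetic (500 surrogate records of 4,097 samples) for segmentation and
fold counts, and train the published Study-1 A–E stack end-to-end on 200
strongly separated surrogate records for 10 epochs — enough for the
separability the generator guarantees, while the published epoch counts
(50–150) remain available through `run_study()`'s defaults. The
shuffled-label control uses 100 records at the same architecture. These
sizes are the package's chosen desk-scale study conditions; reported
wall-clock timings are informational only, since they are
hardware-dependent.

## Known limitations

* Segment-level (not record-level) splitting for studies 3–6 follows the
  protocol but permits within-record information sharing across folds.
* The macro-average reduction for multi-class sensitivity/specificity is a
  documented choice; other reductions (micro, weighted) would give
  different table values.
* The engine is single-threaded and CPU-bound; the published 150-epoch
  multiclass configurations are hours-scale runs on one core.
* Surrogate data cannot validate clinical performance claims.
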