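---
title: "Methods: energy-efficient seizure detection on iEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-efficient seizure detection on iEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ictalscan)
```

# The problem

Responsive neurostimulation for focal epilepsy needs a seizure detector
that (i) fires within the first seconds of electrographic onset, so a
stimulus can still interrupt the seizure, and (ii) runs continuously on
an implant's power budget. Those two goals pull in opposite directions:
rich classifiers detect earlier and more specifically, but cost energy.
`ictalscan` implements and compares three detectors of increasing
cost — line-length thresholding (the strategy of the only approved
responsive implant), a Random Forest, and an RBF-SVM — on identical
1-second iEEG epochs, scores them with a protocol that separates
*whole-seizure* from *early* detection, and simulates what the winning
classifier loses when it is pushed through a 10-bit ADC, 16-bit
fixed-point arithmetic, and a compact flash-resident tree format.

# Data model and preprocessing

The unit of analysis is a **one-seizure block**: a segment of
multichannel iEEG containing exactly one annotated seizure (clinically,
1 h; tests and the acceptance run use 600 s blocks, and every
duration-dependent metric normalizes by analyzed time). Channels belong
to physical electrodes; **local re-referencing** subtracts each
electrode's per-sample mean from its channels, removing far-field
common signals.

Preprocessing follows the fixed chain: decimation to 256 Hz
(anti-aliased, integer factors), 0.5 Hz high-pass (2nd order) for slow
drifts, a biquad notch at the powerline frequency (half-width 2 Hz, a
design the source protocol leaves open), and a 6th-order Butterworth
low-pass at 50 Hz that removes high-frequency burst content responsible
for false positives. Offline filtering is zero-phase
(forward–backward, with steady-state initial conditions so constant
inputs produce no startup transient — without this, the 0.5 Hz
high-pass rings for seconds at the block edges); a causal single-pass
variant (`zero_phase = FALSE`) exists for the embedded simulation,
since an implant cannot filter backwards in time.

Epochs are contiguous, non-overlapping, 1 s long; a trailing partial
window is dropped. An epoch is **ictal** iff its half-open interval
intersects the seizure annotation. **Artifact rejection** flags an
epoch per channel when its variance falls below 0.1× the channel's mean
epoch variance, its peak amplitude exceeds 10× the channel's block
standard deviation, or its peak-to-peak range is numerically zero. The
0.1/10 thresholds are package choices (the criteria, but not numbers,
come from the source protocol); 10× deliberately mirrors the ±10σ
full-scale rule of the embedded front end. Flagged epochs are excluded
from training and from ROC scoring and count as non-detections.

# Features

Ten features per epoch and channel, in a fixed order that doubles as
the embedded feature index: mean, mean absolute deviation, variance,
skewness, kurtosis, line length, lag-1 autocorrelation, beta and gamma
band power, and the power ratio. Conventions are fixed and documented
rather than configurable where consistency matters more than choice:

* moments use the population (1/N) convention; kurtosis is non-excess
  (Gaussian → 3); zero-variance epochs return 0 with a degenerate flag;
* line length is `Σ |x(k−1) − x(k)|` over the N−1 successive pairs
  (the classic low-cost feature, sensitive to amplitude *and*
  frequency);
* autocorrelation is lag-1 — the lag is unstated in the source
  protocol, and one sample is the cheapest embedded choice; the lag is
  an argument for sensitivity analyses;
* band powers integrate a Hann-tapered single-window periodogram
  (what Welch's method degenerates to on one 256-sample segment), in
  signal² units; bands are half-open — alpha [7,13), beta [13,30),
  gamma [30,50] — so no bin is counted twice;
* the power ratio is `bp(γ) / (bp(α) + bp(β) + ε)`, ε = 1e−12 signal²,
  floor only; it is the feature designed for low-voltage fast activity
  (LVFA) onsets, where gamma power rises while alpha/beta power falls.

A flat-spectrum check worth recording: on white noise the *ratio of
mean band powers* equals the bin-count ratio 21/23 ≈ 0.91 (21 one-hertz
gamma bins over 23 alpha+beta bins). The mean of per-epoch *ratios* is
noticeably larger (Jensen's inequality at ~23 denominator bins), which
is why the test asserts the ratio of means.

# Detectors

**Line length** is training-free: per block and channel, the line-length
feature is z-scored with the block's own mean and standard deviation
(the reference protocol computes these per 1-h segment — note that this
uses the segment's own ictal epochs in the statistics; a causal
running-statistics variant would avoid the leak but is not the
reference behavior). Detection is `z > 3` by default; since z-scoring
is monotone, the ROC is identical to thresholding raw line length.

**Random Forest** is implemented from scratch (compiled core): 100
bagged CART trees, bootstrap samples of the training size (≈63.2%
unique rows — "about two thirds"), `mtry = ⌈√10⌉ = 4` random candidate
features per node, splits maximizing Gini impurity decrease over
midpoints between consecutive distinct values, growth until purity or
fewer than 5 samples (the stopping floor is a package choice, exposed).
Tie-breaks are deterministic: lowest feature index, then lowest
threshold. Out-of-bag error is computed from each tree's held-out rows.
The score is the seizure vote fraction; the default threshold 0.5 is a
strict majority. Trees are stored in preorder with the left child
adjacent, so a node needs only its right-child address — exactly the
layout the 5-byte on-device format uses.

**SVM**: features are z-scored with training-set statistics (stored in
the model, reapplied at scoring). `(C, γ)` are grid-searched —
defaults C ∈ 2^{−5..15}, γ ∈ 2^{−15..1} in powers of four — by
stratified 5-fold CV accuracy, refit at the best pair (ties toward
smaller C, then smaller γ). The dual is solved by a max-violating-pair
SMO with an in-memory kernel; the contract is the max-margin
optimality of the decision function, not the solver schedule. Training
sets beyond `max_train` rows are stratified-downsampled to bound the
quadratic kernel cost; the acceptance run uses `max_train = 600` and a
reduced grid, stated where used.

**Multichannel fusion**: the reference protocol specifies a logical OR
across the (up to four) detection channels for line length and is
silent for RF/SVM. Concatenating 4×10 features would contradict the
stated 4-of-10 mtry, so per-channel models fused by per-epoch maximum
score are used; thresholding the max equals the OR of per-channel
detections, making score-mode fusion the continuous relaxation of the
stated rule.

# Evaluation protocol

Leave-one-seizure-block-out: for each block, detectors train on all
other blocks and score the held-out block (line length, training-free,
uses the held-out block's own normalization); out-of-fold scores are
pooled for ROC/AUC. AUC uses the rank (tie = ½) convention, so it is
exactly the probability of ranking a random ictal epoch above a random
interictal one. **Early-detection AUC** relabels: only ictal epochs in
the first 10 s after onset are positives; later ictal epochs are
*excluded* (scoring them as negatives would brand genuine-but-late
detections as false alarms — the alternative event-level reading of
the protocol is not derivable from its description, and exclusion is
the conservative choice). **Delay** counts epochs: detecting the k-th
ictal epoch first is k seconds, so 1 s is the floor; a detection 0–5 s
before the labeled onset counts as correct with zero delay (onset
annotation is only reproducible to a few seconds between reviewers).
Misses are excluded from mean delay and reported separately.
**FDR** is false detection events per analyzed non-ictal, non-masked
hour, with consecutive false epochs merged into one event by default
(both variants available). In single-channel mode the channel with the
highest whole-seizure AUC is selected per dataset, ties to the lowest
index.

# Embedded simulation

The front end maps ±10 signal standard deviations onto the 10-bit ADC:
`gain = 2·10·σ·2¹⁰ / V_ref` (the "resolution" in the gain rule is read
as 2^bits counts and the leading 20 as 2×10σ; both factors are config
so alternative readings are reproducible). Quantization is uniform
mid-rise with clipping at the rails — clipping *is* the artifact
suppression. In-range reconstruction error is ≤ LSB/2 by construction.

Fixed-point features recompute the ten features from centered ADC codes
with every feature value truncated (toward zero, saturating) to a
`word_bits`-wide word in a per-feature Q-format whose integer bits are
sized to the feature's dynamic range at the given ADC width (e.g.
2·adc_bits for power-like features). Accumulations use the hardware
MAC's double-width registers, so truncation is applied at feature
output; spectral features are computed with a floating FFT, as on the
target's DSP accelerator, then truncated. The half-code mid-rise offset
is removed before accumulating, which makes the wide-word limit exact:
at `word_bits = 52` the fixed-point pipeline matches the float pipeline
to ≤ 1e−6 relative, the correctness anchor for the Q-format ledger. At
16 bits, coarse steps on the wide-range features are the simulated
truncation error; saturation events are counted and reported.

The serialized forest spends 5 bytes per node — int16 threshold
(per-feature fixed-point scale stored in the header), uint16
child-or-label, uint8 feature index (0xFF marks a leaf) — after a small
header (magic, version, counts, 10 float64 scales, per-tree root
offsets). Preorder layout makes the left child implicit.
Short-circuit voting evaluates trees in training order and stops at 50
negative votes (→ non-seizure) or 51 positive votes (→ seizure), which
provably equals the full 100-tree majority with ties counted as
non-seizure; internal-node visits per decision are the hardware cost
proxy.

# The synthetic generator: what it emulates, what it does not

Background activity is 1/f-shaped colored noise (exponent 1, σ = 20 µV)
plus a drifting-phase 10 Hz alpha rhythm (10 µV), a low-amplitude
powerline sinusoid (2 µV), and a sub-0.5 Hz drift (30 µV) — one
component per preprocessing stage, by design. Seizures occupy a random
mid-block interval (60 s default) on 1–4 seizure-onset-zone channels:

* **LVFA**: background attenuated to 0.4× plus a 40 Hz narrowband
  component whose amplitude ramps linearly from 0 to 30 µV over the
  first 10 s — the ramp deliberately makes the early-detection window
  harder than the established seizure;
* **rhythmic spiking**: biphasic sharp transients at 3 Hz, ~120 µV;
* **rhythmic beta**: a 20 Hz burst, 40 µV, 2 s onset ramp.

An `lvfa_amplitude_neutral` switch rescales the gamma component so
total power is unchanged — a pure spectral redistribution used to show
that band-power features (hence the forest) retain an edge where the
amplitude-driven line length weakens. Artifacts are 2-s flatlines and
0.25-s ±12σ transients at 6/h, never overlapping the seizure ±10 s.
These effect sizes are stated-world choices made once: they describe a
clearly detectable focal seizure with realistic contrast (the source
protocol does not quantify its patients' onset spectra), and they were
not adjusted against test outcomes.

What a green pipeline test establishes: the features separate what they
are designed to separate, training/evaluation are leak-free and
deterministic under seeds, and the embedded path loses almost nothing
at 10-bit/16-bit precision *on signals with this structure*. What it
does not establish: clinical sensitivity/FDR, robustness to
non-stationary backgrounds, electrode drift, state-dependent (sleep)
rhythms, or inter-patient variability — none of which the generator
models.

# Numerical choices and degenerate inputs

* Filters: bilinear-transform Butterworth designs with prewarping;
  coefficients match the reference scientific-Python implementations to
  ~1e−12. Zero-phase filtering applies the magnitude response twice.
* Zero-variance epochs: skewness/kurtosis/autocorrelation return 0 with
  a degenerate flag rather than NaN, so downstream matrices stay finite.
* `power_ratio` ε floor 1e−12 signal²; a pure-gamma epoch returns a
  large finite ratio rather than Inf.
* Split thresholds are midpoints of consecutive distinct values; a node
  that cannot improve Gini becomes a leaf; leaf ties label non-seizure
  (the conservative direction for a detector).
* Forest training, fold assignment, subsampling, and the generator all
  derive per-stage seeds from one integer via a documented hash, so
  every stage is independently reproducible and the whole run is
  bit-identical under a fixed seed.
* The SMO stops at a 1e−3 duality-gap tolerance; the bias is averaged
  over free support vectors (midpoint of the violating-pair bounds when
  none are free).

# Known limitations

* The SVM's in-memory kernel caps training sizes (~6,000 rows); the
  documented downsampling keeps the published protocol's contract but
  is a deviation from training on every epoch of multi-day records.
* Line-length block statistics include ictal epochs (reference
  behavior); the provided causal variant is not the default.
* EDF I/O is not implemented (no EDF library in the supported
  dependency set); recordings interchange as CSV/JSON bundles.
* The embedded simulation models precision effects, not timing, memory
  contention, or power; node visits per decision are a proxy, not a
  cycle count.
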