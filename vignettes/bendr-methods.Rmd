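---
title: "Self-supervised contrastive pre-training for raw EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised contrastive pre-training for raw EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bendr)
```

## The problem

Deep networks for EEG classification must learn both a feature
representation and a classifier from small labeled datasets, while the
signal itself varies strongly across subjects, sessions, and recording
hardware. The approach implemented here treats representation learning
as a self-supervised sequence-modeling problem: compress raw EEG into a
slow sequence of learned vectors (BENDR — BErt-inspired Neural Data
Representations), mask contiguous spans of that sequence, and train a
transformer to produce, at each masked position, an output more similar
to the true hidden vector than to distractors sampled from the same
sequence. The pre-trained stages are then transferred to downstream
classification tasks in six configurations.

Everything here runs at desk scale on synthetic EEG; no external data
are needed. This vignette records the model, its assumptions, the
parameter choices, and what the desk-scale experiments do and do not
demonstrate.

## Harmonization to a canonical representation

All inputs are mapped to a fixed 20 x T representation at 256 Hz:

* **Channels.** The 19 electrodes of the unambiguously placed
  international 10/20 set, in a fixed row order, matched
  case-insensitively with the legacy aliases T3/T4/T5/T6 for
  T7/T8/P7/P8 and bipolar derivations mapped to their first electrode.
  Fpz (absent from the reduced set but common in sleep montages as
  FPz-Cz) is aliased to Fp1 as the nearest frontopolar row; this is a
  pragmatic choice, not a claim about scalp geometry. Surplus channels
  are dropped, missing rows are zero.
* **Sampling rate.** Recordings are first brought to the whole multiple
  or divisor of their native rate nearest 256 Hz (sample repetition
  upward, decimation downward; ties break toward the higher rate), then
  mapped to exactly 256 Hz by nearest-neighbor indexing,
  `round(j * f_in / f_out)` with half-up rounding. Content above the
  target Nyquist must be removed first; `apply_antialias()` is a
  zero-phase Hamming-window FIR low-pass with a transition band of 10%
  of the cutoff, applied forward-backward.
* **Amplitude.** One weight and offset per sequence (all channels
  jointly) map the sequence extremes to exactly [-1, 1], preserving
  inter-channel amplitude ratios. Row 20 carries the constant
  `(trial range) / (dataset range)`, restoring the amplitude
  information the scaling removes. Flat sequences scale to zero (the
  missing-channel sentinel) and are flagged. For downstream trials the
  scaling is applied per extracted trial window; whether the paper-scale
  procedure scales per trial or per session is genuinely open, and the
  per-trial choice keeps trials self-contained.
* **Windows and trials.** Pre-training windows are non-overlapping 60-s
  segments (15,360 samples); trailing remainders are dropped. Trials
  are cropped at `floor((onset + start) * 256)` samples with half-open
  windows; trials overrunning the recording are dropped and counted.

## Encoder and contextualizer

The encoder is six 1D convolution blocks (convolution, GroupNorm, GELU)
with kernel lengths (3, 2, 2, 2, 2, 2) and stride equal to kernel, so
receptive fields tile the input without overlap and the sequence is
downsampled by 96: one 512-dimensional vector per 375 ms at 256 Hz
(effective rate about 2.67 Hz). Because kernel equals stride, each
block is a reshape followed by a dense multiply, which is also how the
implementation computes it. GroupNorm uses 16 groups by default (any
divisor of the filter count is valid; the paper-scale configuration
does not state the group count, and 16 matches the position encoder's
grouping). Convolution biases are enabled; encoder weights use Kaiming
fan-in initialization.

The contextualizer is a standard transformer encoder (8 layers, 8
heads, model dimension 1536, feed-forward 3076 at paper scale) with all
internal normalization removed and T-Fixup-style initialization:
Xavier baselines everywhere, with value projections, attention output
projections and feed-forward weights scaled by `0.67 * N^(-1/4)`.
LayerDrop (p = 0.01) and dropout (p = 0.15) are active during
pre-training only. Position is encoded additively by a grouped
convolution over the sequence (receptive field 25 tokens — more than
9 s of signal — 16 groups, GELU on the convolution branch, same-length
zero padding), which keeps the architecture sequence-length
independent. A fixed start token (a vector of -5, outside the
harmonized signal range) is prepended; its output is reserved for
classification and is never masked or trained during pre-training.

The BENDR dimension (512) and the model dimension (1536) are bridged by
a learned linear up-projection at the input and an untied down-projection
at the output, so that the contrastive similarity and the
classification heads both operate in BENDR space. This bridging is not
specified at paper scale; a learned linear pair is the minimal
mechanism that makes the loss's vectors commensurable.

GELU is computed with the tanh approximation (max error about 1e-3
relative to the exact form); the cached tanh makes the hand-written
backward pass free of additional transcendentals. All gradients in the
package are closed-form and are verified against central finite
differences in the test suite.

## Pre-training objective

For a window encoded as `b_1..b_L`, each position independently begins
a masked span of 10 tokens with probability 0.065 (spans may overlap
and truncate at the end; an interior token is masked with probability
`1 - (1 - 0.065)^10 = 0.489`). Masked positions are replaced by a
single learned mask vector before the transformer. At each masked
position `t` the loss is the negative log-softmax, at temperature
0.1, of the cosine similarities between the transformer output `c_t`
and a candidate set of the true `b_t` plus 20 distractors drawn
uniformly with replacement from the other positions of the same
sequence. The mean over masked positions, plus the mean squared BENDR
activation (weight 1) computed over the full unmasked output of the
batch, is minimized with Adam (decoupled weight decay 0.01) under a
cosine schedule with 5% linear warm-up. Gradients flow into `c_t` and
into the candidate vectors (hence into the encoder) alike. Batches
whose mask plan comes up empty are resampled once, then skipped.

Evaluation uses deterministic evenly spaced masking: `N_m =
max(1, floor(0.5 * L * 0.065))` spans of 10, spaced `floor(L / N_m)`
apart from the first position — half the training mask budget, with no
overlaps. The span-count formula is applied in BENDR steps, not raw
samples: spans "of 10" are token spans, and the samples reading would
demand ~500 spans in a 160-token sequence, which is impossible.
Accuracy counts a masked position as correct only when the target
similarity strictly exceeds every distractor similarity; ties are
errors.

## Fine-tuning

Six transfer configurations are supported, crossing pre-trained versus
random initialization, full transformer versus pooled-BENDR linear
head, and frozen versus trainable encoder (see `finetune_spec()`).
The pooled head averages four contiguous near-equal sub-sequences of
the BENDR and concatenates them. During fine-tuning, trials are
regularized by masking contiguous time spans of 10% of the trial's
BENDR (start probability 0.01 per token, using the frozen pre-training
mask vector) and zeroing contiguous feature spans of 10% of the
features (51 of 512; start probability 0.005 per feature). Class
imbalance is handled by per-epoch undersampling: every class
contributes exactly the minority count, drawn with replacement for the
larger classes. Metrics are balanced accuracy (mean per-class recall),
plain accuracy, and AUROC (via pROC); normalized scores are
`(value - chance) / (1 - chance)` with chance `1/K` for accuracy/BAC
and 0.5 for AUROC. Evaluation is leave-subjects-out with subjects
assigned to folds atomically, summarized with a 1,000-resample
bootstrap 95% interval over subject means.

## Synthetic EEG

The generator emulates the heterogeneity the harmonizer must absorb:
subjects with sampling rates drawn from {100, 160, 250, 256, 2048} Hz,
montages ranging from the full 19-electrode set through supersets with
auxiliary channels to two-electrode sleep-style pairs, and per-subject
amplitude scales. Signals are sums of band-limited oscillations
(defaults: posterior 10 Hz, frontal 5 Hz, central 20 Hz) with simple
spatial gain vectors, amplitude-modulated by slow sinusoidal envelopes,
over 1/f noise synthesized in the frequency domain with random phases
(exponent 1). The default envelope timescale of 1-5 s places
predictive temporal structure at the token rate, which is what makes
the contrastive task learnable; a long-context mode (20-60 s
envelopes) makes information at lags beyond 20 s useful. Labeled
trials embed a lateralized band-power effect (by default 10 Hz over
C3/C4 at a given power ratio); the standard separable fixture uses a
prominent 30 uV effect rhythm in 6-s trials, at the high end of
physiological rhythm amplitudes, chosen so that a linear readout of
encoder features is comfortably above chance while the null (ratio 1)
dataset is exactly exchangeable. No volume-conduction realism and no
artifacts (EOG/EMG) are simulated: passing tests show the pipeline's
mechanics and learning dynamics, not clinical-grade performance on real
EEG.

## Desk-scale study design

The test suite runs complete studies with reduced sizes, chosen once:

* **Pre-training corpus:** 8 subjects, 240 s each, rates
  {256, 160, 250, 100} Hz, mixed montages; 15-s windows (128 windows).
* **Tiny model:** 64 encoder filters, 2 transformer layers, 4 heads,
  model dimension 64, feed-forward 128.
* **Optimization:** 2,000 steps, batch 2, peak learning rate 1e-3 for
  the tiny model (a standard small-Adam rate; the paper-scale defaults
  remain 1e-4 for pre-training and 5e-5 for fine-tuning, with peak
  rates treated as per-dataset configuration).
* **Learning criterion:** evenly spaced evaluation accuracy on the
  training corpus rises from ~1/21 untrained to several times the 3/21
  target (typical runs reach 0.5-0.6); two of up to three seeds must
  clear the target. At this scale the model does not generalize to
  held-out subjects — each synthetic subject has its own spectral
  fingerprint and eight subjects are far too few — so the criterion
  measures the learning property, not cross-subject transfer, which at
  full scale requires corpus sizes far beyond a test suite.
* **Chance calibration** is measured on white-noise input. On smooth
  EEG-like data even an untrained network scores slightly above 1/21,
  because its residual paths propagate neighboring tokens and
  neighboring tokens are correlated; white noise removes that
  structure and makes the binomial chance model exact.
* **Fine-tune recovery:** variant 2 (pre-trained encoder, pooled
  linear head) on the separable fixture reaches balanced accuracy
  at least 0.8 on a held-out subject within 20 epochs; on the null
  fixture all six variants stay inside a simultaneous 95% chance band
  (Bonferroni over variants), guarding against label leakage anywhere
  in the pipeline.

## Numerical and interface choices

* Sample indexing is 0-based half-open in the harmonization arithmetic
  (documented per function); R-facing token positions are 1-based.
* Degenerate inputs: flat sequences scale to zero with a flag; a trial
  range exceeding the stored dataset range clamps the amplitude channel
  to 1 with a warning; zero vectors make cosine similarity an error
  rather than a silent NaN.
* The EDF reader/writer is a minimal 16-bit implementation (one data
  record per second, integer rates); the writer quantizes with the
  reader's exact affine map, and the test suite cross-checks files
  against an independent Python EDF implementation. EDF+ annotation
  channels are parsed for onset/duration/label; the writer emits
  events as a sidecar CSV. A delimited-text format covers fixtures.
* Checkpoints are RDS containers with a schema version, named sub-trees
  for encoder, contextualizer and heads, and optional optimizer state,
  so encoder-only loading (variants 2 and 6) and resumption both work.
* Run configuration is declarative YAML; unknown keys are errors.
  The command-line entry point (`inst/cli/bendr`) is a thin wrapper
  over `cmd_generate()`, `cmd_pretrain()`, `cmd_evaluate()` and
  `cmd_finetune()`.

## Known limitations

* The contrastive learning demonstrated at desk scale is
  within-corpus; cross-subject generalization of representations needs
  orders of magnitude more data and is out of scope here.
* The GroupNorm statistics couple positions within a sequence, so
  encoder locality (one token per 96 samples) is exact for the
  convolution path but only approximate end-to-end; the tests assert
  dominance of the direct effect rather than strict locality.
* No artifact rejection, re-referencing, or ICA is performed anywhere,
  matching the minimalist preprocessing philosophy of the method.
* The tanh-approximate GELU differs from the exact Gaussian CDF form
  by up to ~1e-3; all gradients are exact for the approximation used.
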