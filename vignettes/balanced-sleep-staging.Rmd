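---
title: "Balanced sleep staging with a two-branch attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced sleep staging with a two-branch attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Overnight polysomnography (PSG) is scored in 30-second epochs into five
stages: wake (W), three NREM depths (N1, N2, N3) and REM. The class mix is
severely imbalanced — in large adult cohorts N1 occupies only about 3–5% of
the night — and N1 is also the hardest class on its merits: it has almost no
characteristic grapho-elements, its spectral content overlaps wake (residual
alpha) and N2 (emerging theta), and human scorers rely heavily on the
surrounding epochs to call it. Plain training ignores N1; plain
inverse-frequency reweighting recovers N1 recall but damages N2 and overall
accuracy, because the network is pushed to find N1 evidence inside single
epochs where there is little to find.

`nocturnet` implements a two-branch architecture and training schedule that
treats this as a trade-off to be managed rather than a constant to be
picked.

## Model

**Feature extractor.** Each 30-s, 5-channel epoch (EEG C3, C4; left/right
EOG; chin EMG; 125 Hz, so a 5 × 3750 tensor) passes through three cascaded
1-d attention residual blocks. A block is

    conv(k = 7) → BN → ReLU → conv(k = 7) → BN → F
    F ⊙ M_C ⊙ M_T  + projected skip → ReLU

with two soft attention maps computed from the intermediate feature
`F ∈ R^{C×T}`:

* channel attention `M_C = softmax(MLP(avgpool_t(F)) + MLP(maxpool_t(F)))` —
  a shared bottleneck MLP (reduction ratio r, default 16) applied to the
  temporally average- and max-pooled channel descriptors, normalised over
  channels, answering *what* feature channels matter;
* temporal attention `M_T = 1 + softmax_t(maxpool_c(F))` — parameter-free,
  answering *where* in the epoch the attended waveform lives. The cascaded
  softmax bounds every gain in (1, 2), so temporal emphasis cannot run away;
  the gains above baseline sum to exactly 1.

Global average pooling yields a 256-dimensional epoch feature (the last
block width).

**Two-branch classifier.** The epoch learning branch (ELB) scores epoch *k*
from its own 256 features. The sequential learning branch (SLB) scores it
from the concatenated features of the context window — N epochs before and
after, N = 2, i.e. a 1280-long input. At test time the stage is
`argmax( α·p_ep + (1−α)·p_seq )` with α = 0.5 by default; ties break to the
earlier stage in (W, N1, N2, N3, REM).

**Transitive training.** The training loss is

    L = α·L_ep + (1−α)·L_seq,    α = 1 − (T/T_max)²

where `L_ep` is the unweighted cross-entropy of the ELB, `L_seq` the
inverse-frequency class-weighted cross-entropy of the SLB, and T the current
training epoch. Two mechanisms make this a *transitive* handover rather than
a simple mixture:

1. **Schedule.** α starts at 1 and decays quadratically to 0: the feature
   extractor first learns universal patterns from the true class
   distribution, and rebalanced contextual learning dominates late.
2. **Gradient gate.** `L_seq` backpropagates only into the SLB; the SLB's
   input features are detached, so the CNN (and ELB) receive exactly
   `α·∂L_ep/∂θ` and the reweighted loss can never distort the universal
   features. This is asserted bitwise in the test suite.

Class weights are `w_c ∝ 1/n_c`, normalised to mean 1 so that `L_seq` stays
on the same scale as `L_ep` and the convex combination in `L` is meaningful.
The weighted cross-entropy normalises by the sum of sample weights in the
batch, which is unbiased under class-imbalanced batches. Probabilities are
clamped at 1e-12 before the log.

## Training procedure and defaults

Adam with initial learning rate 1e-3 and mini-batches of 200; one
multiplicative decay to 10% after 70% of the 140,000 total iterations; a
training epoch is 3,500 iterations; α and validation metrics are recomputed
at each training-epoch boundary; the checkpoint with the highest validation
macro-F1 (MF1) is kept, last wins on ties. Sampling is plain shuffling
without class-balanced batching — avoiding resampling is the point of the
method. These defaults describe the full-scale regime; every experiment in
this package runs a scaled-down configuration (below).

During training, the centre epoch and its 2N context epochs pass through
the CNN in one combined batch, so batch-norm statistics pool over all of
them; backpropagation through those statistics is exact. Ablation regimes
for the rebalancing comparison drop the ELB from the loss: `none` trains the
CNN through the *unweighted* sequence loss, `weighted` through the
inverse-frequency weighted one, with no gradient gate in either.

## Implementation notes

No deep-learning framework is used: the forward pass, backpropagation
(including the attention modules, batch-norm batch statistics and the
gradient gate) and Adam are implemented in C++ (RcppArmadillo), single
precision, with loss accumulation in double. Convolutions are realised as
im2col + GEMM. Correctness is established in the test suite by (a) an
independent double-precision R replica of the forward pass, which must agree
with the C++ path to float precision, and (b) central finite-difference
gradient checks against that replica, run separately for the gated
transitive objective (CNN gradients must equal `α·∂L_ep/∂θ`) and the
ungated sequence-only objective. Training is deterministic per seed on a
fixed platform (single-threaded, own Mersenne-Twister batch sampler).

Numerical edge cases worth knowing: the temporal attention map is strictly
inside (1, 2) in exact arithmetic, but for feature maps with a very large
dynamic range the float softmax can underflow to exactly 1 at off-peak
positions; invariant tests on the float path therefore use closed bounds,
while the double-precision operations `channel_attention()` /
`temporal_attention()` satisfy the strict ones. Argmax ties break towards
the earlier stage in the canonical order. BN uses eps 1e-5 and momentum 0.1.

## Preprocessing

The standard staging chain, and nothing else: EEG/EOG band-pass 0.3–35 Hz,
chin EMG high-pass 10 Hz, hard clipping at ±500 µV, resampling to 125 Hz —
in that order. Filters are 4th-order Butterworth sections applied
forward–backward (zero phase), so K-complex and spindle morphology is not
phase-distorted; the band-pass is realised as cascaded high- and low-pass
sections, which keeps the very low 0.3 Hz edge numerically safe.
Resampling is polyphase with a rational rate ratio, exact for the common
PSG rates (100/125/128/250 Hz). No normalisation, detrending or artifact
rejection is applied — preprocessing beyond this chain does not help
staging models, and amplitude scale is information the EMG channel needs.
Epoch *i* covers samples `[i·3750, (i+1)·3750)`; a hypnogram longer than
the signal is truncated with a warning. `UNSCORED` epochs are dropped from
training and evaluation but their signal remains available as temporal
context for neighbours; context windows never cross record boundaries and
replicate the edge epoch where the window would run out of the recording
(zero-filled epochs would be out-of-distribution for the CNN).

## What the simulator emulates — and what it does not

The package must be testable without access-restricted cohort data, so it
ships a generative model of scored PSG with two calibrated properties:

**Hypnogram dynamics.** Stage sequences are a first-order Markov chain whose
stationary distribution equals typical adult overnight proportions
(W 28.7%, N1 3.7%, N2 41.0%, N3 12.6%, REM 14.0%) *exactly by
construction*: a sleep-structured proposal kernel (routes W–N1–N2–N3 and
N2–REM, sticky self-transitions giving bout lengths of minutes) is converted
into a Metropolis–Hastings chain with that stationary law. The construction
is reversible, so directional cycle asymmetries of real sleep (e.g. the
rarity of N3→REM without passing N2) are only partly captured; marginal
proportions and typical bout durations are the calibrated quantities.

**Signals.** Per stage and channel, band-limited Gaussian noise shaped on a
common band grid (delta/theta/alpha/sigma/beta) with stage-typical RMS
amplitudes, plus deterministic transients: 13 Hz spindle bursts and
K-complex-like biphasic waves in N2 (fewer K-complexes in N3), slow eye
movements in N1, rapid eye movements in REM (anti-correlated on the two EOG
channels), and a broadband 20–60 Hz EMG tone ordered W > N1 > N2 > N3 > REM.
A lognormal amplitude jitter (sd 0.15) varies epochs. Signals are
stationary within epochs and Gaussian apart from the transients — real EEG
microstructure, artifacts, arousals and subject covariates are deliberately
out of scope. Consequently, passing tests demonstrate the *mechanism* of
the method (that rebalanced contextual learning trades off as described),
not clinical-grade performance on real PSG.

**The ambiguity dial λ.** The scientific crux is that N1 is
context-dependent. The simulator operationalises this: at ambiguity λ, each
N1 epoch's generation parameters are a (1−λ, λ) mixture of the N1 profile
and a mimicked stage (W or N2, drawn per epoch) — including transient rates
and EMG tone. At λ = 0 a single-epoch linear probe on band powers separates
N1 well; at λ = 1 the epoch itself is uninformative and only the
surrounding stage sequence identifies N1, which is exactly the mechanism
the sequence branch must exploit. The probe experiment in the test suite
verifies this monotone degradation.

Raw-signal export (`simulate_psg()` + `write_edf()`) synthesises at 250 Hz
so that the preprocessing resampler is exercised nontrivially;
epoch-dataset simulation synthesises directly at 125 Hz.

## Scaled-down experiments

The full-scale regime (thousands of records, 140k iterations) is not a
desk-scale computation, so the package's own experiments run a reduced but
structurally identical configuration, chosen once as the package's study
conditions:

* data: 30 simulated records × 840 epochs (7 h), λ = 0.8, split 80/10/10
  into train/validation/test by record;
* model: block widths (16, 32, 64), reduction ratio 8, ELB 64→64→5,
  SLB 320→128→64→5, block strides (8,4), (2,2), (2,2) — the stride schedule
  is free because global pooling absorbs the temporal length, and an
  aggressive first block keeps the experiment CPU-friendly;
* training: 3,000 iterations per regime, batch 16, 150 iterations per
  training epoch (T_max = 20), learning-rate decay at 70%;
* three regimes (`none`, `weighted`, `transitive`) × three seeds; within a
  seed all regimes share byte-identical data, initialisation and batch
  sequences, so differences are attributable to the rebalancing strategy
  alone.

The expected (and tested) pattern is directional, not a reproduction of
cohort-scale numbers: weighting raises N1 recall over no rebalancing at a
cost in overall accuracy, and the transitive schedule keeps most of the N1
gain while staying above the weighted regime's accuracy in the majority of
seeds.

## Design choices where the design was open

* **Softmax in the channel attention** (not a sigmoid as in older
  squeeze-and-excitation designs): kept exactly in this softmax form; the
  ~1/C magnitude shrinkage it induces is absorbed by the following
  normalisation layers, so no rescaling is added.
* **Shared MLP** for the average- and max-pooled channel descriptors, one
  hidden bottleneck layer — the convention of the attention lineage the
  architecture follows.
* **Residual skip wraps the attention modules**, with a 1×1 strided
  projection and its own BN on the skip path.
* **Learning-rate decay direction**: "10% decay after 70%" is read as decay
  *to* 10% (×0.1), the dominant step-decay convention; the factor is a
  config field (`lr_decay_factor`) for anyone preferring ×0.9.
* **Branch depths**: ELB 256→128→5 and SLB 1280→512→128→5 at full scale —
  the stated branch asymmetry (the SLB has more capacity and a harder
  input) with ReLU activations; both are config fields.
* **Per-record metrics** omit classes absent from that record's human
  scoring (reported as `NA`, macro-F1 over present classes); global metrics
  keep every class with the convention F1 = 0 when precision + recall = 0.
* **Stability split**: an epoch is stable iff both neighbours exist within
  the record and share its label; record-boundary epochs are transitional,
  keeping the stable/transitional partition exhaustive.
* **Trainer weights for partially occupied label sets**: the public
  `class_weights()` errors on a zero count (weights for an absent class are
  undefined), while the trainer computes weights over the classes actually
  present — absent classes never appear in the loss, which lets
  deliberately restricted toy datasets (e.g. three-stage smoke tests) run.

## Known limitations

* The simulator's reversible Markov dynamics and within-epoch-stationary
  Gaussian signals are a mechanism testbed, not a PSG emulator; results on
  real cohorts require real data and full-scale training.
* Single precision bounds the reproducibility of long trainings across
  BLAS builds; per-platform determinism is tested, cross-platform bitwise
  equality is not promised.
* The EDF layer covers continuous 16-bit EDF/EDF+ with voltage channels —
  the subset staging pipelines need — not annotations or discontinuous
  recordings.
* Only the five canonical channels are supported; montage re-referencing is
  delegated to the channel map at EDF load time.
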