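---
title: "Methods: sparse-attention MIL on blood-volume-pulse waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-attention MIL on blood-volume-pulse waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`pulsemil` recognizes binary affect (low/high arousal, and analogously
valence) from a single 30 Hz blood-volume-pulse (BVP) waveform per session,
with only a weak session-level label derived from a 1-9 self-report rating
(1-4 is "low", 5-9 is "high"; the integer scale never ties at the 4.5
midpoint). The physiological premise is that high arousal manifests as
acute, transient sympathetic "events" — brief surges of heart rate and pulse
amplitude — confined to a small part of the session, while most of the
recording is uninformative. That makes the task a multiple-instance learning
(MIL) problem: sessions are bags, non-overlapping 128-sample chunks
(about 4 s) are instances, and no chunk-level labels exist.

## The model

Each chunk is encoded by a **multi-scale temporal dynamics encoder**: a
two-layer convolutional stem (1→16→16 channels, kernel 3) followed by three
parallel dilated-convolution branches whose effective receptive fields are
aligned with the canonical heart-rate-variability timescales:

* short (16→64, kernel 2): 6 frames = 0.2 s, the HF / beat-to-beat scale;
* medium (16→32 k3 d15, 32→64 k2 d31): 66 frames = 2.2 s, the LF scale;
* long (16→32 k3 d31, 32→64 k3 d31): 129 frames = 4.3 s, the VLF scale
  (the whole chunk).

Branch outputs are concatenated (192 channels), fused by a 1x1 convolution
to a 256-channel sequence, and pooled over the 128 time steps by softmax
attention with an affine 256→1 scorer, giving one 256-d embedding per
chunk. All convolutions are stride 1 with same-length zero padding and GELU
activations, and there are no normalization layers: with these exact shapes
the model counts 164,996 trainable parameters at inference and 197,892 in
training configuration (the difference is the 256→128 contrastive
projection head, 32,896 parameters). Those two totals, and the receptive
fields above, are asserted exactly in the test suite; the hidden widths
(scorer 81, classifier 47) were chosen so that both the receptive fields
and the parameter totals hold simultaneously.

A **attention scorer** (256→81→1 MLP with GELU) gives each chunk a scalar
relevance score. Scores are normalized by **sigma-gamma scaling** — division
by a running estimate of the score standard deviation times a learnable
gain — and sparsified by **alpha-entmax** attention, which unlike softmax
can assign exactly zero weight to irrelevant chunks. The session
representation is formed by **gated temporal pooling**

$$h_{pooled} = \sum_{i=1}^{T} \alpha_i \, (g_i \odot h_i),$$

where the gates \(g_i = \sigma(W h_i + b) \in (0,1)^{256}\) weight feature
dimensions and the entmax weights \(\alpha_i\) weight chunks. A shared
affine→GELU→affine classifier serves both as the chunk-level auxiliary head
and, applied to \(h_{pooled}\), as the session classifier; sharing one
parameter set makes the Phase-2 "handover" an identity and is the only
arrangement consistent with the stated train/inference parameter gap.

## Entmax numerics

`entmax_bisect()` solves \(p_i = [(\alpha-1)z_i - \tau]_+^{1/(\alpha-1)}\)
with \(\tau\) found by 50 bisection iterations on
\([\max((\alpha-1)z)-1, \max((\alpha-1)z)]\), which shrinks the bracket to
\(\approx 10^{-15}\); the result is renormalized defensively. The backward
rule uses the Jacobian \(J = \mathrm{diag}(s) - ss^\top/\Sigma s\) with
\(s_i = p_i^{2-\alpha}\) on the support; since \(J\) is symmetric the same
routine serves as JVP and VJP. The tests verify bisection against the
closed-form sparsemax projection at \(\alpha = 2\), the softmax limit at
\(\alpha \to 1\), support monotonicity in \(\alpha\), and the Jacobian
against central finite differences.

For sigma-gamma scaling the per-call standard deviation is computed per
session and folded into a single global running estimate (momentum 0.99,
epsilon 1e-5); the scaled scores always use the running value, so
evaluation is deterministic, and the backward pass treats the running
estimate as a constant (a stop-gradient, as is conventional for running
statistics). Gamma starts at 1 and is trained.

## The three-phase curriculum

Training uses AdamW (batch of 8 sessions; each batch item is the complete
chunk sequence of one session, and attention is always normalized within a
session, never across sessions) with a cosine-annealed learning rate that
restarts at each phase boundary. With the canonical epoch counts
(15, 15, 21) the phases span epochs 0-14, 15-29 and 30-50:

* **Phase 0 — representation.** The encoder, scorer and projection head are
  trained with a supervised contrastive loss over the unit-normalized
  projections of the batch's chunks (positives = chunks sharing the same
  binary label; temperature 0.1; at most 32 chunks per session enter the
  batch) plus \(\lambda_{entropy} = 0.01\) times an entropy-regularization
  term \(-H(\cdot)\) on the scorer's internal softmax distribution, which
  keeps early attention broad. Learning rate 3e-4, weight decay 1e-4.
* **Phase 1 — chunk discrimination.** The projection is frozen; the shared
  classifier is trained as a chunk-level auxiliary head with focal loss
  (\(\gamma = 2\), class weights = inverse training-split class frequency
  normalized to mean 1) on only the Top-K chunks ranked by the scorer's
  entmax (\(\alpha = 1.5\)) attention, with K annealed from 0.9 to 0.3 of
  the chunks across the phase. Chunks inherit their session's label (the
  MIL assumption). Each selected chunk's focal term is weighted by its
  renormalized entmax attention weight — the usual attention-MIL coupling —
  so the scorer is actively trained in this phase: lowering the loss means
  both classifying salient chunks correctly and shifting attention toward
  the chunks that classify well, which progressively cleans the weak-label
  noise on non-event chunks. (A plain unweighted mean over the Top-K
  chunks would leave the scorer without any Phase-1 gradient, since Top-K
  selection is discrete.) Two thirds of the way through the phase (epoch
  25 canonically) the gate/pooling parameters are unfrozen, but the
  session loss is not yet active. Learning rate 2e-4, weight decay 5e-4.
* **Phase 2 — session exploitation.** Everything is fine-tuned on the
  session cross-entropy alone, with the scorer at 0.1x the base rate
  (1e-4) and the pooling entmax \(\alpha_g\) annealed linearly from 1.5 to
  1.8 across the phase, tightening sparsity as training concludes.
  Gradients reach the scorer through the entmax Jacobian.

Schedules are linear (the annealing shape was otherwise unspecified) and
are defined relative to the phase boundaries, so reduced epoch counts keep
proportionally the same curriculum. The best-validation-accuracy checkpoint
(later epochs win ties) is retained alongside the final model. Curriculum
ablations are expressed as variants: `no-topk` holds the Top-K ratio at 1,
`no-aux` skips Phase 1, `no-supcon` skips Phase 0, `direct` trains Phase 2
only.

Every phase loss is verified end-to-end against central finite differences
through the full network (convolutions, pooling, scorer, entmax, gate,
classifier, projection) in the test suite.

## The synthetic generator

Because the affect corpus the method is aimed at is restricted-access, the
package ships a generator whose sessions emulate the relevant structure of
real BVP recordings:

* a cardiac pulse train whose inter-beat intervals are modulated by
  sinusoids centred in the HF (0.25 Hz, 0.03 s), LF (0.1 Hz, 0.04 s) and
  VLF (0.02 Hz, 0.05 s) bands, with per-session random phases and baseline
  heart rate drawn uniformly from 60-90 bpm;
* a two-lobe pulse template (systolic Gaussian, sd 60 ms, unit amplitude;
  dicrotic Gaussian, relative amplitude 0.35, delay 250 ms, sd 90 ms) —
  canonical, easily peak-detectable PPG morphology;
* sparse high-arousal events occupying whole 128-frame chunks (aligned to
  the chunk grid so the chunk-level ground truth is unambiguous), adding
  +20 bpm of heart rate and multiplying pulse amplitude by 1.5 inside the
  event chunks;
* additive white noise (sd 0.05 by default, i.e. 5% of the systolic peak)
  and Poisson-placed motion-artifact impulses (5x pulse amplitude, 3
  samples wide, 2 per minute) caricaturing rPPG extraction artifacts;
* weak labels: high-arousal sessions (and only they) contain events; their
  ratings are drawn uniformly from 5-9, low-arousal from 1-4. Valence
  ratings are uniform on 1-9 and physiologically inert unless the optional
  sustained baseline-HR shift is enabled.

The event surge and gain are synthetic conventions — no published
characterization of real "emotional events" in BVP amplitude exists — so
passing the synthetic benchmark demonstrates that the pipeline can learn
and localize transient events under weak labels, not that it attains any
particular accuracy on real recordings. Real rPPG also exhibits
non-stationary drift, correlated noise, and label noise that the generator
does not model.

## Problem sizes in the test suite

The end-to-end benchmark trains the canonical model on 200 synthetic
sessions of 20 chunks (86 s), half high-arousal with 3 event chunks each,
for 5/5/10 epochs at batch 8, and checks test accuracy, attention
localization (mean entmax mass on event chunks at least 3x the uniform
share) and the sparse-vs-diffuse entropy ordering of entmax vs softmax
attention. The directional ablation checks (full curriculum vs direct
Phase-2-only training, gated vs average pooling, 3 vs 1 branches; medians
over 3 seeds) run at a reduced scale — 100 sessions of 10 chunks, 1/4/3
epochs, with the split stratified by class so the small test set always
contains both classes — chosen so the whole suite completes comfortably on
one CPU while still exercising every curriculum path; the canonical
baseline run is shared across the three comparisons.

## Numerical and degenerate-input choices

* GELU uses the tanh approximation
  \(0.5x(1+\tanh(\sqrt{2/\pi}(x + 0.044715x^3)))\) — the form most deep-
  learning frameworks ship — implemented as a fused compiled kernel whose
  forward pass caches the tanh term so the backward pass is purely
  polynomial; at these activation volumes the elementwise transcendental,
  not the matrix algebra, dominates CPU training time.
* Chunking drops trailing remainder frames (no padding); waveforms shorter
  than one chunk are rejected (training) or skipped with a warning
  (diagnostics).
* Split sizes use half-up rounding on the validation and test fractions,
  the training set takes the remainder; 527 sessions give 421/53/53.
* Top-K uses ceiling and a floor of one chunk; ties break toward the
  smaller index for determinism.
* One-chunk sessions receive attention weight 1 directly.
* Zero-variance score batches leave the running std unchanged with a
  warning; probabilities are clamped at 1e-12 before logs; near-zero
  projections are epsilon-stabilized with a warning.
* Weight decay applies to weight matrices only, not biases or the gamma
  gain.
* All randomness (generation, initialization, shuffling, subsampling)
  derives from explicit integer seeds; repeated runs are bit-identical.

## Known limitations

* The confusion-matrix convention is rows = true, columns = predicted,
  positive class "high"; outputs state this explicitly.
* Two independent binary models are trained (arousal, valence); nothing is
  shared between affect dimensions.
* The gate bias is initialized to +2 (gates start near 0.88, mostly open),
  so the pooled session representation at the Phase-2 handover has the
  same scale as the chunk embeddings on which the shared classifier was
  pretrained; gates then learn to close on unreliable feature dimensions.
* Checkpoints are RDS artifacts (version-tagged) created at run time; the
  package's own fixtures are all generated programmatically.
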