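---
title: "Disagreement-routed encoder fusion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disagreement-routed encoder fusion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Patient portal messages are short, informally written, and usually touch
several topics at once — a symptom report wrapped around an appointment
question, a thank-you note that mentions a medication. Triage needs the one
*primary* concern per message, which makes this a single-label multi-class
problem over an imbalanced schema (by default A = active symptoms,
L = logistics, P = prescriptions, U = other/updates, with A alone covering
more than 40% of a typical corpus).

Different pretrained sentence encoders err on different messages: a generic
encoder handles everyday phrasing, a biomedical one clinical vocabulary, a
social-media one colloquial style. ConcernFusion turns that diversity into a
routing architecture rather than an averaging one:

1. one **baseline classifier** per encoder — the frozen (or fine-tuned)
   encoder's mean-pooled last-hidden-layer embedding, followed by a softmax
   head;
2. a **router** that keeps the consensus label wherever all baselines agree
   and forwards the remaining, genuinely hard messages;
3. a **fusion head** trained *only on disagreement messages*, consuming the
   K per-encoder embeddings stacked into a `K × d` matrix.

The working assumption is that unanimity is a cheap, well-calibrated
confidence signal: where all baselines agree they are nearly always right,
so modelling effort should concentrate on the disagreement set. The
disagreement-bucket analysis (messages grouped by 0, 2 or 3 distinct
baseline labels) makes this measurable — on bucket 0 the routed system
equals its baselines *by construction*, so all improvement must come from
buckets 2 and 3, and the bucket accuracies recombine exactly to overall
accuracy (`Σ_b n_b·acc_b / n`), which the tests assert as an identity.

Fusion heads, in increasing capacity:

- **average** — column-wise mean over the K rows, dense layer, softmax. A
  sanity baseline: with identical rows it reduces exactly to the
  single-encoder head.
- **attention** — additive attention: score `s_k = vᵀ tanh(W_a e_k)`,
  weights `softmax(s)` (always summing to 1), fused vector `Σ w_k e_k`,
  dense + softmax. Lets the model privilege the encoder that is informative
  *for this message*.
- **cnn** — the stack is a single-channel 2-D grid; for each filter size
  `(h, w)` with `h ≤ K`: valid convolution, ReLU, global max pooling; the
  pooled features are concatenated, dropped out, and classified by a dense
  softmax layer. Cross-encoder filters (h ≥ 2) can detect *patterns of
  disagreement* between encoders, which the other heads cannot.

Majority voting over the baselines, with ties resolved by the schema's
ascending lexicographic order (A before L before P before U — the same
order used for every argmax tie in the package), is implemented as the
classical comparison.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `labelSchema()` | A, L, P, U | stored sorted; the order *is* the tie-break order |
| fold plan | 10 folds × 3 repeats | stratified; repeat r reseeded with `seed + r` |
| rebalance `strategy` | — | `class_weight`, `oversample`, `focal`, `none` |
| focal `gamma` | 2 | canonical focusing value; 0 recovers cross-entropy |
| focal/weight `alpha` | inverse frequency | `w_c = N/(K·n_c)`, so `Σ w_c n_c = N` |
| head training | lr 0.05, 300 epochs | full-batch Adam on analytic gradients |
| `fusionConfig` CNN | heights {2,3} (capped at K), width 5, 64 filters/size, dropout 0.1 | TextCNN-style convention |
| attention hidden width | 64 | |
| fusion training | lr 0.01, 150 epochs | |
| `commonDim` | 768 | dimension of the usual BERT-family encoders |

The published architecture details of the original CNN fusion layer are not
available, so the CNN defaults follow the TextCNN convention and are fully
configurable; every fitted object records its configuration and seed.

## Rebalancing

All three strategies act at training time only, inside each fold:

- **class_weight** scales each example's loss by the inverse-frequency
  weight of its true class (weighted empirical risk);
- **oversample** duplicates minority-class items, drawn uniformly with
  replacement under a derived seed, until every class matches the majority
  count — originals are always retained, and test folds are never
  resampled;
- **focal** uses `−α(1−p)^γ log p`, whose gradient through the softmax is
  implemented analytically; probabilities are clamped to
  `[1e-12, 1 − 1e-12]` before the logarithm.

## The synthetic generator

Real message corpora in this domain cannot be shared, so the generator
emulates the *statistical structure* the framework relies on:

- class proportions default to 44.3 / 13.4 / 14.1 / 28.2% (A/P/L/U), the
  imbalance profile of a real annotated portal-message corpus;
- message texts are assembled from per-class templates and keyword
  vocabularies; with probability `q` a secondary-topic sentence from
  another class is appended without changing the primary label. `q = 0.3`
  by default: multi-topic messages are common in real portals and this
  rate makes the mock-encoder task non-trivial while keeping it learnable;
- embeddings for encoder k and class c are
  `s·g_k(c)·μ_c + σ·ε`, with axis-aligned orthogonal class directions
  `μ_c` (chosen so single-encoder and fused error rates are analytically
  controllable), `s = 3`, `σ = 1`, gain 1 on the encoder's complementary
  classes and `γ_low = 0.3` elsewhere. The default complementary sets —
  encoder 1 → {A, U}, encoder 2 → {P}, encoder 3 → {L} — cover the schema,
  so the concatenated representation is strictly more informative than any
  single encoder; `dim = 16` keeps the CNN fast while leaving 12
  pure-noise dimensions.

Under these defaults roughly 60–70% of messages end up in a disagreement
bucket — the minority-specialist encoders (P-only, L-only) are weak on most
classes, so unanimity is comparatively rare. That is a harder routing
regime than a real deployment (where fine-tuned baselines agree far more
often), which makes it a conservative test of the fusion head: it must
carry most of the corpus.

What the generator deliberately does **not** emulate: realistic clinical
language, annotation noise and inter-annotator ambiguity, correlated
(non-isotropic) encoder errors, and message-length effects. Passing tests
therefore demonstrate that the machinery is correct and that fusion
recovers complementary signal when it exists — not that any particular
accuracy will be reached on real clinical text.

## Numerical and design choices

- **Pooling.** "Last hidden layer" embeddings are mean-pooled over
  non-padding tokens rather than taking the CLS vector; mean pooling is
  robust across encoder families with different CLS conventions, and the
  choice is recorded on the `EncoderSpec` (`cls` is accepted).
- **Mock encoder.** Lowercase, strip punctuation, whitespace-tokenize; each
  token maps through a 31-bit polynomial hash over its UTF-8 bytes to a
  seeded unit-norm Gaussian vector; the message embedding is the token
  mean, and an empty token list gives the zero vector. Hashing is explicit
  (not R's internal randomized hashing) so embeddings are identical across
  platforms and processes.
- **Stratified CV.** Whether to stratify is genuinely open; stratification
  is adopted because with a 13% minority class, unstratified folds
  destabilize macro metrics. Per repeat, each class's ids are shuffled and
  dealt round-robin with the fold pointer continuing across classes, which
  guarantees both fold sizes and per-fold class counts within ±1 of the
  ideal allocation.
- **Dimension reconciliation.** Encoders with `dim ≠ commonDim` are mapped
  through a *fixed* seeded Gaussian projection with variance `1/commonDim`
  (identity when dimensions match, which covers the standard all-768
  case). A random norm-preserving projection keeps the fusion training
  objective unchanged across runs and avoids adding `K·d·commonDim`
  trainable parameters to a head that is fitted on a few hundred
  disagreement examples; the projection is recorded in the fitted model so
  predictions are exactly reproducible.
- **Fusion labels.** The fusion head is trained on the *gold* labels of the
  disagreement messages, never on any baseline's prediction; train-side
  disagreement is computed from the fold's own baselines predicting on
  their own training split. The optimism this induces (training-set
  disagreement is measured on seen data) is a known property of the design
  and is listed under limitations.
- **Optimization.** All heads train with full-batch Adam (β₁ 0.9, β₂
  0.999) on analytic gradients, including backpropagation through the
  attention softmax and through the CNN's ReLU/max-pool path; weights are
  initialized from small seeded Gaussians, biases at zero. Dropout uses
  inverted scaling and an epoch-indexed derived seed, and is inactive at
  prediction time. Training is a pure function of (data, config, seed).
- **Ties and zero divisions.** Every argmax tie resolves to the earliest
  schema label, making `(0.25, 0.25, 0.25, 0.25)` predict A and the
  majority-vote rule consistent with the probability argmax. Precision or
  recall with a zero denominator scores 0 with a warning — conservative
  for macro averages.
- **Confidence intervals.** t-based by default
  (`mean ± t₀.₉₇₅,ₙ₋₁·SD/√n`); a normal-approximation variant is available.
  Model selection within an encoder category uses mean macro-F1 with mean
  accuracy as tie-break, and the criterion is part of the report.
- **Degenerate inputs.** If the baselines agree on every training message,
  the fusion training set is empty: training refuses with an explicit
  error, and the experiment harness falls back to consensus labels with a
  prominent log line rather than crashing.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script size their simulations for a
single CPU: the end-to-end benchmark uses `n = 2000` messages per seed
(75/25 stratified split, 5 seeds in the tests, 3 in the acceptance script),
the cross-validation hygiene audit uses `n = 400` with 5 folds × 2 repeats,
and unit fixtures stay below a few hundred rows. These sizes are large
enough for the complementarity effect to be stable across seeds while
keeping a full run in minutes.

## Limitations

- Train-side disagreement routing is mildly optimistic (see above); a
  nested split for the router would remove it at the cost of data and is
  not implemented.
- The fusion head sees only messages the baselines disagree on, so its
  training set shrinks exactly when the baselines are strong; with very
  accurate baselines the head may be under-trained.
- Real transformer backends are referenced by checkpoint identifier but no
  backend ships with the package; all shipped experiments run on the mock
  encoder or on synthetic embeddings.
- Majority-vote probabilities are vote shares, not calibrated
  probabilities; consensus predictions carry probability 1 on the
  consensus label by convention.
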