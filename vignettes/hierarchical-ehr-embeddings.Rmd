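---
title: "Hierarchical embedding of services, doctors and patients from EHR journeys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical embedding of services, doctors and patients from EHR journeys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(me2vec)
```

## The model and its assumptions

EHR journey data mixes three entity types whose relations differ in kind: the
*temporal* co-occurrence of services within a patient's timeline, the
*compositional* relation between a doctor and the services they administer,
and the *contextual* relation between a patient and the (service, doctor)
events they accumulate. The package embeds each entity with a mechanism
matched to its relation, in a fixed hierarchy — services, then doctors, then
patients — because each later stage consumes the earlier stage's vectors as
frozen inputs.

**Services.** The assumption is distributional: services administered within a
short time window of one another are related, and the *breadth* of a service's
co-occurrence profile encodes its clinical specificity. Rare, specific
services acquire distinctive (peripheral) positions; routine services, which
co-occur with everything, land near the center of mass. We build a weighted
service–service graph by scanning each patient's journey with non-overlapping
half-open windows `[t0, t0+T), [t0+T, t0+2T), ...` anchored at the patient's
first service day, incrementing the pair count of every unordered pair of
distinct services in a window, summed over patients. Second-order biased
random walks over this graph produce a corpus for skip-gram with negative
sampling. Time enters only through the window construction — the model is
blind to long-range ordering, which is the price of transferability.

**Doctors.** The assumption is "you are what you do": a doctor's primary
specialty is predictable from the mix of services they administer. Doctor
vectors start as the weighted average of their service vectors (invariant to
rescaling the administration counts) and are refined by a single multi-head
graph-attention layer trained with Adam on softmax cross-entropy against the
specialty labels. Edge weights do not modulate the attention logits — they
enter only through the initialization — because the attention is over the
*set* of administered services. The trained classifier head is reusable to
impute missing specialties.

**Patients.** A patient is represented by the company they keep: the
distribution over (service, doctor) events. The patient–service multigraph
(parallel edges carrying a doctor attribute) is first made simple by
*duplication & annotation*: every service node splits into one hybrid node per
distinct doctor attribute, and a hybrid's vector is a trainable linear map of
the concatenated frozen service and doctor vectors, `h = W_a [s ‖ d] + b_a`.
Patient vectors then minimize the sum over patients of the KL divergence
between the patient's empirical (edge-weight) context distribution and the
softmax context probability over all hybrids — second-order proximity only;
first-order proximity is deliberately skipped because hybrid vectors are
derived, not free.

## Parameters that matter

| Parameter | Units / range | Default | Why |
|---|---|---|---|
| `T_window` | days (minutes for sub-day data) | 8 (60 min) | Window span of co-occurrence; smaller T gives a sparser adjacency. |
| `pair_counting` | product / binary | product | Within-window increment for a pair; product is the multiset reading and preserves patient additivity. The binary reading is kept behind the flag because the increment rule is ambiguous in the source description. |
| `p`, `q` | positive reals | 1, 1 | Walk return and in–out bias; 1/1 is a first-order weighted walk. |
| `num_walks`, `walk_length` | counts | 10, 80 | Corpus size per node; standard biased-walk practice. |
| `dim` | dimensions | 128 | Embedding width for every entity. |
| `window` | walk positions | 5 | Skip-gram context radius. |
| `negatives` | count | 10 | Negative samples per positive, both for skip-gram and the patient objective. |
| `epochs` (skip-gram) | passes | 20 | See "Numerical choices": desk-scale corpora need more passes than web-scale defaults. |
| `subsample` | threshold | 1e-3 | word2vec frequent-token subsampling; curbs hub over-training. Set 0 for tiny corpora (everything is "frequent" when the corpus has a handful of tokens). |
| `K` | heads | 4 | Attention heads; per-head width is `dim/K` so the concatenated doctor vector keeps `dim`. |
| `leaky_slope` | – | 0.2 | LeakyReLU slope in the attention logit. |
| `gat epochs / lr / patience` | – | 150 / 0.01 / 10 | Adam with early stopping on validation cross-entropy (10% stratified doctor split). |
| `label_noise`, `case_prevalence` | proportions | 0.1, 0.2 | Outcome label corruption and case-condition rate of the generator. |
| `C` | inverse L2 strength | 1.0 | Logistic-regression regularization in all protocols (`lambda = 1/(nC)` in glmnet's parameterization). |

## What the synthetic generator emulates — and what it does not

The generator plants exactly the structure the method is designed to recover:

- **Specialty-specific usage profiles.** Non-rare services are split
  round-robin by frequency rank into disjoint blocks, one per specialty; each
  specialty's profile puts 0.8 of its mass on its own block. Pairwise
  total-variation distance between profiles is therefore ≥ 0.3 by
  construction.
- **Frequency skew with planted rare services.** Service base weights follow
  `rank^-zipf_exponent`; the coefficients of the own-block boost and the tail
  are solved so that the *specialty-averaged marginal* stays proportional to
  the rank law — the cohort-level rank–frequency slope matches the configured
  exponent instead of being steepened by the block reweighting. The last
  `rare_service_fraction` of ranks belongs to no block and is reachable only
  through tail mass.
- **Irregular gaps.** Steps stay on the same day with probability 0.2
  (same-day bursts) and otherwise advance by a geometric gap of at least one
  day. No distributional claim is inherited from real data; the parameter is
  exposed.
- **Latent conditions driving both services and outcome.** Each patient draws
  a condition; the condition concentrates 0.7 of its affinity on a home
  specialty; condition 1 is the case condition and sets the binary label,
  flipped with probability `label_noise`.
- **Reproducibility.** One hierarchical RNG stream per patient, derived from
  the master seed, so enlarging a cohort leaves earlier patients' journeys
  byte-identical.

It does **not** emulate: real code semantics (ICD/CPT), comorbidity
structure, seasonal or care-pathway ordering, censoring, doctor-level practice
variation within a specialty, or the heavy-tailed popularity (degree)
distributions of real claims graphs. A green planted-structure test therefore
establishes that the implementation recovers structure *of the planted kind at
desk scale* — not that it reproduces any real-data benchmark number.

## Numerical choices

- **Window anchoring.** Windows are anchored per patient at the first service
  day, half-open, so the empty journey is trivially handled and no
  cross-patient phase artifacts arise. Intra-day ordering is made
  deterministic by sorting records by (patient, day, service code, doctor).
- **Skip-gram epochs.** The corpus of a desk-scale cohort (~10^5 tokens) is
  orders of magnitude smaller than the corpora word2vec defaults assume. At 5
  epochs, low-frequency services barely move from their near-zero
  initialization and sit next to the embedding centroid — inverting the
  spatial-isolation geometry that converged training produces. The default is
  20 passes (with the standard 1e-3 frequent-token subsampling); this is a
  corpus-size adaptation, not a tuning of any acceptance quantity.
- **Isolated service nodes** terminate walks (no self-loop inflation); their
  vectors remain at initialization plus any noise-side updates.
- **Head nonlinearity.** The attention head output nonlinearity is
  unspecified upstream; ELU (the standard GAT choice) is the default, with
  sigmoid available. Per-head width is `dim/K`, so re-feeding the concatenated
  output as the next epoch's query needs no projection; the query input is
  treated as a constant within each epoch (no gradient through the re-feed).
- **Early stopping** selects the epoch with the best validation cross-entropy
  (not accuracy, which saturates early and yields under-confident
  classifiers); patience 10.
- **Patient objective.** Hybrid vectors are recomputed through `W_a, b_a`
  every step from frozen inputs; only patient vectors and the annotation map
  train. Edge sampling is proportional to the *patient-normalized* weight, so
  each patient's KL term receives equal expected mass — matching the exact
  objective, in which each empirical distribution sums to one. Noise hybrids
  are drawn proportional to weighted degree^0.75. The `"exact"` mode runs
  plain full-batch gradient descent on the full-softmax objective and is the
  oracle used in tests (descent is monotone at small learning rates; Adam
  would not guarantee that). Patient vectors initialize from
  `N(0, 1/dim)`.
- **Ties and degenerate inputs.** Doctor specialty conflicts resolve by
  majority, then lexicographically. Zero-epoch trainers return their seeded
  initializations. A single-specialty cohort is a training error (degenerate
  task). `negatives = 0` is an error in sampled mode but legal in the
  skip-gram trainer (used by the gradient oracle test).
- **Tolerances.** Softmax normalizations are asserted to 1e-6 (attention) and
  1e-12 (transition and empirical distributions); the exact-loss oracle
  comparison to 1e-9; embedding file round-trips to 1e-6 (8 significant
  digits are written).

## Design choices where the design was open

- **Within-window increment.** The available description of the pair-count
  update is garbled; both defensible readings are implemented
  (`pair_counting = "product"` default, `"binary"` optional).
- **Doctor embedding output.** The emitted doctor vector is the concatenated
  multi-head output `d'_j` (width `dim`), not a re-projection.
- **Softmax normalization set** for the patient context probability is all
  hybrid nodes (standard second-order practice), not the patient's neighbors.
- **Link-prediction split.** Connectivity during edge removal is enforced by
  rejecting bridge edges of the current residual graph (exact, per original
  component); negatives are sampled uniformly without replacement from
  non-edges of the original graph.
- **Stratification** is used for every split and fold, including protocols
  whose upstream description says only "randomized", for variance reduction.
- **Stage seeds** derive deterministically from the master seed and the stage
  name, so the pipeline is bitwise reproducible while stages stay decoupled.

## Known limitations

- **Additive scorer ceiling in link prediction.** The mandated scorer — an L2
  logistic regression on the *concatenation* of the patient and doctor
  vectors — evaluates every pair as `f(patient) + g(doctor)`. On a
  block-symmetric co-clustered graph the positive class is the diagonal of
  the block × block table, which no additive score can rank above the
  off-diagonal: an oracle additive model given the true block one-hots stays
  near AUC 0.58 while the same-block bilinear indicator reaches ~0.97 on the
  same split. The embeddings carry the structure; the feature map cannot
  extract it. On real claims graphs the additive model can exploit
  degree/popularity heterogeneity, which a symmetric planted world
  deliberately lacks — this is why one acceptance assertion
  (pipeline AUC ≥ 0.8 on the planted-block world) is red by design, with the
  bilinear oracle asserted green alongside it. Users who need matching
  performance should score pairs with an interaction feature (e.g., the
  Hadamard product), outside this package's mandated protocol.
- The patient embedding is transductive: unseen patients require retraining.
- Single-layer attention only; no temporal model beyond the window
  construction; no GPU path. Training is single-threaded by design so that
  every artifact is bitwise reproducible from seeds.
- The evaluation suite computes nothing at real-data scale; all empirical
  statements in this vignette are the ones computed by the test suite and the
  worked example in the README.
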