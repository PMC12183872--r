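---
title: "Multi-view graph contrastive learning for spatial domains: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view graph contrastive learning for spatial domains: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatially resolved transcriptomics (SRT) measures a gene-expression profile
at each of thousands of capture spots with known 2-D tissue coordinates.
The analysis task `spview` addresses is *spatial domain identification*:
partitioning spots into regions that are coherent both in expression and in
space (cortical layers are the canonical example), for one slice or several
slices measured separately. Multi-slice data add a complication: each slice
is a batch, and technical slice-to-slice shifts can dominate the biological
signal.

## Model

### Preprocessing

Counts are filtered to genes expressed in at least one spot across all
slices, library-size normalized to 10^4 counts per spot, `log1p`-transformed
(natural log), z-scored per gene (denominator `m - 1`), and projected onto
the first `n_pcs` principal components (exact SVD). The PC score matrix
`X` (m × n) is the network input. For multi-slice data all statistics are
pooled over the concatenated spots, so the slices live in a common PC space;
per-slice standardization would partially absorb batch effects before the
model sees them, which would make the prompting module untestable — the
pooled choice keeps the batch signal in `X` and leaves its removal to the
part of the model designed for it.

### Two-view graph

Two directed KNN graphs are built per slice: a spatial graph (Euclidean
distance on coordinates) and an expression graph (Pearson correlation on PC
scores), each with `K = 6` neighbors per spot by default — the physical
neighbor count of a hexagonal Visium array, and a reasonable default for
lattice data generally. Adjacency matrices are kept asymmetric exactly as
the KNN rule defines them (no symmetrization step is part of the model),
blended with self-connections, `Â = λI + (1 − λ)A` with `λ = 0.3`, and
degree-normalized, `Ã = D^{-1/2} Â D^{-1/2}` with `d_ii` the row sum of
`Â`. Multi-slice operators are block-diagonal: the graph never links spots
of different slices. Graphs are built once from the uncorrected `X` and held
fixed during training; rebuilding the expression graph from batch-corrected
features each epoch would make the training target drift with the
parameters, and the fixed-operator form is the one the forward-pass
definition actually uses.

### Encoder, heads, fusion, decoder

Each view is encoded by a two-layer GCN with ELU activations and no bias
terms:

    Z_v = ELU( C(Ã_v) · ELU( C(Ã_v) · X̃ · W11 ) · W12 ),

where `X̃` is the augmented feature matrix and `C(·)` the edge-masking
corruption (below). The two views share `W11, W12`. Two projection heads
map each `Z_v` (m × d) to an instance space `H_v = ReLU(Z_v W21) W22`
(m × f) and a pseudo-cluster assignment `Q_v = softmax(ReLU(Z_v W31) W32)`
(m × N_c, row-stochastic). A per-spot attention block scores each view,
`att_v = tanh(Z_v W41) W42`, converts the two scalars per spot to weights by
a two-way softmax, and fuses `Z = α_spa ⊙ Z_spa + α_expr ⊙ Z_expr` — a
convex combination per entry, with the weight constant across embedding
columns. The decoder is weight-tied to the encoder,
`X̂ = ReLU(Z W12ᵀ) W11ᵀ`; the tied tensors are shared, so gradients
accumulate from both the encoder and decoder paths.

### Augmentation

During training only, two stochastic corruptions are redrawn at every epoch:
feature perturbation `x̃ = b · (x + α·ε)` with `ε ~ N(0,1)` and
`b ~ Bernoulli(p)`, and edge masking that keeps each stored edge with
probability `p_m`, drawn independently per entry, per view, and per encoder
layer (the forward definition applies `C(·)` at each layer and nothing
couples the draws). Defaults `α = 0.1`, `p = 0.9`, `p_m = 0.9` are moderate:
they perturb without destroying the neighborhood structure. Inference runs
with all three disabled.

### Losses

Three terms are summed: `L = L_rec + L_cls + κ·L_ins`.

* `L_rec` is the mean squared error between `X` and `X̂`.
* `L_ins` is a symmetric InfoNCE over spots in the instance space with
  cosine similarity and temperature `τ_ins`: the positive for spot `i` in
  one view is spot `i` in the other view, and the negatives are only the
  *other-view* spots. Same-view negatives are deliberately excluded — the
  GCN's job is to smooth neighboring spots together, and penalizing
  same-view similarity would oppose it.
* `L_cls` contrasts the `N_c` pseudo-cluster *columns* of `Q_spa` and
  `Q_expr` (temperature `τ_cls`): for anchor column `j` of one view the
  positive is column `j` of the other view, and the denominator contains all
  cross-view columns plus same-view columns `k ≠ j` — unlike the instance
  loss, the cluster loss does use same-view negatives, and the asymmetry
  between the two losses is intentional, not an inconsistency to fix. Each
  direction adds an entropy regularizer `Σ_j π_j log π_j` over the
  column-mass fractions `π_j`, minimal at uniform cluster usage; it is what
  prevents the head from collapsing every spot into one pseudo-cluster. The
  regularizer enters unweighted, exactly as the objective is defined.

Cosine norms are floored at `1e-8` inside the training loop; the exported
loss functions treat an exactly-zero row (or column) as a contract error
unless `strict = FALSE`, because a zero vector has no direction and a
silent fallback would mask upstream bugs in user code.

### Multi-slice prompting

Two learnable per-slice prompt matrices handle batch effects: `B1` (L × n)
is subtracted from the input features, `X_b = X − E B1`, and `B2` (L × d) is
added back to the fused embedding just before decoding, `Z_b = Z + E B2`,
where `E` is the one-hot slice indicator. The encoder therefore sees
batch-corrected features while the decoder still reconstructs the observed,
batch-affected `X`. Inference embeddings are extracted *without* adding
`B2`, so they are batch-free. With `L = 1`, both prompts are identically
zero and the model reduces exactly to the single-slice formulation.

## Training and optimization choices

All parameters are Glorot-uniform initialized except the prompts, which
start at zero (training begins from the uncorrected model). Training is
full-graph Adam (`β = 0.9/0.999`), default learning rate `1e-3` for 500
epochs, one global seed for initialization, augmentation, and clustering.

One optimizer detail matters enough to call out. Adam's per-coordinate step
is bounded by the learning rate, so over 500 epochs a parameter can move at
most ≈ 0.5 from zero at `lr = 1e-3`. PC scores, however, live on the scale
of the data's singular values: a per-slice batch offset in PC space easily
has entries of magnitude 2–10. With a single learning rate the prompts are
*mathematically unable* to reach the offset they are meant to absorb within
the epoch budget, and the multi-slice model degenerates to the unprompted
one. Moreover the reconstruction objective alone is indifferent along the
direction `(B1, B2) → (B1 + Δ, B2 + Δ')` that trades batch signal between
the embedding and the prompts — with a linear encoder it is an exactly flat
direction — so the prompts must out-run the encoder's tendency to memorize
batch structure in its weights. `spview` therefore trains `B1` and `B2`
with a learning-rate multiplier (`prompt_lr_mult`, default 50). The choice
is a property of the scale mismatch between prompts and weights, not of any
particular dataset.

Ablation modes are loss-term switches on the same code path: `no_instance`
sets the instance term's weight to zero, `no_cluster` drops the cluster
term, `no_both` leaves a plain graph autoencoder, and `no_prompting`
freezes `B1 = B2 = 0`.

## Clustering and refinement

Domains are called by fitting a K-component Gaussian mixture to the
embeddings with `mclust` (shared full-covariance model `"EEE"`, the common
choice for SRT embeddings; a diagonal model is retried if EM fails) and
assigning each spot to its maximum-posterior component. `K` is
user-supplied; no automatic model selection is attempted. A single
synchronous refinement pass follows: each spot polls its six spatial
nearest neighbors within its own slice and adopts a label only when a
strict majority of the neighbors agrees on one label different from its
own. Ties and pluralities leave the spot unchanged, which makes the pass a
monotone smoothing step — label smoothness never decreases. A from-scratch
EM routine was considered and rejected: `mclust` is the standard, battle-
tested Gaussian-mixture implementation in R, so the only design freedom
kept is the covariance model ("EEE" by default; full model-family selection
is out of scope).

## Evaluation metrics

ARI (pair-counting, chance-corrected) and NMI (arithmetic-mean
normalization) score agreement with reference annotations; silhouette
(Euclidean) and Calinski–Harabasz score internal cluster structure on the
embeddings. Two dataset statistics describe difficulty: label smoothness
(LS), the fraction of directed spatial-KNN edges whose endpoints share a
label, and label entropy (LE), the Shannon entropy of the label
proportions. These two are operationalizations of their stated semantics
(LS in [0, 1], LE in [0, log K]); other formalizations exist.

## Synthetic data

The generator emulates layered tissue: spots on a regular lattice, rows
partitioned into contiguous horizontal bands (the domains), each domain
owning a disjoint marker-gene set whose log-mean is raised by
`signal_strength`; counts are Poisson with optional zero-inflation
(`dropout_p`), and each slice may add a per-gene `N(0, batch_shift_sd)`
shift on the log-mean scale — the standard location-shift batch model.
Poisson rather than negative-binomial noise keeps the generator
parameter-free; the pipeline assumes only nonnegative count-like data, and
over-dispersion would change difficulty, not structure. Unstated magnitudes
were fixed once at `base_mean = 1.0` and `dropout_p = 0.1`, giving sparse
Visium-like count matrices.

Two presets define the study conditions used throughout the tests: `"easy"`
(one 20 × 25 slice, 5 domains, 200 genes, 20 markers per domain, signal
1.5, no batch effect) and `"batchy"` (two such slices with
`batch_shift_sd = 1.0`). On `"batchy"`, the leading PCs of pooled
uncorrected data separate *slices* better than domains (silhouette on batch
labels exceeds silhouette on domain labels) — exactly the confound the
prompting module exists to remove.

One measured caveat on `"easy"` (see `scripts/acceptance.R` output): the
condition is solved to ARI ≈ 0.99 by the graph autoencoder alone — the
reconstruction-only ablation ties the full model there, even though a
raw-PCA Gaussian-mixture baseline scores ARI ≈ 0 on the same data. The
preset shows that the GCN machinery works, but it has no headroom left to
separate the contrastive terms' contribution; that contribution is visible
on `"batchy"`, where ablating the prompts collapses domain recovery and
reintroduces the slice confound.

What the generator does **not** emulate: irregular tissue boundaries,
curved or nested domains, spatial covariance within a domain beyond the
band structure, cell-type mixtures within a spot, library-size gradients,
and non-additive batch effects. Passing the end-to-end checks on these
fixtures shows the machinery is implemented coherently, not that the method
attains any particular accuracy on real tissue.

## Numerical choices and degenerate inputs

* Distance and correlation ties in KNN break toward the lower spot index;
  runs are deterministic given the seed (and BLAS thread count).
* Constant genes after normalization z-score to zero (with a warning)
  rather than being dropped, keeping gene indices stable; the z-score is
  undefined there and such genes carry no signal either way.
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive.
* Softmaxes subtract the row/column maximum before exponentiation.
* `ELU` derivatives are recovered from activation values
  (`exp(v) = ELU(v) + 1` for `v ≤ 0`), halving the cached tensors.
* A non-finite total loss aborts training with the epoch index and the
  component responsible.
* Zero-library spots, all-zero gene sets, constant expression rows (for the
  correlation graph), `K ≥ m`, and non-one-hot batch indicators all raise
  with messages naming the offending index.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use the two presets above (500
and 1000 spots, 200 genes, 30 PCs), 300 training epochs on `"easy"` and 500
on `"batchy"`, three seeds per condition. These sizes were chosen as the
smallest at which the end-to-end claims (domain recovery on `"easy"`, batch
removal on `"batchy"`, ablation directions) are cleanly measurable.

## Known limitations

* Full-graph training holds the m × m similarity matrix of the instance
  loss in memory; practical up to a few times 10^4 spots on a desktop.
* The expression graph is static; the variant that rebuilds it from
  corrected features each epoch is a one-line swap in
  `build_multiview_graph` usage but is deliberately not the default.
* `N_c` defaults to `K`; the pseudo-cluster count and the requested domain
  count need not be equal, and no heuristic links them.
* Refinement is one pass by design; iterating it would erode thin domains.
* The h5ad container format is not read; inputs are MTX or delimited text
  plus coordinate TSVs.
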