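---
title: "Methods: tensor completion for disease-associated lncRNA-miRNA pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensor completion for disease-associated lncRNA-miRNA pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `tritensor`, its
assumptions, the parameters that matter, the numerical choices made
where the formulation left room, and what the synthetic test bed does
and does not establish.

## Model and assumptions

The package predicts which lncRNA–miRNA pairs are associated with which
diseases, starting from three binary bipartite association networks:
disease–lncRNA, disease–miRNA and lncRNA–miRNA. Its two substantive
assumptions are:

* **Triangle closure defines the signal.** A (disease, lncRNA, miRNA)
  triple is treated as a known association exactly when all three of
  its projected pairs are edges. Entities participating in no triangle
  are dropped. The retained triples populate a binary tensor `T`.
* **Functionally similar entities share associations.** Similar
  diseases associate with similar pairs, and similar lncRNAs/miRNAs
  associate with similar diseases. This licenses both the
  neighbor-profile smoothing and the low multilinear-rank completion:
  if associations are driven by a modest number of latent disease,
  lncRNA and miRNA programs, `T` is approximately a Tucker product
  `⟦G; Z1, Z2, Z3⟧` with small core ranks.

The pipeline is: similarities → weighted K-nearest-neighbor profile
(WKNNP) smoothing → nonnegative Tucker completion by multiplicative
updates → per-disease ranking of unobserved pairs by the reconstructed
score `T*`.

The triangle-closure step is implemented as an exhaustive,
order-independent enumeration: the set of triangles does not depend on
any scan order, and index maps use first-appearance order so repeated
runs are bit-identical.

## Similarities

* **Disease semantic similarity** uses a MeSH-style poly-hierarchy.
  Each disease's DAG contains itself and every ancestor obtained by
  truncating its tree numbers. The disease contributes 1 to itself and
  each ancestor contributes `Δ` times the best contribution among its
  children inside the DAG (`Δ = 0.5`, dimensionless decay per
  hierarchy level — the standard choice for this family of semantic
  measures; contributions of positions sharing a heading are merged by
  maximum). Pair similarity is the shared-ancestor contribution mass
  divided by the two semantic values. Diseases absent from the
  vocabulary are flagged and fall back to profile similarity (below).
* **GIP kernels.** Each entity's binary interaction profile is a row
  of the relevant adjacency matrix; the Gaussian kernel bandwidth is
  the inverse mean squared profile norm, so the kernel adapts to
  network density. An all-zero profile matrix is an error (bandwidth
  undefined); individual zero profiles are fine. Bandwidths are
  computed once per matrix and never recomputed after smoothing —
  similarities are a fixed preprocessing product.
* **Functional similarity** of two RNAs averages best-match semantic
  similarities between their associated disease sets, in both
  directions. An RNA with no associated disease gets similarity 0 (with
  a warning). The miRNA measure uses the same symmetric form as the
  lncRNA measure.
* **Combination.** Each axis similarity is the elementwise mean of its
  two sources; for the disease axis, pairs in which either disease
  lacks a usable DAG take the GIP value alone. There is no published
  closed form for this disease-level integration; the symmetric mean
  mirrors the RNA axes and is the package's choice. All similarities
  are clipped to `[0, 1]` after arithmetic to absorb floating-point
  overshoot.

## WKNNP smoothing

For each entity on an axis, its `K` most similar *other* entities that
carry at least one known association contribute their tensor slices.
Sorted by similarity descending (ties broken by index order), neighbor
`t` gets weight `w_t = α^{t−1} · sim_t` and the estimate is
`Σ w_t · slice_t / Q` with `Q = Σ sim_t` over the *undecayed*
similarities. The numerator/normalizer asymmetry is deliberate and kept
as the estimator's definition: weights sum to less than one unless
`α → 1`, so the estimate is conservatively shrunk toward zero for
entities whose neighborhoods are exhausted quickly. Defaults `K = 3`
and `α = 0.1` (strong decay: effectively the nearest neighbor dominates),
fusion weights `(1, 1, 1)`. Entities with fewer than `K` eligible
neighbors use all they have; with none, their estimated slice is zero
and a warning is raised. Fusion takes the elementwise maximum of the
observed tensor and the blended estimate, so known positives are never
down-weighted and all entries stay in `[0, 1]`.

## Nonnegative Tucker completion

The decomposition minimizes `‖T − ⟦G; Z1, Z2, Z3⟧‖_F²` under
nonnegativity, by cyclic multiplicative updates (modes 1, 2, 3, then
the core). The factor update for mode 1 is
`Z1 ← Z1 ∗ (T(1) S1ᵀ) / (Z1 S1 S1ᵀ)` with
`S1 = G(1) (Z2 ⊗ Z3)ᵀ`; unfoldings keep the remaining modes in
increasing order with the last varying fastest, which is exactly the
ordering that makes this Kronecker identity hold. The core update
multiplies `G` by the ratio of the data and the current reconstruction,
both contracted with the transposed factors; in vectorized form this is
the standard NMF update with design matrix `Q = Z3 ⊗ Z2 ⊗ Z1` (the
tests verify this against the explicit Kronecker expression). No
orthogonalization is performed anywhere: the factors are nonnegative
"soft memberships", not orthonormal bases.

Numerical choices:

* **Denominator guard** `1e-12` added before each division — standard
  multiplicative-update stabilization.
* **Stopping rule**: relative squared residual
  `‖T − T̂‖² / ‖T‖² < 1e-4` or 500 sweeps, both configurable; an
  absolute-threshold mode is also provided. Whether the threshold is
  relative or absolute is a genuine open choice; relative is the
  default because it is scale-free.
* **Initialization.** Multiplicative updates cannot revive an exact
  zero, and experiments during development showed that from
  unstructured uniform random starts the coupled mode updates can lock
  every component onto one part of a block-structured tensor: the
  excluded block's rows shrink super-exponentially in *all three*
  factors simultaneously (each mode's numerator depends on the other
  modes' dying rows) and underflow to exact zero within ~10 sweeps, a
  local minimum that per-sweep rescaling does not escape. The default
  initialization is therefore data-driven: each factor starts as the
  absolute values of the leading left singular vectors of the
  corresponding unfolding, floored at `1e-6`, and the core as the data
  contracted with the transposed factors. This start spreads components
  over the data's actual multilinear structure, is deterministic, and
  removed the collapse entirely in our test bed. A seeded uniform
  `(0.1, 1.1)` random initialization remains available
  (`init = "random"`).
* **Monotonicity monitor.** The squared residual after every sweep is
  recorded; if the final residual exceeds the initial one the fit
  aborts with the trace, since that indicates a numerical fault rather
  than slow convergence.
* **Degenerate inputs**: ranks are validated against the tensor
  dimensions; a rank close to the smallest dimension triggers a
  warning (the completion then approaches interpolation of the
  training entries, which defeats generalization).

Ranking excludes training positives by default and breaks score ties
by index order, making ranks contiguous and reproducible.

## Cross-validation design

Held-out positives must not leak through preprocessing: in the default
*strict* mode, every fold recomputes the GIP and functional
similarities from the bipartite support projected out of the masked
training tensor, then re-runs smoothing and completion. (The initial,
non-CV fit uses the full input networks, which typically contain pairs
beyond the triangle-closed tensor support.) A *fast* mode freezes the
full-data similarities, trading a small optimistic bias for speed; it
is off by default. The negative/candidate set is every cell that is
zero in the training tensor, i.e. all unobserved triples. Global LOOCV
ranks a held-out triple against all of them; local LOOCV only against
the unobserved pairs of its own disease, with per-disease AUCs averaged
over diseases having at least one positive. The k-fold scheme
stratifies partitions over diseases (so no fold empties a disease) with
a plain random option; the reported spread is the standard deviation of
the per-repeat average AUCs.

Inside cross-validation the default fitting budget is 100 sweeps at
relative tolerance `1e-3` — cross-validation refits the model once per
fold (hundreds of times per run), and on the desk-scale problems this
package targets the rankings are stable well before the tighter
single-fit default.

## The synthetic test bed

`fixture_spec()` describes coupled bipartite networks with planted
block structure: each axis's entities split into latent blocks
(default 2); within-block pairs get edges with probability 0.8,
cross-block pairs 0.05; observed lists then suffer 5% false-negative
and 1% false-positive edge flips. A MeSH-like descriptor file groups
same-block diseases under shared ancestors, so semantic similarity
correlates with block identity just as the model assumes. The default
size, 12 diseases × 10 lncRNAs × 15 miRNAs, is the smallest that gives
nondegenerate cross-validation (a couple hundred positive triples)
while keeping a full leave-one-out run under a minute. Ground truth is
the triangle set of the noise-free networks; triangles destroyed by
the flips are flagged as held-out "future" associations for recovery
checks.

What the fixture emulates: coupled networks whose triangles form an
approximately low-multilinear-rank tensor, similarity structure aligned
with the latent blocks, and edge-level noise that genuinely exercises
the triangle-closure step (a single dropped edge can delete several
triples). What it does not emulate: the heavy-tailed degree
distributions, annotation biases and inter-database inconsistencies of
real curated association data. Passing the end-to-end tests therefore
shows the pipeline recovers planted structure of the kind it assumes —
not that real-data performance will match any particular figure.

Two quantitative notes on the generator. First, with the default
within-block edge probability 0.8, a within-block triangle is present
with probability ≈ 0.5, so even the flip-free tensor is a Bernoulli
sample of the blocks: rank-(2,2,2) truncations then capture only
~70–77% of its Frobenius mass. Only the deterministic sub-family
(within-block probability 1, cross-block 0, no flips) is exactly
block-structured, and that is the configuration on which the
rank-concentration test asserts its 80% bound. Second, chance-level
checks on small instances average several label-free score draws,
because a single draw's sampling error at a few dozen positives
exceeds the nominal band.

## Known limitations

* The multiplicative updates converge slowly near the optimum
  (sublinear tail); the defaults favor ranking stability over residual
  polish.
* Local minima remain possible for adversarial structures even with
  the data-driven start; the residual trace is exposed so users can
  compare runs.
* Similarity recomputation inside strict-mode LOOCV makes leave-one-out
  quadratic-ish in the number of positives; for large real datasets the
  k-fold schemes are the practical choice.
* `K` and `α` are global (no per-axis values), and nothing is learned
  from data: all hyperparameters are fixed inputs.
* Identifiers are opaque strings; no identifier harmonization across
  databases is attempted, and inconsistent duplicate records are
  simply deduplicated with a warning.
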