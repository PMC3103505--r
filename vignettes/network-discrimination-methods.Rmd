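---
title: "Methods: weighted connectome construction, graph measures and group discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome construction, graph measures and group discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdiscrim)
```

`netdiscrim` discriminates two groups of subjects — typically a
dysmyelinated mutant against background controls — from the topology of
their weighted structural brain networks. This vignette documents the
models and procedures, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## From tensors to networks

**Tracking.** Fiber trajectories are integrated through a voxel grid of
diffusion tensors with one bidirectional streamline per seed voxel center.
Three deterministic update rules are provided: FACT follows the voxel's
principal eigenvector; TEND propagates the incoming direction through the
tensor (`v_out ∝ D v_in`); TL (tensorline) blends the two with the local
fractional anisotropy as mixing weight, `v_out ∝ FA·e1 + (1−FA)·D̂v_in`
(the deflection term is normalized before blending so the two terms live on
the same scale). Direction lookup is nearest-neighbor — the tensor of the
containing voxel — matching the voxel-wise definition of FACT at toy
scale; no interpolation scheme is invented beyond it. Eigenvector sign is
chosen for continuity (`dot(v_new, v_old) ≥ 0`). Tracking stops where FA
falls to the threshold, where a step would turn by more than the curvature
threshold, at the volume boundary, and at the length budget; the stopping
check runs *before* a point is appended, so trajectory endpoints always lie
in the tracked (high-FA) region and therefore inside a labeled termination
region when one exists.

Defaults (units in parentheses): step 0.025 mm, maximum trace length
200 mm (each direction of the bidirectional integration receives half, so
the whole-trajectory bound holds exactly), curvature threshold 80° per
step, FA threshold 0.12. Seeds are all voxels with FA strictly above the
threshold (brute-force seeding). A deliberately low FA threshold avoids
building a group difference into seed counts before any network exists.

**Arc weights.** An arc between regions *i* and *j* collects the
trajectories whose two endpoints lie in those regions (an endpoint rule,
not a passes-through rule). The default weight is an effective fiber count
modulated by pathway integrity: each trajectory contributes the arithmetic
mean of the inverse of its per-step mean diffusivity, and the sum is
divided by `n_i + n_j`, the surface-voxel counts of the two regions
(6-connected boundary voxels; matrix-only pipelines default to 1). Mean
diffusivity reflects average local water mobility independent of
directionality, hence fiber integrity; mean-FA and pure-count weights are
kept as variants because they are the common alternatives and make the
weighting choice testable. MD must be strictly positive along a used
trajectory; a nonpositive sample is an error naming the trajectory rather
than a silent skip.

**Backbone.** Analysis networks are connectivity backbones: the maximum
spanning tree (connectedness with maximal total weight) plus remaining
edges in strictly decreasing weight order until the average node degree
first reaches 4 — for 150 nodes, exactly 300 edges. Equal-weight ties are
broken by ascending node-pair order purely for determinism. A disconnected
input falls back to its largest component with a warning.

## The six measures

All measures act on symmetric nonnegative weight matrices with zero
diagonal.

* **Clustering `C`** — geometric triangle mean per node,
  `C_i = 1/(k_i(k_i−1)) Σ_{j,h} (ŵ_ij ŵ_ih ŵ_jh)^{1/3}`, with weights
  scaled by the network maximum by default so `C_i ∈ [0,1]` and the
  unweighted coefficient is recovered when all weights are equal.
  `scaled = FALSE` reproduces unnormalized magnitudes, which published
  tables sometimes report (values far above 1 are a sign the scaling was
  not applied there).
* **Characteristic path length `L`** — arc length is inverse weight,
  `l_ij = 1/w_ij`; geodesics by Dijkstra; `L` is the mean over ordered
  pairs. Disconnected networks are an error that points the caller to
  global efficiency, whose convention (1/∞ = 0) tolerates them.
* **Modularity `Q`** — `Q = Σ_c (e_cc − a_c²)` on weight fractions.
  Partitions come from recursive leading-eigenvector bisection of the
  weighted modularity matrix with a Kernighan–Lin-style single-node
  refinement pass after each split; a split is kept only if it increases
  `Q` (tolerance 1e-10).
* **Efficiencies** — `E_glob` is the mean inverse geodesic; `E_loc`
  averages `E_glob` over each node's neighbor subgraph (node excluded;
  fewer than two neighbors contributes 0).
* **Small-worldness `σ = γ/λ`** — `γ = C/⟨C_rand⟩` and `λ = L/⟨L_rand⟩`
  over a null ensemble of degree-preserving double-edge-swap
  randomizations (10 swap attempts per edge) with the weight multiset
  reassigned at random; disconnected draws are resampled with bounded
  retries. With zero swaps the ensemble is the network itself and
  `γ = λ = σ = 1` exactly.

**Null-ensemble sizes.** The path-length null is tame: its per-draw
relative error is about 1%, so 20 draws suffice (`ensemble_size = 20`).
The clustering null is not: a degree-4 backbone randomization carries only
a handful of triangles, making per-draw `C_rand` noise ~37%; a 20-draw
mean would leave an ~8% Monte-Carlo error on γ, comparable to real group
effects. The clustering null therefore uses 150 draws by default
(`gamma_ensemble`), bringing the error to ~3%; the first 20 draws serve
both ratios. The ensemble loop (swaps, weight shuffle, connectivity check,
triangle sums, all-pairs Dijkstra) is implemented in compiled code, driven
by R's RNG so that seeding behaves identically to the rest of the package.
When a metric table is built for many networks at once, every network
receives the *same* ensemble seed (common random numbers): the remaining
Monte-Carlo error then acts as a shared offset that largely cancels in
group comparisons instead of inflating within-group variance.

## Representation spaces, classification, testing

Each network measure defines a representation space in which a subject is
one point whose coordinates are that measure's values under the N tracking
variants (3 here); M measures jointly give an M·N-dimensional space, laid
out measures-first in the canonical order C, L, Q, E_glob, E_loc, σ.

Classification is two-class LDA with pooled within-class covariance and
equal priors (the design is balanced), evaluated leave-one-out: each
subject is held out in turn and receives the posterior probability of the
first class; prediction thresholds the posterior at 0.5, with a posterior
exactly at the threshold counted incorrect and logged. Because up to 18
coordinates can face 10 training subjects, the pooled covariance receives
a diagonal ridge loading `ridge · trace(S)/d` with `ridge = 1e-6` — enough
to make the solve well-posed without visibly moving well-conditioned
solutions. Per-fold boundary hyperplanes are normalized to unit normal and
averaged into a mean boundary hyperplane (no canonical averaging rule
exists; the unweighted mean of unit normals is the least-structured
choice). Forward sequential selection ranks measures by single-measure
LOO accuracy (ties broken by the canonical order), then appends
next-ranked measures while accuracy strictly improves. Note that under a
null configuration the *selected* accuracy is optimistically biased — it
is the maximum of six LOO accuracies — while per-measure accuracies stay
at chance; the package reports both.

Group differences are tested per measure with a max-t permutation test:
pooled-variance two-sample t per tracking variant, statistic
`max_k |t_k|`, null distribution by label permutation — exact enumeration
of all `choose(nA+nB, nA)` assignments when that count is at most 20,000
(924 for 6 vs 6), Monte-Carlo otherwise with the identity assignment
always counted, so `p > 0` and `p ≥ 1/924` at this design size. The test
is two-sided via `|t|` because both decreases (C, Q, efficiencies, σ) and
increases (L) are of interest.

## The synthetic generator

`group_design()` emulates the study conditions end to end: two groups of
6 subjects, 150-node networks in 6 planted modules (within-module edge
probability 0.3, between 0.02), log-normal arc weights (sdlog 0.5) with
within-module arcs centred on `base_weight` and between-module arcs on
half of it — the weight contrast is what lets the weight-ranked backbone
retain the clustered, modular structure that real control connectomes
show; with module-independent weights the backbone degenerates into a
weight-random subgraph with near-zero clustering. The case group shares a
single lesioned base: every weight multiplied by `1 − attenuation`
(default 0.3; global integrity loss) and 10% of edges relocated by
degree-preserving double-edge swaps with their weights (network
randomization; one draw per group, since the mutant animals carry the same
lesion process). Per-subject variability is multiplicative log-normal
weight jitter (sdlog 0.05), and each subject's network is expanded into
three algorithm variants by independent log-normal jitter of the same
size, sharing the edge support. All randomness flows from one master seed
through a documented splitting scheme (`split_seed()`), so sample sets are
bitwise reproducible.

What the generator does *not* emulate: real mouse neuroanatomy or atlas
geometry, MRI noise physics, distance-dependent connection probability,
genuinely different tractography biases between variants (the variants are
exchangeable perturbations), or subject-specific lesion topographies.
Passing tests therefore show that the pipeline recovers a planted
modular-attenuation effect of realistic size — not that it would recover
any particular biological effect.

A known, deliberate limitation follows from the lesion model: the same
relocated strong edges that destroy triangles (lowering γ) also act as
shortcuts that shorten case-group geodesics relative to the null (lowering
λ), so the two ratios partially cancel in σ = γ/λ and the sign of the net
σ effect depends on the single rewiring draw. Across replicate seeds the
pipeline flags C, E_glob and E_loc essentially always and reaches perfect
leave-one-out accuracy, while σ is flagged in only roughly half to
three-quarters of replicates. Alternative lesion models (per-subject
rewiring; relocated edges given fresh weak weights) were examined and
recover σ even less often, so the canonical construction is kept and the
behavior documented rather than tuned away.

## Numerical choices and degenerate inputs

* Symmetry is validated to 1e-9; negative weights and nonzero diagonals
  are errors, not warnings.
* Nodes of degree < 2 contribute 0 to clustering and local efficiency;
  the all-zero tensor has FA 0; tensor eigenvalues are clamped at 0.
* Backbone edge ties break by ascending node-pair order; average degree
  counts each undirected edge twice.
* Matrices are written to CSV at 17 significant digits so write–read
  round-trips are exact.
* Problem sizes in the shipped tests: brute-force oracles run on 6–8-node
  graphs (exhaustive triples, simple paths, all 4140 partitions of 8
  elements, all 1296 labeled spanning trees of 6 nodes); null calibration
  uses 1000 replicates of the exact 6-vs-6 test; effect recovery uses 50
  replicate pipelines at the full 150-node design; smaller 30–80-node
  designs back the remaining properties.
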