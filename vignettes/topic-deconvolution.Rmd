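---
title: "Topic-model deconvolution of spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-model deconvolution of spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

## The problem and the model

Capture-based spatial transcriptomics measures expression at spots that cover
roughly 1–20 cells, so a spot's profile is a mixture over cell types.
spotdecon estimates the mixing proportions by projecting both modalities into
a shared latent space learned from an annotated single-cell reference.

The latent space is a latent Dirichlet allocation (LDA) topic model over the
$V$ genes shared by the two matrices. For cell $m$ of $M$ reference cells,
topic occurrences follow $Z_{\cdot m} \sim \mathrm{Multinomial}(\theta_m)$
with $\theta_m \sim \mathrm{Dirichlet}(\alpha)$, and topic $k$ emits genes as
$W_{k\cdot} \sim \mathrm{Multinomial}(\varphi_k)$ with $\varphi_k \sim
\mathrm{Dirichlet}(\beta)$. Online variational Bayes estimates the
gene-by-topic distribution $\varphi$ ($K \times V$) and the topic-by-cell
distribution $Z$ ($K \times M$).

The user's cell-type labels turn $Z$ into a topic profile per type,

$$T_{kn} = \frac{\sum_m Z_{km} A_{mn}}{\sum_m A_{mn}},$$

with $A$ the one-hot label matrix, and Bayes' theorem inverts it:

$$C_{nk} = \frac{T_{kn} Q_n}{P_k}, \qquad P_k = \sum_n T_{kn} Q_n,$$

where $Q_n$ is the cell-type prior (by default the label frequencies of the
reference) and $C_{nk}$ the probability that topic $k$ belongs to type $n$.

Spatial spots are folded into the same space with $\varphi$ frozen — the key
assumption being that the latent topic structure is shared across
technologies applied to one tissue. The per-spot topic distribution
$Y_{\cdot j}$ then converts to proportions as
$ST_{nj} = \sum_k C_{nk} Y_{kj}$, renormalized to sum to one per spot.

Cells can be re-annotated the same way, $SC_{nm} = \sum_k C_{nk} Z_{km}$, and
the fraction of cells whose argmax type matches their given label is the
model-selection criterion: `fit_celltopics()` trains one model per candidate
topic number and keeps the most accurate one, breaking ties toward the
smallest (simplest) $K$. The default candidate grid is $\{N, \lceil 1.5N
\rceil, 2N, 3N\}$ for $N$ cell types; accuracy is evaluated on the full
training set, matching the re-annotation framing of the criterion. All of
this runs behind one fitting call returning a classed model object with
`print`, `summary`, `coef`, `plot` and `predict` methods.

## Tunable parameters

* `alpha` (document–topic prior): symmetric, default $1/K$; `beta`
  (topic–gene prior): symmetric scalar, default 0.01. Small values favor
  sparse, cell-type-like topics.
* `passes` (default 20) and `batch_size` (default 256 cells) control the
  online variational schedule with learning rate $(\tau_0 + t)^{-\kappa}$,
  $\tau_0 = 1$, $\kappa = 0.7$; training stops early when the per-token
  variational score changes by less than $10^{-4}$ between passes. Given one
  seed, training is bit-reproducible.
* Normalization: each column is scaled to `scale_factor` (default 10,000)
  total counts, then each gene row is divided by its standard deviation. We
  use the population SD and do **not** center: LDA needs non-negative token
  weights, so variance standardization must be a pure rescaling.
  Zero-variance rows are set to zero. The normalized, fractional values enter
  the variational updates as expected token counts.
* Feature genes (`feature_mode`): per-type markers by one-vs-rest Wilcoxon
  rank-sum (default, `n_top` per type, ties on $p$ broken by descending
  log-fold-change then gene id), all shared genes, highly variable genes
  (variance/mean dispersion of depth-scaled counts), or markers plus HVGs.
  Restricted contrasts let transcriptionally similar types be compared only
  against each other.
* At prediction time the per-gene SDs are recomputed on the spatial matrix by
  default (`gene_sd = "spatial"`), mirroring the per-modality normalization
  of cells and spots; `gene_sd = "reference"` reuses the single-cell SDs.
  Re-estimation needs enough spots to be stable — for toy inputs with a
  handful of spots the reference option is the right choice, and the test
  suite exercises both.

## What the simulators emulate

`simulate_random_spots()` builds each spot from 2–10 reference cells sampled
without replacement, sums their raw counts, and down-samples any spot
exceeding 25,000 total UMIs to 20,000 (multivariate hypergeometric, i.e.
sampling molecules without replacement). The realized cell-type frequencies
are the ground truth. `simulate_depth_series()` fixes 10 cells per spot for
1,000 spots and down-samples every spot to 20,000, 15,000, 10,000, 5,000,
2,500 and 1,000 counts; levels are nested by default (each depth is a
subsample of the previous) so the series isolates depth from sampling noise.

`simulate_tme()` reproduces a structured tumor microenvironment with four
compartments of 250 spots each — tumor core, invasive margin, tumor stroma
(two 125-spot co-localization variants) and tertiary lymphoid structure.
Each compartment fixes the mean fractions of one correlated cell-type pair
(e.g. malignant 50% with CD8 T 30% in the core), lets a stated set of free
types share the residual mass via a symmetric Dirichlet, and excludes all
other types exactly. The generation law for the correlated pair is the one
genuinely open design choice here: we draw the pair from a bivariate
logit-normal around the fixed means and calibrate the latent correlation at
generation time (bisection on reused normal draws, monotone in the latent
parameter) so that the *realized*, integer-discretized proportions hit the
target correlation of 0.7. Proportions are realized as 10 cell picks per
spot by largest-remainder apportionment, so they live on a 0.1 grid; the
calibration compensates for the attenuation this discretization causes.

`make_block_fixture()` is the synthetic single-cell reference used
throughout the tests: each type owns a private block of marker genes at
`marker_strength` (default 8×) the background rate, a `noise` fraction of
reads is spread uniformly, and counts are multinomial draws at fixed depth.
This emulates well-separated cell types with clean markers. It deliberately
does **not** emulate dropout beyond multinomial sampling, batch effects,
ambient RNA, or transcriptionally overlapping subtypes — so passing recovery
tests demonstrates correctness of the machinery, not performance on tissues
with similar subtypes (where any reference-based method degrades).

## Evaluation metrics

With simulated truth available, `spot_correlation()` scores each spot by the
Pearson correlation between predicted and true proportion vectors,
`celltype_correlation()` scores each type across spots, and
`presence_split_rmse()` splits types by `truth > 0` versus `truth == 0` and
reports the RMSE within each group — sensitivity (recovering what is there)
versus specificity (not inventing what is not). "Present" means strictly
positive: the simulators produce exact zeros, so no epsilon is needed.
Without truth, `signature_score()` provides summed-marker scores or
bin-controlled module scores (24 expression bins, 100 controls per marker).

## Spatial domains and cell mapping

`cluster_domains()` k-means-clusters spots on the concatenation of their own
composition (weight 0.5) and the mean composition of their neighbors; the
neighbor rule is 6 nearest spots, the hex-grid degree of common arrays, with
a radius alternative. Initialization is seeded k-means++, making the
partition reproducible. `define_regions()` labels spots by Euclidean
distance (array units) to the nearest spot of a chosen core cluster: within
2 units is the edge immediately surrounding the core, within 4 units the
border, beyond 4 the stroma; a distance exactly at the threshold counts as
border (the strict inequalities of the motivating rule leave equality
undefined, and spots on the boundary are operationally border tissue).

`map_cells_to_spots()` apportions 10 slots per spot to types by largest
remainder on the deconvolved proportions and fills each quota with the
reference cells of that type most cosine-similar to the spot's topic vector,
recycling cells (with a warning) when a quota exceeds the pool.

## 3D reconstruction

`pairwise_align()` couples two slides by fused Gromov–Wasserstein optimal
transport, minimizing
$(1-\lambda) \sum_{ij} c(X_{\cdot i}, X'_{\cdot j})\,\Pi_{ij} + \lambda
\sum_{ijkl} (D_{ik} - D'_{jl})^2\, \Pi_{ij}\Pi_{kl}$
over couplings with uniform marginals, where $X$ holds per-spot topic
profiles and $D$ intra-slide spot distances. Choices left open by the
formulation, and our defaults: the feature cost $c$ is the squared Euclidean
distance between topic columns (bounded and symmetric; cosine and KL options
are provided), the marginals are uniform (each spot carries equal mass), and
$\lambda = 0.1$ — weakly structural, so topics dominate while geometry
regularizes; $\lambda$ is exposed and worth a sensitivity sweep on real
series. The solver is conditional gradient with an exact quadratic line
search; each linear subproblem is solved by an exact transportation simplex
(degeneracy handled by lexicographic perturbation, with flows recomputed on
the optimal basis tree at the unperturbed marginals), so returned couplings
are polytope vertices with marginals exact to machine precision rather than
entropically smoothed approximations.

`procrustes_pair()` turns a coupling into a rigid transform in closed form:
center both coordinate sets at their coupling-weighted means, SVD the
$2\times 2$ cross-covariance $H = Z_a^c\, \Pi\, (Z_b^c)^\top = U S V^\top$,
and take $R = U\,\mathrm{diag}(1, \det(UV^\top))\,V^\top$ — the determinant
correction guarantees a proper rotation, never a reflection.
`stack_layers()` chains adjacent pairs sequentially (matching serial
sectioning; no joint multi-slide optimization) and assigns $z$ = section
index × `z_spacing` (default 1 array unit, as true section thickness is
platform-specific).

## Numerical conventions

* Probability tables are validated to conservation identities:
  $\sum_k T_{kn} = 1$, $\sum_n C_{nk} = 1$, $\sum_n SC_{nm} = 1$,
  $\sum_k Y_{kj} = 1$ at $10^{-8}$, and $ST$ columns renormalized to 1.
* Argmax ties (cell annotation, dominant spot type) resolve to the
  lexicographically first type name; Wilcoxon ties resolve by fold change
  then gene id; remainder ties in apportionment by larger proportion then
  name. Everything stochastic takes a seed and restores the caller's RNG
  state.
* Spot fold-in iterates the per-spot variational update to a mean change
  below $10^{-6}$ with a cap of 100 iterations, from a deterministic uniform
  start. Spots with zero feature counts get the uniform topic distribution
  with a warning rather than an error.
* A topic used by no cell type makes $C$ undefined ($P_k = 0$) and is an
  error; an empty gene intersection between modalities is an error
  (annotation mismatch); columns with zero totals cannot be depth-scaled and
  are an error naming the columns.

## Scale of the validation suite

The test and acceptance suites run at desk scale, chosen to finish in
minutes while leaving clear separations: a 5-type reference of 500 cells ×
200 genes (20 markers per type) with 200 simulated spots for recovery
checks; 11 types × 660 cells for the microenvironment design; 1,000 spots
for the depth series; alignment toys of 3–30 spots where exhaustive oracles
(all 24 permutation couplings, known rigid transforms) are available. At
these sizes re-annotation accuracy is ≥ 0.95, median per-spot correlation is
≥ 0.9, and absent-type RMSE is ≤ 0.05.

## Known limitations

The method assumes the reference covers the cell populations present in the
tissue; types absent from the reference cannot be estimated. Transcription-
ally similar subtypes share topics and their proportions blur into each
other. The simulators draw real cells with replacement-free sampling but do
not model segmentation error, lateral diffusion, or platform-specific spot
geometry — compartments are defined compositionally, not geometrically.
Sequential alignment accumulates drift over long series; a joint multi-slide
formulation is out of scope.
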