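---
title: "spatcomm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatcomm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

`spatcomm` connects three analyses that are usually run separately:

1. **Integration.** Dissociated scRNA-seq profiles are matched to spatial
   units (cells or spots) by an attention-based graph neural network that
   produces matching descriptors $f_i \in \mathbb{R}^D$ per unit and a
   similarity matrix $M_{ij} = \langle f_i^{sc}, f_j^{st} \rangle$.
2. **Decomposition.** Spot-level data plus per-spot cell-type proportions are
   converted into a single-cell-resolution map: integer per-type cell counts
   per spot, an expression-matched cell subset, and a probabilistic placement
   of each cell inside its spot.
3. **Communication.** On the single-cell map, a K-nearest-neighbor cell graph
   with a 200 micrometre cutoff restricts ligand-receptor (L-R) scoring to
   plausible paracrine range; a permutation test over cell-type labels gives
   per-combination p-values, and significant combinations yield per-pair
   scores $S = \sqrt{L_i R_j}$. A receptor-to-TF random walk filters receiver
   cells to those with downstream transcription-factor activity.

A benchmark-metric suite (per-gene PCC, SSIM, RMSE, JSD, accuracy-score
ranking, Wasserstein distance-ratio, distance enrichment score) and seeded
synthetic-data generators round out the package so everything is testable
offline.

# The integration network

Each unit is encoded as $x^{(0)} = d + \mathrm{MLP}_{enc}(p)$, where $d$ is a
linear lift of the unit's expression features (log1p of library-normalized
values, z-scored per gene) and $p$ its 2-D position. Dissociated cells carry
no position; their $p = (0,0)$, so the encoder contributes a learned constant.
Layers alternate self-attention (within a modality; the self-edge set is the
complete graph, including the unit itself) and cross-attention (between
modalities), each a residual update
$x^{(l+1)} = x^{(l)} + \mathrm{MLP}([x^{(l)} \| m])$ with multi-head
scaled-dot-product messages. Defaults: $L = 4$ layers (self, cross, self,
cross), $D = 64$, 4 heads, 500 epochs of full-batch Adam at 1e-3, seed 0. The
attention logits are scaled by $1/\sqrt{d_h}$, the standard stabilization for
dot-product attention.

Two points were genuinely open and are resolved as follows:

* The objective is the sum of cosine similarities between the reconstruction
  $\mathrm{softmax}(M)^\top A$ and the spatial truth $B$ (per gene and per
  spot); cosine terms are bounded above by 1, so the negated sum is minimized
  (equivalently, cosine agreement is maximized).
* $M$'s constraint is unstated. We pass $M$ through a column-wise softmax (per
  spot, over cells) before reconstruction so the weights are nonnegative and
  normalized; the exported mapping keeps the raw inner products, and
  `mapping_probabilities()` produces row- or column-softmax views.
* Descriptors are **not** L2-normalized before the inner product: their
  magnitude is allowed to carry confidence information.

The MLP output layers are zero-initialized, so at initialization every
residual layer is the identity and the descriptors are a linear map of the
encoded inputs; this gives a closed-form check used by the tests and makes
early training stable.

No deep-learning framework is assumed: gradients come from a small
reverse-mode tape (`R/autodiff.R`) whose every operator is verified against
central finite differences in the test suite.

# Spot decomposition

Integer allocation rounds $N_{cell}\beta_i$ half-up per type and, when the
total exceeds $N_{cell}$, takes back the round-ups that gained the least
(smallest fractional part first, ties by type order) so every count stays
within one cell of $N_{cell}\beta_i$. $N_{cell}$ defaults to 20. The subset search
scores random per-type subsets against the spot profile by squared error
(default budget 1000 subsets/spot, exhaustive when the candidate space is
smaller), which realizes the loosely specified "iterative refinement" as
seeded random restarts. The allocation can produce exactly $N_{cell}$ cells,
and the subset size is allowed to reach that cap.

Placement draws a quadrant with probability $(R_q + 1)/\sum_i (R_i + 1)$
(ratios of the cell's type in the nearest neighbor spot per quadrant; empty
quadrants are excluded and the mass renormalized), an angle uniform within
the quadrant's 90-degree arc, and a radial weight $\alpha \in (0, 1]$ whose
half-interval probabilities are proportional to $R_{center} + 1$ and
$R_{neighbor} + 1$ (these two weights are the only consistent normalization
that makes the half-interval probabilities sum to one). The radius is $\alpha\, d_{min}/2$, so no cell ever
leaves the half-distance disc around its spot center. Isolated spots (no
neighbor at all) fall back to a default $d_{min}$ of 100 um, one Visium-like
pitch.

# The subgraph attention network

Context subgraphs are unions of short random walks from the anchor node (or
anchor pair), truncated to nodes within `max_dist` hops of an anchor.
Node features concatenate user attributes with structural vectors, supplied
by a pluggable hook whose deterministic default replaces an external
random-walk embedding trainer (top adjacency eigenvectors scaled by
$\sqrt{|\lambda|}$, signs fixed). With a learnable linear map and an
inner-product link score, fine-tuning can recover a signed spectral
reconstruction of the adjacency, which is exactly what edge prediction needs.

Each translation layer computes a multi-head semantic association matrix
$\bar{A}_{ij} = \mathrm{softmax}_j((W_1 h_i)^\top (W_2 h_j))$ (rows sum to 1
per head; heads are averaged for the update) and applies
$H^{k+1} = f_{NN}(W_s H^k \bar{A}^k + H^k)$ with $f_{NN}$ after the residual
sum. The default $f_{NN}$ is a leaky rectifier (slope
0.2); the residual-identity closed form ($W_s = 0$, identity $f_{NN}$) is a
test hook. The contextual embedding concatenates the $K$ per-layer
embeddings in ascending order.

Masked pretraining replaces the anchor's *attribute* vector with a learned
mask token (structure and structural vector untouched) and predicts the node
identity with a linear head over the full node vocabulary; the head is
zero-initialized so the initial loss is exactly $\log |V|$. The prediction
head is a linear projection + softmax over the vocabulary, the simplest
parameterization consistent with the likelihood. Fine-tuning maximizes the logistic likelihood of
positive edges against uniformly sampled non-edges (1:1), scoring each pair
inside its own context subgraph with $S = \sigma(\tilde{h}_i^\top \tilde{h}_j)$.
At inference, `score_links()` averages a few subgraph samples per pair to
reduce context-sampling variance.

# Communication scoring

The cell graph connects each cell to its K nearest neighbors (default K = 6,
a typical spatial-neighborhood size) among
cells within 200 um, symmetrized by union. "Expressing" means a normalized
value strictly above zero. The permutation test permutes type labels over
cells and reports $p = |\{x \in C: x \ge C^0\}| / Z$ with $Z = 1000$ by
default; $p = 0$ is possible under this counting rule, and a `(card+1)/(Z+1)` correction is
available behind a flag. No multiple-testing correction is applied by
default (raw p < 0.05 is thresholded); Benjamini-Hochberg is available via
`bh = TRUE`. The TF filter runs a random walk with restart (restart 0.5)
from the receptor and calls TFs above the 90th percentile of TF scores
"activated" — both values are package conventions, configurable.

The event embedding keeps the conventional single-cell pipeline (scale, PCA,
kNN graph) but
the final 2-D step is a deterministic isomap-style embedding (classical MDS
on kNN-graph geodesics) rather than UMAP, which is not available in this R
stack. Duplicate events land on coincident points and planted blocks
separate, which is what the tests assert; fine UMAP-specific geometry is not
reproduced.

# Benchmark metrics

Per-gene metrics: PCC on raw vectors; SSIM on
max-scaled vectors with $C_1 = 0.01$, $C_2 = 0.03$ squared where the formula
squares them; RMSE on population z-scores; JSD on sum-normalized vectors in
log base 2 (so it is bounded by 1). Zero-variance vectors yield PCC 0 (with
a warning) and a zero z-score vector. The accuracy score ranks methods per
metric (best = N, average ranks on ties) and averages the four ranks.

The 2-D ground metric for the expression-weighted Wasserstein distance is a
design choice; we use the mean of exact 1-D Wasserstein-1 distances along x
and y, isolated in one internal function so
a different ground metric can be swapped in. The DES running sum adds
$(1 - p_j)/\sum_{matched}(1 - p)$ on matches and subtracts $1/n_{unmatched}$
on misses (a GSEA-style miss penalty that keeps the statistic bounded in
$[-1, 1]$); the reported value is
the signed maximum deviation from zero.

# The synthetic world

`simulate_paired_datasets()` draws negative-binomial counts
(variance $\mu + \phi\mu^2$, $\phi = 0.3$) with a 5-fold marker up-regulation
per type, places cells in a 1000x1000 um field at Visium-like 100 um pitch,
and caps placement at 18 cells per pitch bin so binned spots carry 1-18 cells
by construction, mirroring the simulated-grid benchmark the evaluation
emulates. Signaling genes (LIGi/RECi/TFi) get heterogeneous lognormal
baselines so distinct L-R combinations differ. The generator does not model
platform optics, segmentation error, batch effects or doublets, so a green
recovery test establishes correctness of the algorithms on well-posed input,
not robustness to real-platform noise.

For the link-prediction benchmark, the planted two-community world uses
within-community density 0.8 and cross density 0.02. This is deliberate: in
a sparse community graph, held-out edges are nearly indistinguishable from
same-community non-edges (the Bayes-optimal AUROC is ~0.75 at density 0.3),
so an AUROC > 0.9 criterion is only meaningful in a strongly assortative
world where edge status is predictable from community plus local spectral
structure.

# Numerical and degenerate-input conventions

* Softmaxes subtract the row maximum; attention-row sums are asserted to 1e-9.
* Zero-norm vectors in the cosine objective are skipped, counted and warned
  about rather than propagating NaN.
* Permutation p-values count ties as successes, so identical counts give
  p = 1.
* All stochastic stages take an explicit seed and are bitwise reproducible;
  training is full-batch, so given a seed the whole pipeline is
  deterministic (the `manifest.json` checksums of two identical runs match).

# Known limitations

* Full-graph attention is quadratic in the number of units; the package
  targets desk-scale data (hundreds to a few thousand units), not atlases.
* Multi-subunit receptor complexes, pathway enrichment, histology-based
  per-spot cell counting and cross-dataset transfer of trained weights are
  out of scope.
* The LOO validation helper constructs folds; re-training per fold is the
  caller's loop.
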