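# spatcomm

Integrating dissociated single-cell RNA-seq with spatial transcriptomics,
reconstructing single-cell-resolution maps from multi-cell spots, and
inferring spatially constrained ligand-receptor (L-R) cell-cell
communication — with the full benchmark-metric suite and seeded synthetic
data so every stage runs and is testable offline.

## Who this is for

Spatial platforms trade resolution for coverage: spot-based assays (10X
Visium and kin) mix 1-20 cells per spot, while dissociated scRNA-seq has
cell-level transcriptomes but no positions. `spatcomm` is for analysts who
have both modalities from the same tissue and want (1) per-spot cell-type
composition, (2) a plausible single-cell spatial map, and (3) statistically
tested, spatially constrained communication calls at single-cell resolution.

## What it computes

**Integration.** An attention graph network embeds cells and spatial units
(`x⁽⁰⁾ = d + MLP_enc(p)`), alternates self-/cross-attention residual layers,
and emits matching descriptors `f ∈ R^D`. The similarity matrix
`M_ij = <f_i^sc, f_j^st>` is trained full-batch so that the column-softmax
reconstruction `softmax(M)ᵀA` maximizes cosine agreement with the spatial
truth per gene and per spot. Gradients come from a small reverse-mode
autodiff tape written in R (every operator is finite-difference checked).

**Decomposition.** Per spot: integer per-type counts
`ω_i = ⌊N_cell β_i⌋ (+1 if the fractional part ≥ 0.5)` capped at `N_cell`
(default 20), a squared-error-optimal cell subset from seeded random
restarts, and probabilistic placement — quadrant drawn with probability
`(R_q+1)/Σ(R_i+1)`, angle uniform within the quadrant, radius `α·d_min/2`
with `α`'s half-interval weighted by the type's abundance in the parent vs
neighbor spot.

**Communication.** KNN cell graph (K = 6) under a 200 µm cutoff; receiver
cells filtered by a random-walk-with-restart from the receptor over a
receptor→TF network; permutation p-values
`p = card{x ∈ C : x ≥ C⁰}/Z` over Z label permutations; significant
combinations emit per-pair scores `S = √(L_i · R_j)`.

**Metrics.** Per-gene PCC / SSIM (C₁ = 0.01, C₂ = 0.03) / RMSE (population
z-scores) / JSD (base 2), accuracy-score rank aggregation, the Wasserstein
distance-ratio for spatial L-R tendency, and the distance enrichment score
(DES). A subgraph attention network (random-walk context subgraphs,
masked-node pretraining, contextual link prediction) supports graph-based
communication modeling.

## Worked example

```r
library(spatcomm)

# simulate a two-type tissue and bin it into Visium-like 100 um spots
paired <- simulate_paired_datasets(sim_config(seed = 1))
grid <- simulate_grid_spots(paired$map$dataset, paired$map$annotation, pitch = 100)

sc <- normalize_counts(paired$sc$expr)
st <- normalize_counts(grid$dataset$expr)
st_ds <- spatial_dataset(st, grid$dataset$coords, "spot",
                         cells_per_spot = grid$dataset$cells_per_spot)

genes <- select_training_genes(sc, paired$sc$annotation, st, n_top_per_type = 15)
length(genes$genes)
#> [1] 30

cfg <- train_config(n_layers = 4, dim = 32, n_heads = 4, epochs = 120,
                    lr = 2e-3, seed = 1)
M <- fit_mapping(sc, st_ds, genes, cfg)
props <- celltype_probability_map(M, paired$sc$annotation)
round(props[1:3, ], 3)
#>          type1 type2
#> spot_0_0 1.000 0.000
#> spot_0_1 0.997 0.003
#> spot_0_2 0.982 0.018
cor(as.numeric(props),
    as.numeric(grid$proportions[rownames(props), colnames(props)]))
#> [1] 0.8468206
```

The simulation placed `type1` in the left half of the field; the mapping
recovers near-pure `type1` composition for the left-edge spots, and the
per-spot proportion estimates correlate with the simulated truth at
PCC 0.85. Continuing to the single-cell map and communication calls:

```r
recon <- reconstruct_single_cell_map(st_ds, props, sc, paired$sc$annotation,
                                     budget = 200, seed = 1)
nrow(recon$placements)
#> [1] 300

nets <- simulate_networks(3)
graph <- build_cell_graph(recon$dataset, k = 6, cutoff_um = 200)
tab <- ccc_scores(graph, recon$dataset$expr, nets$lr_db, recon$annotation,
                  network = nets$network, Z = 200, seed = 1)
head(attr(tab, "combinations"), 4)
#>   ligand receptor sender_type receiver_type observed pvalue p_adj
#> 1   LIG1     REC1       type1         type1      759      0     0
#> 2   LIG1     REC1       type2         type1      160      1     1
#> 3   LIG1     REC1       type1         type2      148      1     1
#> 4   LIG1     REC1       type2         type2      261      0     0
```

With spatially segregated types, within-type L-R combinations have far more
adjacent co-expressing pairs than any label permutation (p = 0), while
cross-type combinations in this layout do not (p = 1). Each significant
combination expands into per-cell-pair rows with scores `√(L·R)` in `tab`.

A one-call orchestration (`run_pipeline(config, out_dir)`) runs
simulate → preprocess → integrate → decompose → ccc → evaluate from a JSON
config and writes a manifest with md5 checksums; reruns with the same config
are bitwise identical. A thin CLI wrapper lives at `inst/cli/spatcomm.R`
(subcommands `simulate`, `preprocess`, `integrate`, `decompose`, `ccc`,
`evaluate`, `run`).

## Documentation

`vignettes/spatcomm-methods.Rmd` describes the models, every tunable
parameter with its default and rationale, what the synthetic world does and
does not emulate, numerical conventions, and known limitations.
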