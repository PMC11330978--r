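#' Quality-control thresholds for raw count matrices
#'
#' Defaults follow common single-cell practice: cells with more than 20%
#' mitochondrial counts are removed; total-count and genes-per-cell caps are
#' disabled by default because sensible values are dataset-specific.
#'
#' @param max_mito_fraction maximum allowed mitochondrial count fraction
#'   (strictly greater is removed); in `[0, 1]`.
#' @param max_total_counts optional cap on a cell's total counts.
#' @param max_genes_per_cell optional cap on the number of detected genes.
#' @param min_cells_per_gene genes detected in fewer cells are dropped
#'   (applied after cell filtering).
#' @param min_genes_per_cell cells detecting fewer genes are dropped.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.20, max_total_counts = NULL,
                          max_genes_per_cell = NULL, min_cells_per_gene = 0L,
                          min_genes_per_cell = 0L) {
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must be in [0, 1]")
  }
  structure(list(max_mito_fraction = max_mito_fraction,
                 max_total_counts = max_total_counts,
                 max_genes_per_cell = max_genes_per_cell,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_per_cell = as.integer(min_genes_per_cell)),
            class = "qc_thresholds")
}

#' Filter low-quality cells, then sparsely detected genes
#'
#' Cells failing any criterion (mitochondrial fraction, total counts, detected
#' genes) are removed first; genes detected in fewer than
#' `min_cells_per_gene` of the surviving cells are removed second. The
#' operation is idempotent.
#'
#' @param matrix an `expression_matrix` with layer `"raw"`.
#' @param mito_prefixes gene-name prefixes identifying mitochondrial genes.
#' @param thresholds a [qc_thresholds()] object.
#' @return the filtered `expression_matrix` (still `"raw"`).
#' @export
qc_filter <- function(matrix, mito_prefixes = c("MT-", "mt-"),
                      thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (expr_layer(matrix) != "raw") stop("qc_filter expects the raw layer")
  m <- unclass(matrix)
  is_mito <- Reduce(`|`, lapply(mito_prefixes, function(p) startsWith(rownames(m), p)))
  if (is.null(is_mito)) is_mito <- rep(FALSE, nrow(m))
  totals <- colSums(m)
  mito_frac <- if (any(is_mito)) colSums(m[is_mito, , drop = FALSE]) / pmax(totals, 1) else
    rep(0, ncol(m))
  n_genes <- colSums(m > 0)

  fail_mito <- mito_frac > thresholds$max_mito_fraction
  fail_total <- if (!is.null(thresholds$max_total_counts)) totals > thresholds$max_total_counts else
    rep(FALSE, ncol(m))
  fail_ngene <- if (!is.null(thresholds$max_genes_per_cell)) n_genes > thresholds$max_genes_per_cell else
    rep(FALSE, ncol(m))
  fail_min_genes <- n_genes < thresholds$min_genes_per_cell
  keep_cells <- !(fail_mito | fail_total | fail_ngene | fail_min_genes)
  if (!any(keep_cells)) {
    stop(sprintf(paste0("all cells removed by QC (mito: %d, total-count: %d, ",
                        "max-genes: %d, min-genes: %d)"),
                 sum(fail_mito), sum(fail_total), sum(fail_ngene), sum(fail_min_genes)))
  }
  m <- m[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(m > 0) >= thresholds$min_cells_per_gene
  m <- m[keep_genes, , drop = FALSE]
  expression_matrix(m, layer = "raw")
}

#' Library-size normalization
#'
#' Scales each unit (column) so its total equals `target_sum`:
#' `X'_ij = X_ij / sum_i X_ij * T`. Within-unit rank order of genes is
#' preserved.
#'
#' @param matrix an `expression_matrix` with layer `"raw"`.
#' @param target_sum the post-normalization column total `T`.
#' @return an `expression_matrix` with layer `"normalized"`.
#' @export
normalize_counts <- function(matrix, target_sum = 1e4) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (expr_layer(matrix) != "raw") stop("normalize_counts expects the raw layer")
  m <- unclass(matrix)
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  if (length(zero)) stop("zero-total units: ", paste(utils::head(zero, 5L), collapse = ", "))
  out <- sweep(m, 2L, totals, "/") * target_sum
  expression_matrix(out, layer = "normalized")
}

# internal: one-vs-rest Wilcoxon rank-sum statistic per gene for one group.
# Returns the W statistic (rank-sum of the group minus its minimum), so larger
# W = gene higher in the group. Vectorized over genes via row-wise ranks.
rank_sum_stat <- function(logm, in_group) {
  n1 <- sum(in_group)
  ranks <- t(apply(logm, 1L, rank))  # ties get average ranks
  rs <- rowSums(ranks[, in_group, drop = FALSE])
  rs - n1 * (n1 + 1) / 2
}

#' Select training genes shared by both modalities
#'
#' For each cell type, genes are ranked by a one-vs-rest Wilcoxon rank-sum
#' statistic on log1p-normalized single-cell values (ties broken by gene
#' name); the top `n_top_per_type` per type are pooled, deduplicated,
#' intersected with the spatial gene list, and genes with all-zero counts in
#' either modality are dropped.
#'
#' @param sc_matrix normalized single-cell `expression_matrix`.
#' @param sc_annotation `cell_type_annotation` covering every cell.
#' @param st_matrix normalized spatial `expression_matrix`.
#' @param n_top_per_type markers retained per cell type.
#' @return a `training_gene_set` list: `genes` (ordered unique character) and
#'   `per_type_markers` (ranked character vectors per type).
#' @export
select_training_genes <- function(sc_matrix, sc_annotation, st_matrix,
                                  n_top_per_type = 100L) {
  stopifnot(inherits(sc_matrix, "expression_matrix"),
            inherits(st_matrix, "expression_matrix"))
  check_annotated(colnames(sc_matrix), sc_annotation)
  labels <- sc_annotation$labels[colnames(sc_matrix)]
  types <- sc_annotation$type_order[sc_annotation$type_order %in% labels]
  if (length(types) < 2L) stop("need at least 2 cell types")
  logm <- log1p(unclass(sc_matrix))
  per_type <- lapply(types, function(ty) {
    w <- rank_sum_stat(logm, labels == ty)
    ord <- order(-w, rownames(sc_matrix))
    utils::head(rownames(sc_matrix)[ord], n_top_per_type)
  })
  names(per_type) <- types
  pooled <- unique(unlist(per_type, use.names = FALSE))
  pooled <- intersect(pooled, rownames(st_matrix))
  sc_zero <- rownames(sc_matrix)[rowSums(unclass(sc_matrix)) == 0]
  st_zero <- rownames(st_matrix)[rowSums(unclass(st_matrix)) == 0]
  pooled <- setdiff(pooled, union(sc_zero, st_zero))
  if (!length(pooled)) stop("no training genes survive intersection/zero filters")
  per_type <- lapply(per_type, function(g) g[g %in% pooled])
  structure(list(genes = pooled, per_type_markers = per_type),
            class = "training_gene_set")
}

#' Leave-one-out folds over a gene set
#'
#' @param training_genes character vector (or `training_gene_set`) of n >= 2
#'   genes.
#' @return list of n folds, each `list(train, test)`; gene k is held out in
#'   fold k.
#' @export
loo_folds <- function(training_genes) {
  genes <- if (inherits(training_genes, "training_gene_set")) training_genes$genes else
    training_genes
  n <- length(genes)
  if (n < 2L) stop("need at least 2 genes for leave-one-out")
  lapply(seq_len(n), function(k) list(train = genes[-k], test = genes[k]))
}
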