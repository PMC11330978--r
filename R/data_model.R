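#' Expression matrix container
#'
#' A genes x units (cells or spots) matrix of nonnegative expression values
#' with explicit name indices and a layer tag recording how the values were
#' derived from raw counts.
#'
#' @param values numeric matrix, genes in rows, units in columns, no NaN/NA,
#'   all values >= 0. The `"raw"` layer must be integer-valued (or zero).
#' @param gene_names character vector of unique gene symbols; defaults to
#'   `rownames(values)`.
#' @param unit_names character vector of unique unit (cell/spot) names;
#'   defaults to `colnames(values)`.
#' @param layer one of `"raw"`, `"normalized"`, `"scaled01"`, `"zscore"`.
#' @return an object of class `expression_matrix`: the matrix with dimnames
#'   set and a `layer` attribute.
#' @export
expression_matrix <- function(values, gene_names = rownames(values),
                              unit_names = colnames(values),
                              layer = c("raw", "normalized", "scaled01", "zscore")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(gene_names) || is.null(unit_names)) {
    stop("gene_names and unit_names are required (or set dimnames on 'values')")
  }
  gene_names <- trimws(as.character(gene_names))
  unit_names <- trimws(as.character(unit_names))
  if (length(gene_names) != nrow(values)) stop("gene_names length != nrow(values)")
  if (length(unit_names) != ncol(values)) stop("unit_names length != ncol(values)")
  dup_g <- unique(gene_names[duplicated(gene_names)])
  if (length(dup_g)) stop("duplicate gene names: ", paste(dup_g, collapse = ", "))
  dup_u <- unique(unit_names[duplicated(unit_names)])
  if (length(dup_u)) stop("duplicate unit names: ", paste(dup_u, collapse = ", "))
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) stop("expression values must be finite, no NA/NaN")
  if (any(values < 0)) stop("negative expression values not allowed")
  if (layer == "raw" && any(abs(values - round(values)) > 1e-8)) {
    stop("'raw' layer must be integer-valued counts")
  }
  dimnames(values) <- list(gene_names, unit_names)
  structure(values, layer = layer, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d units [layer=%s]\n",
              nrow(x), ncol(x), expr_layer(x)))
  invisible(x)
}

#' Layer tag of an expression matrix
#' @param x an `expression_matrix`
#' @return the layer string
#' @export
expr_layer <- function(x) attr(x, "layer")

# internal: rebuild an expression_matrix from a plain matrix keeping checks
as_expression_matrix <- function(values, layer) {
  expression_matrix(values, rownames(values), colnames(values), layer = layer)
}

#' Read an expression matrix from disk
#'
#' Supports a dense TSV (genes in rows, first column = gene name, header row =
#' unit names) and Matrix-Market coordinate format with sidecar name files
#' (one gene name per line, one unit name per line; indices 1-based on disk).
#'
#' @param path path to the TSV or `.mtx` file.
#' @param format `"dense_tsv"` or `"matrix_market_triplet"`.
#' @param genes_path,units_path sidecar name files, required for the
#'   Matrix-Market format.
#' @return an `expression_matrix` with layer `"raw"`, row/column order as on
#'   disk.
#' @export
load_expression <- function(path, format = c("dense_tsv", "matrix_market_triplet"),
                            genes_path = NULL, units_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- trimws(as.character(tab[[1L]]))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    expression_matrix(vals, genes, colnames(tab)[-1L], layer = "raw")
  } else {
    if (is.null(genes_path) || is.null(units_path)) {
      stop("matrix_market_triplet needs genes_path and units_path")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- trimws(readLines(genes_path))
    units <- trimws(readLines(units_path))
    expression_matrix(m, genes, units, layer = "raw")
  }
}

#' Write an expression matrix as dense TSV
#' @param x an `expression_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spatial dataset: expression plus 2-D coordinates
#'
#' Coordinates are continuous micrometres in a Cartesian plane (origin
#' arbitrary); all downstream geometry (the 200 um neighbourhood cutoff,
#' nearest-spot distances) assumes metric units.
#'
#' @param expr an `expression_matrix` over the spatial units.
#' @param coords data.frame with columns `unit`, `x`, `y` (micrometres).
#' @param resolution `"single_cell"` or `"spot"`.
#' @param cells_per_spot optional positive integer vector named by spot.
#' @return a `spatial_dataset` list.
#' @export
spatial_dataset <- function(expr, coords, resolution = c("single_cell", "spot"),
                            cells_per_spot = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(expr, "expression_matrix"))
  if (!all(c("unit", "x", "y") %in% names(coords))) {
    stop("coords needs columns unit, x, y")
  }
  coords$unit <- trimws(as.character(coords$unit))
  units <- colnames(expr)
  missing_in_expr <- setdiff(coords$unit, units)
  if (length(missing_in_expr)) {
    stop("units in coords but not expression: ", paste(missing_in_expr, collapse = ", "))
  }
  missing_in_coords <- setdiff(units, coords$unit)
  if (length(missing_in_coords)) {
    stop("units missing from coords: ", paste(missing_in_coords, collapse = ", "))
  }
  coords <- coords[match(units, coords$unit), c("unit", "x", "y")]
  rownames(coords) <- NULL
  if (any(!is.finite(coords$x)) || any(!is.finite(coords$y))) stop("coordinates must be finite")
  if (!is.null(cells_per_spot)) {
    cells_per_spot <- cells_per_spot[units]
    if (anyNA(cells_per_spot) || any(cells_per_spot < 1)) {
      stop("cells_per_spot must cover all units with positive integers")
    }
  }
  structure(list(expr = expr, coords = coords, resolution = resolution,
                 cells_per_spot = cells_per_spot),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset [%s]: %d genes x %d units\n",
              x$resolution, nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' Load a spatial dataset from an expression table and a coordinate table
#'
#' Units are aligned by name between the two files; the row order of the
#' coordinate file is irrelevant. Any unit present in one file but not the
#' other is an error.
#'
#' @param expr_path dense TSV expression file (see [load_expression()]).
#' @param coords_path CSV/TSV with columns `unit`, `x`, `y` (delimiter
#'   auto-detected from the header line).
#' @param resolution `"single_cell"` or `"spot"`.
#' @return a `spatial_dataset`.
#' @export
load_spatial <- function(expr_path, coords_path, resolution = c("single_cell", "spot")) {
  resolution <- match.arg(resolution)
  expr <- load_expression(expr_path, "dense_tsv")
  header <- readLines(coords_path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  coords <- utils::read.table(coords_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  spatial_dataset(expr, coords, resolution)
}

#' Cell type annotation
#'
#' @param labels named character vector: unit name -> type label.
#' @param type_order optional ordered unique type labels; defaults to order of
#'   first appearance.
#' @return a `cell_type_annotation` list with `labels` and `type_order`.
#' @export
cell_type_annotation <- function(labels, type_order = NULL) {
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop("labels must be named by unit")
  }
  labels <- stats::setNames(as.character(labels), trimws(names(labels)))
  if (anyDuplicated(names(labels))) stop("duplicate unit names in annotation")
  if (is.null(type_order)) type_order <- unique(unname(labels))
  if (!all(labels %in% type_order)) stop("labels outside type_order")
  structure(list(labels = labels, type_order = type_order),
            class = "cell_type_annotation")
}

# internal: assert every unit of a matrix/dataset is annotated
check_annotated <- function(units, annotation) {
  miss <- setdiff(units, names(annotation$labels))
  if (length(miss)) {
    stop("units without annotation: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Ligand-receptor pair database
#' @param pairs data.frame with columns `ligand`, `receptor` (and optionally
#'   `pathway`); duplicates rejected, empty symbols rejected.
#' @return an `lr_database` data.frame.
#' @export
lr_database <- function(pairs) {
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    stop("pairs needs columns ligand, receptor")
  }
  pairs$ligand <- trimws(as.character(pairs$ligand))
  pairs$receptor <- trimws(as.character(pairs$receptor))
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor))) {
    stop("empty gene symbols in L-R table")
  }
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate L-R pairs")
  class(pairs) <- c("lr_database", "data.frame")
  pairs
}

#' Read a two-column ligand-receptor TSV
#' @param path TSV with header columns `ligand`, `receptor`
#' @return an `lr_database`
#' @export
load_lr_pairs <- function(path) {
  lr_database(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' Receptor to transcription-factor signaling network
#'
#' Directed weighted edges from receptors through intermediates to
#' transcription factors; used by the random-walk TF activity filter.
#'
#' @param edges data.frame with columns `source`, `target`, `weight` (> 0).
#' @param tf_nodes character vector naming which nodes are transcription
#'   factors.
#' @return a `receptor_tf_network` list with `edges` and `tf_nodes`.
#' @export
receptor_tf_network <- function(edges, tf_nodes) {
  if (!all(c("source", "target", "weight") %in% names(edges))) {
    stop("edges needs columns source, target, weight")
  }
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  if (any(edges$source == edges$target)) stop("self-loops not allowed")
  structure(list(edges = edges, tf_nodes = unique(trimws(tf_nodes))),
            class = "receptor_tf_network")
}

#' Read a receptor-TF network TSV
#' @param path TSV with columns `source`, `target`, `weight`, `is_tf`
#'   (logical flag on the *target* row marking TF nodes).
#' @return a `receptor_tf_network`
#' @export
load_tf_network <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tfs <- unique(tab$target[as.logical(tab$is_tf)])
  receptor_tf_network(tab[, c("source", "target", "weight")], tfs)
}

#' Write a single-cell spatial map to disk
#'
#' Emits `<prefix>_cells.tsv` (columns cell, x, y, cell_type) and
#' `<prefix>_expression.tsv` (dense genes x cells). Reloading with
#' [read_single_cell_map()] reproduces coordinates bit-exactly.
#'
#' @param dataset a `spatial_dataset` with `resolution == "single_cell"`.
#' @param annotation a `cell_type_annotation` covering every cell.
#' @param prefix output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
write_single_cell_map <- function(dataset, annotation, prefix) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (dataset$resolution != "single_cell") stop("dataset must be single_cell resolution")
  cells <- colnames(dataset$expr)
  check_annotated(cells, annotation)
  tab <- data.frame(cell = dataset$coords$unit, x = dataset$coords$x,
                    y = dataset$coords$y,
                    cell_type = unname(annotation$labels[dataset$coords$unit]))
  cells_path <- paste0(prefix, "_cells.tsv")
  expr_path <- paste0(prefix, "_expression.tsv")
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(dataset$expr, expr_path)
  invisible(c(cells_path, expr_path))
}

#' Reload a single-cell spatial map written by [write_single_cell_map()]
#' @param prefix the same path prefix
#' @return list with `dataset` (a `spatial_dataset`) and `annotation`
#' @export
read_single_cell_map <- function(prefix) {
  tab <- utils::read.table(paste0(prefix, "_cells.tsv"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = c(
                             cell = "character", x = "numeric", y = "numeric",
                             cell_type = "character"))
  expr <- load_expression(paste0(prefix, "_expression.tsv"), "dense_tsv")
  coords <- data.frame(unit = tab$cell, x = tab$x, y = tab$y)
  ds <- if (nrow(tab)) spatial_dataset(expr, coords, "single_cell") else
    structure(list(expr = expr, coords = coords, resolution = "single_cell",
                   cells_per_spot = NULL), class = "spatial_dataset")
  ann <- if (nrow(tab)) cell_type_annotation(stats::setNames(tab$cell_type, tab$cell)) else NULL
  list(dataset = ds, annotation = ann)
}
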