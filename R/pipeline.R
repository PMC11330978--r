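# End-to-end orchestration: simulate -> preprocess -> integrate -> decompose
# -> ccc -> evaluate, driven by a single declarative JSON config.

pipeline_schema <- function() list(
  seed = NULL,
  simulate = names(formals(sim_config)),
  preprocess = c("target_sum", "n_top_per_type", "max_mito_fraction",
                 "min_cells_per_gene", "min_genes_per_cell"),
  integrate = c("n_layers", "dim", "n_heads", "epochs", "lr"),
  decompose = c("n_cell", "budget"),
  ccc = c("k", "cutoff_um", "Z", "alpha"),
  evaluate = character(0)
)

#' Validate a pipeline run configuration
#'
#' @param config a named list (e.g. parsed from JSON). Unknown keys at either
#'   level are rejected by name; a `seed` is required so every stage is
#'   explicitly seeded.
#' @return the validated config (with defaults filled), invisibly usable by
#'   [run_pipeline()].
#' @export
validate_run_config <- function(config) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set an explicit seed")
  for (section in setdiff(names(schema), "seed")) {
    allowed <- schema[[section]]
    bad <- setdiff(names(config[[section]]), allowed)
    if (length(bad)) {
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    }
  }
  config
}

#' Run the full pipeline from a declarative config
#'
#' Stages: simulate paired data and grid spots, preprocess (QC, normalize,
#' training genes), integrate (fit the mapping), decompose spots to single
#' cells, score spatial CCC, and evaluate predicted spot expression against
#' the simulated truth. Writes all outputs plus a `manifest.json` with the
#' config, stage timings and md5 checksums; identical config + seed
#' reproduces identical outputs.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  seed <- as.integer(config$seed)

  sim_args <- config$simulate
  sim_args$seed <- seed
  sim <- clock("simulate", do.call(sim_config, as.list(sim_args)))
  paired <- simulate_paired_datasets(sim)
  grid <- simulate_grid_spots(paired$map$dataset, paired$map$annotation, sim$pitch)
  nets <- simulate_networks(sim$n_lr)

  pp <- config$preprocess
  target_sum <- if (!is.null(pp$target_sum)) pp$target_sum else 1e4
  n_top <- if (!is.null(pp$n_top_per_type)) pp$n_top_per_type else 20L
  sc_norm <- clock("preprocess", {
    thr <- qc_thresholds(
      max_mito_fraction = if (!is.null(pp$max_mito_fraction)) pp$max_mito_fraction else 0.20,
      min_cells_per_gene = if (!is.null(pp$min_cells_per_gene)) pp$min_cells_per_gene else 0L,
      min_genes_per_cell = if (!is.null(pp$min_genes_per_cell)) pp$min_genes_per_cell else 0L)
    normalize_counts(qc_filter(paired$sc$expr, thresholds = thr), target_sum)
  })
  st_norm <- normalize_counts(grid$dataset$expr, target_sum)
  st_ds <- spatial_dataset(st_norm, grid$dataset$coords, "spot",
                           cells_per_spot = grid$dataset$cells_per_spot)
  genes <- select_training_genes(sc_norm, paired$sc$annotation, st_norm, n_top)
  writeLines(genes$genes, file.path(out_dir, "training_genes.txt"))

  ig <- config$integrate
  cfg <- train_config(n_layers = if (!is.null(ig$n_layers)) ig$n_layers else 4L,
                      dim = if (!is.null(ig$dim)) ig$dim else 32L,
                      n_heads = if (!is.null(ig$n_heads)) ig$n_heads else 4L,
                      epochs = if (!is.null(ig$epochs)) ig$epochs else 60L,
                      lr = if (!is.null(ig$lr)) ig$lr else 1e-3,
                      seed = seed)
  mapping <- clock("integrate", fit_mapping(sc_norm, st_ds, genes, cfg))
  utils::write.table(data.frame(cell = rownames(mapping), unclass(mapping),
                                check.names = FALSE),
                     file.path(out_dir, "mapping.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  props <- celltype_probability_map(mapping, paired$sc$annotation)

  dc <- config$decompose
  recon <- clock("decompose", reconstruct_single_cell_map(
    st_ds, props, sc_norm, paired$sc$annotation,
    n_cell = if (!is.null(dc$n_cell)) dc$n_cell else 20L,
    budget = if (!is.null(dc$budget)) dc$budget else 200L,
    seed = seed))
  write_single_cell_map(recon$dataset, recon$annotation,
                        file.path(out_dir, "single_cell_map"))

  cc <- config$ccc
  ccc <- clock("ccc", {
    graph <- build_cell_graph(recon$dataset,
                              k = if (!is.null(cc$k)) cc$k else 6L,
                              cutoff_um = if (!is.null(cc$cutoff_um)) cc$cutoff_um else 200)
    ccc_scores(graph, recon$dataset$expr, nets$lr_db, recon$annotation,
               network = nets$network,
               alpha = if (!is.null(cc$alpha)) cc$alpha else 0.05,
               Z = if (!is.null(cc$Z)) cc$Z else 200L, seed = seed)
  })
  utils::write.table(as.data.frame(ccc), file.path(out_dir, "ccc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- clock("evaluate", {
    w <- mapping_probabilities(mapping, "cells")       # per-spot over cells
    pred <- t(w) %*% t(unclass(sc_norm)[genes$genes, , drop = FALSE])
    truth <- t(unclass(st_norm)[genes$genes, , drop = FALSE])
    metric_report(t(truth), t(pred))
  })
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(config = config,
                   timings = timings,
                   checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
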