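#' Simulation configuration
#'
#' The stated world of the generators: a Visium-like 1000 x 1000 um field at
#' 100 um spot pitch, negative-binomial counts with type-specific marker
#' up-regulation, 1-18 cells per grid spot, and a small panel of signaling
#' genes (ligand LIGi / receptor RECi / transcription factor TFi per planted
#' pair) expressed at heterogeneous baseline levels.
#'
#' @param n_types number of cell types.
#' @param n_genes background genes (markers are carved out of these).
#' @param markers_per_type up-regulated marker genes per type.
#' @param cells_per_type cells of each type in the spatial map (and in the
#'   dissociated draw).
#' @param layout `"domains"` (vertical strips), `"layered_cortex"`
#'   (horizontal bands), or `"random"` (types spatially mixed).
#' @param field_size square field side, micrometres.
#' @param pitch grid spot pitch, micrometres.
#' @param max_cells_per_spot hard cap enforced at placement time (default 18).
#' @param marker_effect fold-change of a marker in its own type.
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param base_mean baseline NB mean per gene.
#' @param n_lr number of signaling ligand-receptor-TF triplets.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_types = 2L, n_genes = 60L, markers_per_type = 10L,
                       cells_per_type = 150L, layout = c("domains", "layered_cortex", "random"),
                       field_size = 1000, pitch = 100, max_cells_per_spot = 18L,
                       marker_effect = 5, dispersion = 0.3, base_mean = 2,
                       n_lr = 3L, seed = 0L) {
  layout <- match.arg(layout)
  if (n_types * markers_per_type > n_genes) stop("more markers than genes")
  structure(list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 cells_per_type = as.integer(cells_per_type), layout = layout,
                 field_size = field_size, pitch = pitch,
                 max_cells_per_spot = as.integer(max_cells_per_spot),
                 marker_effect = marker_effect, dispersion = dispersion,
                 base_mean = base_mean, n_lr = as.integer(n_lr),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal: gene panel and per-type NB means
sim_gene_model <- function(config) {
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  sig <- if (config$n_lr > 0) c(sprintf("LIG%d", seq_len(config$n_lr)),
                                sprintf("REC%d", seq_len(config$n_lr)),
                                sprintf("TF%d", seq_len(config$n_lr))) else character(0)
  all_genes <- c(genes, sig)
  types <- sprintf("type%d", seq_len(config$n_types))
  mu <- matrix(config$base_mean, length(all_genes), config$n_types,
               dimnames = list(all_genes, types))
  markers <- list()
  for (t in seq_len(config$n_types)) {
    idx <- ((t - 1L) * config$markers_per_type + 1L):(t * config$markers_per_type)
    mu[idx, t] <- config$base_mean * config$marker_effect
    markers[[types[t]]] <- genes[idx]
  }
  # heterogeneous baseline for signaling genes so combos differ
  if (length(sig)) {
    mu[sig, ] <- matrix(rep(stats::rlnorm(length(sig), meanlog = log(config$base_mean),
                                          sdlog = 0.6), config$n_types),
                        ncol = config$n_types)
  }
  list(genes = all_genes, types = types, mu = mu, markers = markers)
}

# internal: NB draw for a set of cells given their types
sim_counts <- function(model, cell_types, config) {
  size <- 1 / config$dispersion
  n <- length(cell_types)
  counts <- matrix(0L, length(model$genes), n)
  for (t in seq_along(model$types)) {
    idx <- which(cell_types == model$types[t])
    if (!length(idx)) next
    counts[, idx] <- stats::rnbinom(length(model$genes) * length(idx),
                                    mu = model$mu[, t], size = size)
  }
  rownames(counts) <- model$genes
  counts
}

#' Simulate a paired dissociated + spatial single-cell dataset
#'
#' Draws a single-cell spatial map (cells with known types and coordinates,
#' placement capped at `max_cells_per_spot` per pitch-sized grid bin) and an
#' independent dissociated draw from the same count model. Ground truth is
#' retained throughout.
#'
#' @param config a [sim_config()].
#' @return list with `sc` (list: `expr` raw `expression_matrix`,
#'   `annotation`), `map` (list: `dataset` single-cell `spatial_dataset`,
#'   `annotation`), `model` (gene panel, markers, means), `config`.
#' @export
simulate_paired_datasets <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    model <- sim_gene_model(config)
    n_map <- config$n_types * config$cells_per_type
    map_types <- rep(model$types, each = config$cells_per_type)
    fs <- config$field_size
    nbin <- max(1L, floor(fs / config$pitch))
    occupancy <- matrix(0L, nbin, nbin)
    xs <- numeric(n_map); ys <- numeric(n_map)
    for (i in seq_len(n_map)) {
      repeat {
        xy <- switch(config$layout,
          domains = {
            t <- match(map_types[i], model$types)
            c(stats::runif(1, (t - 1) * fs / config$n_types, t * fs / config$n_types),
              stats::runif(1, 0, fs))
          },
          layered_cortex = {
            t <- match(map_types[i], model$types)
            c(stats::runif(1, 0, fs),
              stats::runif(1, (t - 1) * fs / config$n_types, t * fs / config$n_types))
          },
          random = stats::runif(2, 0, fs))
        bx <- min(nbin, 1L + floor(xy[1] / config$pitch))
        by <- min(nbin, 1L + floor(xy[2] / config$pitch))
        if (occupancy[bx, by] < config$max_cells_per_spot) {
          occupancy[bx, by] <- occupancy[bx, by] + 1L
          xs[i] <- xy[1]; ys[i] <- xy[2]
          break
        }
      }
    }
    map_cells <- sprintf("cell%04d", seq_len(n_map))
    map_counts <- sim_counts(model, map_types, config)
    colnames(map_counts) <- map_cells
    map_expr <- expression_matrix(map_counts, layer = "raw")
    map_ds <- spatial_dataset(map_expr, data.frame(unit = map_cells, x = xs, y = ys),
                              "single_cell")
    map_ann <- cell_type_annotation(stats::setNames(map_types, map_cells),
                                    type_order = model$types)

    sc_types <- rep(model$types, each = config$cells_per_type)
    sc_cells <- sprintf("sc%04d", seq_along(sc_types))
    sc_counts <- sim_counts(model, sc_types, config)
    colnames(sc_counts) <- sc_cells
    sc_expr <- expression_matrix(sc_counts, layer = "raw")
    sc_ann <- cell_type_annotation(stats::setNames(sc_types, sc_cells),
                                   type_order = model$types)
    list(sc = list(expr = sc_expr, annotation = sc_ann),
         map = list(dataset = map_ds, annotation = map_ann),
         model = model, config = config)
  })
}

#' Bin a single-cell map into grid spots
#'
#' Cells are binned into square spots of side `pitch`; spot expression is the
#' sum of member-cell counts (total counts conserved), spot centers are bin
#' centers, and the true per-spot type proportions and cell counts are
#' recorded.
#'
#' @param single_cell_map a single-cell `spatial_dataset`.
#' @param annotation matching `cell_type_annotation`.
#' @param pitch spot side length (micrometres).
#' @return list with `dataset` (spot `spatial_dataset` with
#'   `cells_per_spot`), `proportions` (spots x types, rows sum to 1),
#'   `members` (list of member cells per spot).
#' @export
simulate_grid_spots <- function(single_cell_map, annotation, pitch = 100) {
  coords <- single_cell_map$coords
  bx <- floor(coords$x / pitch)
  by <- floor(coords$y / pitch)
  bin <- sprintf("spot_%d_%d", bx, by)
  members <- split(coords$unit, bin)
  spots <- names(members)
  m <- unclass(single_cell_map$expr)
  spot_expr <- vapply(members, function(cells) rowSums(m[, cells, drop = FALSE]),
                      numeric(nrow(m)))
  centers <- do.call(rbind, lapply(strsplit(sub("^spot_", "", spots), "_"),
                                   function(p) as.numeric(p)))
  coords_spot <- data.frame(unit = spots,
                            x = (centers[, 1L] + 0.5) * pitch,
                            y = (centers[, 2L] + 0.5) * pitch)
  types <- annotation$type_order
  prop <- t(vapply(members, function(cells) {
    tab <- table(factor(annotation$labels[cells], levels = types))
    as.numeric(tab) / length(cells)
  }, numeric(length(types))))
  colnames(prop) <- types
  rownames(prop) <- spots
  counts_per_spot <- vapply(members, length, 1L)
  expr <- expression_matrix(spot_expr, layer = "raw")
  ds <- spatial_dataset(expr, coords_spot, "spot",
                        cells_per_spot = counts_per_spot)
  list(dataset = ds, proportions = prop, members = members)
}

#' Plant a ligand-receptor communication signal
#'
#' Boosts the ligand in sender-type cells that have a receiver-type cell
#' within `radius`, and the receptor plus downstream TF in those receivers.
#' Returns the modified map and the ground-truth table of planted
#' (sender, receiver) pairs.
#'
#' @param single_cell_map a single-cell `spatial_dataset` (raw counts).
#' @param annotation matching `cell_type_annotation`.
#' @param ligand,receptor,tf gene names present in the matrix.
#' @param sender_type,receiver_type communicating cell types.
#' @param radius interaction radius (micrometres); 0 plants nothing.
#' @param boost count increment added to the boosted genes.
#' @return list with `dataset` (modified), `truth` (data.frame sender,
#'   receiver, distance).
#' @export
plant_lr_signal <- function(single_cell_map, annotation, ligand, receptor,
                            tf = NULL, sender_type, receiver_type, radius,
                            boost = 20L) {
  coords <- single_cell_map$coords
  m <- unclass(single_cell_map$expr)
  labels <- annotation$labels[coords$unit]
  senders <- coords$unit[labels == sender_type]
  receivers <- coords$unit[labels == receiver_type]
  truth <- list()
  if (radius > 0 && length(senders) && length(receivers)) {
    xy <- as.matrix(coords[, c("x", "y")])
    rownames(xy) <- coords$unit
    for (s in senders) {
      d <- sqrt(colSums((t(xy[receivers, , drop = FALSE]) - xy[s, ])^2))
      hit <- receivers[d <= radius & receivers != s]
      if (length(hit)) {
        truth[[length(truth) + 1L]] <- data.frame(sender = s, receiver = hit,
                                                  distance = d[d <= radius & receivers != s])
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sender = character(0), receiver = character(0), distance = numeric(0))
  rownames(truth) <- NULL
  if (nrow(truth)) {
    m[ligand, unique(truth$sender)] <- m[ligand, unique(truth$sender)] + boost
    m[receptor, unique(truth$receiver)] <- m[receptor, unique(truth$receiver)] + boost
    if (!is.null(tf)) {
      m[tf, unique(truth$receiver)] <- m[tf, unique(truth$receiver)] + boost
    }
  }
  expr <- expression_matrix(m, layer = expr_layer(single_cell_map$expr))
  list(dataset = spatial_dataset(expr, coords, "single_cell"), truth = truth)
}

#' Simulate a ligand-receptor database and receptor-TF network
#'
#' One triplet per signaling pair: LIGi - RECi in the database, and a layered
#' acyclic network RECi -> INTi -> TFi (plus a direct RECi -> TFi edge) with
#' positive weights; every receptor reaches at least one TF.
#'
#' @param n_pairs number of L-R pairs (matches `sim_config$n_lr`).
#' @return list with `lr_db` (an `lr_database`) and `network`
#'   (a `receptor_tf_network`).
#' @export
simulate_networks <- function(n_pairs = 3L) {
  i <- seq_len(n_pairs)
  lr <- lr_database(data.frame(ligand = sprintf("LIG%d", i),
                               receptor = sprintf("REC%d", i)))
  edges <- rbind(
    data.frame(source = sprintf("REC%d", i), target = sprintf("INT%d", i), weight = 1),
    data.frame(source = sprintf("INT%d", i), target = sprintf("TF%d", i), weight = 1),
    data.frame(source = sprintf("REC%d", i), target = sprintf("TF%d", i), weight = 0.5))
  net <- receptor_tf_network(edges, tf_nodes = sprintf("TF%d", i))
  list(lr_db = lr, network = net)
}
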