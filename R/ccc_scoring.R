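#' Spatial cell graph with a distance cutoff
#'
#' Euclidean distances between single cells; each cell is connected to its K
#' nearest neighbors among cells within `cutoff_um` (default 200 um, the
#' paracrine signaling range), and the edge set is symmetrized by union.
#'
#' @param single_cell_map a single-cell `spatial_dataset` (or a coords
#'   data.frame with columns unit, x, y).
#' @param k neighbors per cell (default 6).
#' @param cutoff_um maximum edge length in micrometres.
#' @return a `cell_graph` list: `adj` (sparse symmetric 0/1 Matrix with cell
#'   dimnames), `dist` (dense distance matrix), `k`, `cutoff`.
#' @export
build_cell_graph <- function(single_cell_map, k = 6L, cutoff_um = 200) {
  coords <- if (inherits(single_cell_map, "spatial_dataset")) {
    if (single_cell_map$resolution != "single_cell") {
      stop("cell graph needs single-cell resolution")
    }
    single_cell_map$coords
  } else single_cell_map
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 cells")
  xy <- as.matrix(coords[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(coords$unit, coords$unit)
  adj <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    eligible <- which(di <= cutoff_um)
    if (!length(eligible)) next
    nb <- eligible[order(di[eligible])][seq_len(min(k, length(eligible)))]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  structure(list(adj = Matrix::Matrix(adj * 1, sparse = TRUE), dist = d,
                 k = as.integer(k), cutoff = cutoff_um),
            class = "cell_graph")
}

#' Random-walk-with-restart scores over a signaling network
#'
#' Solves the stationary distribution `s = r e + (1 - r) W' s` exactly,
#' where `W` is the row-normalized transition matrix of the directed network
#' and `e` is the indicator of the seed (receptor) node.
#'
#' @param network a `receptor_tf_network`.
#' @param seed_node node to restart from.
#' @param restart_prob restart probability `r`.
#' @return named numeric vector of stationary scores over all network nodes.
#' @export
rwr_scores <- function(network, seed_node, restart_prob = 0.5) {
  nodes <- unique(c(network$edges$source, network$edges$target))
  if (!seed_node %in% nodes) stop("seed node not in network: ", seed_node)
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w[cbind(network$edges$source, network$edges$target)] <- network$edges$weight
  rs <- rowSums(w)
  sinks <- rs == 0
  w[!sinks, ] <- w[!sinks, , drop = FALSE] / rs[!sinks]
  w[sinks, ] <- 0  # walk terminates at sinks (restart handles mass loss)
  e <- as.numeric(nodes == seed_node)
  s <- solve(diag(n) - (1 - restart_prob) * t(w), restart_prob * e)
  stats::setNames(s, nodes)
}

#' Filter receiver cells by downstream TF activity
#'
#' Runs a random walk with restart from the receptor over the receptor-TF
#' network; TFs scoring above the threshold (default: the 90th percentile of
#' TF scores) count as downstream-activated. A cell is an eligible receiver
#' iff it expresses the receptor (> 0) and at least one activated TF (> 0).
#' If the receptor is absent from the network, all receptor-expressing cells
#' are eligible (with a warning).
#'
#' @param expression an `expression_matrix` over the single cells.
#' @param network a `receptor_tf_network` (or NULL to skip the filter).
#' @param receptor receptor gene symbol.
#' @param restart_prob RWR restart probability.
#' @param score_threshold absolute score threshold; NULL uses the 90th
#'   percentile among TF nodes.
#' @return character vector of eligible receiver cell names.
#' @export
tf_activity_filter <- function(expression, network, receptor, restart_prob = 0.5,
                               score_threshold = NULL) {
  m <- unclass(expression)
  if (!receptor %in% rownames(m)) return(character(0))
  expresses_rec <- colnames(m)[m[receptor, ] > 0]
  if (is.null(network)) return(expresses_rec)
  nodes <- unique(c(network$edges$source, network$edges$target))
  if (!receptor %in% nodes) {
    warning("receptor ", receptor, " absent from network; skipping TF filter")
    return(expresses_rec)
  }
  s <- rwr_scores(network, receptor, restart_prob)
  tf_scores <- s[intersect(network$tf_nodes, names(s))]
  tf_scores <- tf_scores[tf_scores > 0]  # unreachable TFs are never activated
  if (!length(tf_scores)) return(character(0))
  thr <- if (is.null(score_threshold)) stats::quantile(tf_scores, 0.9, names = FALSE) else
    score_threshold
  active_tfs <- names(tf_scores)[tf_scores >= thr]
  active_tfs <- intersect(active_tfs, rownames(m))
  if (!length(active_tfs)) return(character(0))
  tf_expr <- colSums(m[active_tfs, , drop = FALSE] > 0) > 0
  intersect(expresses_rec, colnames(m)[tf_expr])
}

# internal: qualified sender/receiver indicator vectors for one L-R/type combo
lr_indicators <- function(m, labels, ligand, receptor, type_a, type_b,
                          eligible_receivers) {
  cells <- colnames(m)
  lig_pos <- if (ligand %in% rownames(m)) m[ligand, ] > 0 else rep(FALSE, length(cells))
  send <- (labels == type_a) & lig_pos
  recv <- (labels == type_b) & (cells %in% eligible_receivers)
  list(send = send, recv = recv)
}

#' Observed adjacent sender-receiver pair count
#'
#' `C0` = number of ordered 1-hop-adjacent pairs (i, j) where i is a type-A
#' cell expressing the ligand and j is a type-B eligible receiver. Self-pairs
#' are impossible (the graph has no self-edges).
#'
#' @param graph a `cell_graph`.
#' @param expression `expression_matrix` over the same cells.
#' @param ligand,receptor gene symbols.
#' @param type_a,type_b sender and receiver types.
#' @param annotation `cell_type_annotation`.
#' @param eligible_receivers receiver cells passing [tf_activity_filter()];
#'   defaults to all receptor-expressing cells.
#' @return integer count.
#' @export
count_lr_pairs <- function(graph, expression, ligand, receptor, type_a, type_b,
                           annotation, eligible_receivers = NULL) {
  m <- unclass(expression)
  cells <- colnames(m)
  check_annotated(cells, annotation)
  labels <- annotation$labels[cells]
  if (is.null(eligible_receivers)) {
    eligible_receivers <- if (receptor %in% rownames(m)) cells[m[receptor, ] > 0] else
      character(0)
  }
  ind <- lr_indicators(m, labels, ligand, receptor, type_a, type_b, eligible_receivers)
  adj <- graph$adj[cells, cells]
  as.numeric(t(ind$send * 1) %*% (adj %*% (ind$recv * 1)))
}

#' Permutation p-value for one L-R / type-pair combination
#'
#' Cell-type labels are randomly permuted over cells `Z` times, the adjacent
#' pair count recomputed each time, and
#' `p = card(x in C : x >= C0) / Z`. Ties count toward p (so a count equal
#' to every permuted count gives p = 1), and `p = 0` is possible when `C0`
#' exceeds all permutations; `plus_one = TRUE` applies the
#' `(card + 1) / (Z + 1)` correction instead.
#'
#' @inheritParams count_lr_pairs
#' @param Z number of permutations (>= 1).
#' @param seed integer seed.
#' @param plus_one apply the add-one correction (default off, as printed).
#' @return a `permutation_null` list: `observed`, `background` (length Z),
#'   `p_value`.
#' @export
permutation_pvalue <- function(graph, expression, ligand, receptor, type_a, type_b,
                               annotation, eligible_receivers = NULL, Z = 1000L,
                               seed = 0L, plus_one = FALSE) {
  if (Z < 1L) stop("Z must be >= 1")
  m <- unclass(expression)
  cells <- colnames(m)
  labels <- annotation$labels[cells]
  if (is.null(eligible_receivers)) {
    eligible_receivers <- if (receptor %in% rownames(m)) cells[m[receptor, ] > 0] else
      character(0)
  }
  adj <- graph$adj[cells, cells]
  lig_pos <- if (ligand %in% rownames(m)) m[ligand, ] > 0 else rep(FALSE, length(cells))
  rec_ok <- cells %in% eligible_receivers
  count_for <- function(lab) {
    s <- (lab == type_a) & lig_pos
    r <- (lab == type_b) & rec_ok
    as.numeric(t(s * 1) %*% (adj %*% (r * 1)))
  }
  observed <- count_for(labels)
  background <- withr::with_seed(seed, {
    vapply(seq_len(Z), function(z) count_for(sample(labels)), numeric(1))
  })
  card <- sum(background >= observed)
  p <- if (plus_one) (card + 1) / (Z + 1) else card / Z
  structure(list(observed = observed, background = background, p_value = p),
            class = "permutation_null")
}

#' Single-cell CCC score table
#'
#' For every (sender type, receiver type, L-R pair) combination whose
#' permutation p-value is below `alpha`, emits one row per adjacent eligible
#' (sender, receiver) cell pair with score `S = sqrt(L_i * R_j)` (expression
#' of the ligand in the sender times the receptor in the receiver).
#'
#' @param graph a `cell_graph`.
#' @param expression `expression_matrix` over the cells.
#' @param lr_db an `lr_database`.
#' @param annotation `cell_type_annotation`.
#' @param network optional `receptor_tf_network` for the TF filter.
#' @param alpha significance level (default 0.05).
#' @param Z permutations per combination.
#' @param seed integer seed.
#' @param bh apply Benjamini-Hochberg correction across combinations before
#'   thresholding (default off).
#' @param type_pairs optional 2-column matrix restricting (sender type,
#'   receiver type) combinations; default all ordered pairs.
#' @return a `ccc_score_table` data.frame with columns sender, receiver,
#'   sender_type, receiver_type, ligand, receptor, score, pvalue; attribute
#'   `combinations` holds the per-combination test table.
#' @export
ccc_scores <- function(graph, expression, lr_db, annotation, network = NULL,
                       alpha = 0.05, Z = 1000L, seed = 0L, bh = FALSE,
                       type_pairs = NULL) {
  if (!nrow(lr_db)) stop("empty L-R database")
  m <- unclass(expression)
  cells <- colnames(m)
  check_annotated(cells, annotation)
  labels <- annotation$labels[cells]
  types <- annotation$type_order[annotation$type_order %in% labels]
  if (is.null(type_pairs)) {
    type_pairs <- as.matrix(expand.grid(sender = types, receiver = types,
                                        stringsAsFactors = FALSE))
  }
  combos <- list(); tests <- list()
  ctr <- 0L
  for (r in seq_len(nrow(lr_db))) {
    lig <- lr_db$ligand[r]; rec <- lr_db$receptor[r]
    eligible <- tf_activity_filter(expression, network, rec)
    for (tp in seq_len(nrow(type_pairs))) {
      ta <- unname(type_pairs[tp, 1L]); tb <- unname(type_pairs[tp, 2L])
      ctr <- ctr + 1L
      pn <- permutation_pvalue(graph, expression, lig, rec, ta, tb, annotation,
                               eligible, Z = Z, seed = seed + ctr)
      tests[[ctr]] <- data.frame(ligand = lig, receptor = rec, sender_type = ta,
                                 receiver_type = tb, observed = pn$observed,
                                 pvalue = pn$p_value, stringsAsFactors = FALSE)
      combos[[ctr]] <- list(lig = lig, rec = rec, ta = ta, tb = tb,
                            eligible = eligible)
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- if (bh) stats::p.adjust(tests$pvalue, "BH") else tests$pvalue
  rows <- list()
  adjm <- as.matrix(graph$adj[cells, cells]) > 0
  for (i in which(tests$p_adj < alpha)) {
    cb <- combos[[i]]
    ind <- lr_indicators(m, labels, cb$lig, cb$rec, cb$ta, cb$tb, cb$eligible)
    senders <- cells[ind$send]; receivers <- cells[ind$recv]
    if (!length(senders) || !length(receivers)) next
    sub <- adjm[senders, receivers, drop = FALSE]
    hits <- which(sub, arr.ind = TRUE)
    if (!nrow(hits)) next
    si <- senders[hits[, 1L]]; rj <- receivers[hits[, 2L]]
    rows[[length(rows) + 1L]] <- data.frame(
      sender = unname(si), receiver = unname(rj),
      sender_type = cb$ta, receiver_type = cb$tb,
      ligand = cb$lig, receptor = cb$rec,
      score = unname(sqrt(m[cb$lig, si] * m[cb$rec, rj])),
      pvalue = tests$pvalue[i], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sender = character(0), receiver = character(0),
               sender_type = character(0), receiver_type = character(0),
               ligand = character(0), receptor = character(0),
               score = numeric(0), pvalue = numeric(0))
  rownames(out) <- NULL
  structure(out, combinations = tests,
            class = c("ccc_score_table", "data.frame"))
}

#' Low-dimensional embedding of CCC events
#'
#' Builds the events x L-R-pairs score matrix, scales it, takes principal
#' components, builds a k-nearest-neighbor graph, and embeds in 2-D with a
#' deterministic manifold embedding (classical MDS on kNN-graph geodesic
#' distances). Duplicate events land on coincident points.
#'
#' @param score_table a `ccc_score_table` (or an events x pairs matrix).
#' @param n_neighbors kNN graph degree.
#' @param n_pcs principal components retained.
#' @param seed integer seed (tie-breaking only; the embedding is otherwise
#'   deterministic).
#' @return events x 2 coordinate matrix (columns `x`, `y`).
#' @export
embed_ccc_events <- function(score_table, n_neighbors = 10L, n_pcs = 10L, seed = 0L) {
  if (is.data.frame(score_table)) {
    if (nrow(score_table) < 3L) stop("need at least 3 events")
    pair <- paste(score_table$ligand, score_table$receptor, sep = "_")
    event <- paste(score_table$sender, score_table$receiver, sep = "->")
    mat <- matrix(0, length(unique(event)), length(unique(pair)),
                  dimnames = list(unique(event), unique(pair)))
    for (r in seq_len(nrow(score_table))) {
      mat[event[r], pair[r]] <- mat[event[r], pair[r]] + score_table$score[r]
    }
  } else {
    mat <- as.matrix(score_table)
  }
  if (nrow(mat) < 3L) stop("need at least 3 events")
  x <- scale(mat)
  x[!is.finite(x)] <- 0
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  kk <- min(n_neighbors, n - 1L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(d[i, ]), i)[seq_len(kk)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj * d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # zero-distance duplicates: igraph drops 0-weight edges from the adjacency
  # product, so re-add them explicitly with a tiny positive weight
  dup <- which(adj & d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup)) {
    g <- igraph::add_edges(g, t(dup), weight = rep(1e-12, nrow(dup)))
  }
  geo <- igraph::distances(g)
  geo[!is.finite(geo)] <- max(geo[is.finite(geo)], 1) * 2
  emb <- withr::with_seed(seed, stats::cmdscale(geo, k = 2L))
  colnames(emb) <- c("x", "y")
  rownames(emb) <- rownames(mat)
  emb
}
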