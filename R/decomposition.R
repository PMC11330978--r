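#' Integer cell-count allocation for one spot
#'
#' Rounds `N_cell * beta_i` half-up per type: the fractional part >= 0.5 adds
#' one to the integer part. If the rounded counts exceed `n_cell`, types with
#' the smallest fractional parts are decremented (ties broken by type order)
#' until the total fits. If everything rounds to zero the single largest
#' proportion gets one cell.
#'
#' @param beta nonnegative per-type proportions (need not sum to exactly 1).
#' @param n_cell maximum number of cells in the spot.
#' @return integer vector `omega`, same length/names as `beta`,
#'   `sum(omega) <= n_cell`.
#' @export
integer_allocation <- function(beta, n_cell) {
  if (any(beta < 0)) stop("beta must be nonnegative")
  if (n_cell < 1) stop("n_cell must be positive")
  x <- n_cell * beta
  fl <- floor(x)
  fr <- x - fl
  omega <- fl + (fr >= 0.5)
  if (sum(omega) == 0) {
    omega[which.max(beta)] <- 1
    return(stats::setNames(as.integer(omega), names(beta)))
  }
  # cap: first take back the round-ups that gained the least (smallest
  # fractional part), keeping every count within one cell of n_cell * beta
  while (sum(omega) > n_cell) {
    cand <- which(omega > fl)
    if (!length(cand)) cand <- which(omega > 0)
    pick <- cand[order(fr[cand], cand)][1L]
    omega[pick] <- omega[pick] - 1L
  }
  stats::setNames(as.integer(omega), names(beta))
}

#' Pick the best cell subset reproducing a spot's expression
#'
#' Draws `budget` random subsets honoring the per-type counts `omega` and
#' keeps the one minimizing the squared error between the spot profile and
#' the summed member profiles. When the candidate space is no larger than
#' `budget` the search is exhaustive, so an exact additive decomposition is
#' always found if one exists.
#'
#' @param spot_expr named numeric vector: the spot's expression over genes.
#' @param candidates_by_type list: type -> character vector of candidate cell
#'   ids.
#' @param omega named integer vector of per-type counts (see
#'   [integer_allocation()]).
#' @param profiles genes x cells matrix of candidate expression profiles
#'   (gene names must cover `names(spot_expr)`).
#' @param budget number of random subsets to score.
#' @param seed integer seed.
#' @return list with `cells` (selected ids) and `objective` (squared error).
#' @export
choose_cell_subset <- function(spot_expr, candidates_by_type, omega, profiles,
                               budget = 1000L, seed = 0L) {
  omega <- omega[omega > 0]
  if (!length(omega)) stop("omega has no positive entries")
  pools <- candidates_by_type[names(omega)]
  sizes <- vapply(pools, length, 1L)
  if (any(sizes == 0L) || any(sizes < omega)) {
    bad <- names(omega)[sizes < omega]
    stop("candidate pool smaller than omega for type(s): ",
         paste(bad, collapse = ", "))
  }
  genes <- names(spot_expr)
  prof <- profiles[genes, , drop = FALSE]
  score <- function(cells) sum((spot_expr - rowSums(prof[, cells, drop = FALSE]))^2)

  n_comb <- prod(mapply(function(s, k) choose(s, k), sizes, omega))
  withr::with_seed(seed, {
    if (is.finite(n_comb) && n_comb <= budget) {
      per_type <- mapply(function(pool, k) {
        combs <- utils::combn(pool, k, simplify = FALSE)
      }, pools, omega, SIMPLIFY = FALSE)
      grid <- expand.grid(lapply(per_type, seq_along))
      best <- NULL; best_obj <- Inf
      for (r in seq_len(nrow(grid))) {
        cells <- unlist(mapply(function(combs, i) combs[[i]], per_type, grid[r, ],
                               SIMPLIFY = FALSE), use.names = FALSE)
        obj <- score(cells)
        if (obj < best_obj) { best_obj <- obj; best <- cells }
      }
    } else {
      best <- NULL; best_obj <- Inf
      for (b in seq_len(budget)) {
        cells <- unlist(mapply(function(pool, k) sample(pool, k), pools, omega,
                               SIMPLIFY = FALSE), use.names = FALSE)
        obj <- score(cells)
        if (obj < best_obj) { best_obj <- obj; best <- cells }
      }
    }
  })
  list(cells = best, objective = best_obj)
}

#' Per-spot geometry for cell placement
#'
#' For each spot: the distance to its nearest neighbor (`d_min`) and the
#' nearest neighbor spot in each of the four quadrants around it (quadrant q
#' covers angles in (90q-90, 90q] degrees).
#'
#' @param coords data.frame with columns `unit`, `x`, `y` for all spots.
#' @param default_d_min fallback `d_min` when a spot has no neighbor
#'   (single-spot datasets).
#' @return named list per spot: `center`, `d_min`, `quadrant_neighbor`
#'   (length-4 character, NA when a quadrant is empty).
#' @export
spot_geometry <- function(coords, default_d_min = 100) {
  n <- nrow(coords)
  xy <- as.matrix(coords[, c("x", "y")])
  out <- vector("list", n)
  names(out) <- coords$unit
  for (i in seq_len(n)) {
    dx <- xy[, 1L] - xy[i, 1L]
    dy <- xy[, 2L] - xy[i, 2L]
    d <- sqrt(dx^2 + dy^2)
    d[i] <- Inf
    d_min <- if (all(is.infinite(d))) default_d_min else min(d)
    ang <- (atan2(dy, dx) * 180 / pi) %% 360
    ang[ang == 0] <- 360
    quad <- ceiling(ang / 90)
    qn <- rep(NA_character_, 4L)
    for (q in 1:4) {
      in_q <- which(quad == q & is.finite(d))
      if (length(in_q)) qn[q] <- coords$unit[in_q[which.min(d[in_q])]]
    }
    out[[i]] <- list(center = xy[i, ], d_min = d_min, quadrant_neighbor = qn)
  }
  out
}

#' Place one cell inside a spot
#'
#' A quadrant is drawn with probability `(R_q + 1) / sum(R_i + 1)` over the
#' nonempty quadrants, the angle `theta` uniformly within that quadrant's
#' 90-degree arc, and the radial weight `alpha` from one of the two
#' half-intervals (0, 0.5] / (0.5, 1] with probabilities proportional to
#' `R_center + 1` and `R_neighbor + 1`, then uniformly within the chosen
#' half. The placement radius `alpha * d_min / 2` never exceeds `d_min / 2`.
#' Uses the current RNG state; seed at the caller.
#'
#' @param geometry one spot's entry from [spot_geometry()].
#' @param r_center ratio of the placed cell's type in the parent spot.
#' @param r_neighbors length-4 numeric: the type's ratio in each quadrant's
#'   nearest neighbor spot (NA or 0 for empty quadrants).
#' @return list with `x`, `y`, `theta` (degrees in (0, 360]), `alpha`,
#'   `quadrant`.
#' @export
place_cell <- function(geometry, r_center, r_neighbors = rep(0, 4)) {
  if (geometry$d_min <= 0) stop("d_min must be positive")
  r_neighbors[is.na(r_neighbors)] <- 0
  nonempty <- !is.na(geometry$quadrant_neighbor)
  wq <- (r_neighbors + 1) * ifelse(nonempty | !any(nonempty), 1, 0)
  if (all(wq == 0)) wq <- rep(1, 4)
  q <- sample.int(4L, 1L, prob = wq / sum(wq))
  theta <- stats::runif(1L, 90 * q - 90, 90 * q)
  if (theta == 90 * q - 90) theta <- 90 * q  # open lower bound
  r_nb <- r_neighbors[q]
  p_inner <- (r_center + 1) / (r_center + r_nb + 2)
  alpha <- if (stats::runif(1L) < p_inner) stats::runif(1L, 0, 0.5) else
    stats::runif(1L, 0.5, 1)
  if (alpha == 0) alpha <- 0.5  # alpha in (0, 1]
  list(x = geometry$center[["x"]] + alpha * geometry$d_min * cospi(theta / 180) / 2,
       y = geometry$center[["y"]] + alpha * geometry$d_min * sinpi(theta / 180) / 2,
       theta = theta, alpha = alpha, quadrant = q)
}

#' Reconstruct a single-cell-resolution map from spots
#'
#' For every spot: allocate integer per-type cell counts from the proportion
#' estimates, pick the cell subset best reproducing the spot profile, and
#' place each picked cell inside the spot with the quadrant/radius
#' distribution driven by the type's abundance in neighboring spots.
#'
#' @param st_spots a spot-resolution `spatial_dataset`.
#' @param proportions spots x types matrix (rows sum to 1), e.g. from
#'   [celltype_probability_map()].
#' @param sc_data single-cell `expression_matrix` supplying candidate
#'   profiles.
#' @param annotation `cell_type_annotation` over the single cells.
#' @param n_cell global max cells per spot (overridden per spot by
#'   `st_spots$cells_per_spot`).
#' @param budget subset-search budget per spot.
#' @param seed integer seed; the whole reconstruction is deterministic.
#' @return list with `dataset` (single-cell `spatial_dataset`), `annotation`,
#'   and `placements` (data.frame cell, source_cell, spot, cell_type, x, y,
#'   theta, alpha).
#' @export
reconstruct_single_cell_map <- function(st_spots, proportions, sc_data, annotation,
                                        n_cell = 20L, budget = 1000L, seed = 0L) {
  stopifnot(inherits(st_spots, "spatial_dataset"))
  if (st_spots$resolution != "spot") stop("st_spots must have spot resolution")
  check_annotated(colnames(sc_data), annotation)
  spots <- colnames(st_spots$expr)
  if (!all(spots %in% rownames(proportions))) stop("proportions missing spots")
  types <- colnames(proportions)
  labels <- annotation$labels[colnames(sc_data)]
  candidates <- split(colnames(sc_data), labels)
  geo <- spot_geometry(st_spots$coords)
  genes <- intersect(rownames(st_spots$expr), rownames(sc_data))
  prof <- unclass(sc_data)[genes, , drop = FALSE]

  rows <- list()
  withr::with_seed(seed, {
    for (s in spots) {
      beta <- stats::setNames(as.numeric(proportions[s, ]), colnames(proportions))
      if (all(beta == 0)) {
        warning("spot ", s, " has all-zero proportions; skipped")
        next
      }
      nc <- if (!is.null(st_spots$cells_per_spot)) st_spots$cells_per_spot[[s]] else n_cell
      omega <- integer_allocation(beta, nc)
      omega <- omega[names(omega) %in% names(candidates)]
      omega <- pmin(omega, vapply(candidates[names(omega)], length, 1L))
      omega <- omega[omega > 0]
      if (!length(omega)) next
      y <- unclass(st_spots$expr)[genes, s]
      sel <- choose_cell_subset(y, candidates, omega, prof, budget = budget,
                                seed = sample.int(.Machine$integer.max, 1L))
      for (cid in sel$cells) {
        ty <- labels[[cid]]
        r_center <- proportions[s, ty]
        qn <- geo[[s]]$quadrant_neighbor
        r_nb <- vapply(qn, function(q) {
          if (is.na(q)) NA_real_ else proportions[q, ty]
        }, numeric(1))
        pc <- place_cell(geo[[s]], r_center, r_nb)
        rows[[length(rows) + 1L]] <- data.frame(
          cell = sprintf("%s.%s.%d", s, cid, length(rows) + 1L),
          source_cell = cid, spot = s, cell_type = ty,
          x = pc$x, y = pc$y, theta = pc$theta, alpha = pc$alpha,
          stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(rows)) stop("no cells placed")
  placed <- do.call(rbind, rows)
  expr <- expression_matrix(prof[, placed$source_cell, drop = FALSE],
                            gene_names = genes, unit_names = placed$cell,
                            layer = expr_layer(sc_data))
  ds <- spatial_dataset(expr, data.frame(unit = placed$cell, x = placed$x,
                                         y = placed$y), "single_cell")
  ann <- cell_type_annotation(stats::setNames(placed$cell_type, placed$cell),
                              type_order = types[types %in% placed$cell_type])
  list(dataset = ds, annotation = ann, placements = placed)
}
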