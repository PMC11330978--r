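#' Per-gene Pearson correlation across spots
#'
#' @param truth,prediction numeric vectors over spots.
#' @return correlation in [-1, 1]; constant input returns 0 with a warning.
#' @export
gene_pcc <- function(truth, prediction) {
  if (stats::sd(truth) == 0 || stats::sd(prediction) == 0) {
    warning("constant input vector; PCC set to 0")
    return(0)
  }
  stats::cor(truth, prediction)
}

#' Per-gene structural similarity (single global window)
#'
#' Each vector is scaled by its own maximum into [0, 1]; then
#' `SSIM = (2 u~ u + C1^2)(2 cov + C2^2) / ((u~^2 + u^2 + C1^2)(s~^2 + s^2 + C2^2))`
#' with C1 = 0.01, C2 = 0.03 and population (n-denominator) moments.
#'
#' @param truth,prediction numeric vectors over spots.
#' @param C1,C2 stabilizing constants.
#' @return SSIM value in [-1, 1].
#' @export
gene_ssim <- function(truth, prediction, C1 = 0.01, C2 = 0.03) {
  scale01 <- function(v) if (max(v) > 0) v / max(v) else v
  x <- scale01(truth); y <- scale01(prediction)
  n <- length(x)
  ux <- mean(x); uy <- mean(y)
  vx <- mean((x - ux)^2); vy <- mean((y - uy)^2)
  cxy <- mean((x - ux) * (y - uy))
  ((2 * uy * ux + C1^2) * (2 * cxy + C2^2)) /
    ((uy^2 + ux^2 + C1^2) * (vy + vx + C2^2))
}

#' Per-gene RMSE of z-scored spatial expression
#'
#' Each vector is z-scored across spots with the population (n) denominator;
#' a zero-variance vector becomes the zero vector.
#'
#' @param truth,prediction numeric vectors over spots.
#' @return nonnegative RMSE.
#' @export
gene_rmse <- function(truth, prediction) {
  zscore <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  sqrt(mean((zscore(prediction) - zscore(truth))^2))
}

#' Per-gene Jensen-Shannon divergence of spatial distributions
#'
#' Vectors are normalized to probabilities by their sums; JSD is computed in
#' log base 2 (bounded by 1) with the convention 0 * log(0) = 0.
#'
#' @param truth,prediction nonnegative vectors over spots with positive sums.
#' @return JSD in [0, 1].
#' @export
gene_jsd <- function(truth, prediction) {
  if (sum(truth) <= 0 || sum(prediction) <= 0) stop("vectors must have positive sums")
  p <- truth / sum(truth)
  q <- prediction / sum(prediction)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  kl(q, m) / 2 + kl(p, m) / 2
}

#' Per-gene metric report
#'
#' @param truth,prediction genes x spots matrices with matching dimnames.
#' @return a data.frame with one row per gene (pcc, ssim, rmse, jsd) plus an
#'   `aggregate` attribute holding the unweighted means.
#' @export
metric_report <- function(truth, prediction) {
  genes <- intersect(rownames(truth), rownames(prediction))
  if (!length(genes)) stop("no shared genes")
  rows <- lapply(genes, function(g) {
    x <- as.numeric(truth[g, ]); y <- as.numeric(prediction[g, ])
    data.frame(gene = g,
               pcc = suppressWarnings(gene_pcc(x, y)),
               ssim = gene_ssim(x, y),
               rmse = gene_rmse(x, y),
               jsd = if (sum(x) > 0 && sum(y) > 0) gene_jsd(x, y) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "aggregate") <- colMeans(out[, c("pcc", "ssim", "rmse", "jsd")],
                                     na.rm = TRUE)
  out
}

#' Accuracy-score ranking across methods
#'
#' PCC and SSIM are ranked ascending (best method gets rank N), RMSE and JSD
#' descending (best gets N); ties receive average ranks. AS is the mean of
#' the four ranks.
#'
#' @param metric_table data.frame with columns method, pcc, ssim, rmse, jsd
#'   (one row per method, mean metric values).
#' @return the table with added rank columns and `as` (accuracy score).
#' @export
accuracy_score <- function(metric_table) {
  stopifnot(all(c("method", "pcc", "ssim", "rmse", "jsd") %in% names(metric_table)))
  out <- metric_table
  out$rank_pcc <- rank(out$pcc, ties.method = "average")
  out$rank_ssim <- rank(out$ssim, ties.method = "average")
  out$rank_rmse <- rank(-out$rmse, ties.method = "average")
  out$rank_jsd <- rank(-out$jsd, ties.method = "average")
  out$as <- (out$rank_pcc + out$rank_ssim + out$rank_rmse + out$rank_jsd) / 4
  out
}

# internal: 1-D Wasserstein-1 distance between two weighted empirical
# distributions on the line (exact, via the quantile-function integral)
wasserstein_1d <- function(x, wx, y, wy) {
  wx <- wx / sum(wx); wy <- wy / sum(wy)
  ox <- order(x); oy <- order(y)
  x <- x[ox]; wx <- wx[ox]; y <- y[oy]; wy <- wy[oy]
  cx <- cumsum(wx); cy <- cumsum(wy)
  qs <- sort(unique(c(0, cx, cy)))
  qs <- qs[qs < 1 - 1e-15]
  mids <- qs + diff(c(qs, 1)) / 2
  qx <- x[pmin(findInterval(mids, c(0, cx), left.open = TRUE), length(x))]
  qy <- y[pmin(findInterval(mids, c(0, cy), left.open = TRUE), length(y))]
  sum(abs(qx - qy) * diff(c(qs, 1)))
}

#' Spatial communication tendency of an L-R pair
#'
#' Treats ligand and receptor expression as weights over unit coordinates
#' and computes the Wasserstein-1 distance between the two weighted spatial
#' distributions (mean of the 1-D distances along x and y). The null
#' permutes coordinates over units; `d_ratio = d_real / mean(d_simulation)`.
#' Left/right one-sided permutation p-values flag short- and long-range
#' tendency.
#'
#' @param ligand_expr,receptor_expr nonnegative weights per unit.
#' @param coords units x 2 coordinate matrix (or data.frame with x, y).
#' @param n_perm number of coordinate permutations; ligand and receptor
#'   coordinates are permuted independently so a co-localized pair scores
#'   below its null.
#' @param seed integer seed.
#' @return a `spatial_tendency` list: `d_real`, `d_simulation`, `d_ratio`,
#'   `p_left` (short-range: d_real small), `p_right` (long-range).
#' @export
wasserstein_ratio <- function(ligand_expr, receptor_expr, coords, n_perm = 1000L,
                              seed = 0L) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y")])
  if (sum(ligand_expr) <= 0 || sum(receptor_expr) <= 0) {
    stop("ligand/receptor weights must have positive sums")
  }
  dist_for <- function(xy_l, xy_r) {
    (wasserstein_1d(xy_l[, 1L], ligand_expr, xy_r[, 1L], receptor_expr) +
       wasserstein_1d(xy_l[, 2L], ligand_expr, xy_r[, 2L], receptor_expr)) / 2
  }
  d_real <- dist_for(coords, coords)
  sims <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    dist_for(coords[sample(nrow(coords)), , drop = FALSE],
             coords[sample(nrow(coords)), , drop = FALSE])
  }, numeric(1)))
  structure(list(d_real = d_real, d_simulation = sims,
                 d_ratio = d_real / mean(sims),
                 p_left = mean(sims <= d_real),
                 p_right = mean(sims >= d_real)),
            class = "spatial_tendency")
}

#' Distance enrichment score
#'
#' Walks the ranked expected-interaction list: a match adds its weight
#' `(1 - pvalue) / sum of matched weights`; a miss subtracts
#' `1 / n_unmatched`. The DES is the running sum's maximum deviation from 0
#' (signed: fully matched lists reach +1, fully unmatched reach -1).
#'
#' @param expected data.frame with columns `lr` (interaction id, ranked best
#'   first) and `pvalue`.
#' @param observed character vector of interaction ids reported by the tool.
#' @return the signed DES in [-1, 1], with attribute `running` (the walk).
#' @export
des <- function(expected, observed) {
  stopifnot(all(c("lr", "pvalue") %in% names(expected)))
  matched <- expected$lr %in% observed
  n_unmatched <- sum(!matched)
  w <- (1 - expected$pvalue)
  w_match_total <- sum(w[matched])
  steps <- ifelse(matched,
                  if (w_match_total > 0) w / w_match_total else 0,
                  -1 / max(n_unmatched, 1L))
  running <- cumsum(steps)
  peak <- which.max(abs(running))
  structure(running[peak], running = running)
}
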