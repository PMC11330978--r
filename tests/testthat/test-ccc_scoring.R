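two_cells <- function(dist) {
  expr <- expression_matrix(matrix(c(1L, 2L), 1, 2,
                                   dimnames = list("g1", c("a", "b"))),
                            layer = "raw")
  spatial_dataset(expr, data.frame(unit = c("a", "b"), x = c(0, dist), y = 0),
                  "single_cell")
}

test_that("cell graph respects the distance cutoff and matches brute force", {
  expect_equal(sum(build_cell_graph(two_cells(150))$adj), 2)  # one symmetric edge
  expect_equal(sum(build_cell_graph(two_cells(250))$adj), 0)  # beyond 200 um

  withr::with_seed(60, {
    n <- 20
    coords <- data.frame(unit = sprintf("c%02d", 1:n),
                         x = runif(n, 0, 400), y = runif(n, 0, 400))
    expr <- make_raw_matrix(3, n)
    colnames(expr) <- coords$unit
    ds <- spatial_dataset(expression_matrix(unclass(expr),
                                            unit_names = coords$unit,
                                            layer = "raw"),
                          coords, "single_cell")
    g <- build_cell_graph(ds, k = 4, cutoff_um = 180)
    # brute-force oracle over all pairs
    d <- as.matrix(dist(coords[, c("x", "y")]))
    oracle <- matrix(FALSE, n, n)
    for (i in 1:n) {
      di <- d[i, ]; di[i] <- Inf
      elig <- which(di <= 180)
      if (length(elig)) {
        oracle[i, elig[order(di[elig])][seq_len(min(4, length(elig)))]] <- TRUE
      }
    }
    oracle <- oracle | t(oracle)
    expect_identical(unname(as.matrix(g$adj) > 0), oracle)
  })
  expect_error(build_cell_graph(two_cells(10)$coords[1, ]), "at least 2")
})

test_that("random walk with restart matches a power-iteration oracle", {
  net <- receptor_tf_network(data.frame(
    source = c("R", "R", "I1", "I2", "I1"),
    target = c("I1", "I2", "TF1", "TF2", "TF2"),
    weight = c(2, 1, 1, 1, 3)), tf_nodes = c("TF1", "TF2"))
  s <- rwr_scores(net, "R", restart_prob = 0.5)
  # independent oracle: iterate s <- r e + (1-r) W' s to convergence
  nodes <- names(s)
  w <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  w[cbind(net$edges$source, net$edges$target)] <- net$edges$weight
  rs <- rowSums(w); w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  e <- as.numeric(nodes == "R")
  v <- e
  for (i in 1:200) v <- 0.5 * e + 0.5 * as.numeric(t(w) %*% v)
  expect_equal(unname(s), v, tolerance = 1e-8)
  expect_error(rwr_scores(net, "missing"), "not in network")
})

test_that("TF filter keeps only receptor cells with activated TFs", {
  net <- receptor_tf_network(data.frame(source = "R1", target = "TF1", weight = 1),
                             tf_nodes = "TF1")
  m <- matrix(c(1, 1,   # cell1: R1+, TF1+
                1, 0,   # cell2: R1+, TF1-
                0, 1),  # cell3: R1-, TF1+
              nrow = 2, dimnames = list(c("R1", "TF1"), paste0("cell", 1:3)))
  expr <- expression_matrix(m, layer = "raw")
  expect_identical(tf_activity_filter(expr, net, "R1"), "cell1")
  expect_warning(out <- tf_activity_filter(expr, net, "R9"), NA)  # R9 not a gene
  expect_identical(out, character(0))
  net2 <- receptor_tf_network(data.frame(source = "RX", target = "TF1", weight = 1),
                              tf_nodes = "TF1")
  expect_warning(out2 <- tf_activity_filter(expr, net2, "R1"), "absent")
  expect_setequal(out2, c("cell1", "cell2"))
})

test_that("pair counting matches enumeration, including A = B", {
  n <- 4
  coords <- data.frame(unit = paste0("c", 1:n), x = c(0, 50, 0, 50),
                       y = c(0, 0, 50, 50))
  m <- matrix(1L, 2, n, dimnames = list(c("L", "R"), coords$unit))
  expr <- expression_matrix(m, layer = "raw")
  ds <- spatial_dataset(expr, coords, "single_cell")
  g <- build_cell_graph(ds, k = 4, cutoff_um = 200)   # complete graph
  ann <- cell_type_annotation(setNames(c("A", "A", "B", "B"), coords$unit))
  expect_equal(count_lr_pairs(g, expr, "L", "R", "A", "B", ann), 4)
  # A = B: ordered pairs among the two A cells, self-pairs excluded
  expect_equal(count_lr_pairs(g, expr, "L", "R", "A", "A", ann), 2)
  # no-edge graph counts zero
  far <- spatial_dataset(expr, transform(coords, x = x * 100, y = y * 100),
                         "single_cell")
  g0 <- build_cell_graph(far, k = 4, cutoff_um = 200)
  expect_equal(count_lr_pairs(g0, expr, "L", "R", "A", "B", ann), 0)
})

test_that("permutation p-values handle extremes and ties per the count rule", {
  n <- 6
  coords <- data.frame(unit = paste0("c", 1:n),
                       x = c(0, 10, 1000, 1010, 2000, 2010), y = 0)
  m <- matrix(0L, 2, n, dimnames = list(c("L", "R"), coords$unit))
  m["L", 1] <- 5L; m["R", 2] <- 5L
  expr <- expression_matrix(m, layer = "raw")
  ds <- spatial_dataset(expr, coords, "single_cell")
  g <- build_cell_graph(ds, k = 2, cutoff_um = 200)
  ann <- cell_type_annotation(setNames(rep(c("A", "B"), 3), coords$unit))
  # only c1 (A) expresses L and only c2 (B) expresses R, and they are adjacent:
  # every permutation that separates them scores 0 < 1
  pn <- permutation_pvalue(g, expr, "L", "R", "A", "B", ann, Z = 200, seed = 1)
  expect_equal(pn$observed, 1)
  expect_lt(pn$p_value, 1)
  expect_equal(pn$p_value, mean(pn$background >= pn$observed))

  # single-type labels: every permutation is the identity relabeling, so all
  # counts tie the observed one and p = 1 (ties count toward p)
  m2 <- matrix(1L, 2, n, dimnames = dimnames(m))
  expr2 <- expression_matrix(m2, layer = "raw")
  ann1 <- cell_type_annotation(setNames(rep("A", n), coords$unit))
  pn2 <- permutation_pvalue(g, expr2, "L", "R", "A", "A", ann1, Z = 50, seed = 1)
  expect_gt(pn2$observed, 0)
  expect_equal(pn2$p_value, 1)

  expect_error(permutation_pvalue(g, expr, "L", "R", "A", "B", ann, Z = 0),
               "Z must be")
  # plus-one correction never returns exactly zero
  pn3 <- permutation_pvalue(g, expr, "L", "R", "A", "B", ann, Z = 50, seed = 1,
                            plus_one = TRUE)
  expect_gt(pn3$p_value, 0)
})

test_that("ccc_scores emits sqrt(L*R) for significant adjacent pairs only", {
  n <- 6
  coords <- data.frame(unit = paste0("c", 1:n), x = c(0, 20, 40, 60, 80, 100),
                       y = 0)
  m <- matrix(0L, 2, n, dimnames = list(c("LIG1", "REC1"), coords$unit))
  ann <- cell_type_annotation(setNames(c("A", "B", "A", "B", "A", "B"),
                                       coords$unit))
  m["LIG1", c(1, 3, 5)] <- 4L
  m["REC1", c(2, 4, 6)] <- 9L
  expr <- expression_matrix(m, layer = "raw")
  ds <- spatial_dataset(expr, coords, "single_cell")
  g <- build_cell_graph(ds, k = 5, cutoff_um = 200)
  db <- lr_database(data.frame(ligand = "LIG1", receptor = "REC1"))
  tab <- ccc_scores(g, expr, db, ann, alpha = 1.01, Z = 20, seed = 1)
  expect_true(all(tab$score == 6))  # sqrt(4 * 9)
  adj <- as.matrix(g$adj) > 0
  for (i in seq_len(nrow(tab))) {
    expect_true(adj[tab$sender[i], tab$receiver[i]])
    expect_identical(unname(ann$labels[tab$sender[i]]), "A")
  }
  expect_error(ccc_scores(g, expr, db[0, ], ann), "empty")
})

test_that("event embedding is deterministic, collapses duplicates, separates blocks", {
  withr::with_seed(61, {
    block1 <- matrix(rnorm(30, 5), 10, 3)
    block2 <- matrix(rnorm(30, -5), 10, 3)
    mat <- rbind(cbind(block1, matrix(0, 10, 3)), cbind(matrix(0, 10, 3), block2))
    rownames(mat) <- paste0("e", 1:20)
    mat <- rbind(mat, dup = mat[1, ])  # exact duplicate of event 1
  })
  emb1 <- embed_ccc_events(mat, n_neighbors = 4, seed = 1)
  emb2 <- embed_ccc_events(mat, n_neighbors = 4, seed = 1)
  expect_identical(emb1, emb2)
  expect_lt(sqrt(sum((emb1["e1", ] - emb1["dup", ])^2)), 1e-6)

  lab <- rep(1:2, each = 10)
  d_within <- mean(dist(emb1[1:10, ])) + mean(dist(emb1[11:20, ]))
  d_between <- mean(as.matrix(dist(emb1[1:20, ]))[1:10, 11:20])
  expect_gt(d_between, d_within / 2)
  expect_error(embed_ccc_events(mat[1:2, ]), "at least 3")
})
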