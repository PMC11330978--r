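ns <- asNamespace("spatcomm")

make_params <- function(n_genes, cfg, seed = 5) {
  withr::with_seed(seed, ns$gat_init_params(n_genes, cfg))
}

test_that("point encoder adds a position embedding to the lifted expression", {
  cfg <- train_config(n_layers = 2, dim = 8, n_heads = 2, epochs = 1)
  p <- make_params(6, cfg)
  feat <- matrix(rnorm(18), 3, 6)
  pos <- matrix(rnorm(6), 3, 2)

  # zeroed encoder MLP: x0 is exactly the lifted expression
  p0 <- p
  p0$enc_W1[] <- 0; p0$enc_W2[] <- 0; p0$enc_b1[] <- 0; p0$enc_b2[] <- 0
  x0 <- encode_nodes(feat, pos, p0)
  expect_equal(x0, sweep(feat %*% p$lift_W, 2, as.numeric(p$lift_b), "+"),
               tolerance = 1e-12)

  # identical units get identical states
  feat2 <- feat[c(1, 1, 3), ]; pos2 <- pos[c(1, 1, 3), ]
  x <- encode_nodes(feat2, pos2, p)
  expect_equal(x[1, ], x[2, ])

  # scaling positions changes states only through the position term
  x_a <- encode_nodes(feat, pos, p)
  x_b <- encode_nodes(feat, 2 * pos, p)
  enc <- function(q) {
    h <- pmax(sweep(q %*% p$enc_W1, 2, as.numeric(p$enc_b1), "+"), 0)
    sweep(h %*% p$enc_W2, 2, as.numeric(p$enc_b2), "+")
  }
  expect_equal(x_b - x_a, enc(2 * pos) - enc(pos), tolerance = 1e-10)

  expect_error(encode_nodes(feat, pos[1:2, ], p), "mismatch")
})

test_that("attention messages match a brute-force softmax oracle", {
  cfg <- train_config(n_layers = 2, dim = 8, n_heads = 2, epochs = 1)
  p <- make_params(6, cfg)
  withr::with_seed(21, {
    xq <- matrix(rnorm(32), 4, 8)
    xs <- matrix(rnorm(32), 4, 8)
  })
  res <- attention_message(xq, xs, p, l = 1, n_heads = 2)

  # independent re-evaluation, one query/head at a time
  q <- sweep(xq %*% p$W1_1, 2, as.numeric(p$b1_1), "+")
  k <- sweep(xs %*% p$W2_1, 2, as.numeric(p$b2_1), "+")
  v <- sweep(xs %*% p$W3_1, 2, as.numeric(p$b3_1), "+")
  msg <- matrix(0, 4, 8)
  for (h in 1:2) {
    idx <- ((h - 1) * 4 + 1):(h * 4)
    for (i in 1:4) {
      logits <- as.numeric(q[i, idx] %*% t(k[, idx])) / sqrt(4)
      a <- exp(logits) / sum(exp(logits))
      expect_equal(sum(res$attention[[h]][i, ]), 1, tolerance = 1e-9)
      expect_equal(res$attention[[h]][i, ], a, tolerance = 1e-6)
      msg[i, idx] <- colSums(a * v[, idx])
    }
  }
  expect_equal(res$message, msg, tolerance = 1e-6)

  # single source: attention 1, message = value
  res1 <- attention_message(xq, xs[1, , drop = FALSE], p, l = 1, n_heads = 2)
  expect_true(all(abs(unlist(res1$attention) - 1) < 1e-12))
  expect_equal(res1$message[1, ], v[1, ], tolerance = 1e-6)

  # identical sources: uniform attention 1/J
  xs_same <- xs[rep(1, 5), ]
  res2 <- attention_message(xq, xs_same, p, l = 1, n_heads = 2)
  expect_true(all(abs(unlist(res2$attention) - 0.2) < 1e-9))

  expect_error(attention_message(xq, xs[0, , drop = FALSE], p), "empty source")
})

test_that("gnn_forward reduces to a linear map with zeroed MLPs", {
  cfg <- train_config(n_layers = 4, dim = 8, n_heads = 2, epochs = 1)
  p <- make_params(5, cfg)
  for (l in 1:4) {
    p[[paste0("mlpW2_", l)]][] <- 0
    p[[paste0("mlpb2_", l)]][] <- 0
  }
  withr::with_seed(22, {
    scf <- matrix(rnorm(15), 3, 5); stf <- matrix(rnorm(20), 4, 5)
    stp <- matrix(rnorm(8), 4, 2)
  })
  scp <- matrix(0, 3, 2)
  out <- gnn_forward(scf, stf, scp, stp, p, cfg)
  x0 <- encode_nodes(scf, scp, p)
  expect_equal(out$f_sc, sweep(x0 %*% p$out_W, 2, as.numeric(p$out_b), "+"),
               tolerance = 1e-10)
})

test_that("gnn_forward is permutation-equivariant in spot order", {
  cfg <- train_config(n_layers = 2, dim = 8, n_heads = 2, epochs = 1)
  p <- make_params(5, cfg)
  withr::with_seed(23, {
    scf <- matrix(rnorm(15), 3, 5); stf <- matrix(rnorm(30), 6, 5)
    stp <- matrix(rnorm(12), 6, 2)
  })
  scp <- matrix(0, 3, 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  out1 <- gnn_forward(scf, stf, scp, stp, p, cfg)
  out2 <- gnn_forward(scf, stf[perm, ], scp, stp[perm, ], p, cfg)
  expect_equal(out2$f_st, out1$f_st[perm, ], tolerance = 1e-8)
  expect_equal(out2$f_sc, out1$f_sc, tolerance = 1e-8)
})

test_that("similarity_and_loss reproduces the cosine-agreement objective", {
  withr::with_seed(24, {
    fa <- matrix(rnorm(12), 3, 4); fb <- matrix(rnorm(8), 2, 4)
    A <- matrix(abs(rnorm(15)) + 0.1, 3, 5,
                dimnames = list(paste0("c", 1:3), paste0("g", 1:5)))
    B <- matrix(abs(rnorm(10)) + 0.1, 2, 5,
                dimnames = list(paste0("s", 1:2), paste0("g", 1:5)))
  })
  res <- similarity_and_loss(fa, fb, A, B)
  expect_equal(unclass(res$M), fa %*% t(fb), ignore_attr = TRUE)

  # independent oracle: column softmax, reconstruction, cosine sums
  M <- fa %*% t(fb)
  w <- apply(M, 2, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
  P <- t(w) %*% A
  cossum <- function(X, Y) sum(vapply(seq_len(nrow(X)), function(i) {
    sum(X[i, ] * Y[i, ]) / sqrt(sum(X[i, ]^2) * sum(Y[i, ]^2))
  }, numeric(1)))
  oracle <- -(cossum(t(P), t(B)) + cossum(P, B))
  expect_equal(res$loss, oracle, tolerance = 1e-6)

  # orthogonal descriptors give the zero similarity matrix
  res0 <- similarity_and_loss(matrix(c(1, 0, 0, 0), 1), matrix(c(0, 0, 0, 1), 1),
                              A[1, , drop = FALSE], B[1, , drop = FALSE])
  expect_equal(unclass(res0$M)[1, 1], 0)

  # near-one-hot mapping onto exact expression copies: loss -> -(genes + spots)
  A2 <- B[, , drop = FALSE]
  rownames(A2) <- paste0("c", 1:2)
  f_big <- diag(2) * 50
  res1 <- similarity_and_loss(f_big, f_big, A2, B)
  expect_equal(res1$loss, -(ncol(B) + nrow(B)), tolerance = 1e-6)
})

test_that("fit_mapping is reproducible and its loss settles", {
  m <- make_raw_matrix(10, 12, seed = 30)
  sc <- normalize_counts(m)
  coords <- data.frame(unit = colnames(m), x = runif(12) * 500, y = runif(12) * 500)
  st <- spatial_dataset(sc, coords, "single_cell")
  cfg <- train_config(n_layers = 2, dim = 8, n_heads = 2, epochs = 15, seed = 3)
  M1 <- fit_mapping(sc, st, rownames(sc), cfg)
  M2 <- fit_mapping(sc, st, rownames(sc), cfg)
  expect_identical(attr(M1, "loss_trajectory"), attr(M2, "loss_trajectory"))
  expect_identical(unclass(M1), unclass(M2))
  lt <- attr(M1, "loss_trajectory")
  expect_lt(tail(lt, 1), lt[1] + 1e-8)
  expect_error(fit_mapping(sc, st, "g01", cfg), "at least 2")
})

test_that("celltype_probability_map aggregates softmax mass by type", {
  M <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("s", 1:3)))
  class(M) <- c("mapping_matrix", "matrix", "array")
  ann1 <- cell_type_annotation(setNames(rep("T1", 4), paste0("c", 1:4)))
  p1 <- celltype_probability_map(M, ann1)
  expect_true(all(abs(p1 - 1) < 1e-12))

  # uniform M: spot proportions equal global type frequencies
  Mu <- matrix(0, 4, 3, dimnames = dimnames(M))
  class(Mu) <- class(M)
  ann2 <- cell_type_annotation(setNames(c("A", "A", "A", "B"), paste0("c", 1:4)))
  p2 <- celltype_probability_map(Mu, ann2)
  expect_equal(unname(p2[, "A"]), rep(0.75, 3), tolerance = 1e-12)
  expect_identical(unname(attr(p2, "assigned_type")), rep("A", 3))

  expect_error(celltype_probability_map(M, cell_type_annotation(
    setNames("A", "c1"))), "without annotation")
})
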