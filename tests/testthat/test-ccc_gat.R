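ns <- asNamespace("spatcomm")

path3 <- igraph::make_graph(~ a - b, b - c)

test_that("subgraph sampling honors anchors and minimum size", {
  sg <- sample_subgraphs(path3, "a", walk_length = 2, n_walks = 3, seed = 1)
  expect_identical(sg$nodes[1], "a")
  expect_true(all(sg$nodes %in% c("a", "b", "c")))
  expect_gte(length(sg$nodes), 2)
  expect_identical(dim(sg$adj), c(length(sg$nodes), length(sg$nodes)))

  g_iso <- igraph::add_vertices(path3, 1, name = "z")
  expect_error(sample_subgraphs(g_iso, "z"), "isolated")

  # hub anchor with many walks covers the whole star
  star <- igraph::make_star(7, "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:7)
  sg2 <- sample_subgraphs(star, "s1", walk_length = 2, n_walks = 50, seed = 2)
  expect_setequal(sg2$nodes, paste0("s", 1:7))
})

test_that("initial embeddings are the learned linear map of stacked features", {
  withr::with_seed(51, {
    attrs <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
    struct <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
    W_e <- matrix(rnorm(36), 6, 6)
  })
  sg <- sample_subgraphs(path3, "a", walk_length = 2, n_walks = 5, seed = 3)
  h <- init_embeddings(sg, attrs, struct, W_e)
  expect_equal(unname(h),
               cbind(attrs[sg$nodes, ], struct[sg$nodes, ]) %*% W_e,
               ignore_attr = TRUE)

  # attribute-only W_e (zero structural block) reproduces the attributes
  W_id <- rbind(diag(4), matrix(0, 2, 4))
  h2 <- init_embeddings(sg, attrs, struct, W_id)
  expect_equal(unname(h2), unname(attrs[sg$nodes, ]))

  expect_error(init_embeddings(sg, attrs[1:2, , drop = FALSE], struct, W_e),
               "missing attribute")
})

test_that("context translation matches a step-by-step oracle", {
  cfg <- subgat_config(d = 4, n_heads = 2, n_layers = 1, f_nn = "identity")
  withr::with_seed(52, {
    H <- matrix(rnorm(16), 4, 4)
    params <- ns$subgat_init_params(2, 2, 4, cfg)
  })
  out <- context_translate(H, params, k = 1, config = cfg)

  # per-head rows sum to one
  for (a in out$abar_heads) expect_true(all(abs(rowSums(a) - 1) < 1e-9))

  # independent evaluation
  q <- H %*% t(params$Wa1_1)
  kk <- H %*% t(params$Wa2_1)
  abars <- lapply(1:2, function(h) {
    idx <- ((h - 1) * 2 + 1):(h * 2)
    z <- q[, idx] %*% t(kk[, idx])
    t(apply(z, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  })
  abar <- (abars[[1]] + abars[[2]]) / 2
  expect_equal(out$abar, abar, tolerance = 1e-6)
  oracle <- t(abar) %*% H %*% t(params$Ws_1) + H
  expect_equal(out$H, oracle, tolerance = 1e-6)

  # W_s = 0 with identity f_NN is the residual identity across layers
  p0 <- params; p0$Ws_1[] <- 0
  h_cur <- H
  for (i in 1:3) h_cur <- context_translate(h_cur, p0, k = 1, config = cfg)$H
  expect_equal(h_cur, H, tolerance = 1e-12)

  expect_error(context_translate(H[1, , drop = FALSE], params, 1, cfg),
               "at least 2")
})

test_that("contextual embedding concatenates layers in ascending order", {
  h1 <- matrix(1, 3, 2); h2 <- matrix(2, 3, 2); h3 <- matrix(3, 3, 2)
  ht <- contextual_embedding(list(h1, h2, h3))
  expect_identical(dim(ht), c(3L, 6L))
  expect_identical(ht[, 1:2], h1)
  expect_identical(ht[, 3:4], h2)
  expect_identical(ht[, 5:6], h3)
  expect_identical(contextual_embedding(list(h1)), h1)
})

test_that("masked pretraining starts at the uniform loss and is reproducible", {
  world <- make_community_graph(n_per = 6, p_in = 0.9, p_out = 0.1, seed = 4,
                                attr_dim = 4)
  g <- world$graph
  cfg <- subgat_config(d = 8, n_heads = 2, n_layers = 2, walk_length = 4,
                       n_walks = 2, epochs = 2, lr = 0, seed = 6)
  # lr = 0 freezes training: every step shows the zero-head uniform softmax
  m <- pretrain_masked(g, world$attrs, cfg)
  expect_equal(m$loss_trajectory[1], log(length(m$vocab)), tolerance = 1e-10)

  cfg2 <- subgat_config(d = 8, n_heads = 2, n_layers = 2, walk_length = 4,
                        n_walks = 2, epochs = 3, lr = 5e-3, seed = 6)
  m1 <- pretrain_masked(g, world$attrs, cfg2)
  m2 <- pretrain_masked(g, world$attrs, cfg2)
  expect_identical(m1$loss_trajectory, m2$loss_trajectory)
  expect_lt(tail(m1$loss_trajectory, 1), m1$loss_trajectory[1])
})

test_that("masked-node class prediction beats the untrained model", {
  world <- make_community_graph(n_per = 8, p_in = 0.8, p_out = 0.05, seed = 7,
                                attr_dim = 6, attr_shift = 2)
  g <- world$graph
  cfg <- subgat_config(d = 8, n_heads = 2, n_layers = 2, walk_length = 4,
                       n_walks = 3, epochs = 25, lr = 5e-3, seed = 8)
  model <- pretrain_masked(g, world$attrs, cfg)

  class_of <- setNames(world$membership, rownames(world$adj))
  predict_class <- function(params) {
    withr::with_seed(99, {
      preds <- vapply(model$vocab, function(v) {
        sg <- sample_subgraphs(g, v, cfg$walk_length, cfg$n_walks, cfg$max_dist)
        feat <- ns$subgat_features(sg$nodes, world$attrs,
                                   model$structural_vectors,
                                   mask_node = v, mask_token = params$mask_token)
        h2 <- feat %*% params$W_e
        layers <- list()
        for (k in 1:cfg$n_layers) {
          h2 <- context_translate(h2, params, k, cfg)$H
          layers[[k]] <- h2
        }
        ht <- contextual_embedding(layers)
        logits <- ht[1, , drop = FALSE] %*% params$head_W + params$head_b
        model$vocab[which.max(logits)]
      }, character(1))
    })
    mean(class_of[preds] == class_of[model$vocab])
  }
  acc_trained <- predict_class(model$params)
  expect_gt(acc_trained, 0.9)
})

test_that("link scorer is symmetric and neutral at zero embeddings", {
  world <- make_community_graph(n_per = 6, p_in = 0.9, p_out = 0.1, seed = 9,
                                attr_dim = 4)
  cfg <- subgat_config(d = 8, n_heads = 2, n_layers = 2, walk_length = 4,
                       n_walks = 2, epochs = 2, lr = 1e-3, seed = 10)
  scorer <- finetune_links(world$graph, world$attrs, config = cfg)
  nodes <- igraph::V(world$graph)$name
  s_ij <- score_links(scorer, rbind(c(nodes[1], nodes[2])), seed = 3)
  # symmetry of the score function itself: inner product is commutative, and
  # the pair subgraph is anchored at both endpoints
  sg <- sample_subgraphs(world$graph, c(nodes[1], nodes[2]), 4, 2, 3, seed = 3)
  ctx <- ns$subgat_context_embed(sg, scorer$attrs, scorer$structural_vectors,
                                 scorer$params, cfg)
  expect_equal(sum(ctx[1, ] * ctx[2, ]), sum(ctx[2, ] * ctx[1, ]))

  # zeroed embedding matrix gives S = 0.5 exactly
  p0 <- scorer$params; p0$W_e[] <- 0
  ctx0 <- ns$subgat_context_embed(sg, scorer$attrs, scorer$structural_vectors,
                                  p0, cfg)
  expect_equal(1 / (1 + exp(-sum(ctx0[1, ] * ctx0[2, ]))), 0.5)

  expect_error(finetune_links(world$graph, world$attrs,
                              positive_edges = matrix(character(0), 0, 2),
                              config = cfg), "no positive")
})
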