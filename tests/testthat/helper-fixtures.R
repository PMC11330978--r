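# shared fixtures and small independent statistics used as test oracles

make_raw_matrix <- function(n_genes = 10, n_units = 6, seed = 1, mu = 5) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n_units, mu = mu, size = 2), n_genes, n_units,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("u%02d", seq_len(n_units))))
    m[rowSums(m) == 0, 1] <- 1  # avoid all-zero genes
    expression_matrix(m, layer = "raw")
  })
}

# area under the ROC curve via the rank-sum identity
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# planted two-community graph with community-informative attributes
make_community_graph <- function(n_per = 30, p_in = 0.8, p_out = 0.02, seed = 1,
                                 attr_dim = 8, attr_shift = 1.5) {
  withr::with_seed(seed, {
    n <- 2L * n_per
    memb <- rep(1:2, each = n_per)
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      p <- if (memb[i] == memb[j]) p_in else p_out
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
    }
    rownames(adj) <- colnames(adj) <- sprintf("v%03d", seq_len(n))
    attrs <- matrix(rnorm(n * attr_dim), n, attr_dim) +
      outer(ifelse(memb == 1, attr_shift, -attr_shift), rep(1, attr_dim))
    rownames(attrs) <- rownames(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
    list(graph = g, adj = adj, membership = memb, attrs = attrs)
  })
}

# graph with training edges removed; held-out positives and sampled negatives
split_edges <- function(world, holdout_frac = 0.2, seed = 2) {
  withr::with_seed(seed, {
    el <- igraph::as_edgelist(world$graph)
    hold <- sample(nrow(el), round(holdout_frac * nrow(el)))
    test_pos <- el[hold, , drop = FALSE]
    g_train <- igraph::graph_from_edgelist(el[-hold, , drop = FALSE],
                                           directed = FALSE)
    miss <- setdiff(rownames(world$adj), igraph::V(g_train)$name)
    if (length(miss)) g_train <- igraph::add_vertices(g_train, length(miss), name = miss)
    negs <- matrix(character(0), 0L, 2L)
    nodes <- rownames(world$adj)
    while (nrow(negs) < nrow(test_pos)) {
      i <- sample(nodes, 1L); j <- sample(nodes, 1L)
      if (i != j && world$adj[i, j] == 0) negs <- rbind(negs, c(i, j))
    }
    list(train_graph = g_train, test_pos = test_pos, test_neg = negs)
  })
}
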