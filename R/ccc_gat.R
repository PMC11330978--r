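#' Configuration for the subgraph attention network
#'
#' @param d embedding width (divisible by `n_heads`).
#' @param n_heads attention heads in each translation layer.
#' @param n_layers number of translation layers `K`; the contextual embedding
#'   concatenates all `K` per-layer embeddings (width `K * d`).
#' @param walk_length,n_walks random-walk subgraph sampling parameters.
#' @param max_dist nodes farther than this many hops from the anchor are
#'   dropped from a context subgraph (keeps subgraphs local).
#' @param struct_dim width of the structural (spectral) node vectors.
#' @param f_nn nonlinearity applied after the residual sum: `"leaky_relu"`
#'   (default, slope 0.2), `"relu"`, or `"identity"`.
#' @param epochs,lr,seed training controls.
#' @param negative_ratio sampled negative edges per positive during
#'   fine-tuning.
#' @return a `subgat_config` list.
#' @export
subgat_config <- function(d = 64L, n_heads = 4L, n_layers = 2L, walk_length = 8L,
                          n_walks = 5L, max_dist = 3L, struct_dim = 8L,
                          f_nn = c("leaky_relu", "relu", "identity"),
                          epochs = 20L, lr = 1e-3, seed = 0L, negative_ratio = 1) {
  f_nn <- match.arg(f_nn)
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  structure(list(d = as.integer(d), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), walk_length = as.integer(walk_length),
                 n_walks = as.integer(n_walks), max_dist = as.integer(max_dist),
                 struct_dim = as.integer(struct_dim), f_nn = f_nn,
                 epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                 negative_ratio = negative_ratio),
            class = "subgat_config")
}

#' Sample a context subgraph around an anchor
#'
#' Takes the union of `n_walks` random walks of `walk_length` steps from the
#' anchor (both anchors for a pair), keeps nodes within `max_dist` hops of an
#' anchor, and returns the induced adjacency. Uses the current RNG state when
#' `seed` is NULL.
#'
#' @param graph an igraph graph with named vertices.
#' @param anchor one or two vertex names (pair anchors for link prediction).
#' @param walk_length,n_walks,max_dist see [subgat_config()].
#' @param seed optional integer seed.
#' @return a `context_subgraph` list: `nodes` (anchors first), `adj`
#'   (binary adjacency among members), `anchor`.
#' @export
sample_subgraphs <- function(graph, anchor, walk_length = 8L, n_walks = 5L,
                             max_dist = 3L, seed = NULL) {
  if (!all(anchor %in% igraph::V(graph)$name)) stop("anchor not in graph")
  if (any(igraph::degree(graph, anchor) == 0)) stop("isolated anchor: ", anchor[1L])
  run <- function() {
    nodes <- anchor
    for (a in anchor) {
      for (w in seq_len(n_walks)) {
        walk <- igraph::random_walk(graph, start = a, steps = walk_length + 1L)
        nodes <- union(nodes, igraph::V(graph)$name[walk])
      }
    }
    d <- igraph::distances(graph, v = anchor, to = nodes)
    nodes <- nodes[apply(d, 2L, min) <= max_dist]
    nodes <- c(anchor, setdiff(nodes, anchor))
    if (length(nodes) < 2L) stop("context subgraph must contain at least 2 nodes")
    sub <- igraph::induced_subgraph(graph, nodes)
    adj <- as.matrix(igraph::as_adjacency_matrix(sub))
    adj <- adj[nodes, nodes]
    structure(list(nodes = nodes, adj = adj, anchor = anchor),
              class = "context_subgraph")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Deterministic spectral structural node vectors
#'
#' Pluggable stand-in for an external structural-embedding trainer: the top
#' eigenvectors of the adjacency matrix, scaled by sqrt(|eigenvalue|), with
#' the sign fixed so the largest-magnitude entry is positive.
#'
#' @param graph an igraph graph with named vertices.
#' @param dim number of spectral dimensions.
#' @return nodes x dim matrix with node row names.
#' @export
spectral_structural_embedding <- function(graph, dim = 8L) {
  adj <- as.matrix(igraph::as_adjacency_matrix(graph))
  eig <- eigen(adj, symmetric = TRUE)
  k <- min(dim, ncol(eig$vectors))
  ord <- order(-abs(eig$values))[seq_len(k)]
  v <- eig$vectors[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
    v[, j] <- v[, j] * sqrt(abs(eig$values[ord[j]]))
  }
  if (k < dim) v <- cbind(v, matrix(0, nrow(v), dim - k))
  rownames(v) <- igraph::V(graph)$name
  v
}

# internal: initialize all trainable parameters of the subgraph network
subgat_init_params <- function(attr_dim, struct_dim, n_nodes, config) {
  d <- config$d
  p <- list(
    W_e = ad_init_matrix(attr_dim + struct_dim, d),
    mask_token = matrix(stats::rnorm(attr_dim, sd = 0.1), 1L),
    head_W = matrix(0, config$n_layers * d, n_nodes),  # zero head: uniform init loss
    head_b = matrix(0, 1L, n_nodes)
  )
  for (k in seq_len(config$n_layers)) {
    p[[paste0("Ws_", k)]] <- ad_init_matrix(d, d) * 0.1
    p[[paste0("Wa1_", k)]] <- ad_init_matrix(d, d)
    p[[paste0("Wa2_", k)]] <- ad_init_matrix(d, d)
  }
  p
}

#' Initial node embeddings of a subgraph
#'
#' `h_i = W_e [attributes(v_i) || structural_vector(v_i)]`.
#'
#' @param subgraph a `context_subgraph`.
#' @param node_attributes nodes x a matrix (row names = node names).
#' @param structural_vectors nodes x s matrix (row names = node names).
#' @param W_e learnable `(a + s) x d` embedding matrix.
#' @return |V_c| x d embedding matrix, rows ordered as `subgraph$nodes`.
#' @export
init_embeddings <- function(subgraph, node_attributes, structural_vectors, W_e) {
  miss <- setdiff(subgraph$nodes, rownames(node_attributes))
  if (length(miss)) stop("missing attribute rows: ", paste(miss, collapse = ", "))
  feat <- cbind(node_attributes[subgraph$nodes, , drop = FALSE],
                structural_vectors[subgraph$nodes, , drop = FALSE])
  out <- feat %*% W_e
  rownames(out) <- subgraph$nodes
  out
}

# internal: f_NN dispatch on a tape node
ad_f_nn <- function(tape, x, f_nn) {
  switch(f_nn,
         identity = x,
         relu = ad_relu(tape, x),
         leaky_relu = {
           pos <- ad_relu(tape, x)
           neg <- ad_relu(tape, ad_scale(tape, x, -1))
           ad_sub(tape, pos, ad_scale(tape, neg, 0.2))
         })
}

# internal: one translation layer on the tape; returns list(H_next, Abar)
ad_context_translate <- function(tape, h, params_nodes, k, config) {
  pn <- params_nodes
  n_heads <- config$n_heads
  q <- ad_matmul_nt(tape, h, pn[[paste0("Wa1_", k)]])  # H W1^T
  kk <- ad_matmul_nt(tape, h, pn[[paste0("Wa2_", k)]])
  # per-head attention over head-sliced projections
  d <- config$d
  dh <- d %/% n_heads
  abars <- lapply(seq_len(n_heads), function(hh) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    qh <- ad_slice_cols(tape, q, idx)
    kh <- ad_slice_cols(tape, kk, idx)
    ad_softmax_rows(tape, ad_matmul_nt(tape, qh, kh))
  })
  abar <- abars[[1L]]
  if (n_heads > 1L) {
    for (hh in 2L:n_heads) abar <- ad_add(tape, abar, abars[[hh]])
    abar <- ad_scale(tape, abar, 1 / n_heads)
  }
  msg <- ad_matmul_tn(tape, abar, h)                    # t(Abar) H : aggregate
  msg <- ad_matmul_nt(tape, msg, pn[[paste0("Ws_", k)]])
  out <- ad_f_nn(tape, ad_add(tape, msg, h), config$f_nn)
  list(h = out, abar = abar, abar_heads = abars)
}

#' One context-translation layer (plain values)
#'
#' Computes the multi-head semantic association matrix
#' `Abar_ij = softmax_j((W1 h_i)'(W2 h_j))` (rows sum to 1 per head, heads
#' averaged for the update) and the residual update
#' `H^{k+1} = f_NN(W_s H^k Abar^k + H^k)`.
#'
#' @param H |V_c| x d embedding matrix (rows = nodes).
#' @param params parameter list holding `Ws_k`, `Wa1_k`, `Wa2_k`.
#' @param k layer index.
#' @param config a [subgat_config()].
#' @return list with `H` (updated embeddings), `abar` (head-averaged), and
#'   `abar_heads` (list of per-head attention matrices).
#' @export
context_translate <- function(H, params, k = 1L, config = subgat_config()) {
  if (nrow(H) < 2L) stop("subgraph must contain at least 2 nodes")
  tape <- ad_tape()
  pn <- gat_param_nodes(tape, params)
  out <- ad_context_translate(tape, ad_const(tape, H), pn, k, config)
  if (any(!is.finite(out$h$value))) stop("non-finite embeddings in translation layer")
  list(H = out$h$value, abar = out$abar$value,
       abar_heads = lapply(out$abar_heads, function(a) a$value))
}

#' Contextual embedding by layer concatenation
#'
#' @param per_layer_embeddings list of K matrices (|V_c| x d), ascending
#'   layer order.
#' @return |V_c| x (K*d) matrix `h~_i = h_i^1 (+) ... (+) h_i^K`.
#' @export
contextual_embedding <- function(per_layer_embeddings) {
  do.call(cbind, per_layer_embeddings)
}

# internal: full tape forward over a subgraph; returns contextual embedding node
ad_subgat_forward <- function(tape, feat, pn, config) {
  h <- ad_matmul(tape, ad_const(tape, feat), pn$W_e)
  layers <- vector("list", config$n_layers)
  for (k in seq_len(config$n_layers)) {
    out <- ad_context_translate(tape, h, pn, k, config)
    h <- out$h
    layers[[k]] <- h
  }
  ad_concat_cols(tape, layers)
}

# internal: assemble [attributes || structural] features with optional mask
subgat_features <- function(nodes, attrs, struct, mask_node = NULL, mask_token = NULL) {
  a <- attrs[nodes, , drop = FALSE]
  if (!is.null(mask_node)) a[mask_node, ] <- as.numeric(mask_token)
  cbind(a, struct[nodes, , drop = FALSE])
}

#' Masked-node pretraining
#'
#' For each node, a context subgraph is sampled, the anchor's attribute
#' vector is replaced by a learned mask token (structure untouched), and the
#' model is trained to recover the masked node's identity with a linear
#' projection + softmax over the full node vocabulary.
#'
#' @param graph an igraph graph with named vertices.
#' @param node_attributes nodes x a attribute matrix.
#' @param config a [subgat_config()].
#' @param structural_vectors optional nodes x s matrix; defaults to
#'   [spectral_structural_embedding()].
#' @return a `subgat_model` list: `params`, `config`, `vocab`,
#'   `structural_vectors`, `loss_trajectory` (mean per-epoch NLL).
#' @export
pretrain_masked <- function(graph, node_attributes, config = subgat_config(),
                            structural_vectors = NULL) {
  vocab <- igraph::V(graph)$name
  if (length(vocab) < 2L) stop("node vocabulary must have >= 2 nodes")
  if (is.null(structural_vectors)) {
    structural_vectors <- spectral_structural_embedding(graph, config$struct_dim)
  }
  attrs <- node_attributes[vocab, , drop = FALSE]
  losses <- numeric(config$epochs)
  params <- NULL
  withr::with_seed(config$seed, {
    params <- subgat_init_params(ncol(attrs), ncol(structural_vectors),
                                 length(vocab), config)
    opt <- adam_state(params, lr = config$lr)
    for (epoch in seq_len(config$epochs)) {
      epoch_loss <- 0
      for (v in sample(vocab)) {
        sg <- tryCatch(sample_subgraphs(graph, v, config$walk_length,
                                        config$n_walks, config$max_dist),
                       error = function(e) NULL)
        if (is.null(sg)) next
        mask_pos <- 1L  # the anchor is the masked node
        tape <- ad_tape()
        pn <- gat_param_nodes(tape, params)
        feat <- subgat_features(sg$nodes, attrs, structural_vectors,
                                mask_node = v, mask_token = params$mask_token)
        # mask token participates in the gradient: rebuild its row on-tape
        feat0 <- feat
        feat0[mask_pos, seq_len(ncol(attrs))] <- 0
        sel <- matrix(0, 1L, length(sg$nodes)); sel[1L, mask_pos] <- 1
        pad <- ad_concat_cols(tape, list(pn$mask_token,
                                         ad_const(tape, matrix(0, 1L, ncol(structural_vectors)))))
        feat_node <- ad_add(tape, ad_const(tape, feat0),
                            ad_matmul_tn(tape, ad_const(tape, sel), pad))
        h <- ad_matmul(tape, feat_node, pn$W_e)
        layers <- vector("list", config$n_layers)
        for (k in seq_len(config$n_layers)) {
          h <- ad_context_translate(tape, h, pn, k, config)$h
          layers[[k]] <- h
        }
        ctx <- ad_concat_cols(tape, layers)
        masked_h <- ad_matmul(tape, ad_const(tape, sel), ctx)  # 1 x Kd
        logits <- ad_add_rowvec(tape, ad_matmul(tape, masked_h, pn$head_W), pn$head_b)
        ls <- ad_log_softmax_row(tape, logits)
        target <- match(v, vocab)
        onehot <- matrix(0, 1L, length(vocab)); onehot[1L, target] <- -1
        loss <- ad_sum(tape, ad_mul(tape, ls, ad_const(tape, onehot)))
        epoch_loss <- epoch_loss + as.numeric(loss$value)
        ad_backward(tape, loss)
        grads <- lapply(pn, function(n) n$grad)
        stp <- adam_step(opt, params, grads)
        opt <- stp$state; params <- stp$params
      }
      losses[epoch] <- epoch_loss / length(vocab)
    }
  })
  structure(list(params = params, config = config, vocab = vocab,
                 structural_vectors = structural_vectors,
                 loss_trajectory = losses),
            class = "subgat_model")
}

# internal: contextual embeddings for a set of nodes within one subgraph
subgat_context_embed <- function(sg, attrs, struct, params, config) {
  feat <- subgat_features(sg$nodes, attrs, struct)
  tape <- ad_tape()
  pn <- gat_param_nodes(tape, params)
  ctx <- ad_subgat_forward(tape, feat, pn, config)
  out <- ctx$value
  rownames(out) <- sg$nodes
  out
}

#' Fine-tune the pretrained model for contextual link prediction
#'
#' Each candidate pair is scored within its own context subgraph:
#' `S(v_i, v_j) = sigmoid(h~_i' h~_j)`. The logistic objective sums
#' `log S` over positive edges and `log(1 - S)` over sampled negatives
#' (uniform non-edges at `negative_ratio` per positive).
#'
#' @param graph an igraph graph with named vertices (training edges only).
#' @param node_attributes nodes x a attribute matrix.
#' @param positive_edges 2-column character matrix of positive pairs;
#'   defaults to the graph's edges.
#' @param model a pretrained `subgat_model` (or NULL to train from scratch).
#' @param config a [subgat_config()]; defaults to the model's.
#' @return a `link_scorer` list with `params`, `config`,
#'   `structural_vectors`, `attrs`, `graph`, `loss_trajectory`.
#' @export
finetune_links <- function(graph, node_attributes, positive_edges = NULL,
                           model = NULL, config = NULL) {
  if (is.null(config)) config <- if (!is.null(model)) model$config else subgat_config()
  vocab <- igraph::V(graph)$name
  struct <- if (!is.null(model)) model$structural_vectors else
    spectral_structural_embedding(graph, config$struct_dim)
  attrs <- node_attributes[vocab, , drop = FALSE]
  if (is.null(positive_edges)) {
    positive_edges <- igraph::as_edgelist(graph)
  }
  if (!nrow(positive_edges)) stop("no positive edges")
  losses <- numeric(config$epochs)
  params <- if (!is.null(model)) model$params else NULL
  withr::with_seed(config$seed + 1L, {
    if (is.null(params)) {
      params <- subgat_init_params(ncol(attrs), ncol(struct), length(vocab), config)
    }
    opt <- adam_state(params, lr = config$lr)
    adj <- as.matrix(igraph::as_adjacency_matrix(graph)) > 0
    for (epoch in seq_len(config$epochs)) {
      # negatives resampled each epoch, uniform over non-edges
      n_neg <- ceiling(nrow(positive_edges) * config$negative_ratio)
      negs <- matrix(character(0), 0L, 2L)
      while (nrow(negs) < n_neg) {
        i <- sample(vocab, n_neg, replace = TRUE)
        j <- sample(vocab, n_neg, replace = TRUE)
        ok <- i != j & !adj[cbind(i, j)]
        negs <- rbind(negs, cbind(i[ok], j[ok]))
      }
      negs <- negs[seq_len(n_neg), , drop = FALSE]
      pairs <- rbind(cbind(positive_edges, 1), cbind(negs, 0))
      pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
      epoch_loss <- 0
      for (r in seq_len(nrow(pairs))) {
        vi <- pairs[r, 1L]; vj <- pairs[r, 2L]; y <- as.numeric(pairs[r, 3L])
        sg <- tryCatch(sample_subgraphs(graph, c(vi, vj), config$walk_length,
                                        config$n_walks, config$max_dist),
                       error = function(e) NULL)
        if (is.null(sg)) next
        feat <- subgat_features(sg$nodes, attrs, struct)
        tape <- ad_tape()
        pn <- gat_param_nodes(tape, params)
        ctx <- ad_subgat_forward(tape, feat, pn, config)
        si <- matrix(0, 1L, length(sg$nodes)); si[1L, 1L] <- 1
        sj <- matrix(0, 1L, length(sg$nodes)); sj[1L, 2L] <- 1
        hi <- ad_matmul(tape, ad_const(tape, si), ctx)
        hj <- ad_matmul(tape, ad_const(tape, sj), ctx)
        logit <- ad_matmul_nt(tape, hi, hj)  # 1x1
        s <- ad_sigmoid(tape, logit)
        # -(y log S + (1-y) log(1-S)) via a stable custom node
        sval <- min(max(s$value, 1e-12), 1 - 1e-12)
        loss <- ad_node(tape, matrix(-(y * log(sval) + (1 - y) * log(1 - sval)), 1, 1),
                        list(s), function(g) {
                          list(matrix(as.numeric(g) * (-(y / sval) + (1 - y) / (1 - sval)), 1, 1))
                        })
        epoch_loss <- epoch_loss + as.numeric(loss$value)
        ad_backward(tape, loss)
        grads <- lapply(pn, function(n) n$grad)
        grads$head_W <- NULL; grads$head_b <- NULL  # head is pretraining-only
        stp <- adam_step(opt, params, grads)
        opt <- stp$state; params <- stp$params
      }
      losses[epoch] <- epoch_loss / nrow(pairs)
    }
  })
  structure(list(params = params, config = config, structural_vectors = struct,
                 attrs = attrs, graph = graph, loss_trajectory = losses),
            class = "link_scorer")
}

#' Score candidate links with a fine-tuned model
#'
#' @param scorer a `link_scorer`.
#' @param pairs 2-column character matrix of node pairs.
#' @param seed seed for the context-subgraph sampling.
#' @param n_samples context subgraphs averaged per pair (reduces sampling
#'   variance of the contextual embeddings).
#' @return numeric vector of probabilities `S(v_i, v_j)`; symmetric in the
#'   pair by construction (inner product of the two contextual embeddings).
#' @export
score_links <- function(scorer, pairs, seed = 0L, n_samples = 3L) {
  cfg <- scorer$config
  withr::with_seed(seed, {
    apply(pairs, 1L, function(pr) {
      scores <- vapply(seq_len(n_samples), function(s) {
        sg <- tryCatch(sample_subgraphs(scorer$graph, pr, cfg$walk_length,
                                        cfg$n_walks, cfg$max_dist),
                       error = function(e) NULL)
        if (is.null(sg)) return(0.5)
        ctx <- subgat_context_embed(sg, scorer$attrs, scorer$structural_vectors,
                                    scorer$params, cfg)
        1 / (1 + exp(-sum(ctx[1L, ] * ctx[2L, ])))
      }, numeric(1))
      mean(scores)
    })
  })
}
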