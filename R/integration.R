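#' Training configuration for the integration network
#'
#' The network alternates self- and cross-attention layers, so `n_layers`
#' must be even and at least 2. Defaults: 4 layers (self, cross, self,
#' cross), width 64, 4 heads, 500 epochs of full-graph Adam at 1e-3.
#'
#' @param n_layers even number of message-passing layers (odd layers
#'   aggregate along self-edges, even layers along cross-edges).
#' @param dim node state width `D`; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling initialization (and nothing else;
#'   training is deterministic full-batch).
#' @return a `train_config` list.
#' @export
train_config <- function(n_layers = 4L, dim = 64L, n_heads = 4L, epochs = 500L,
                         lr = 1e-3, seed = 0L) {
  if (n_layers < 2L || n_layers %% 2L != 0L) stop("n_layers must be even and >= 2")
  if (dim %% n_heads != 0L) stop("dim must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers), dim = as.integer(dim),
                 n_heads = as.integer(n_heads), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed)),
            class = "train_config")
}

# internal: parameter initialization (caller controls the RNG state)
gat_init_params <- function(n_genes, config, enc_hidden = 32L) {
  D <- config$dim
  p <- list(
    lift_W = ad_init_matrix(n_genes, D), lift_b = matrix(0, 1, D),
    enc_W1 = ad_init_matrix(2L, enc_hidden), enc_b1 = matrix(0, 1, enc_hidden),
    enc_W2 = ad_init_matrix(enc_hidden, D), enc_b2 = matrix(0, 1, D),
    out_W = ad_init_matrix(D, D), out_b = matrix(0, 1, D)
  )
  for (l in seq_len(config$n_layers)) {
    p[[paste0("W1_", l)]] <- ad_init_matrix(D, D)
    p[[paste0("W2_", l)]] <- ad_init_matrix(D, D)
    p[[paste0("W3_", l)]] <- ad_init_matrix(D, D)
    p[[paste0("b1_", l)]] <- matrix(0, 1, D)
    p[[paste0("b2_", l)]] <- matrix(0, 1, D)
    p[[paste0("b3_", l)]] <- matrix(0, 1, D)
    p[[paste0("mlpW1_", l)]] <- ad_init_matrix(2L * D, 2L * D)
    p[[paste0("mlpb1_", l)]] <- matrix(0, 1, 2L * D)
    # zero-init the MLP output so every layer starts as the identity residual
    p[[paste0("mlpW2_", l)]] <- matrix(0, 2L * D, D)
    p[[paste0("mlpb2_", l)]] <- matrix(0, 1, D)
  }
  p
}

# internal: wrap raw parameter matrices as tape leaves
gat_param_nodes <- function(tape, params) lapply(params, function(p) ad_param(tape, p))

# internal: tape forward of the position-aware point encoder
ad_encode <- function(tape, expr_node, pos_node, pn) {
  lifted <- ad_add_rowvec(tape, ad_matmul(tape, expr_node, pn$lift_W), pn$lift_b)
  h <- ad_relu(tape, ad_add_rowvec(tape, ad_matmul(tape, pos_node, pn$enc_W1), pn$enc_b1))
  penc <- ad_add_rowvec(tape, ad_matmul(tape, h, pn$enc_W2), pn$enc_b2)
  ad_add(tape, lifted, penc)
}

# internal: multi-head scaled-dot-product attention message (tape)
ad_attention <- function(tape, xq, xs, pn, l, n_heads) {
  D <- ncol(xq$value)
  dh <- D %/% n_heads
  q <- ad_add_rowvec(tape, ad_matmul(tape, xq, pn[[paste0("W1_", l)]]), pn[[paste0("b1_", l)]])
  k <- ad_add_rowvec(tape, ad_matmul(tape, xs, pn[[paste0("W2_", l)]]), pn[[paste0("b2_", l)]])
  v <- ad_add_rowvec(tape, ad_matmul(tape, xs, pn[[paste0("W3_", l)]]), pn[[paste0("b3_", l)]])
  heads <- lapply(seq_len(n_heads), function(h) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- ad_slice_cols(tape, q, idx)
    kh <- ad_slice_cols(tape, k, idx)
    vh <- ad_slice_cols(tape, v, idx)
    logits <- ad_scale(tape, ad_matmul_nt(tape, qh, kh), 1 / sqrt(dh))
    a <- ad_softmax_rows(tape, logits)
    ad_matmul(tape, a, vh)
  })
  ad_concat_cols(tape, heads)
}

# internal: residual update x + MLP([x || m])
ad_residual_update <- function(tape, x, m, pn, l) {
  cat <- ad_concat_cols(tape, list(x, m))
  h <- ad_relu(tape, ad_add_rowvec(tape, ad_matmul(tape, cat, pn[[paste0("mlpW1_", l)]]),
                                   pn[[paste0("mlpb1_", l)]]))
  upd <- ad_add_rowvec(tape, ad_matmul(tape, h, pn[[paste0("mlpW2_", l)]]),
                       pn[[paste0("mlpb2_", l)]])
  ad_add(tape, x, upd)
}

# internal: full tape forward; returns descriptor nodes for both sides
ad_gnn_forward <- function(tape, sc_expr, sc_pos, st_expr, st_pos, pn, config) {
  sc_e <- ad_const(tape, sc_expr); st_e <- ad_const(tape, st_expr)
  sc_p <- ad_const(tape, sc_pos); st_p <- ad_const(tape, st_pos)
  xa <- ad_encode(tape, sc_e, sc_p, pn)
  xb <- ad_encode(tape, st_e, st_p, pn)
  for (l in seq_len(config$n_layers)) {
    if (l %% 2L == 1L) {  # self-edges: complete graph within each modality
      ma <- ad_attention(tape, xa, xa, pn, l, config$n_heads)
      mb <- ad_attention(tape, xb, xb, pn, l, config$n_heads)
    } else {              # cross-edges: every unit attends to the other modality
      ma <- ad_attention(tape, xa, xb, pn, l, config$n_heads)
      mb <- ad_attention(tape, xb, xa, pn, l, config$n_heads)
    }
    xa2 <- ad_residual_update(tape, xa, ma, pn, l)
    xb2 <- ad_residual_update(tape, xb, mb, pn, l)
    if (any(!is.finite(xa2$value)) || any(!is.finite(xb2$value))) {
      stop("non-finite node state at layer ", l)
    }
    xa <- xa2; xb <- xb2
  }
  fa <- ad_add_rowvec(tape, ad_matmul(tape, xa, pn$out_W), pn$out_b)
  fb <- ad_add_rowvec(tape, ad_matmul(tape, xb, pn$out_W), pn$out_b)
  list(fa = fa, fb = fb)
}

# internal: network input features from a normalized expression matrix
# (log1p, then per-gene standardization across units; zero-variance genes
# contribute a zero feature)
gat_input_features <- function(expr, genes) {
  x <- t(log1p(unclass(expr)[genes, , drop = FALSE]))  # units x genes
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
}

#' Encode units into layer-0 node states
#'
#' The point encoder adds a position embedding to a linear lift of the
#' expression features: `x^(0) = d + MLP_enc(p)`. Dissociated cells carry no
#' position, so their `p = (0, 0)` and the encoder output is a learned
#' constant offset.
#'
#' @param expr_features units x genes numeric feature matrix.
#' @param positions units x 2 coordinate matrix (zeros for dissociated cells).
#' @param params parameter list from the integration network.
#' @return units x D layer-0 state matrix.
#' @export
encode_nodes <- function(expr_features, positions, params) {
  if (nrow(expr_features) != nrow(positions)) stop("width mismatch: units differ")
  if (ncol(positions) != 2L) stop("positions must be units x 2")
  if (ncol(expr_features) != nrow(params$lift_W)) {
    stop("expression width does not match lift parameters")
  }
  tape <- ad_tape()
  pn <- gat_param_nodes(tape, params)
  ad_encode(tape, ad_const(tape, expr_features), ad_const(tape, positions), pn)$value
}

#' One multi-head attention message pass
#'
#' Queries come from the first state set, keys/values from the second;
#' per head `a_ij = softmax_j(q_i' k_j / sqrt(d_h))` and
#' `m_i = sum_j a_ij v_j`. Attention rows sum to 1 per head.
#'
#' @param states_query n_q x D state matrix.
#' @param states_source n_s x D state matrix (n_s >= 1).
#' @param params parameter list; layer `l` projections are used.
#' @param l layer index.
#' @param n_heads number of heads.
#' @return list with `message` (n_q x D) and `attention` (list of per-head
#'   n_q x n_s weight matrices).
#' @export
attention_message <- function(states_query, states_source, params, l = 1L,
                              n_heads = 4L) {
  if (nrow(states_source) < 1L) stop("empty source side")
  tape <- ad_tape()
  pn <- gat_param_nodes(tape, params)
  xq <- ad_const(tape, states_query)
  xs <- ad_const(tape, states_source)
  D <- ncol(states_query)
  dh <- D %/% n_heads
  q <- sweep(states_query %*% params[[paste0("W1_", l)]], 2L, params[[paste0("b1_", l)]], "+")
  k <- sweep(states_source %*% params[[paste0("W2_", l)]], 2L, params[[paste0("b2_", l)]], "+")
  attn <- lapply(seq_len(n_heads), function(h) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    z <- q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE]) / sqrt(dh)
    e <- exp(z - apply(z, 1L, max))
    e / rowSums(e)
  })
  msg <- ad_attention(tape, xq, xs, pn, l, n_heads)$value
  list(message = msg, attention = attn)
}

#' Full forward pass producing matching descriptors
#'
#' Runs `n_layers` residual attention updates, alternating self-edges (odd
#' layers) and cross-edges (even layers), then projects final states to
#' matching descriptors `f = W x^(L) + b`.
#'
#' @param sc_features,st_features units x genes feature matrices.
#' @param sc_positions,st_positions units x 2 coordinates (zeros for sc).
#' @param params parameter list (see internals of [fit_mapping()]).
#' @param config a [train_config()].
#' @return list with `f_sc` and `f_st` descriptor matrices (units x D).
#' @export
gnn_forward <- function(sc_features, st_features, sc_positions, st_positions,
                        params, config = train_config()) {
  tape <- ad_tape()
  pn <- gat_param_nodes(tape, params)
  out <- ad_gnn_forward(tape, sc_features, sc_positions, st_features, st_positions,
                        pn, config)
  list(f_sc = out$fa$value, f_st = out$fb$value)
}

#' Similarity matrix and reconstruction loss
#'
#' `M_ij = <f_i^sc, f_j^st>`. M is passed through a column-wise softmax (per
#' spot, over cells) and used to reconstruct spot expression `P = softmax(M)' A`;
#' the loss is the negated sum of per-gene and per-spot cosine similarities
#' between `P` and the spatial truth `B`, so minimizing it maximizes cosine
#' agreement.
#'
#' @param f_sc,f_st descriptor matrices (cells x D, spots x D).
#' @param A cells x genes expression of the dissociated data.
#' @param B spots x genes expression of the spatial data.
#' @return list with `M` (a `mapping_matrix`), `loss` (scalar) and
#'   `n_skipped` zero-norm cosine terms.
#' @export
similarity_and_loss <- function(f_sc, f_st, A, B) {
  M <- f_sc %*% t(f_st)
  dimnames(M) <- list(rownames(A), rownames(B))
  tape <- ad_tape()
  ms <- ad_const(tape, t(M))                    # spots x cells
  w <- ad_softmax_rows(tape, ms)                # per-spot weights over cells
  p <- ad_matmul(tape, w, ad_const(tape, A))    # spots x genes reconstruction
  lossn <- ad_neg_cos_agreement(tape, p, B)
  if (lossn$skipped > 0) {
    warning(lossn$skipped, " zero-norm cosine terms skipped")
  }
  list(M = structure(M, class = c("mapping_matrix", "matrix", "array")),
       loss = as.numeric(lossn$value), n_skipped = lossn$skipped)
}

#' Fit the cell-to-spot mapping
#'
#' Trains the attention network end-to-end with Adam on the cosine-agreement
#' objective and returns the similarity matrix M over (cells, spots). Fully
#' deterministic given `config$seed`.
#'
#' @param sc_data normalized single-cell `expression_matrix` (no positions).
#' @param st_data a `spatial_dataset` with normalized expression.
#' @param genes training genes shared by both matrices (>= 2).
#' @param config a [train_config()].
#' @param verbose print loss every 50 epochs.
#' @return a `mapping_matrix` (cells x spots inner products) with attributes
#'   `loss_trajectory` and `params`.
#' @export
fit_mapping <- function(sc_data, st_data, genes, config = train_config(),
                        verbose = FALSE) {
  genes <- if (inherits(genes, "training_gene_set")) genes$genes else genes
  if (length(genes) < 2L) stop("need at least 2 training genes")
  stopifnot(inherits(st_data, "spatial_dataset"))
  sc_expr <- if (inherits(sc_data, "spatial_dataset")) sc_data$expr else sc_data
  genes <- intersect(genes, intersect(rownames(sc_expr), rownames(st_data$expr)))
  if (length(genes) < 2L) stop("fewer than 2 training genes shared by both matrices")

  A <- t(unclass(sc_expr)[genes, , drop = FALSE])        # cells x genes
  B <- t(unclass(st_data$expr)[genes, , drop = FALSE])   # spots x genes
  sc_feat <- gat_input_features(sc_expr, genes)
  st_feat <- gat_input_features(st_data$expr, genes)
  sc_pos <- matrix(0, nrow(A), 2L)
  st_pos <- as.matrix(st_data$coords[, c("x", "y")])
  st_pos <- scale(st_pos)  # centre/scale coordinates for the encoder
  st_pos[!is.finite(st_pos)] <- 0

  params <- withr::with_seed(config$seed, gat_init_params(length(genes), config))
  opt <- adam_state(params, lr = config$lr)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    tape <- ad_tape()
    pn <- gat_param_nodes(tape, params)
    fwd <- ad_gnn_forward(tape, sc_feat, sc_pos, st_feat, st_pos, pn, config)
    m <- ad_matmul_nt(tape, fwd$fa, fwd$fb)      # cells x spots
    w <- ad_softmax_rows(tape, ad_node(tape, t(m$value), list(m),
                                       function(g) list(t(g))))
    p <- ad_matmul(tape, w, ad_const(tape, A))
    lossn <- ad_neg_cos_agreement(tape, p, B)
    losses[epoch] <- as.numeric(lossn$value)
    ad_backward(tape, lossn)
    grads <- lapply(pn, function(n) n$grad)
    st <- adam_step(opt, params, grads)
    opt <- st$state; params <- st$params
    if (verbose && epoch %% 50L == 0L) {
      message(sprintf("epoch %d loss %.4f", epoch, losses[epoch]))
    }
  }
  tape <- ad_tape()
  pn <- gat_param_nodes(tape, params)
  fwd <- ad_gnn_forward(tape, sc_feat, sc_pos, st_feat, st_pos, pn, config)
  M <- fwd$fa$value %*% t(fwd$fb$value)
  dimnames(M) <- list(colnames(sc_expr), colnames(st_data$expr))
  structure(M, class = c("mapping_matrix", "matrix", "array"),
            loss_trajectory = losses, params = params)
}

#' Softmax-normalized mapping probabilities
#' @param M a `mapping_matrix`.
#' @param over `"spots"`: each cell's row becomes a probability over spots;
#'   `"cells"`: each spot's column becomes a probability over cells.
#' @return a probability matrix of the same shape.
#' @export
mapping_probabilities <- function(M, over = c("spots", "cells")) {
  over <- match.arg(over)
  m <- unclass(M)
  softmax_rows <- function(x) {
    e <- exp(x - apply(x, 1L, max))
    e / rowSums(e)
  }
  if (over == "spots") softmax_rows(m) else t(softmax_rows(t(m)))
}

#' Cell-type probability map per spot
#'
#' Row-softmaxes M over spots, aggregates the per-cell mass by annotated
#' type, and renormalizes per spot; for single-cell spatial data the label of
#' each unit is the argmax type.
#'
#' @param M a `mapping_matrix` with cell row names and spot column names.
#' @param sc_annotation a `cell_type_annotation` covering every cell.
#' @return spots x types probability matrix with attribute `assigned_type`
#'   (named character argmax labels).
#' @export
celltype_probability_map <- function(M, sc_annotation) {
  check_annotated(rownames(M), sc_annotation)
  w <- mapping_probabilities(M, "spots")           # cells x spots
  labels <- sc_annotation$labels[rownames(M)]
  agg <- rowsum(w, group = labels)                 # types x spots
  types <- sc_annotation$type_order[sc_annotation$type_order %in% rownames(agg)]
  agg <- agg[types, , drop = FALSE]
  p <- t(agg)                                      # spots x types
  p <- p / rowSums(p)
  assigned <- colnames(p)[max.col(p, ties.method = "first")]
  names(assigned) <- rownames(p)
  structure(p, assigned_type = assigned)
}
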