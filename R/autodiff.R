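# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Both attention networks in this package are trained with gradient descent;
# no deep-learning framework is assumed, so gradients come from this small
# tape. Every op appends a node (value + backward closure) to a tape; the
# reverse sweep accumulates gradients into parameter leaves. Values are plain
# numeric matrices throughout (scalars are 1x1).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  tape$nodes[[length(tape$nodes) + 1L]] <- node
  node
}

# leaf holding trainable parameters (grad collected after backward)
ad_param <- function(tape, value) ad_node(tape, value)

# leaf holding constants (gradient discarded)
ad_const <- function(tape, value) ad_node(tape, value)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# reverse sweep from a scalar loss node
ad_backward <- function(tape, loss_node) {
  stopifnot(length(loss_node$value) == 1L)
  loss_node$grad <- matrix(1, 1, 1)
  for (i in rev(seq_along(tape$nodes))) {
    node <- tape$nodes[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) ad_accum(node$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# a %*% t(b) without materializing a transpose node
ad_matmul_nt <- function(tape, a, b) {
  ad_node(tape, a$value %*% t(b$value), list(a, b), function(g) {
    list(g %*% b$value, t(g) %*% a$value)
  })
}

# t(a) %*% b without materializing a transpose node
ad_matmul_tn <- function(tape, a, b) {
  ad_node(tape, t(a$value) %*% b$value, list(a, b), function(g) {
    list(b$value %*% t(g), a$value %*% g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

# add a 1 x D bias row-vector to every row of an n x D matrix
ad_add_rowvec <- function(tape, a, v) {
  ad_node(tape, sweep(a$value, 2L, as.numeric(v$value), "+"), list(a, v), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, list(a), function(g) list(g * mask))
}

ad_slice_cols <- function(tape, a, idx) {
  nc <- ncol(a$value)
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, idx] <- g
    list(out)
  })
}

ad_concat_cols <- function(tape, parts) {
  vals <- lapply(parts, function(p) p$value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), parts, function(g) {
    lapply(seq_along(parts), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# row-wise softmax; rows sum to one
ad_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

# scalar sum of all elements
ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(a$value), ncol(a$value)))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

# log-softmax over a single row vector (1 x V), numerically stable
ad_log_softmax_row <- function(tape, a) {
  z <- a$value - max(a$value)
  ls <- z - log(sum(exp(z)))
  ad_node(tape, ls, list(a), function(g) {
    list(g - sum(g) * exp(ls))
  })
}

# Negated cosine-agreement loss between a reconstruction P and a target B
# (same shape): -(sum over columns cos(P[,k], B[,k]) + sum over rows
# cos(P[j,], B[j,])). Zero-norm target/reconstruction vectors are skipped and
# counted; the count is exposed via attribute on the node value's environment.
ad_neg_cos_agreement <- function(tape, p, b_const) {
  B <- b_const
  P <- p$value
  cos_terms <- function(X, Y, margin) {
    # returns list(value, grad wrt X) for sum of cosines along margin
    if (margin == 2L) { X <- t(X); Y <- t(Y) }  # operate on rows
    nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
    ok <- nx > 0 & ny > 0
    dots <- rowSums(X * Y)
    cosv <- ifelse(ok, dots / (nx * ny), 0)
    g <- matrix(0, nrow(X), ncol(X))
    if (any(ok)) {
      g[ok, ] <- Y[ok, , drop = FALSE] / (nx[ok] * ny[ok]) -
        (cosv[ok] / nx[ok]^2) * X[ok, , drop = FALSE]
    }
    if (margin == 2L) g <- t(g)
    list(value = sum(cosv), grad = g, skipped = sum(!ok))
  }
  by_col <- cos_terms(P, B, 2L)
  by_row <- cos_terms(P, B, 1L)
  skipped <- by_col$skipped + by_row$skipped
  node <- ad_node(tape, matrix(-(by_col$value + by_row$value), 1, 1), list(p),
                  function(g) list(-as.numeric(g) * (by_col$grad + by_row$grad)))
  node$skipped <- skipped
  node
}

# ---- parameter utilities ----------------------------------------------------

# Xavier/Glorot normal init, seeded by the caller's RNG state
ad_init_matrix <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

# Adam optimizer over a flat named list of matrices
adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g^2
    mhat <- state$m[[k]] / (1 - state$beta1^state$t)
    vhat <- state$v[[k]] / (1 - state$beta2^state$t)
    params[[k]] <- params[[k]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
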