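# Minimal reverse-mode automatic differentiation on dense matrices.
# Internal engine backing the sequence models: a tape records nodes in
# creation order; ad_backward() replays it in reverse. Values are plain
# numeric matrices (biases are numeric vectors). Not exported.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backfn <- backfn
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_leaf <- function(tape, val) ad_node(tape, val)

ad_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# ---- primitive operations ------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tape, av %*% bv, function(g) {
    ad_acc(a, tcrossprod(g, bv))
    ad_acc(b, crossprod(av, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, function(g) {
    ad_acc(a, g); ad_acc(b, g)
  })
}

# add a bias vector (length ncol(a)) to every row
ad_bias <- function(tape, a, b) {
  ad_node(tape, sweep(a$val, 2L, b$val, "+"), function(g) {
    ad_acc(a, g); ad_acc(b, colSums(g))
  })
}

# add a constant array (no gradient flows into the constant)
ad_addc <- function(tape, a, cst) {
  ad_node(tape, a$val + cst, function(g) ad_acc(a, g))
}

ad_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tape, av * bv, function(g) {
    ad_acc(a, g * bv); ad_acc(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, function(g) ad_acc(a, g * s))
}

ad_tanh <- function(tape, a) {
  y <- tanh(a$val)
  ad_node(tape, y, function(g) ad_acc(a, g * (1 - y^2)))
}

ad_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$val))
  ad_node(tape, y, function(g) ad_acc(a, g * y * (1 - y)))
}

ad_relu <- function(tape, a) {
  av <- a$val
  ad_node(tape, pmax(av, 0), function(g) ad_acc(a, g * (av > 0)))
}

ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$val[idx, , drop = FALSE], function(g) {
    d <- matrix(0, nrow(a$val), ncol(a$val))
    agg <- rowsum(g, group = idx, reorder = TRUE)
    d[as.integer(rownames(agg)), ] <- agg
    ad_acc(a, d)
  })
}

ad_cols <- function(tape, a, cols) {
  ad_node(tape, a$val[, cols, drop = FALSE], function(g) {
    d <- matrix(0, nrow(a$val), ncol(a$val))
    d[, cols] <- g
    ad_acc(a, d)
  })
}

ad_concat_cols <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(parts, function(p) p$val)), function(g) {
    for (k in seq_along(parts))
      ad_acc(parts[[k]], g[, starts[k]:ends[k], drop = FALSE])
  })
}

# assemble a big matrix from parts placed at given row indices
ad_stack_rows_at <- function(tape, parts, idxs, nrow_total) {
  val <- matrix(0, nrow_total, ncol(parts[[1]]$val))
  for (k in seq_along(parts)) val[idxs[[k]], ] <- parts[[k]]$val
  ad_node(tape, val, function(g) {
    for (k in seq_along(parts))
      ad_acc(parts[[k]], g[idxs[[k]], , drop = FALSE])
  })
}

# row-wise softmax (inputs already masked additively where needed)
ad_softmax_rows <- function(tape, a) {
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  ad_node(tape, s, function(g) {
    ad_acc(a, s * (g - rowSums(g * s)))
  })
}

# row-wise layer normalization with learned gain/bias vectors
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  av <- a$val
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  out <- sweep(sweep(xh, 2L, gamma$val, "*"), 2L, beta$val, "+")
  ad_node(tape, out, function(g) {
    dxh <- sweep(g, 2L, gamma$val, "*")
    ad_acc(gamma, colSums(g * xh))
    ad_acc(beta, colSums(g))
    ad_acc(a, inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)))
  })
}

# mean squared error over masked cells: sum(((p-t)*m)^2)/sum(m)
ad_masked_mse <- function(tape, pred, target, mask) {
  nv <- sum(mask)
  if (nv == 0) stop("no valid cells in batch")
  diff <- (pred$val - target) * mask
  ad_node(tape, sum(diff^2) / nv, function(g) {
    ad_acc(pred, g * 2 * diff / nv)
  })
}

# root mean squared error of a column-vector prediction vs numeric target
ad_rmse <- function(tape, pred, target) {
  d <- pred$val - target
  n <- length(d)
  if (!n) stop("empty batch")
  v <- sqrt(mean(d^2))
  ad_node(tape, v, function(g) {
    if (v > 0) ad_acc(pred, g * d / (n * v))
  })
}

# attention pooling: given per-position weights W (B x S, post-softmax)
# and features X ((B*S) x d, batch-major rows), return B x d weighted sums
ad_attnpool <- function(tape, w, x, B, S) {
  wv <- w$val; xv <- x$val
  d <- ncol(xv)
  out <- matrix(0, B, d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    out[b, ] <- wv[b, ] %*% xv[rows, , drop = FALSE]
  }
  ad_node(tape, out, function(g) {
    dw <- matrix(0, B, S)
    dx <- matrix(0, nrow(xv), d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      xb <- xv[rows, , drop = FALSE]
      dw[b, ] <- g[b, , drop = FALSE] %*% t(xb)
      dx[rows, ] <- outer(wv[b, ], g[b, ])
    }
    ad_acc(w, dw); ad_acc(x, dx)
  })
}

# a %*% t(b)
ad_matmul_bt <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tape, tcrossprod(av, bv), function(g) {
    ad_acc(a, g %*% bv)
    ad_acc(b, crossprod(g, av))
  })
}

# reshape a batch-major (B*S) x 1 column into a B x S matrix
ad_reshape_rows <- function(tape, a, B, S) {
  ad_node(tape, matrix(a$val, B, S, byrow = TRUE), function(g) {
    ad_acc(a, matrix(as.vector(t(g)), ncol = 1L))
  })
}

# ---- Adam optimizer ------------------------------------------------------

adam_state <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(weights)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    weights[[k]] <- weights[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}
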