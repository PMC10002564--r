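# Reverse-mode automatic differentiation on dense matrices.
#
# Every value in the computation graph is a "node": an environment holding the
# forward value (`val`, always a base matrix), the accumulated adjoint
# (`grad`), the parent nodes and a backward closure. Nodes are registered on a
# tape in creation order; `ad_backward()` walks the tape in reverse. The op
# set is exactly what the channel networks, graph encoders and predictor need;
# batched sequence ops (convolution, pooling, attention) treat a matrix of
# B*L rows as B stacked length-L blocks so that a whole minibatch is a single
# node, keeping the tape short.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

ad_leaf <- function(tape, val) {
  if (!is.matrix(val)) val <- as.matrix(val)
  ad_node(tape, val)
}

# add adjoint g into node p (no-op for constants created off-tape)
ad_acc <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

ad_backward <- function(node, seed_grad = NULL) {
  tape <- node$tape
  if (is.null(seed_grad)) {
    seed_grad <- matrix(1, nrow(node$val), ncol(node$val))
  }
  node$grad <- seed_grad
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

## ---- elementary ops -------------------------------------------------------

op_mm <- function(a, b) {
  ad_node(a$tape, a$val %*% b$val, list(a, b), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[1]], g %*% t(nd$parents[[2]]$val))
    ad_acc(nd$parents[[2]], crossprod(nd$parents[[1]]$val, g))
  })
}

# b: same shape as a, or a 1-row matrix broadcast over a's rows
op_add <- function(a, b) {
  bv <- b$val
  broadcast <- nrow(bv) == 1L && nrow(a$val) > 1L
  val <- if (broadcast) sweep(a$val, 2L, bv[1L, ], "+") else a$val + bv
  ad_node(a$tape, val, list(a, b), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[1]], g)
    if (broadcast) {
      ad_acc(nd$parents[[2]], matrix(colSums(g), 1L))
    } else {
      ad_acc(nd$parents[[2]], g)
    }
  })
}

op_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad)
    ad_acc(nd$parents[[2]], -nd$grad)
  })
}

op_mul <- function(a, b) {
  ad_node(a$tape, a$val * b$val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * nd$parents[[2]]$val)
    ad_acc(nd$parents[[2]], nd$grad * nd$parents[[1]]$val)
  })
}

op_smul <- function(a, s) {
  ad_node(a$tape, a$val * s, list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * s)
  })
}

# scale row i of a by column vector c[i] (c: n x 1 node)
op_colmul <- function(a, c) {
  ad_node(a$tape, a$val * as.vector(c$val), list(a, c), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[1]], g * as.vector(nd$parents[[2]]$val))
    ad_acc(nd$parents[[2]], matrix(rowSums(g * nd$parents[[1]]$val), ncol = 1L))
  })
}

op_rowsums <- function(a) {
  ad_node(a$tape, matrix(rowSums(a$val), ncol = 1L), list(a), function(nd) {
    p <- nd$parents[[1]]
    ad_acc(p, matrix(rep(as.vector(nd$grad), ncol(p$val)), nrow(p$val)))
  })
}

op_hcat <- function(a, b) {
  na <- ncol(a$val)
  ad_node(a$tape, cbind(a$val, b$val), list(a, b), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[1]], g[, seq_len(na), drop = FALSE])
    ad_acc(nd$parents[[2]], g[, -seq_len(na), drop = FALSE])
  })
}

op_vcat <- function(nodes) {
  sizes <- vapply(nodes, function(n) nrow(n$val), integer(1))
  ad_node(nodes[[1]]$tape, do.call(rbind, lapply(nodes, function(n) n$val)),
          nodes, function(nd) {
    g <- nd$grad
    off <- 0L
    for (k in seq_along(nd$parents)) {
      ad_acc(nd$parents[[k]], g[off + seq_len(sizes[k]), , drop = FALSE])
      off <- off + sizes[k]
    }
  })
}

# gather rows (with repetition); backward scatter-adds
op_rows <- function(a, idx) {
  ad_node(a$tape, a$val[idx, , drop = FALSE], list(a), function(nd) {
    p <- nd$parents[[1]]
    g <- matrix(0, nrow(p$val), ncol(p$val))
    # rowsum() aggregates duplicate indices
    agg <- rowsum(nd$grad, group = idx)
    g[as.integer(rownames(agg)), ] <- agg
    ad_acc(p, g)
  })
}

# constant sparse matrix S (dgCMatrix or base) times node x
op_spmm <- function(S, x) {
  ad_node(x$tape, as.matrix(S %*% x$val), list(x), function(nd) {
    ad_acc(nd$parents[[1]], as.matrix(Matrix::crossprod(S, nd$grad)))
  })
}

## ---- nonlinearities -------------------------------------------------------

op_leakyrelu <- function(a, slope = 0.01) {
  v <- a$val
  pos <- v > 0
  val <- v * pos + (slope * v) * !pos
  ad_node(a$tape, val, list(a), function(nd) {
    d <- pos + slope * !pos
    ad_acc(nd$parents[[1]], nd$grad * d)
  })
}

# fast row maxima (ties towards the first column)
.row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, "first"))]

op_tanh <- function(a) {
  val <- tanh(a$val)
  ad_node(a$tape, val, list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * (1 - nd$val^2))
  })
}

op_sigmoid <- function(a) {
  val <- 1 / (1 + exp(-a$val))
  ad_node(a$tape, val, list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * nd$val * (1 - nd$val))
  })
}

# exact GELU: x * pnorm(x)
op_gelu <- function(a) {
  v <- a$val
  ad_node(a$tape, v * stats::pnorm(v), list(a), function(nd) {
    x <- nd$parents[[1]]$val
    ad_acc(nd$parents[[1]], nd$grad * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

op_softmax_rows <- function(a) {
  v <- a$val
  m <- v - .row_max(v)
  e <- exp(m)
  p <- e / rowSums(e)
  ad_node(a$tape, p, list(a), function(nd) {
    g <- nd$grad
    pr <- nd$val
    ad_acc(nd$parents[[1]], pr * (g - rowSums(g * pr)))
  })
}

# softmax of a column vector within segments seg (integer vector, 1..nseg)
op_segsoftmax <- function(a, seg) {
  v <- as.vector(a$val)
  mx <- tapply(v, seg, max)[as.character(seg)]
  e <- exp(v - mx)
  tot <- as.vector(tapply(e, seg, sum))[seg]
  p <- e / tot
  ad_node(a$tape, matrix(p, ncol = 1L), list(a), function(nd) {
    g <- as.vector(nd$grad)
    pr <- as.vector(nd$val)
    inner <- as.vector(tapply(g * pr, seg, sum))[seg]
    ad_acc(nd$parents[[1]], matrix(pr * (g - inner), ncol = 1L))
  })
}

## ---- normalization & regularization ---------------------------------------

# layer normalization across each row, learnable gain/bias (1 x d nodes)
op_layernorm <- function(a, gain, bias, eps = 1e-5) {
  x <- a$val
  n <- nrow(x)
  d <- ncol(x)
  crep <- function(v) rep(v, each = n)
  mu <- .rowMeans(x, n, d)
  xc <- x - mu
  sd_ <- sqrt(.rowMeans(xc * xc, n, d) + eps)
  xh <- xc / sd_
  val <- xh * crep(gain$val[1L, ]) + crep(bias$val[1L, ])
  ad_node(a$tape, val, list(a, gain, bias), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[2]], matrix(.colSums(g * xh, n, d), 1L))
    ad_acc(nd$parents[[3]], matrix(.colSums(g, n, d), 1L))
    dxh <- g * crep(gain$val[1L, ])
    dx <- (dxh - .rowMeans(dxh, n, d) -
             xh * .rowMeans(dxh * xh, n, d)) / sd_
    ad_acc(nd$parents[[1]], dx)
  })
}

# 1-d batch normalization over the rows (batch dimension); gamma/beta 1 x d.
# state: environment with running mean/var (momentum update in train mode).
op_batchnorm <- function(a, gamma, beta, state, mode = c("train", "eval"),
                         eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  x <- a$val
  n <- nrow(x)
  train <- mode == "train"
  if (train && n < 2L) {
    stop("batch normalization in train mode needs a batch of at least 2 ",
         "(batch variance is undefined for a single row)")
  }
  fw <- bn_forward(x, gamma$val[1L, ], beta$val[1L, ], state$mean,
                   state$var, as.integer(train), eps)
  if (train) {
    state$mean <- (1 - momentum) * state$mean + momentum * fw$mean
    state$var <- (1 - momentum) * state$var + momentum * fw$var * n / (n - 1)
  }
  ad_node(a$tape, fw$y, list(a, gamma, beta), function(nd) {
    bw <- bn_backward(nd$grad, fw$xh, fw$sd, gamma$val[1L, ],
                      as.integer(train))
    ad_acc(nd$parents[[2]], matrix(bw$dgamma, 1L))
    ad_acc(nd$parents[[3]], matrix(bw$dbeta, 1L))
    ad_acc(nd$parents[[1]], bw$dx)
  })
}

# inverted dropout; identity in eval mode
op_dropout <- function(a, p, mode = "train") {
  if (mode != "train" || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$val)), nrow(a$val)) >= p) / (1 - p)
  ad_node(a$tape, a$val * mask, list(a), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * mask)
  })
}

## ---- batched sequence ops -------------------------------------------------

# shift each of B stacked length-L blocks by one row (dir = +1: row i-1 -> i)
.seq_shift <- function(x, dir, B, L) {
  shift_blocks(x, B, L, as.integer(dir))
}

# length-preserving kernel-3 1-d convolution along the block axis.
# x: (B*L) x Cin; W: list of three Cin x Cout matrices (prev, centre, next);
# b: 1 x Cout bias.
op_conv1d_seq <- function(x, W, b, B, L) {
  xp <- .seq_shift(x$val, +1L, B, L)
  xn <- .seq_shift(x$val, -1L, B, L)
  val <- sweep(xp %*% W[[1]]$val + x$val %*% W[[2]]$val + xn %*% W[[3]]$val,
               2L, b$val[1L, ], "+")
  ad_node(x$tape, val, list(x, W[[1]], W[[2]], W[[3]], b), function(nd) {
    g <- nd$grad
    xv <- nd$parents[[1]]$val
    ad_acc(nd$parents[[2]], crossprod(xp, g))
    ad_acc(nd$parents[[3]], crossprod(xv, g))
    ad_acc(nd$parents[[4]], crossprod(xn, g))
    ad_acc(nd$parents[[5]], matrix(colSums(g), 1L))
    dx <- g %*% t(nd$parents[[3]]$val) +
      .seq_shift(g %*% t(nd$parents[[2]]$val), -1L, B, L) +
      .seq_shift(g %*% t(nd$parents[[4]]$val), +1L, B, L)
    ad_acc(nd$parents[[1]], dx)
  })
}

# max-pool each length-L block with kernel = stride = k (L divisible by k)
op_maxpool_seq <- function(x, B, L, k = 4L) {
  xv <- x$val
  G <- (B * L) %/% k
  C <- ncol(xv)
  best <- xv[seq(1L, B * L, by = k), , drop = FALSE]
  arg <- matrix(seq(1L, B * L, by = k), G, C)
  for (o in 2L:k) {
    cand <- xv[seq(o, B * L, by = k), , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- matrix(seq(o, B * L, by = k), G, C)[upd]
  }
  ad_node(x$tape, best, list(x), function(nd) {
    p <- nd$parents[[1]]
    dx <- matrix(0, nrow(p$val), C)
    ix <- cbind(as.vector(arg), rep(seq_len(C), each = G))
    dx[ix] <- dx[ix] + as.vector(nd$grad)
    ad_acc(p, dx)
  })
}

# multi-head self-attention within each of B stacked length-L blocks.
# x: (B*L) x d; Wq/Wk/Wv/Wo: d x d. Dropout applied to attention weights in
# train mode. One tape node for the whole batch. Block-diagonal score and
# context products are computed without a per-sample loop by summing over
# the head channels: for head column c,
#   S[r, j] += Q[r, c] * K[block(r) row j, c]
# which is an elementwise product against the block-expanded key matrix.
op_attention_seq <- function(x, Wq, Wk, Wv, Wo, B, L, heads,
                             dropout = 0, mode = "eval") {
  d <- ncol(x$val)
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  Q <- x$val %*% Wq$val
  K <- x$val %*% Wk$val
  V <- x$val %*% Wv$val
  scale <- 1 / sqrt(dh)
  fw <- attn_block_forward(Q, K, V, B, L, heads, scale, dropout,
                           mode == "train")
  O <- fw$O
  val <- O %*% Wo$val
  ad_node(x$tape, val, list(x, Wq, Wk, Wv, Wo), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[5]], crossprod(O, g))
    dO <- g %*% t(nd$parents[[5]]$val)
    bw <- attn_block_backward(dO, Q, K, V, fw$A, fw$M, B, L, heads, scale)
    xv <- nd$parents[[1]]$val
    ad_acc(nd$parents[[2]], crossprod(xv, bw$dQ))
    ad_acc(nd$parents[[3]], crossprod(xv, bw$dK))
    ad_acc(nd$parents[[4]], crossprod(xv, bw$dV))
    ad_acc(nd$parents[[1]],
           bw$dQ %*% t(nd$parents[[2]]$val) +
             bw$dK %*% t(nd$parents[[3]]$val) +
             bw$dV %*% t(nd$parents[[4]]$val))
  })
}

# cached linear-index permutations for the row-major flatten
.flatten_cache <- new.env(parent = emptyenv())
.flatten_perm <- function(B, L, d) {
  key <- paste(B, L, d)
  p <- .flatten_cache[[key]]
  if (is.null(p)) {
    # y[b, (l-1)*d + c] = x[(b-1)*L + l, c]; both column-major linearized
    l <- rep(rep(seq_len(L), each = 1L), times = d)
    idx <- expand.grid(b = seq_len(B), l = seq_len(L), c = seq_len(d))
    # column-major order of y: b fastest, then j = (l-1)*d + c
    jj <- expand.grid(b = seq_len(B), c = seq_len(d), l = seq_len(L))
    jj <- jj[order((jj$l - 1L) * d + jj$c, jj$b), ]
    fwd <- (jj$c - 1L) * (B * L) + (jj$b - 1L) * L + jj$l
    p <- list(fwd = fwd, inv = order(fwd))
    .flatten_cache[[key]] <- p
  }
  p
}

# flatten each of B stacked length-L blocks row-major: (B*L) x d -> B x (L*d)
op_flatten_seq <- function(x, B, L) {
  d <- ncol(x$val)
  p <- .flatten_perm(B, L, d)
  val <- matrix(x$val[p$fwd], B, L * d)
  ad_node(x$tape, val, list(x), function(nd) {
    dx <- matrix(as.vector(nd$grad)[p$inv], B * L, d)
    ad_acc(nd$parents[[1]], dx)
  })
}

# mean cross-entropy of logits (n x K) against integer class labels (1..K);
# stores the softmax probabilities on the node as `probs`.
op_ce_logits <- function(logits, y) {
  z <- logits$val
  m <- z - apply(z, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  n <- nrow(z)
  ll <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  nd <- ad_node(logits$tape, matrix(ll, 1L, 1L), list(logits), function(nd) {
    gp <- p
    gp[cbind(seq_len(n), y)] <- gp[cbind(seq_len(n), y)] - 1
    ad_acc(nd$parents[[1]], gp * (as.vector(nd$grad) / n))
  })
  nd$probs <- p
  nd
}

## ---- parameter context ----------------------------------------------------

# Wraps a named list of parameter matrices for one forward/backward pass:
# `$n(name)` returns a cached leaf node so every use of a parameter shares a
# node and gradients accumulate; `$grads()` collects them afterwards.
ad_context <- function(tape, params) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$params <- params
  ctx$nodes <- list()
  ctx$n <- function(name) {
    nd <- ctx$nodes[[name]]
    if (is.null(nd)) {
      nd <- ad_leaf(ctx$tape, ctx$params[[name]])
      ctx$nodes[[name]] <- nd
    }
    nd
  }
  ctx$grads <- function() {
    out <- list()
    for (nm in names(ctx$nodes)) {
      g <- ctx$nodes[[nm]]$grad
      if (!is.null(g)) out[[nm]] <- g
    }
    out
  }
  ctx
}

## ---- Adam optimizer -------------------------------------------------------

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

# One Adam step. grads: named list; weight_decay adds an L2 penalty gradient
# (classic L2, applied before the moment update).
adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    st$m[[nm]] <- m; st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / b1t) / (sqrt(v / b2t) + eps)
  }
  params
}

# seeded uniform Glorot-style initialization
init_weight <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

bn_state_new <- function(d) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, d)
  st$var <- rep(1, d)
  st
}
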