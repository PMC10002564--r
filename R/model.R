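# The pair-classification model: three channel networks over the pretrained
# drug representations, multi-head self-attention fusion, and a linear-layer
# predictor. The batched differentiable forward lives here; thin single-pair
# wrappers expose each channel with the row-count contract (2 / 50 / 6 rows,
# 58-row fused stack) for inspection and testing.

#' Model configuration
#'
#' @param dim Hidden width of every channel (default 64, the reference
#'   setting; the desk profile uses 32).
#' @param dropout Dropout probability, applied after each channel's final
#'   activation and to attention weights.
#' @param attn_heads Number of self-attention heads (`dim` divisible by it).
#' @param Nl Number of event classes.
#' @param channel_mask Enabled channels, a subset of
#'   `c("network", "sequence", "graph")`; single-channel masks give the
#'   NC/SC/GC ablation variants.
#' @param use_residual Keep the sequence channel's residual connection
#'   (`FALSE` gives the NO_ADD variant).
#' @param use_fusion_attention Fuse the channel stack with self-attention
#'   (`FALSE` gives the NO_ATTEN variant: plain concatenation).
#' @param use_graph_conv Keep the graph channel's convolution along the
#'   stacking direction (`FALSE` gives the NO_CONV variant).
#' @param freeze_cse Precompute the chemical-structure embeddings once and
#'   train only the channels (default trains the graph encoders end-to-end).
#' @param rounds Message-passing iterations of the graph encoders.
#' @param dim_cse Width of the chemical-structure embeddings.
#' @param seed Seed for parameter initialization.
#' @return A `mseddi_config` list.
#' @export
mseddi_config <- function(dim = 64, dropout = 0.2, attn_heads = 4, Nl,
                          channel_mask = c("network", "sequence", "graph"),
                          use_residual = TRUE, use_fusion_attention = TRUE,
                          use_graph_conv = TRUE, freeze_cse = FALSE,
                          rounds = 3, dim_cse = dim, seed = 1) {
  channel_mask <- match.arg(channel_mask, several.ok = TRUE)
  stopifnot(dim >= 1, dropout >= 0, dropout < 1, attn_heads >= 1,
            dim %% attn_heads == 0, Nl >= 1, length(channel_mask) >= 1)
  structure(list(dim = as.integer(dim), dropout = dropout,
                 attn_heads = as.integer(attn_heads), Nl = as.integer(Nl),
                 channel_mask = channel_mask,
                 use_residual = isTRUE(use_residual),
                 use_fusion_attention = isTRUE(use_fusion_attention),
                 use_graph_conv = isTRUE(use_graph_conv),
                 freeze_cse = isTRUE(freeze_cse),
                 rounds = as.integer(rounds), dim_cse = as.integer(dim_cse),
                 seed = as.integer(seed)),
            class = "mseddi_config")
}

# rows contributed by each enabled channel (2 + 50 + 6 = 58 when all on)
channel_rows <- function(cfg) {
  sum(c(network = 2L, sequence = 50L, graph = 6L)[cfg$channel_mask])
}

#' Initialize an untrained model
#'
#' Builds all trainable weights (channels, fusion, predictor and -- unless
#' `freeze_cse` -- the three graph encoders) with seeded Glorot-style
#' uniform draws, plus the batch-normalization running statistics.
#'
#' @param cfg A [mseddi_config()].
#' @param dim_kge Width of the knowledge-graph embeddings.
#' @param dim_sne Width of the notation embeddings.
#' @param n_atom_features,n_bond_features Atom/bond feature widths of the
#'   molecular graphs (needed unless `freeze_cse`).
#' @return An `mseddi_model` object (`params`, `bn`, `cfg`).
#' @export
init_mseddi <- function(cfg, dim_kge, dim_sne, n_atom_features = NULL,
                        n_bond_features = NULL) {
  d <- cfg$dim
  with_local_seed(cfg$seed, {
    p <- list()
    bn <- list()
    ones <- function(w) matrix(1, 1L, w)
    zeros <- function(w) matrix(0, 1L, w)
    if ("network" %in% cfg$channel_mask) {
      p$net_W1 <- init_weight(dim_kge, d)
      p$net_bn_g <- ones(d); p$net_bn_b <- zeros(d)
      p$net_W2 <- init_weight(d, d)
      bn$net <- bn_state_new(d)
    }
    if ("sequence" %in% cfg$channel_mask) {
      p$seq_conv_p <- init_weight(dim_sne, d)
      p$seq_conv_c <- init_weight(dim_sne, d)
      p$seq_conv_n <- init_weight(dim_sne, d)
      p$seq_conv_b <- zeros(d)
      p$seq_bn_g <- ones(d); p$seq_bn_b <- zeros(d)
      p$seq_Wq <- init_weight(d, d); p$seq_Wk <- init_weight(d, d)
      p$seq_Wv <- init_weight(d, d); p$seq_Wo <- init_weight(d, d)
      p$seq_ln1_g <- ones(d); p$seq_ln1_b <- zeros(d)
      p$seq_ff1 <- init_weight(d, 2L * d)
      p$seq_ff2 <- init_weight(2L * d, d)
      p$seq_ln2_g <- ones(d); p$seq_ln2_b <- zeros(d)
      bn$seq <- bn_state_new(d)
    }
    if ("graph" %in% cfg$channel_mask) {
      for (v in .encoder_variants) {
        p[[paste0("g_", v, "_W1")]] <- init_weight(cfg$dim_cse, d)
        p[[paste0("g_", v, "_bn_g")]] <- ones(d)
        p[[paste0("g_", v, "_bn_b")]] <- zeros(d)
        p[[paste0("g_", v, "_W2")]] <- init_weight(d, d)
        bn[[paste0("g_", v)]] <- bn_state_new(d)
      }
      p$gconv_p <- init_weight(d, d); p$gconv_c <- init_weight(d, d)
      p$gconv_n <- init_weight(d, d); p$gconv_b <- zeros(d)
      p$gconv_bn_g <- ones(d); p$gconv_bn_b <- zeros(d)
      bn$gconv <- bn_state_new(d)
      if (!cfg$freeze_cse) {
        stopifnot(!is.null(n_atom_features), !is.null(n_bond_features))
        p <- c(p, init_encoder_params(n_atom_features, n_bond_features,
                                      graph_encoder_config(cfg$dim_cse,
                                                           cfg$rounds)))
      }
    }
    R <- channel_rows(cfg)
    if (cfg$use_fusion_attention) {
      p$fus_Wq <- init_weight(d, d); p$fus_Wk <- init_weight(d, d)
      p$fus_Wv <- init_weight(d, d); p$fus_Wo <- init_weight(d, d)
      p$fus_ln_g <- ones(d); p$fus_ln_b <- zeros(d)
    }
    p$pred_W1 <- init_weight(R * d, d)
    p$pred_bn_g <- ones(d); p$pred_bn_b <- zeros(d)
    p$pred_W2 <- init_weight(d, cfg$Nl)
    bn$pred <- bn_state_new(d)
    structure(list(params = p, bn = bn, cfg = cfg), class = "mseddi_model")
  })
}

# two-linear-layer perceptron block on the tape:
# LeakyReLU(BN1d(x W1)) W2
mlp_fwd <- function(ctx, x, prefix, bn_state, mode) {
  h <- op_mm(x, ctx$n(paste0(prefix, "_W1")))
  h <- op_batchnorm(h, ctx$n(paste0(prefix, "_bn_g")),
                    ctx$n(paste0(prefix, "_bn_b")), bn_state, mode)
  op_mm(op_leakyrelu(h), ctx$n(paste0(prefix, "_W2")))
}

# Differentiable batched forward pass.
# batch: list(ii, jj) 1-based drug indices (+ y labels for the loss);
# inputs: list(H_kge [Nd x dim_kge], H_sne [(Nd*100) x dim_sne],
#              ug (union graph of all drugs) or H_cse list of matrices).
# Returns nodes for the fused stack and logits plus layout bookkeeping.
mseddi_forward <- function(model, batch, inputs, mode = "eval",
                           tape = ad_tape(), ctx = NULL, with_head = TRUE) {
  cfg <- model$cfg
  d <- cfg$dim
  B <- length(batch$ii)
  if (is.null(ctx)) ctx <- ad_context(tape, model$params)
  pieces <- list()   # per-channel output nodes
  offsets <- integer(0)
  rows_of <- c(network = 2L, sequence = 50L, graph = 6L)

  if ("network" %in% cfg$channel_mask) {
    xin <- ad_node(tape, inputs$H_kge[c(batch$ii, batch$jj), , drop = FALSE])
    out <- mlp_fwd(ctx, xin, "net", model$bn$net, mode)
    out <- op_dropout(out, cfg$dropout, mode)
    pieces$network <- out       # rows: [i-block (B), j-block (B)]
  }

  if ("sequence" %in% cfg$channel_mask) {
    L0 <- 100L
    take <- function(k) ((k - 1L) * L0 + 1L):(k * L0)
    idx <- integer(2L * L0 * B)
    for (b in seq_len(B)) {
      idx[((b - 1L) * 2L * L0 + 1L):(b * 2L * L0)] <-
        c(take(batch$ii[b]), take(batch$jj[b]))
    }
    xin <- ad_node(tape, inputs$H_sne[idx, , drop = FALSE])
    h <- op_conv1d_seq(xin, list(ctx$n("seq_conv_p"), ctx$n("seq_conv_c"),
                                 ctx$n("seq_conv_n")), ctx$n("seq_conv_b"),
                       B = B, L = 2L * L0)
    h <- op_batchnorm(h, ctx$n("seq_bn_g"), ctx$n("seq_bn_b"),
                      model$bn$seq, mode)
    h <- op_maxpool_seq(h, B = B, L = 2L * L0, k = 4L)
    ps1 <- op_leakyrelu(h)                       # (B*50) x dim
    at <- op_attention_seq(ps1, ctx$n("seq_Wq"), ctx$n("seq_Wk"),
                           ctx$n("seq_Wv"), ctx$n("seq_Wo"),
                           B = B, L = 50L, heads = cfg$attn_heads,
                           dropout = cfg$dropout, mode = mode)
    ps2 <- op_layernorm(at, ctx$n("seq_ln1_g"), ctx$n("seq_ln1_b"))
    ff <- op_mm(op_gelu(op_mm(ps2, ctx$n("seq_ff1"))), ctx$n("seq_ff2"))
    ff <- op_layernorm(ff, ctx$n("seq_ln2_g"), ctx$n("seq_ln2_b"))
    out <- if (cfg$use_residual) op_add(ps1, ff) else ff
    out <- op_dropout(out, cfg$dropout, mode)
    pieces$sequence <- out      # rows: sample-major blocks of 50
  }

  if ("graph" %in% cfg$channel_mask) {
    vouts <- list()
    for (v in .encoder_variants) {
      if (cfg$freeze_cse) {
        hv <- ad_node(tape,
                      inputs$H_cse[[v]][c(batch$ii, batch$jj), , drop = FALSE])
      } else {
        enc <- encoder_forward(ctx, v, inputs$ug, cfg$rounds)
        hv <- op_rows(enc, c(batch$ii, batch$jj))
      }
      vouts[[v]] <- mlp_fwd(ctx, hv, paste0("g_", v),
                            model$bn[[paste0("g_", v)]], mode)
    }
    stackmat <- op_vcat(vouts)   # rows: [mpnn i|j (2B), weave (2B), afp (2B)]
    gidx <- integer(6L * B)
    for (b in seq_len(B)) {
      gidx[((b - 1L) * 6L + 1L):(b * 6L)] <-
        c(b, B + b, 2L * B + b, 3L * B + b, 4L * B + b, 5L * B + b)
    }
    g <- op_rows(stackmat, gidx)  # (B*6) x dim, per-pair stacking order
    if (cfg$use_graph_conv) {
      g <- op_conv1d_seq(g, list(ctx$n("gconv_p"), ctx$n("gconv_c"),
                                 ctx$n("gconv_n")), ctx$n("gconv_b"),
                         B = B, L = 6L)
    }
    g <- op_batchnorm(g, ctx$n("gconv_bn_g"), ctx$n("gconv_bn_b"),
                      model$bn$gconv, mode)
    out <- op_dropout(op_leakyrelu(g), cfg$dropout, mode)
    pieces$graph <- out
  }

  if (!with_head) {
    return(list(ctx = ctx, tape = tape, pieces = pieces, B = B))
  }

  # assemble the per-pair fused stack: for each sample, the enabled
  # channels' rows in the fixed order (network, sequence, graph)
  R <- channel_rows(cfg)
  enabled <- intersect(c("network", "sequence", "graph"),
                       cfg$channel_mask)
  allmat <- op_vcat(unname(pieces[enabled]))
  block_off <- 0L
  sidx <- integer(R * B)
  pos <- 1L
  per_channel_index <- list(
    network = function(b) c(b, B + b),
    sequence = function(b) ((b - 1L) * 50L + 1L):(b * 50L),
    graph = function(b) ((b - 1L) * 6L + 1L):(b * 6L)
  )
  for (b in seq_len(B)) {
    off <- 0L
    for (ch in enabled) {
      n_rows <- rows_of[[ch]]
      sidx[pos:(pos + n_rows - 1L)] <- off + per_channel_index[[ch]](b)
      pos <- pos + n_rows
      off <- off + rows_of[[ch]] * B
    }
  }
  stack <- op_rows(allmat, sidx)   # (B*R) x dim

  fused <- if (cfg$use_fusion_attention) {
    at <- op_attention_seq(stack, ctx$n("fus_Wq"), ctx$n("fus_Wk"),
                           ctx$n("fus_Wv"), ctx$n("fus_Wo"),
                           B = B, L = R, heads = cfg$attn_heads,
                           dropout = cfg$dropout, mode = mode)
    op_layernorm(at, ctx$n("fus_ln_g"), ctx$n("fus_ln_b"))
  } else {
    stack
  }
  flat <- op_flatten_seq(fused, B = B, L = R)   # B x (R*dim)
  logits <- mlp_fwd(ctx, flat, "pred", model$bn$pred, mode)
  list(ctx = ctx, tape = tape, stack = stack, fused = fused,
       logits = logits, pieces = pieces, B = B, R = R)
}

## ---- public single-pair channel operations --------------------------------

#' Two-linear-layer perceptron block
#'
#' `LeakyReLU(BN1d(x %*% W1)) %*% W2` -- the building block used by the
#' network channel, the graph channel's per-variant projections and the
#' predictor. In eval mode the batch normalization uses the supplied running
#' statistics (default: mean 0, variance 1); in train mode it uses batch
#' statistics, which requires at least two rows.
#'
#' @param x Input matrix (rows are the batch dimension).
#' @param W1,W2 Weight matrices.
#' @param mode `"eval"` or `"train"`.
#' @param gamma,beta Batch-norm affine parameters (default identity).
#' @param state Batch-norm running statistics from [bn_state_new] (default
#'   fresh: mean 0, variance 1).
#' @return Matrix with `ncol(W2)` columns.
#' @export
mlp_block <- function(x, W1, W2, mode = c("eval", "train"), gamma = NULL,
                      beta = NULL, state = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  d1 <- ncol(W1)
  if (is.null(gamma)) gamma <- matrix(1, 1L, d1)
  if (is.null(beta)) beta <- matrix(0, 1L, d1)
  if (is.null(state)) state <- bn_state_new(d1)
  tape <- ad_tape()
  h <- op_mm(ad_node(tape, x), ad_node(tape, W1))
  h <- op_batchnorm(h, ad_node(tape, gamma), ad_node(tape, beta), state, mode)
  op_mm(op_leakyrelu(h), ad_node(tape, W2))$val
}

# run the batched forward for one pair given raw per-drug representations
single_pair_forward <- function(model, H_kge_i = NULL, H_kge_j = NULL,
                                H_sne_i = NULL, H_sne_j = NULL,
                                H_cse_i = NULL, H_cse_j = NULL,
                                mode = "eval") {
  cfg <- model$cfg
  inputs <- list()
  if ("network" %in% cfg$channel_mask) {
    inputs$H_kge <- rbind(matrix(H_kge_i, nrow = 1L),
                          matrix(H_kge_j, nrow = 1L))
  } else inputs$H_kge <- matrix(0, 2L, 1L)
  if ("sequence" %in% cfg$channel_mask) {
    stopifnot(nrow(H_sne_i) == 100L, nrow(H_sne_j) == 100L)
    inputs$H_sne <- rbind(H_sne_i, H_sne_j)
  } else inputs$H_sne <- matrix(0, 200L, 1L)
  if ("graph" %in% cfg$channel_mask) {
    stopifnot(!is.null(H_cse_i), !is.null(H_cse_j))
    inputs$H_cse <- lapply(stats::setNames(.encoder_variants,
                                           .encoder_variants), function(v) {
      rbind(matrix(H_cse_i[[v]], nrow = 1L), matrix(H_cse_j[[v]], nrow = 1L))
    })
  }
  stopifnot(cfg$freeze_cse || !("graph" %in% cfg$channel_mask) ||
              !is.null(inputs$H_cse))
  model2 <- model
  model2$cfg$freeze_cse <- TRUE   # representations supplied directly
  mseddi_forward(model2, list(ii = 1L, jj = 2L), inputs, mode = mode,
                 with_head = FALSE)
}

#' Network channel for one drug pair
#'
#' Applies the shared perceptron block to both drugs' knowledge-graph
#' embeddings and stacks the two rows.
#'
#' @param H_kge_i,H_kge_j Knowledge-graph embedding vectors.
#' @param model An `mseddi_model` (from [init_mseddi()]).
#' @param mode `"eval"` or `"train"`.
#' @return A `2 x dim` matrix (row 1 from drug i, row 2 from drug j).
#' @export
network_channel <- function(H_kge_i, H_kge_j, model, mode = "eval") {
  stopifnot("network" %in% model$cfg$channel_mask)
  cfg2 <- model$cfg; cfg2$channel_mask <- "network"
  m2 <- model; m2$cfg <- cfg2
  fw <- single_pair_forward(m2, H_kge_i = H_kge_i, H_kge_j = H_kge_j,
                            mode = mode)
  fw$pieces$network$val
}

#' Sequence channel for one drug pair
#'
#' Concatenates the two drugs' `100 x dim_sne` notation embeddings along the
#' sequence, then applies the convolution / batch-norm / max-pool /
#' LeakyReLU stage, multi-head self-attention with layer norm, and the
#' position-wise feed-forward block with optional residual connection.
#'
#' @param H_sne_i,H_sne_j `100 x dim_sne` notation embeddings.
#' @inheritParams network_channel
#' @return A `50 x dim` matrix.
#' @export
sequence_channel <- function(H_sne_i, H_sne_j, model, mode = "eval") {
  stopifnot("sequence" %in% model$cfg$channel_mask)
  if (nrow(H_sne_i) != 100L || nrow(H_sne_j) != 100L) {
    stop("sequence channel inputs must have exactly 100 rows")
  }
  cfg2 <- model$cfg; cfg2$channel_mask <- "sequence"
  m2 <- model; m2$cfg <- cfg2
  fw <- single_pair_forward(m2, H_sne_i = H_sne_i, H_sne_j = H_sne_j,
                            mode = mode)
  fw$pieces$sequence$val
}

#' Graph channel for one drug pair
#'
#' Projects the three chemical-structure embeddings of each drug through
#' three independent perceptron blocks, stacks the six rows, and applies the
#' convolution along the stacking direction with batch norm and LeakyReLU.
#'
#' @param H_cse_i,H_cse_j Named lists (`mpnn`, `weave`, `afp`) of
#'   `dim_cse`-vectors.
#' @inheritParams network_channel
#' @return A `6 x dim` matrix.
#' @export
graph_channel <- function(H_cse_i, H_cse_j, model, mode = "eval") {
  stopifnot("graph" %in% model$cfg$channel_mask)
  miss <- setdiff(.encoder_variants,
                  intersect(names(H_cse_i), names(H_cse_j)))
  if (length(miss) > 0L) {
    stop("missing chemical-structure embedding variant(s): ",
         paste(miss, collapse = ", "))
  }
  cfg2 <- model$cfg; cfg2$channel_mask <- "graph"
  m2 <- model; m2$cfg <- cfg2
  fw <- single_pair_forward(m2, H_cse_i = H_cse_i, H_cse_j = H_cse_j,
                            mode = mode)
  fw$pieces$graph$val
}

#' Fuse channel outputs and predict the event
#'
#' Stacks the enabled channels' outputs (2 + 50 + 6 = 58 rows with all
#' channels on), applies multi-head self-attention with layer norm (or plain
#' concatenation for the NO_ATTEN variant), flattens row-major and feeds the
#' predictor perceptron block.
#'
#' @param P_kge `2 x dim` network-channel output (or `NULL` if masked).
#' @param P_sne `50 x dim` sequence-channel output (or `NULL`).
#' @param P_cse `6 x dim` graph-channel output (or `NULL`).
#' @inheritParams network_channel
#' @return List with `logits` (length-`Nl` vector), `probs` (softmax,
#'   sums to 1) and `stack` (the fused `R x dim` matrix).
#' @export
fuse_and_predict <- function(P_kge = NULL, P_sne = NULL, P_cse = NULL,
                             model, mode = "eval") {
  cfg <- model$cfg
  present <- c(network = !is.null(P_kge), sequence = !is.null(P_sne),
               graph = !is.null(P_cse))
  if (!any(present[cfg$channel_mask])) stop("no channel enabled")
  stopifnot(all(present[cfg$channel_mask]))
  blocks <- list(network = P_kge, sequence = P_sne,
                 graph = P_cse)[cfg$channel_mask]
  stack_val <- do.call(rbind, blocks)
  R <- channel_rows(cfg)
  stopifnot(nrow(stack_val) == R)
  tape <- ad_tape()
  ctx <- ad_context(tape, model$params)
  stack <- ad_node(tape, stack_val)
  fused <- if (cfg$use_fusion_attention) {
    at <- op_attention_seq(stack, ctx$n("fus_Wq"), ctx$n("fus_Wk"),
                           ctx$n("fus_Wv"), ctx$n("fus_Wo"),
                           B = 1L, L = R, heads = cfg$attn_heads,
                           dropout = cfg$dropout, mode = mode)
    op_layernorm(at, ctx$n("fus_ln_g"), ctx$n("fus_ln_b"))
  } else {
    stack
  }
  flat <- op_flatten_seq(fused, B = 1L, L = R)
  logits <- mlp_fwd(ctx, flat, "pred", model$bn$pred, mode)
  z <- drop(logits$val)
  e <- exp(z - max(z))
  list(logits = z, probs = e / sum(e), stack = fused$val)
}
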