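# Trainable molecular-graph encoders. All three variants share the same
# message-passing skeleton -- linear aggregation over neighbours conditioned
# on edge attributes, linear update with a LeakyReLU -- and differ in their
# readout, mirroring the three published styles:
#   mpnn  : recurrent attention pooling (a Set2Set simplified to an
#           LSTM-free query vector updated by the attended sum),
#   weave : node sum followed by a linear tail layer,
#   afp   : three stacked attention-gated global pooling layers.
# For speed, a whole set of molecules is encoded at once as one disjoint
# union graph; aggregation and readout are sparse matrix products, so a
# forward pass is a handful of tape nodes regardless of batch size.

#' Configuration for the chemical-structure encoders
#'
#' @param dim_cse Output embedding width (also the hidden node-state width).
#' @param rounds Message-passing iterations `T`.
#' @param seed Integer seed for parameter initialization when used
#'   standalone.
#' @return A `graph_encoder_config` list.
#' @export
graph_encoder_config <- function(dim_cse = 64, rounds = 3, seed = 1) {
  stopifnot(dim_cse >= 1, rounds >= 1)
  structure(list(dim_cse = as.integer(dim_cse), rounds = as.integer(rounds),
                 seed = as.integer(seed)),
            class = "graph_encoder_config")
}

.encoder_variants <- c("mpnn", "weave", "afp")

# disjoint union of molecular graphs with precomputed sparse operators:
#   X     : atom-feature matrix for all atoms
#   Ef    : edge-feature matrix, one row per directed edge
#   src   : source atom of each directed edge (messages flow src -> dst)
#   Agg   : n_atoms x n_edges aggregation matrix (sums incoming messages)
#   Msum  : n_mols x n_atoms segment-sum matrix
#   Mmean : n_mols x n_atoms segment-mean matrix
#   seg   : molecule index of each atom
union_graph <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offs <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  seg <- rep(seq_along(graphs), n_atoms)
  src <- integer(0); dst <- integer(0)
  Ef <- NULL
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$bonds) > 0L) {
      src <- c(src, g$bonds$u + offs[i], g$bonds$v + offs[i])
      dst <- c(dst, g$bonds$v + offs[i], g$bonds$u + offs[i])
      Ef <- rbind(Ef, g$bond_features, g$bond_features)
    }
  }
  if (is.null(Ef)) Ef <- matrix(0, 0L, ncol(graphs[[1]]$bond_features))
  N <- sum(n_atoms)
  E <- length(src)
  Agg <- Matrix::sparseMatrix(i = dst, j = seq_len(E), x = 1,
                              dims = c(N, max(E, 0L)))
  Msum <- Matrix::sparseMatrix(i = seg, j = seq_len(N), x = 1,
                               dims = c(length(graphs), N))
  Mmean <- Matrix::sparseMatrix(i = seg, j = seq_len(N),
                                x = 1 / n_atoms[seg],
                                dims = c(length(graphs), N))
  list(X = X, Ef = Ef, src = src, Agg = Agg, Msum = Msum, Mmean = Mmean,
       seg = seg, n_mols = length(graphs), n_atoms = N)
}

# parameter block for one encoder variant (names prefixed "<variant>_")
init_encoder_variant_params <- function(variant, Fa, Fb, dg, dim_cse) {
  p <- list()
  p[[paste0(variant, "_emb")]] <- init_weight(Fa, dg)
  p[[paste0(variant, "_msg_h")]] <- init_weight(dg, dg)
  p[[paste0(variant, "_msg_e")]] <- init_weight(Fb, dg)
  p[[paste0(variant, "_upd_h")]] <- init_weight(dg, dg)
  p[[paste0(variant, "_upd_a")]] <- init_weight(dg, dg)
  if (variant == "mpnn") {
    p$mpnn_s2s <- init_weight(2 * dg, dg)
    p$mpnn_out <- init_weight(2 * dg, dim_cse)
  } else if (variant == "weave") {
    p$weave_out <- init_weight(dg, dim_cse)
  } else {
    p$afp_att <- init_weight(dg, dg)
    p$afp_upd <- init_weight(2 * dg, dg)
    p$afp_out <- init_weight(dg, dim_cse)
  }
  p
}

init_encoder_params <- function(Fa, Fb, cfg) {
  dg <- cfg$dim_cse
  out <- list()
  for (v in .encoder_variants) {
    out <- c(out, init_encoder_variant_params(v, Fa, Fb, dg, cfg$dim_cse))
  }
  out
}

# differentiable forward pass of one variant over a union graph;
# returns an (n_mols x dim_cse) tape node
encoder_forward <- function(ctx, variant, ug, rounds) {
  pn <- function(suffix) ctx$n(paste0(variant, "_", suffix))
  tape <- ctx$tape
  Xc <- ad_node(tape, ug$X)
  Ec <- ad_node(tape, ug$Ef)
  h <- op_leakyrelu(op_mm(Xc, pn("emb")))
  emsg <- op_mm(Ec, pn("msg_e"))
  for (t in seq_len(rounds)) {
    hm <- if (length(ug$src) > 0L) {
      op_add(op_mm(op_rows(h, ug$src), pn("msg_h")), emsg)
    } else {
      emsg
    }
    a <- op_spmm(ug$Agg, hm)
    h <- op_leakyrelu(op_add(op_mm(h, pn("upd_h")), op_mm(a, pn("upd_a"))))
  }
  encoder_readout(ctx, variant, h, ug)
}

encoder_readout <- function(ctx, variant, h, ug) {
  tape <- ctx$tape
  seg <- ug$seg
  if (variant == "weave") {
    return(op_mm(op_spmm(ug$Msum, h), ctx$n("weave_out")))
  }
  if (variant == "mpnn") {
    q <- ad_node(tape, matrix(0, ug$n_mols, ncol(h$val)))
    r <- NULL
    for (s in 1:3) {
      scores <- op_rowsums(op_mul(h, op_rows(q, seg)))
      alpha <- op_segsoftmax(scores, seg)
      r <- op_spmm(ug$Msum, op_colmul(h, alpha))
      q <- op_tanh(op_mm(op_hcat(q, r), ctx$n("mpnn_s2s")))
    }
    return(op_mm(op_hcat(q, r), ctx$n("mpnn_out")))
  }
  # afp: super-node initialized to the node mean, refined by three
  # attention-gated pooling layers
  s <- op_spmm(ug$Mmean, h)
  hk <- op_mm(h, ctx$n("afp_att"))
  for (l in 1:3) {
    scores <- op_rowsums(op_mul(hk, op_rows(s, seg)))
    alpha <- op_segsoftmax(scores, seg)
    r <- op_spmm(ug$Msum, op_colmul(h, alpha))
    s <- op_leakyrelu(op_mm(op_hcat(s, r), ctx$n("afp_upd")))
  }
  op_mm(s, ctx$n("afp_out"))
}

#' Readout of per-node states into a molecule embedding
#'
#' Applies one variant's permutation-invariant pooling to a matrix of node
#' states for a single molecule.
#'
#' @param graph_states Numeric matrix, one row per atom (at least one row).
#' @param variant `"mpnn"`, `"weave"` or `"afp"`.
#' @param params Encoder parameter list (see [init_encoder_params]); only
#'   the readout weights of the chosen variant are used.
#' @return A numeric vector of length `dim_cse`.
#' @export
readout <- function(graph_states, variant = .encoder_variants, params) {
  variant <- match.arg(variant)
  if (!is.matrix(graph_states)) graph_states <- as.matrix(graph_states)
  if (nrow(graph_states) == 0L) stop("readout of an empty graph")
  n <- nrow(graph_states)
  ug <- list(seg = rep(1L, n), n_mols = 1L,
             Msum = Matrix::sparseMatrix(i = rep(1L, n), j = seq_len(n),
                                         x = 1, dims = c(1L, n)),
             Mmean = Matrix::sparseMatrix(i = rep(1L, n), j = seq_len(n),
                                          x = 1 / n, dims = c(1L, n)))
  tape <- ad_tape()
  ctx <- ad_context(tape, params)
  out <- encoder_readout(ctx, variant, ad_node(tape, graph_states), ug)
  drop(out$val)
}

#' Encode one molecule with a chemical-structure encoder
#'
#' Runs `rounds` iterations of message passing followed by the variant's
#' readout; deterministic given the parameters.
#'
#' @param graph A `molgraph` from [smiles_to_molgraph()].
#' @param cfg A [graph_encoder_config()].
#' @param params Encoder parameters from [init_encoder_params]; when `NULL`,
#'   seeded fresh parameters are drawn using `cfg$seed`.
#' @param variant Encoder variant.
#' @return Numeric vector of length `dim_cse`.
#' @export
encode_molecule <- function(graph, cfg = graph_encoder_config(),
                            params = NULL, variant = .encoder_variants) {
  variant <- match.arg(variant)
  if (graph$n_atoms == 0L) stop("readout of an empty graph")
  if (is.null(params)) {
    params <- with_local_seed(cfg$seed, {
      init_encoder_variant_params(variant, ncol(graph$atom_features),
                                  ncol(graph$bond_features), cfg$dim_cse,
                                  cfg$dim_cse)
    })
  }
  ug <- union_graph(list(graph))
  tape <- ad_tape()
  ctx <- ad_context(tape, params)
  drop(encoder_forward(ctx, variant, ug, cfg$rounds)$val)
}
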