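# Cold-start drug-level splitting, feature assembly, supervised training of
# the pair classifier, and prediction.

#' Drug-level cold-start cross-validation split
#'
#' Shuffles the drug set by seed and cuts it into `k` near-equal subsets.
#' For fold `f`, subset `f` is the set of new drugs and the rest are known;
#' every DDI record is routed to exactly one of three pair sets: train
#' (known-known), task1 (known-new) and task2 (new-new).
#'
#' @param bundle A `ddi_bundle`.
#' @param k Number of folds (at least 2, at most the number of drugs).
#' @param seed Integer seed for the drug shuffle.
#' @return A list of `k` `fold_split` objects with fields `fold`,
#'   `known_drugs`, `new_drugs`, `train_pairs`, `task1_pairs`,
#'   `task2_pairs`.
#' @export
cold_start_split <- function(bundle, k = 5, seed = 1) {
  drugs <- bundle$drugs$drug_id
  if (k < 2) stop("k must be at least 2")
  if (k > length(drugs)) stop("k exceeds the number of drugs")
  with_local_seed(seed, {
    shuffled <- sample(drugs)
    grp <- rep(seq_len(k), length.out = 0)
    sizes <- rep(length(drugs) %/% k, k)
    extra <- length(drugs) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    grp <- rep(seq_len(k), times = sizes)
    lapply(seq_len(k), function(f) {
      new_drugs <- sort(shuffled[grp == f])
      known_drugs <- sort(setdiff(drugs, new_drugs))
      new_i <- bundle$ddis$drug_i %in% new_drugs
      new_j <- bundle$ddis$drug_j %in% new_drugs
      n_new <- new_i + new_j
      structure(list(fold = f, known_drugs = known_drugs,
                     new_drugs = new_drugs,
                     train_pairs = bundle$ddis[n_new == 0L, ],
                     task1_pairs = bundle$ddis[n_new == 1L, ],
                     task2_pairs = bundle$ddis[n_new == 2L, ]),
                class = "fold_split")
    })
  })
}

#' @export
print.fold_split <- function(x, ...) {
  cat("<fold_split> fold ", x$fold, ": ", length(x$known_drugs), " known / ",
      length(x$new_drugs), " new drugs; pairs train ", nrow(x$train_pairs),
      ", task1 ", nrow(x$task1_pairs), ", task2 ", nrow(x$task2_pairs),
      "\n", sep = "")
  invisible(x)
}

#' Training configuration
#'
#' Defaults are the reference settings (loss weight 1e-5, batch 512, 350
#' epochs, learning rate 1e-4); the desk profile used throughout the
#' package's examples is `train_config(batch_size = 64, epochs = 50,
#' lr = 1e-3)`.
#'
#' @param weight_decay L2 penalty weight on all trainable parameters.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(weight_decay = 1e-5, batch_size = 512, epochs = 350,
                         lr = 1e-4, seed = 1) {
  stopifnot(weight_decay >= 0, batch_size >= 2, epochs >= 1, lr > 0)
  structure(list(weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble the per-drug representations consumed by the model
#'
#' Extracts knowledge-graph embeddings from a TransE fit (zero vectors, with
#' a warning, for drugs absent from the KG), notation embeddings from a CBOW
#' fit via the fold/pad rule, and parses every SMILES into a molecular graph
#' (batched into one disjoint union graph for the encoders).
#'
#' @param bundle A `ddi_bundle`.
#' @param transe A `transe_fit`.
#' @param cbow A `cbow_fit`.
#' @return An `mseddi_features` object.
#' @export
drug_features <- function(bundle, transe, cbow) {
  ids <- bundle$drugs$drug_id
  H_kge <- extract_drug_kge(transe, ids)
  H_sne <- drug_notation_embeddings(bundle$drugs, cbow)
  graphs <- lapply(bundle$drugs$smiles, smiles_to_molgraph)
  ug <- union_graph(graphs)
  structure(list(drug_ids = ids, H_kge = H_kge, H_sne = H_sne,
                 graphs = graphs, ug = ug,
                 dim_kge = ncol(H_kge), dim_sne = ncol(H_sne),
                 n_atom_features = ncol(ug$X),
                 n_bond_features = ncol(ug$Ef)),
            class = "mseddi_features")
}

# resolve the model inputs (constant representation matrices) for training
# and prediction; precomputes frozen structure embeddings when requested
model_inputs <- function(model, features) {
  inputs <- list(H_kge = features$H_kge, H_sne = features$H_sne,
                 ug = features$ug)
  if ("graph" %in% model$cfg$channel_mask && model$cfg$freeze_cse) {
    enc_params <- with_local_seed(model$cfg$seed + 1L, {
      init_encoder_params(features$n_atom_features,
                          features$n_bond_features,
                          graph_encoder_config(model$cfg$dim_cse,
                                               model$cfg$rounds))
    })
    ctx <- ad_context(NULL, enc_params)
    inputs$H_cse <- lapply(stats::setNames(.encoder_variants,
                                           .encoder_variants), function(v) {
      encoder_forward(ctx, v, features$ug, model$cfg$rounds)$val
    })
  }
  inputs
}

#' Train the pair classifier on the known-known pairs of a fold
#'
#' Minimizes the cross-entropy of the event labels over the fold's training
#' pairs with an L2 penalty (`weight_decay`) on all trainable weights, using
#' Adam over seeded shuffled minibatches. The graph encoders are trained
#' end-to-end through the graph channel unless the model was configured with
#' `freeze_cse`. Task-1/Task-2 pairs are never touched; the drugs the model
#' actually saw are recorded in `drugs_seen`.
#'
#' @param split A `fold_split` from [cold_start_split()].
#' @param features An `mseddi_features` from [drug_features()].
#' @param model_cfg An [mseddi_config()].
#' @param train_cfg A [train_config()].
#' @return An `mseddi_fit`: trained model, `loss_trace` (mean minibatch
#'   loss per epoch), `drugs_seen`, the configs and the feature reference.
#' @export
train_model <- function(split, features, model_cfg, train_cfg) {
  pairs <- split$train_pairs
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty train_pairs")
  model <- init_mseddi(model_cfg, dim_kge = features$dim_kge,
                       dim_sne = features$dim_sne,
                       n_atom_features = features$n_atom_features,
                       n_bond_features = features$n_bond_features)
  inputs <- model_inputs(model, features)
  ii_all <- match(pairs$drug_i, features$drug_ids)
  jj_all <- match(pairs$drug_j, features$drug_ids)
  if (anyNA(ii_all) || anyNA(jj_all)) {
    stop("training pairs reference drugs absent from the feature set")
  }
  y_all <- pairs$event + 1L
  n <- nrow(pairs)
  opt <- adam_state()
  trace <- numeric(train_cfg$epochs)
  with_local_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = train_cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + train_cfg$batch_size - 1L, n)]
        if (length(bi) == 1L) next  # batch statistics undefined
        batch <- list(ii = ii_all[bi], jj = jj_all[bi], y = y_all[bi])
        tape <- ad_tape()
        fw <- mseddi_forward(model, batch, inputs, mode = "train",
                             tape = tape)
        loss <- op_ce_logits(fw$logits, batch$y)
        ad_backward(loss)
        model$params <- adam_step(model$params, fw$ctx$grads(), opt,
                                  lr = train_cfg$lr,
                                  weight_decay = train_cfg$weight_decay)
        ep_loss <- ep_loss + loss$val[1] * length(bi)
      }
      trace[ep] <- ep_loss / n
    }
  })
  structure(list(model = model, inputs = inputs, features = features,
                 train_cfg = train_cfg, loss_trace = trace,
                 fold = split$fold,
                 drugs_seen = sort(unique(c(pairs$drug_i, pairs$drug_j)))),
            class = "mseddi_fit")
}

#' Predict event probabilities for drug pairs
#'
#' Eval-mode forward pass (dropout disabled, batch norm on running
#' statistics), deterministic given the fit.
#'
#' @param object An `mseddi_fit`.
#' @param pairs Tibble with columns `drug_i`, `drug_j` (and optionally
#'   `event`).
#' @param batch_size Pairs per forward pass.
#' @param ... Unused.
#' @return A tibble `(drug_i, drug_j, predicted_event, probability)` with
#'   the per-class probability matrix in attribute `"probs"`.
#' @export
predict.mseddi_fit <- function(object, pairs, batch_size = 256L, ...) {
  if (nrow(pairs) == 0L) stop("no pairs to predict")
  feats <- object$features
  ii <- match(pairs$drug_i, feats$drug_ids)
  jj <- match(pairs$drug_j, feats$drug_ids)
  if (anyNA(ii) || anyNA(jj)) {
    stop("pairs reference drugs absent from the feature set")
  }
  Nl <- object$model$cfg$Nl
  probs <- matrix(NA_real_, nrow(pairs), Nl)
  for (s in seq(1L, nrow(pairs), by = batch_size)) {
    bi <- s:min(s + batch_size - 1L, nrow(pairs))
    fw <- mseddi_forward(object$model,
                         list(ii = ii[bi], jj = jj[bi]), object$inputs,
                         mode = "eval")
    z <- fw$logits$val
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    probs[bi, ] <- e / rowSums(e)
  }
  pred <- apply(probs, 1L, which.max) - 1L   # ties -> lowest index
  out <- tibble::tibble(drug_i = pairs$drug_i, drug_j = pairs$drug_j,
                        predicted_event = pred,
                        probability = probs[cbind(seq_len(nrow(probs)),
                                                  pred + 1L)])
  attr(out, "probs") <- probs
  out
}

#' Evaluate a fit on a pair set
#'
#' @param fit An `mseddi_fit`.
#' @param pairs Tibble of pairs with true `event` labels (non-empty).
#' @return A `ddi_metrics` object (see [ddi_metrics()]).
#' @export
evaluate <- function(fit, pairs) {
  if (nrow(pairs) == 0L) stop("cannot evaluate on an empty pair set")
  pr <- predict(fit, pairs)
  ddi_metrics(pairs$event, attr(pr, "probs"))
}

#' @export
print.mseddi_fit <- function(x, ...) {
  cat("<mseddi_fit> fold ", x$fold, ", channels [",
      paste(x$model$cfg$channel_mask, collapse = ", "), "], dim ",
      x$model$cfg$dim, "; final epoch loss ",
      signif(utils::tail(x$loss_trace, 1), 4), "\n", sep = "")
  invisible(x)
}
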