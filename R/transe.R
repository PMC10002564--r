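# Translational knowledge-graph embedding (TransE). A relation is modelled
# as a vector translation h + r ~ t; training minimizes a margin ranking loss
# between observed triplets and corrupted negatives, with entity vectors
# renormalized to the unit sphere after every epoch.

#' Configuration for TransE training
#'
#' @param dim_kge Embedding width.
#' @param margin Margin `gamma` of the ranking loss (non-negative).
#' @param norm Distance norm, `"L2"` or `"L1"`.
#' @param lr Learning rate of the SGD updates.
#' @param epochs Training epochs.
#' @param negatives_per_positive Corrupted triplets sampled per positive.
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return A `transe_config` list.
#' @export
transe_config <- function(dim_kge = 128, margin = 1, norm = c("L2", "L1"),
                          lr = 0.01, epochs = 500,
                          negatives_per_positive = 1, batch_size = 128,
                          seed = 1) {
  norm <- match.arg(norm)
  stopifnot(dim_kge >= 1, margin >= 0, lr > 0, epochs >= 1,
            negatives_per_positive >= 1, batch_size >= 1)
  structure(list(dim_kge = as.integer(dim_kge), margin = margin, norm = norm,
                 lr = lr, epochs = as.integer(epochs),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "transe_config")
}

#' TransE triplet score
#'
#' The score of a triplet `(h, r, t)` is the negative distance between
#' `h + r` and `t`: always non-positive, and zero exactly when the relation
#' is a perfect translation.
#'
#' @param h,r,t Numeric vectors of equal length (head, relation, tail).
#' @param norm `"L2"` (Euclidean) or `"L1"`.
#' @return A single non-positive number.
#' @examples
#' score_triplet(c(1, 0), c(0, 1), c(1, 1)) # 0: exact translation
#' score_triplet(c(0, 0), c(0, 0), c(3, 4)) # -5
#' @export
score_triplet <- function(h, r, t, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  if (length(h) != length(r) || length(r) != length(t)) {
    stop("h, r and t must have the same dimension")
  }
  d <- h + r - t
  -switch(norm, L2 = sqrt(sum(d^2)), L1 = sum(abs(d)))
}

#' Margin ranking loss for one (positive, negative) pair
#'
#' `max(0, margin - pos_score + neg_score)`; non-negative, non-increasing in
#' the positive score and non-decreasing in the negative score.
#'
#' @param pos_score,neg_score Triplet scores from [score_triplet()].
#' @param margin Non-negative margin.
#' @return A single non-negative number.
#' @export
margin_loss <- function(pos_score, neg_score, margin) {
  pmax(0, margin - pos_score + neg_score)
}

#' Corrupt a triplet for negative sampling
#'
#' Replaces the head or the tail (each side with probability 1/2) by an
#' entity drawn uniformly from the pool, rejecting corruptions that are
#' themselves observed triplets, so that the negative is guaranteed unrelated.
#'
#' @param triplet Character vector `c(head, relation, tail)` or a 1-row
#'   data frame with those columns.
#' @param entity_pool Character vector of candidate entities.
#' @param positive_set Character vector of keys `paste(head, relation, tail)`
#'   for all observed triplets.
#' @param max_retries Attempts before giving up.
#' @return A character vector `c(head, relation, tail)`.
#' @export
corrupt_triplet <- function(triplet, entity_pool, positive_set,
                            max_retries = 100) {
  if (is.data.frame(triplet)) {
    triplet <- c(triplet$head[1], triplet$relation[1], triplet$tail[1])
  }
  if (length(entity_pool) == 0L) stop("entity pool is empty")
  for (i in seq_len(max_retries)) {
    side <- if (stats::runif(1) < 0.5) 1L else 3L
    cand <- triplet
    cand[side] <- entity_pool[sample.int(length(entity_pool), 1L)]
    if (!(paste(cand[1], cand[2], cand[3]) %in% positive_set)) return(cand)
  }
  stop("could not sample a valid negative triplet after ", max_retries,
       " retries (knowledge graph too densely connected)")
}

#' Train TransE on a set of knowledge-graph triplets
#'
#' Seeded uniform initialization, minibatch SGD on the margin ranking loss
#' over (positive, corrupted) pairs, and unit-L2 renormalization of entity
#' vectors after every epoch. Relations are normalized once at
#' initialization.
#'
#' @param triplets Tibble `(head, relation, tail)` (a multiset; duplicates
#'   are kept).
#' @param cfg A [transe_config()].
#' @return A `transe_fit` object: list with `entities` (matrix, one row per
#'   entity), `relations`, `loss_trace` (mean margin loss per epoch) and
#'   `cfg`.
#' @export
train_transe <- function(triplets, cfg = transe_config()) {
  stopifnot(nrow(triplets) >= 1L)
  ents <- sort(unique(c(triplets$head, triplets$tail)))
  rels <- sort(unique(triplets$relation))
  if (length(ents) < 2L) stop("TransE needs at least 2 distinct entities")
  d <- cfg$dim_kge
  pos_keys <- paste(triplets$head, triplets$relation, triplets$tail)
  hi <- match(triplets$head, ents)
  ri <- match(triplets$relation, rels)
  ti <- match(triplets$tail, ents)
  n <- nrow(triplets)
  l2norm <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)

  with_local_seed(cfg$seed, {
    b <- 6 / sqrt(d)
    E <- l2norm(matrix(stats::runif(length(ents) * d, -b, b), ncol = d))
    R <- l2norm(matrix(stats::runif(length(rels) * d, -b, b), ncol = d))
    rownames(E) <- ents
    rownames(R) <- rels
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        for (rep_ in seq_len(cfg$negatives_per_positive)) {
          # corrupt each positive in the batch (vectorized with rejection)
          m <- length(bidx)
          side <- stats::runif(m) < 0.5
          ch <- hi[bidx]; ct <- ti[bidx]
          cand <- sample.int(length(ents), m, replace = TRUE)
          ch[side] <- cand[side]
          ct[!side] <- cand[!side]
          bad <- paste(ents[ch], triplets$relation[bidx], ents[ct]) %in%
            pos_keys
          tries <- 0L
          while (any(bad)) {
            tries <- tries + 1L
            if (tries > 100L) {
              stop("could not sample valid negative triplets after 100 ",
                   "retries (knowledge graph too densely connected)")
            }
            w <- which(bad)
            cand <- sample.int(length(ents), length(w), replace = TRUE)
            ch[w] <- ifelse(side[w], cand, hi[bidx][w])
            ct[w] <- ifelse(side[w], ti[bidx][w], cand)
            bad[w] <- paste(ents[ch[w]], triplets$relation[bidx][w],
                            ents[ct[w]]) %in% pos_keys
          }
          Hp <- E[hi[bidx], , drop = FALSE]
          Tp <- E[ti[bidx], , drop = FALSE]
          Rv <- R[ri[bidx], , drop = FALSE]
          Hn <- E[ch, , drop = FALSE]
          Tn <- E[ct, , drop = FALSE]
          dp <- Hp + Rv - Tp
          dn <- Hn + Rv - Tn
          if (cfg$norm == "L2") {
            ndp <- sqrt(rowSums(dp^2)); ndn <- sqrt(rowSums(dn^2))
            gp <- dp / pmax(ndp, 1e-12); gn <- dn / pmax(ndn, 1e-12)
          } else {
            ndp <- rowSums(abs(dp)); ndn <- rowSums(abs(dn))
            gp <- sign(dp); gn <- sign(dn)
          }
          viol <- cfg$margin + ndp - ndn > 0
          ep_loss <- ep_loss + sum(pmax(0, cfg$margin + ndp - ndn))
          if (any(viol)) {
            v <- which(viol)
            step <- cfg$lr
            # d loss/d(h+r-t) = gp for positives, -gn for negatives
            upd <- function(M, rows, G) {
              agg <- rowsum(G, rows)
              tgt <- as.integer(rownames(agg))
              M[tgt, ] <- M[tgt, ] - step * agg
              M
            }
            E <- upd(E, hi[bidx][v], gp[v, , drop = FALSE])
            E <- upd(E, ti[bidx][v], -gp[v, , drop = FALSE])
            R <- upd(R, ri[bidx][v], gp[v, , drop = FALSE] -
                       gn[v, , drop = FALSE])
            E <- upd(E, ch[v], -gn[v, , drop = FALSE])
            E <- upd(E, ct[v], gn[v, , drop = FALSE])
          }
        }
      }
      E <- l2norm(E)
      trace[ep] <- ep_loss / (n * cfg$negatives_per_positive)
    }
    structure(list(entities = E, relations = R, loss_trace = trace,
                   cfg = cfg), class = "transe_fit")
  })
}

#' Extract per-drug knowledge-graph embeddings
#'
#' Returns the trained entity vector for every drug; drugs absent from the
#' knowledge graph receive a zero vector and a warning.
#'
#' @param fit A `transe_fit`.
#' @param drug_ids Character vector of drug identifiers.
#' @return A matrix with one row per drug (rownames = `drug_ids`).
#' @export
extract_drug_kge <- function(fit, drug_ids) {
  stopifnot(inherits(fit, "transe_fit"))
  d <- ncol(fit$entities)
  out <- matrix(0, length(drug_ids), d, dimnames = list(drug_ids, NULL))
  present <- drug_ids %in% rownames(fit$entities)
  if (any(present)) {
    out[present, ] <- fit$entities[drug_ids[present], , drop = FALSE]
  }
  if (any(!present)) {
    warning("drug(s) absent from the knowledge graph, using zero vectors: ",
            paste(drug_ids[!present], collapse = ", "))
  }
  out
}

#' Mean rank of true tails under a TransE fit
#'
#' For each triplet, scores every entity as a candidate tail and records the
#' rank of the true tail (ties get the average rank). A random embedding
#' gives an expected mean rank of `(N_entities + 1) / 2`.
#'
#' @param fit A `transe_fit`.
#' @param triplets Tibble of triplets to rank (typically the training set).
#' @return Mean rank (numeric scalar).
#' @export
transe_mean_rank <- function(fit, triplets) {
  E <- fit$entities
  R <- fit$relations
  ranks <- vapply(seq_len(nrow(triplets)), function(i) {
    h <- E[triplets$head[i], ]
    r <- R[triplets$relation[i], ]
    pred <- h + r
    dists <- sqrt(colSums((t(E) - pred)^2))
    rank(dists)[[triplets$tail[i]]]
  }, numeric(1))
  mean(ranks)
}

#' @export
print.transe_fit <- function(x, ...) {
  cat("<transe_fit> ", nrow(x$entities), " entities, ", nrow(x$relations),
      " relations, dim ", ncol(x$entities), "; final epoch loss ",
      signif(utils::tail(x$loss_trace, 1), 4), "\n", sep = "")
  invisible(x)
}
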