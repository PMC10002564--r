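# SMILES notation embedding: character-level tokenization (with the
# two-character organic-subset halogens and bracket atoms kept whole), a CBOW
# word-embedding model trained with full-softmax cross-entropy, and the
# fold/pad rule that turns a variable-length token embedding into a fixed
# 100 x dim_sne matrix per drug.

#' Tokenize a SMILES string
#'
#' Character-level tokens, except that the two-character element symbols
#' `Cl` and `Br` and whole bracket atoms (`[...]`) are emitted as single
#' tokens.
#'
#' @param s A non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("CCO")
#' tokenize_smiles("C[NH4+]C")
#' @export
tokenize_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop("SMILES must be a single non-empty string")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: ", s)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop("unbalanced bracket in SMILES: ", s)
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] == "r" ||
               ch == "C" && i < n && chars[i + 1L] == "l") {
      # Cl and Br; note "Cr" is not an organic-subset symbol, so only Br
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        tokens <- c(tokens, two)
        i <- i + 2L
      } else {
        tokens <- c(tokens, ch)
        i <- i + 1L
      }
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Configuration for the CBOW notation embedder
#'
#' @param dim_sne Embedding width `u`.
#' @param window Context half-width; the window is truncated at sequence
#'   boundaries.
#' @param lr Learning rate.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return A `w2v_config` list.
#' @export
w2v_config <- function(dim_sne = 64, window = 5, lr = 0.025, epochs = 50,
                       seed = 1) {
  stopifnot(dim_sne >= 1, window >= 1, lr > 0, epochs >= 1)
  structure(list(dim_sne = as.integer(dim_sne), window = as.integer(window),
                 lr = lr, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "w2v_config")
}

#' CBOW forward pass
#'
#' The mean of the context tokens' input-embedding rows is projected by the
#' output matrix and softmax-normalized into a probability vector over the
#' vocabulary.
#'
#' @param context_indices Integer indices (1-based rows of `W1`) of the
#'   context tokens; must be non-empty.
#' @param W1 Input embedding matrix (`v x u`).
#' @param W2 Output matrix (`u x v`).
#' @return Probability vector of length `v` (sums to 1).
#' @export
cbow_forward <- function(context_indices, W1, W2) {
  if (length(context_indices) == 0L) stop("context must be non-empty")
  h <- colMeans(W1[context_indices, , drop = FALSE])
  z <- drop(h %*% W2)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Train the CBOW notation embedder
#'
#' Minimizes the summed cross-entropy between each token's one-hot label and
#' the softmax prediction from its context mean, by plain SGD over all
#' (token, context) positions. The input embedding matrix `W1` is the
#' notation embedding used downstream.
#'
#' @param corpus List of token vectors (from [tokenize_smiles()]).
#' @param cfg A [w2v_config()].
#' @return A `cbow_fit`: list with `W1` (v x u, rownames = tokens), `W2`,
#'   `vocab` (token -> index tibble), `loss_trace`, `cfg`.
#' @export
train_cbow <- function(corpus, cfg = w2v_config()) {
  stopifnot(length(corpus) >= 1L)
  tokens <- unique(unlist(corpus))
  v <- length(tokens)
  u <- cfg$dim_sne
  seqs <- lapply(corpus, function(tk) match(tk, tokens))

  # precompute all training positions: target index + context indices
  w <- cfg$window
  positions <- list()
  for (s in seqs) {
    L <- length(s)
    if (L < 2L) next
    for (j in seq_len(L)) {
      ctx <- s[max(1L, j - w):min(L, j + w)][-(j - max(1L, j - w) + 1L)]
      positions[[length(positions) + 1L]] <- list(y = s[j], ctx = ctx)
    }
  }

  with_local_seed(cfg$seed, {
    W1 <- matrix(stats::runif(v * u, -0.5 / u, 0.5 / u), v, u)
    W2 <- matrix(0, u, v)
    rownames(W1) <- tokens
    np <- length(positions)
    trace <- numeric(cfg$epochs)
    if (np > 0L) {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(np)
        loss <- 0
        for (k in ord) {
          pos <- positions[[k]]
          h <- colMeans(W1[pos$ctx, , drop = FALSE])
          z <- drop(h %*% W2)
          z <- z - max(z)
          e <- exp(z)
          p <- e / sum(e)
          loss <- loss - log(max(p[pos$y], 1e-12))
          dz <- p
          dz[pos$y] <- dz[pos$y] - 1
          dh <- drop(W2 %*% dz)
          W2 <- W2 - cfg$lr * tcrossprod(h, dz)
          W1[pos$ctx, ] <- W1[pos$ctx, , drop = FALSE] -
            matrix(cfg$lr * dh / length(pos$ctx), length(pos$ctx), u,
                   byrow = TRUE)
        }
        trace[ep] <- loss / np
      }
    }
    vocab <- tibble::tibble(token = tokens, index = seq_len(v))
    structure(list(W1 = W1, W2 = W2, vocab = vocab, loss_trace = trace,
                   cfg = cfg), class = "cbow_fit")
  })
}

#' Embed a token sequence
#'
#' Row `j` of the result is the `W1` row of token `j` (the one-hot product
#' identity). Out-of-vocabulary tokens yield a zero row with a warning.
#'
#' @param tokens Character vector of tokens.
#' @param W1 Embedding matrix with token rownames, or a `cbow_fit`.
#' @param vocab Optional token vocabulary tibble (ignored when `W1` is a
#'   fit).
#' @return A `length(tokens) x u` matrix.
#' @export
embed_sequence <- function(tokens, W1, vocab = NULL) {
  if (inherits(W1, "cbow_fit")) W1 <- W1$W1
  u <- ncol(W1)
  if (length(tokens) == 0L) return(matrix(0, 0L, u))
  idx <- match(tokens, rownames(W1))
  out <- matrix(0, length(tokens), u)
  known <- !is.na(idx)
  out[known, ] <- W1[idx[known], , drop = FALSE]
  if (any(!known)) {
    warning("out-of-vocabulary token(s), using zero rows: ",
            paste(unique(tokens[!known]), collapse = ", "))
  }
  out
}

#' Fold or pad a sequence embedding to a fixed 100 rows
#'
#' Sequences of at most 100 rows are zero-padded. Longer sequences are cut
#' into consecutive chunks of 100 rows (the last chunk may be shorter) and
#' averaged position-wise over the chunks that actually contain a row at that
#' offset, so padding never dilutes real signal.
#'
#' @param mat A `len x u` matrix.
#' @param target Output length (100).
#' @return A `target x u` matrix.
#' @export
fold_and_pad <- function(mat, target = 100L) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  u <- ncol(mat)
  len <- nrow(mat)
  out <- matrix(0, target, u)
  if (len == 0L) return(out)
  if (len <= target) {
    out[seq_len(len), ] <- mat
    return(out)
  }
  counts <- numeric(target)
  for (start in seq(1L, len, by = target)) {
    chunk <- mat[start:min(start + target - 1L, len), , drop = FALSE]
    k <- nrow(chunk)
    out[seq_len(k), ] <- out[seq_len(k), , drop = FALSE] + chunk
    counts[seq_len(k)] <- counts[seq_len(k)] + 1
  }
  out / pmax(counts, 1)
}

#' Notation embeddings for a set of drugs
#'
#' Tokenizes every SMILES, embeds it with a trained CBOW model and applies
#' [fold_and_pad()], returning one `100 x u` block per drug stacked into a
#' single matrix.
#'
#' @param drugs Tibble `(drug_id, smiles)`.
#' @param fit A `cbow_fit`.
#' @param target Rows per drug (100).
#' @return A `(n_drugs*target) x u` matrix; block `i` holds drug `i` in the
#'   order of `drugs$drug_id`.
#' @export
drug_notation_embeddings <- function(drugs, fit, target = 100L) {
  blocks <- lapply(drugs$smiles, function(s) {
    fold_and_pad(embed_sequence(tokenize_smiles(s), fit), target)
  })
  do.call(rbind, blocks)
}

#' @export
print.cbow_fit <- function(x, ...) {
  cat("<cbow_fit> vocabulary ", nrow(x$W1), ", dim ", ncol(x$W1),
      "; final epoch loss ", signif(utils::tail(x$loss_trace, 1), 4),
      "\n", sep = "")
  invisible(x)
}
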