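# Brute-force metric oracles shared by the unit and acceptance tests.

# O(n^2) concordant-pair AUC oracle
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# threshold-loop average-precision oracle
aupr_bruteforce <- function(y, s) {
  P <- sum(y == 1)
  if (P == 0) return(NA_real_)
  th <- sort(unique(s), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- s >= t
    tp <- sum(y[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

macro_f1_bruteforce <- function(truth, pred, Nl) {
  mean(vapply(0:(Nl - 1), function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (tp == 0 && (fp > 0 || fn > 0)) return(0)
    if (tp == 0) return(0)   # class absent from truth and prediction
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1)))
}

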