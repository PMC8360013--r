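# Independent brute-force oracles shared across test files.

# AUC by explicit enumeration of positive/negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# TSS by exhaustive scan of thresholds just below/above every score.
brute_tss <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u - 1e-9, u + 1e-9)
  best <- -Inf
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Poisson-binomial pmf by full 2^n outcome enumeration.
enum_poisbinom <- function(p) {
  n <- length(p)
  bits <- vapply(0:(2^n - 1),
                 function(m) as.integer(intToBits(m))[1:n],
                 integer(n))
  bits <- if (n == 1) matrix(bits, nrow = 1) else bits
  prob <- apply(bits * p + (1 - bits) * (1 - p), 2, prod)
  as.vector(tapply(prob, colSums(bits), sum))
}
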