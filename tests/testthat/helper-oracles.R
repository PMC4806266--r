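# Independent oracles kept free of package code paths.

# Brute-force symmetric K-L divergence: shared equal-width bins via cut(),
# add-one smoothing, explicit two-term sum.
brute_kl <- function(pos, neg, n_bins) {
  pooled <- c(pos, neg)
  if (max(pooled) == min(pooled)) return(0)
  breaks <- seq(min(pooled), max(pooled), length.out = n_bins + 1)
  cp <- as.vector(table(cut(pos, breaks, include.lowest = TRUE))) + 1
  cq <- as.vector(table(cut(neg, breaks, include.lowest = TRUE))) + 1
  p <- cp / sum(cp)
  q <- cq / sum(cq)
  d1 <- 0; d2 <- 0
  for (b in seq_len(n_bins)) {
    d1 <- d1 + p[b] * log(p[b] / q[b])
    d2 <- d2 + q[b] * log(q[b] / p[b])
  }
  d1 + d2
}

# Direct transcription of the confusion-matrix metric definitions.
direct_metrics <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  list(sn = div(tp, tp + fn), sp = div(tn, tn + fp),
       acc = div(tp + tn, tp + tn + fp + fn),
       mcc = {
         d <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
         if (d == 0) 0 else (tp * tn - fp * fn) / d
       })
}

# Exhaustive search over all non-empty masks of n bits for a given
# evaluator; returns the maximum fitness.
exhaustive_best <- function(evaluator, n) {
  best <- -Inf
  for (m in seq_len(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    best <- max(best, evaluator(bits, 1, 1))
  }
  best
}
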