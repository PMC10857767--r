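# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force count of admissible Haar (period, support, shift) triples:
# periods are powers of two in [2, N]; supports are power-of-two multiples
# of the period up to N; shifts are multiples of the support that keep the
# support inside the window.
bruteHaarCount <- function(N) {
  count <- 0L
  for (period in 2^(1:log2(N))) {
    support <- period
    while (support <= N) {
      for (shift in seq(0L, N, by = support)) {
        if (shift + support <= N) count <- count + 1L
      }
      support <- support * 2L
    }
  }
  count
}

# Exhaustive minimum number of extractors (machines) for a set of
# [start, end) intervals: try every assignment of intervals to at most k
# machines, increasing k until one is feasible. Only for tiny instances.
bruteMinExtractors <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(0L)
  feasible <- function(assign, k) {
    for (m in seq_len(k)) {
      idx <- which(assign == m)
      if (length(idx) > 1L) {
        o <- idx[order(start[idx])]
        if (any(start[o][-1L] < end[o][-length(o)])) return(FALSE)
      }
    }
    TRUE
  }
  for (k in seq_len(n)) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    for (r in seq_len(nrow(grid))) {
      if (feasible(grid[r, ], k)) return(k)
    }
  }
  n
}

# Direct recount of all confusion-matrix metrics from prediction/label
# pairs (binary; positive class = second level).
bruteBinaryMetrics <- function(truth, pred) {
  pos <- levels(truth)[2L]
  tp <- sum(truth == pos & pred == pos)
  tn <- sum(truth != pos & pred != pos)
  fp <- sum(truth != pos & pred == pos)
  fn <- sum(truth == pos & pred != pos)
  den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       mcc = if (any(den == 0)) 0 else
         (tp * tn - fp * fn) / sqrt(prod(den)))
}

# Hand entropy in bits.
entropyBits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# A toy interval wavelet: haar with period 2 so any even support works.
intervalWavelet <- function(support, shift, windowLen = 64L, fs = 10) {
  wavelet("haar", 2L, support, shift, windowLen, fs)
}

intervalSpec <- function(support, shift, windowLen = 64L)
  featureSpec(1L, intervalWavelet(support, shift, windowLen))

# Small linearly separable two-class feature matrix for classifier tests.
separableXY <- function(n = 60L, seed = 1L) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(ifelse(y == "b", 3, -3) + rnorm(n, 0, 0.2),
             rnorm(n, 0, 0.2))
  list(X = X, y = y)
}
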