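# Independent oracles and small utilities used across test files.

# Mann-Whitney style auROC: fraction of (positive, negative) bin pairs where
# the positive bin's activity exceeds the negative's (ties count 1/2).
pairwise_auroc <- function(z, behavior) {
  zp <- z[behavior == 1]
  zn <- z[behavior == 0]
  cmp <- outer(zp, zn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Direct term-by-term G evaluation from a raw label vector.
g_by_hand <- function(labels) {
  states <- sort(unique(labels))
  from <- factor(labels[-length(labels)], levels = states)
  to <- factor(labels[-1], levels = states)
  O <- table(from, to)
  N <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / N
  g <- 0
  for (i in seq_along(states)) {
    for (j in seq_along(states)) {
      if (O[i, j] > 0) g <- g + O[i, j] * log(O[i, j] / E[i, j])
    }
  }
  2 * g
}

chars <- function(s) strsplit(s, "")[[1]]

# Frame-level F1 of a detection against ground truth.
f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
}
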