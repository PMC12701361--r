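# Independent brute-force oracles. These deliberately share no code with the
# package: the enrichment oracle walks the full running sum position by
# position, the tau-b oracle enumerates every pair, and the BH oracle is the
# textbook sort/cummin construction.

# Full O(N) running-sum enrichment score on an already-sorted ranking.
es_bruteforce <- function(stats_sorted, geneset, weight = 1) {
  genes <- names(stats_sorted)
  inset <- genes %in% geneset
  N <- length(genes)
  n <- sum(inset)
  w <- abs(stats_sorted)^weight
  wsum <- sum(w[inset])
  if (wsum <= 0) {
    w[inset] <- 1
    wsum <- n
  }
  running <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    running <- running + if (inset[i]) unname(w[i]) / wsum else -1 / (N - n)
    if (running > best_pos) best_pos <- running
    if (running < best_neg) best_neg <- running
  }
  # ties between extrema resolve to the positive side (same rule as the
  # implementation under test, applied with a float-noise tolerance)
  if (best_pos + 1e-12 >= -best_neg) best_pos else best_neg
}

# Tau-b by exhaustive pair enumeration.
taub_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  nx <- sum(choose(table(x), 2))
  ny <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - nx) * (n0 - ny))
}

# Textbook Benjamini-Hochberg step-up.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Tiny random ranked list with unique statistics.
random_ranked <- function(n, seed) {
  withr::with_seed(seed, {
    stats <- round(rnorm(n), 3) + seq_len(n) * 1e-6   # break exact ties
    sort(setNames(stats, paste0("g", seq_len(n))), decreasing = TRUE)
  })
}
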