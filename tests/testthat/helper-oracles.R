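# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration is digit arithmetic, components are
# a hand-rolled union-find over a full pairwise distance matrix.

# Exhaustive enumeration of all C^n equally likely outcome tuples; returns
# the exact probabilities that a fixed UMI is hit 0, 1, or >= 2 times.
enum_collision_probs <- function(C, n) {
  C <- unname(C)
  n <- unname(n)
  total <- C^n
  stopifnot(total <= 2^26)  # keep the enumeration honest but bounded
  idx <- seq(0, total - 1)
  hits <- numeric(total)
  for (p in seq_len(n) - 1) hits <- hits + (floor(idx / C^p) %% C == 0)
  c(p_zero = sum(hits == 0) / total,
    p_one = sum(hits == 1) / total,
    p_multi = sum(hits >= 2) / total)
}

# Pairwise Hamming distance matrix via character matrices (no package code).
bf_hamming_matrix <- function(umis) {
  chars <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  n <- length(umis)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(chars[i, ] != chars[j, ])
  d
}

# Connected components of the distance <= 1 graph by union-find.
bf_cluster_count <- function(umis) {
  n <- length(umis)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  d <- bf_hamming_matrix(umis)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= 1L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

random_umis <- function(n, L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# one-species reference whose molecules all share a single dedup group
single_group_reference <- function(seed = 1) {
  build_reference(1, abundance_skew = 0, seed = seed, canonical_only = TRUE,
                  multilocus_frac = 0)
}
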