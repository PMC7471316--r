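#' UMI pool complexity
#'
#' Number of distinct UMI sequences of length `L` over the DNA alphabet,
#' `C = 4^L`. For example `L = 4` gives 256, `L = 8` gives 65,536 and
#' `L = 12` gives 16,777,216.
#'
#' @param L UMI length in nucleotides (integer >= 1).
#' @return The pool complexity `4^L` as a double (exact for `L <= 26`).
#' @examples
#' pool_complexity(8)  # 65536
#' @export
pool_complexity <- function(L) {
  L <- as.numeric(L)
  if (length(L) == 0L || any(is.na(L)) || any(L < 1) || any(L != floor(L)))
    stop("'L' must be a positive integer (UMI length in nt)")
  4^L
}

#' Closed-form UMI collision probabilities
#'
#' Occupancy ("birthday") probabilities for a fixed UMI when `n` molecules
#' each draw a UMI uniformly at random, with replacement, from the pool of
#' `C = 4^L` sequences:
#' \deqn{p_0 = ((C-1)/C)^n, \quad
#'       p_1 = n \frac{1}{C} ((C-1)/C)^{n-1}, \quad
#'       P = 1 - p_0 - p_1,}
#' where `P` is the probability that the UMI is attached to two or more
#' distinct molecules, so that de-duplication on UMI identity would merge
#' them. `expected_multi = P * C` is the expected number of UMIs sampled
#' multiply; `expected_unique = C * (1 - p_0)` the expected number of
#' distinct UMIs seen at all. Powers are evaluated in log space so the
#' result is stable for large `n` and `C`.
#'
#' @param L UMI length in nucleotides.
#' @param n Number of molecules drawing UMIs (vectorised, each >= 0).
#' @return A data.frame with one row per `n` and columns `L`, `C`, `n`,
#'   `p_zero`, `p_one`, `p_multi`, `expected_unique`, `expected_multi`.
#' @examples
#' collision_stats(8, 10000)$expected_multi  # ~689.5
#' @seealso [expected_unique()], [simulate_saturation()]
#' @export
collision_stats <- function(L, n) {
  C <- pool_complexity(L)
  n <- as.numeric(n)
  if (any(is.na(n)) || any(n < 0)) stop("'n' must be >= 0")
  log_q <- log1p(-1 / C)              # log((C-1)/C)
  p_zero <- exp(n * log_q)
  p_one <- ifelse(n == 0, 0, exp(log(pmax(n, 1)) - log(C) + (n - 1) * log_q))
  p_multi <- pmax(0, 1 - p_zero - p_one)
  data.frame(
    L = L, C = C, n = n,
    p_zero = p_zero, p_one = p_one, p_multi = p_multi,
    expected_unique = C * -expm1(n * log_q),
    expected_multi = p_multi * C
  )
}

#' Expected number of distinct UMIs after n draws
#'
#' `C * (1 - ((C-1)/C)^n)`: the mean of the unique-UMI count that the
#' saturation simulation estimates. When `n << C` this approaches `n`
#' (every molecule uniquely tagged); when `n >> C` it approaches `C`
#' (every UMI in the pool used at least once).
#'
#' @inheritParams collision_stats
#' @return Numeric vector, one value per `n`.
#' @export
expected_unique <- function(L, n) {
  C <- pool_complexity(L)
  n <- as.numeric(n)
  if (any(is.na(n)) || any(n < 0)) stop("'n' must be >= 0")
  C * -expm1(n * log1p(-1 / C))
}

#' Monte-Carlo simulation of UMI saturation
#'
#' Simulates ligating UMIs to molecules: per round, `n` draws uniformly with
#' replacement from the pool of `4^L` UMIs (drawn as integer indices — the
#' pool itself is never materialised, so large `L` costs no memory), then
#' counts distinct UMIs and UMIs seen with multiplicity >= 2. Round `r`
#' reseeds the generator with `seed + r`, so results are reproducible and
#' independent of grid order.
#'
#' @param L UMI length in nucleotides.
#' @param n_grid Vector of draw counts to simulate (each >= 1).
#' @param rounds Simulation rounds per grid point (default 100).
#' @param seed Integer seed.
#' @return An object of class `saturation_sim`: list with `summary` (a
#'   data.frame with per-`n` means, SDs, standard errors and the analytic
#'   expectations), matrices `unique` and `multi` (`rounds` x
#'   `length(n_grid)`), and `L`, `rounds`, `seed`.
#' @examples
#' sim <- simulate_saturation(4, c(100, 500), rounds = 20, seed = 1)
#' sim$summary
#' @export
simulate_saturation <- function(L, n_grid, rounds = 100, seed = 1) {
  C <- pool_complexity(L)
  n_grid <- as.numeric(n_grid)
  if (any(n_grid < 1)) stop("'n_grid' entries must be >= 1")
  if (rounds < 1) stop("'rounds' must be >= 1")
  uniq <- multi <- matrix(NA_real_, nrow = rounds, ncol = length(n_grid))
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    for (j in seq_along(n_grid)) {
      draws <- sample.int(C, n_grid[j], replace = TRUE)
      runs <- rle(sort(draws))$lengths
      uniq[r, j] <- length(runs)
      multi[r, j] <- sum(runs >= 2)
    }
  }
  summary <- data.frame(
    L = L, n = n_grid,
    mean_unique = colMeans(uniq),
    sd_unique = apply(uniq, 2, stats::sd),
    se_unique = apply(uniq, 2, stats::sd) / sqrt(rounds),
    mean_multi = colMeans(multi),
    sd_multi = apply(multi, 2, stats::sd),
    se_multi = apply(multi, 2, stats::sd) / sqrt(rounds),
    expected_unique = expected_unique(L, n_grid),
    expected_multi = collision_stats(L, n_grid)$expected_multi
  )
  structure(list(summary = summary, unique = uniq, multi = multi,
                 L = L, rounds = rounds, seed = seed),
            class = "saturation_sim")
}

#' @export
print.saturation_sim <- function(x, ...) {
  cat(sprintf("UMI saturation simulation: L = %d (C = %s), %d rounds, seed %d\n",
              x$L, format(pool_complexity(x$L), big.mark = ","),
              x$rounds, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Effective UMI pool under single-mismatch merging
#'
#' When de-duplication merges UMIs within Hamming distance 1, two UMIs only
#' remain distinguishable if they differ in at least two positions. The
#' largest such set of length-`L` DNA words is a 4-ary code of minimum
#' distance 2; the parity-check construction (first `L - 1` symbols free,
#' last symbol their sum mod 4) attains the Singleton bound `4^(L-1)`.
#' For `L = 8` the effective pool is therefore 16,384 instead of 65,536.
#'
#' @param L UMI length in nucleotides.
#' @return The effective pool size `4^(L-1)` (1 for `L = 1`).
#' @seealso [parity_check_code()] for an explicit witness code.
#' @export
effective_pool_hamming1 <- function(L) {
  L <- as.numeric(L)
  if (any(L < 1) || any(L != floor(L))) stop("'L' must be a positive integer")
  4^(L - 1)
}

#' Witness code for the effective pool size
#'
#' Materialises codewords of the length-`L` parity-check code over
#' \{A,C,G,T\}: index `i` in `0 .. 4^(L-1) - 1` is written in base 4 as the
#' first `L - 1` symbols and the final symbol is their sum mod 4. Any two
#' distinct codewords are at Hamming distance >= 2: if they differ in one
#' free position they must also differ in the checksum.
#'
#' @param L UMI length in nucleotides (>= 1).
#' @param indices 0-based codeword indices in `[0, 4^(L-1))`; default all
#'   (only allowed for `L <= 8`).
#' @return Character vector of codewords (DNA strings of length `L`).
#' @export
parity_check_code <- function(L, indices = NULL) {
  if (L < 1 || L != floor(L)) stop("'L' must be a positive integer")
  size <- 4^(L - 1)
  if (is.null(indices)) {
    if (L > 8) stop("refusing to materialise ", size,
                    " codewords; pass explicit 'indices'")
    indices <- seq_len(size) - 1
  }
  indices <- as.numeric(indices)
  if (any(indices < 0) || any(indices >= size))
    stop("'indices' must lie in [0, 4^(L-1))")
  alphabet <- c("A", "C", "G", "T")
  digits <- matrix(0, nrow = length(indices), ncol = max(L - 1, 0))
  rem <- indices
  for (pos in seq_len(L - 1)) {          # most-significant digit first
    div <- 4^(L - 1 - pos)
    digits[, pos] <- floor(rem / div)
    rem <- rem %% div
  }
  checksum <- if (L > 1) rowSums(digits) %% 4 else rep(0, length(indices))
  words <- cbind(digits, checksum)
  apply(words, 1, function(d) paste(alphabet[d + 1], collapse = ""))
}

#' Minimal UMI length for a tolerated de-duplication loss
#'
#' Scans UMI lengths upward and returns the smallest `L` for which the
#' expected fraction of molecules lost to UMI collisions,
#' `1 - expected_unique(L, n) / n`, does not exceed `max_distortion`.
#' With `n` around 10^6 molecules per group and a 5% tolerance this lands
#' at 12 nt, the regime in which longer commercial UMIs operate.
#'
#' @param max_molecules Largest expected number of molecules sharing a
#'   de-duplication group (positive).
#' @param max_distortion Tolerated fractional undercount in (0, 1].
#' @param L_max Largest length scanned (default 32).
#' @return The minimal adequate UMI length (integer).
#' @export
recommend_umi_length <- function(max_molecules, max_distortion, L_max = 32) {
  if (max_molecules < 1) stop("'max_molecules' must be positive")
  if (max_distortion <= 0 || max_distortion > 1)
    stop("'max_distortion' must be in (0, 1]")
  for (L in seq_len(L_max)) {
    loss <- 1 - expected_unique(L, max_molecules) / max_molecules
    if (loss <= max_distortion) return(L)
  }
  stop("no UMI length up to ", L_max, " nt meets the tolerance")
}
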