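#' Hamming distance between equal-length sequences
#'
#' Number of mismatching positions. Vectorised over pairs; recycles the
#' shorter argument.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of distances.
#' @examples
#' hamming("ACGT", "TGCA")  # 4
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("Hamming distance requires equal-length sequences")
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

# all Hamming-1 neighbours of each UMI that are present in `universe`;
# returns a two-column matrix of indices into `universe` (i < j)
umi_h1_edges <- function(universe) {
  L <- nchar(universe[1L])
  from <- to <- list()
  k <- 0L
  for (pos in seq_len(L)) {
    for (base in DNA_BASES) {
      neigh <- universe
      substr(neigh, pos, pos) <- base
      j <- match(neigh, universe)
      keep <- !is.na(j) & j > seq_along(universe)  # dedupe + drop self
      if (any(keep)) {
        k <- k + 1L
        from[[k]] <- seq_along(universe)[keep]
        to[[k]] <- j[keep]
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), ncol = 2L))
  cbind(unlist(from), unlist(to))
}

#' De-duplicate one UMI group
#'
#' Collapses the UMIs observed for one grouping key (one isomiR, or one
#' insert sequence) into an estimated molecule count.
#'
#' * `threshold = 0` (or `method = "unique"`): the number of distinct UMIs.
#' * `threshold = 1, method = "cluster"`: the number of connected
#'   components of the graph joining UMIs at Hamming distance <= 1 —
#'   worst-case merging, equivalent to the "effective pool" arithmetic.
#' * `threshold = 1, method = "directional"`: count-aware merging in which
#'   node `u` may absorb neighbour `v` only when
#'   `count(u) >= 2 * count(v) - 1`; clusters are grown from nodes in
#'   descending count (ties broken lexicographically), and the result is
#'   the number of clusters. This asymmetry stops two genuinely distinct
#'   molecules of similar abundance from being merged, while still
#'   absorbing low-count PCR/sequencing-error satellites.
#'
#' @param umi_counts Named integer vector: UMI sequence -> read count.
#' @param threshold Hamming-distance threshold, 0 or 1.
#' @param method One of `"directional"`, `"cluster"`, `"unique"`
#'   (ignored when `threshold = 0`).
#' @return The de-duplicated molecule count (integer >= 1).
#' @examples
#' dedup_group(c(AAAA = 5, AAAT = 1, CCCC = 3), threshold = 1,
#'             method = "cluster")  # 2
#' @export
dedup_group <- function(umi_counts, threshold = 0,
                        method = c("directional", "cluster", "unique")) {
  method <- match.arg(method)
  if (length(umi_counts) == 0L) stop("empty UMI group")
  umis <- names(umi_counts)
  if (is.null(umis) || length(unique(nchar(umis))) != 1L)
    stop("'umi_counts' must be named by UMIs of one common length")
  if (!threshold %in% c(0, 1)) stop("'threshold' must be 0 or 1")
  if (threshold == 0 || method == "unique" || length(umi_counts) == 1L)
    return(length(umi_counts))
  if (method == "cluster") {
    edges <- umi_h1_edges(umis)
    if (nrow(edges) == 0L) return(length(umis))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(umis) - igraph::vcount(g)))
    return(as.integer(igraph::components(g)$no))
  }
  dedup_directional(umi_counts)
}

# UMI-tools-style directional adjacency collapse
dedup_directional <- function(umi_counts) {
  umis <- names(umi_counts)
  counts <- as.numeric(umi_counts)
  ord <- order(-counts, umis)
  edges <- umi_h1_edges(umis)
  adj <- vector("list", length(umis))
  if (nrow(edges) > 0L) {
    adj_split <- split(c(edges[, 2L], edges[, 1L]),
                       factor(c(edges[, 1L], edges[, 2L]),
                              levels = seq_along(umis)))
    adj <- unname(adj_split)
  }
  assigned <- rep(FALSE, length(umis))
  queue <- integer(length(umis))  # every node enters the queue exactly once
  head <- 1L
  tail <- 0L
  n_clusters <- 0L
  for (seed_node in ord) {
    if (assigned[seed_node]) next
    n_clusters <- n_clusters + 1L
    assigned[seed_node] <- TRUE
    tail <- tail + 1L
    queue[tail] <- seed_node
    while (head <= tail) {
      u <- queue[head]
      head <- head + 1L
      nb <- adj[[u]]
      nb <- nb[!assigned[nb] & counts[u] >= 2 * counts[nb] - 1]
      if (length(nb) > 0L) {
        assigned[nb] <- TRUE
        queue[(tail + 1L):(tail + length(nb))] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  n_clusters
}

#' De-duplicate a processed-read library
#'
#' Groups pass-status reads by isomiR (exact insert match against the
#' expanded reference repertoire — the stand-in for genome alignment in
#' this synthetic pipeline) or by raw insert sequence, then applies
#' [dedup_group()] per group. Reads whose insert matches no reference
#' isomiR are dropped and reported in the `unmatched` attribute.
#'
#' @param reads data.frame of processed reads (`umi`, `insert`, `status`);
#'   only `status == "pass"` rows are used.
#' @param reference `smrna_reference`, required for `grouping = "isomir"`.
#' @param grouping `"isomir"` or `"insert"`.
#' @param threshold,method Passed to [dedup_group()].
#' @return data.frame of class `dedup_result`: grouping-key columns plus
#'   `raw_reads`, `dedup_count`, `threshold`, `method`; attribute
#'   `unmatched` holds the dropped-read count.
#' @export
dedup_library <- function(reads, reference = NULL,
                          grouping = c("isomir", "insert"), threshold = 0,
                          method = c("directional", "cluster", "unique")) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  reads <- reads[reads$status == "pass", , drop = FALSE]
  unmatched <- 0L
  if (grouping == "isomir") {
    stopifnot(inherits(reference, "smrna_reference"))
    iso_idx <- match(reads$insert, reference$isomirs$insert)
    unmatched <- sum(is.na(iso_idx))
    reads <- reads[!is.na(iso_idx), , drop = FALSE]
    iso_idx <- iso_idx[!is.na(iso_idx)]
    keys <- reference$isomirs[iso_idx, c("mirna_id", "start_offset",
                                         "end_offset")]
    key_str <- paste(keys$mirna_id, keys$start_offset, keys$end_offset,
                     sep = "\r")
  } else {
    keys <- reads[, "insert", drop = FALSE]
    key_str <- reads$insert
  }
  if (nrow(reads) > 0L && length(unique(nchar(reads$umi))) != 1L)
    stop("mixed UMI lengths in library")
  key_f <- factor(key_str, levels = unique(key_str))
  umi_by_group <- split(reads$umi, key_f)
  dedup <- vapply(umi_by_group, function(u) {
    tab <- table(u)
    as.integer(dedup_group(stats::setNames(as.integer(tab), names(tab)),
                           threshold, method))
  }, integer(1))
  first <- !duplicated(key_f)
  out <- data.frame(keys[first, , drop = FALSE],
                    raw_reads = as.integer(tabulate(key_f)),
                    dedup_count = dedup,
                    threshold = threshold,
                    method = if (threshold == 0) "unique" else method,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(key_f[first]), , drop = FALSE]
  attr(out, "unmatched") <- unmatched
  class(out) <- c("dedup_result", "data.frame")
  out
}

#' UMI duplication-frequency profile
#'
#' For every (group, UMI) pair, its read multiplicity; the histogram of
#' multiplicities reveals whether a library has been over-sequenced
#' (median multiplicity well above 1) or whether under-counting stems from
#' UMI pool exhaustion instead.
#'
#' @inheritParams dedup_library
#' @return List with `histogram` (data.frame `multiplicity`, `n_umis`)
#'   and `median_multiplicity`.
#' @export
duplication_profile <- function(reads, reference = NULL,
                                grouping = c("isomir", "insert")) {
  grouping <- match.arg(grouping)
  reads <- reads[reads$status == "pass", , drop = FALSE]
  if (grouping == "isomir") {
    stopifnot(inherits(reference, "smrna_reference"))
    iso_idx <- match(reads$insert, reference$isomirs$insert)
    reads <- reads[!is.na(iso_idx), , drop = FALSE]
    key <- paste(iso_idx[!is.na(iso_idx)], reads$umi, sep = "\r")
  } else {
    key <- paste(reads$insert, reads$umi, sep = "\r")
  }
  if (length(key) == 0L)
    return(list(histogram = data.frame(multiplicity = integer(0),
                                       n_umis = integer(0)),
                median_multiplicity = NA_real_))
  mult <- as.integer(table(key))
  tab <- table(mult)
  list(
    histogram = data.frame(multiplicity = as.integer(names(tab)),
                           n_umis = as.integer(tab)),
    median_multiplicity = as.numeric(stats::median(mult))
  )
}
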