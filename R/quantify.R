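#' Counts per million
#'
#' @param counts Non-negative numeric vector with positive total.
#' @return `counts * 1e6 / sum(counts)`; always sums to 1e6.
#' @examples
#' cpm(c(1, 1, 2))  # 250000 250000 500000
#' @export
cpm <- function(counts) {
  if (any(counts < 0)) stop("'counts' must be non-negative")
  total <- sum(counts)
  if (!is.finite(total) || total <= 0)
    stop("library total must be positive for CPM")
  counts * 1e6 / total
}

#' Build isomiR- and miRNA-level count tables
#'
#' Quantifies a processed-read library at the isomiR level (raw reads,
#' de-duplicated counts at Hamming thresholds 0 and 1, CPM for each), with
#' a per-miRNA rollup summing its isomiR rows. When the ground truth is
#' available (synthetic libraries) each row also carries `true_molecules`
#' and `fold_underestimate = true_molecules / dedup_h0`. CPM denominators
#' are computed within each column independently, since raw and
#' de-duplicated profiles are compared side by side.
#'
#' @param reads Processed reads (`umi`, `insert`, `status`) from
#'   [process_fastq()].
#' @param reference `smrna_reference` used for isomiR assignment.
#' @param truth Optional truth table from [truth_table()].
#' @param h1_method Merging method for the Hamming-1 columns
#'   (`"directional"` or `"cluster"`).
#' @return Object of class `count_table`: list with data.frames `isomir`
#'   (keyed by `mirna_id`, `start_offset`, `end_offset`) and `mirna`
#'   (keyed by `mirna_id`), each with columns `raw_reads`, `dedup_h0`,
#'   `dedup_h1`, `cpm_raw`, `cpm_h0`, `cpm_h1` and, with truth,
#'   `true_molecules` and `fold_underestimate`; attribute `unmatched`
#'   counts reads whose insert matched no reference isomiR.
#' @export
count_isomirs <- function(reads, reference, truth = NULL,
                          h1_method = c("directional", "cluster")) {
  h1_method <- match.arg(h1_method)
  h0 <- dedup_library(reads, reference, grouping = "isomir", threshold = 0)
  h1 <- dedup_library(reads, reference, grouping = "isomir", threshold = 1,
                      method = h1_method)
  key <- c("mirna_id", "start_offset", "end_offset")
  iso <- data.frame(h0[, key, drop = FALSE],
                    raw_reads = h0$raw_reads,
                    dedup_h0 = h0$dedup_count,
                    stringsAsFactors = FALSE)
  iso$dedup_h1 <- h1$dedup_count[match(
    do.call(paste, c(iso[key], sep = "\r")),
    do.call(paste, c(h1[key], sep = "\r"))
  )]
  if (!is.null(truth)) {
    iso <- merge(iso, truth, by = key, all = TRUE)
    zero <- c("raw_reads", "dedup_h0", "dedup_h1", "true_molecules")
    for (col in zero) iso[[col]][is.na(iso[[col]])] <- 0L
  }
  iso <- iso[order(iso$mirna_id, iso$start_offset, iso$end_offset), ]
  rownames(iso) <- NULL

  mir_cols <- setdiff(names(iso), c(key, "fold_underestimate"))
  mir <- stats::aggregate(iso[mir_cols], by = iso["mirna_id"], FUN = sum)
  mir <- mir[order(mir$mirna_id), ]
  rownames(mir) <- NULL

  add_derived <- function(df) {
    df$cpm_raw <- if (sum(df$raw_reads) > 0) cpm(df$raw_reads) else 0
    df$cpm_h0 <- if (sum(df$dedup_h0) > 0) cpm(df$dedup_h0) else 0
    df$cpm_h1 <- if (sum(df$dedup_h1) > 0) cpm(df$dedup_h1) else 0
    if (!is.null(df$true_molecules))
      df$fold_underestimate <- ifelse(df$dedup_h0 > 0,
                                      df$true_molecules / df$dedup_h0, NA)
    df
  }
  out <- list(isomir = add_derived(iso), mirna = add_derived(mir))
  attr(out, "unmatched") <- attr(h0, "unmatched")
  class(out) <- "count_table"
  out
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d isomiRs over %d miRNAs (%d unmatched reads)\n",
              nrow(x$isomir), nrow(x$mirna), attr(x, "unmatched")))
  utils::str(x$mirna, max.level = 1)
  invisible(x)
}

#' Aggregate multimapping reads across genomic loci
#'
#' Total expression of a multi-locus miRNA: the sum of its uniquely
#' mapping reads over all loci, plus the mean of the per-locus
#' multimapping read counts (each multimapper is reported at every locus
#' it maps to, so the mean — not the sum — counts it once).
#'
#' @param per_locus_counts data.frame with columns `mirna_id`, `locus`,
#'   `unique_reads`, `multi_reads` (one row per locus).
#' @param reference Optional `smrna_reference`; when given, every miRNA
#'   must have as many rows as annotated loci (`n_loci >= 1`).
#' @return data.frame `mirna_id`, `total_expression`; attribute `total`
#'   holds the sum over miRNAs.
#' @examples
#' aggregate_multimappers(data.frame(
#'   mirna_id = "mir-001", locus = 1:2,
#'   unique_reads = c(6, 4), multi_reads = c(8, 8)))  # 10 + 8 = 18
#' @export
aggregate_multimappers <- function(per_locus_counts, reference = NULL) {
  req <- c("mirna_id", "locus", "unique_reads", "multi_reads")
  if (!all(req %in% names(per_locus_counts)))
    stop("'per_locus_counts' needs columns ", paste(req, collapse = ", "))
  if (!is.null(reference)) {
    n_loci <- reference$mirnas$n_loci[
      match(unique(per_locus_counts$mirna_id), reference$mirnas$mirna_id)]
    if (any(is.na(n_loci) | n_loci == 0))
      stop("miRNA with no annotated locus (n_loci = 0)")
  }
  if (nrow(per_locus_counts) == 0L)
    stop("no loci to aggregate (n_loci = 0)")
  uniq <- stats::aggregate(unique_reads ~ mirna_id, per_locus_counts, sum)
  multi <- stats::aggregate(multi_reads ~ mirna_id, per_locus_counts, mean)
  out <- merge(uniq, multi, by = "mirna_id")
  out <- data.frame(mirna_id = out$mirna_id,
                    total_expression = out$unique_reads + out$multi_reads,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id), ]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$total_expression)
  out
}

#' Split per-miRNA counts into per-locus unique/multimapping counts
#'
#' Synthetic stand-in for an aligner's per-locus report: a single-locus
#' miRNA's reads all map uniquely; a multi-locus miRNA's reads map to
#' every locus and are reported as multimappers at each. Feeding the
#' result to [aggregate_multimappers()] recovers the input counts.
#'
#' @param mirna_counts data.frame with `mirna_id` and a count column
#'   (`count`).
#' @param reference `smrna_reference` carrying `n_loci`.
#' @return Per-locus data.frame for [aggregate_multimappers()].
#' @export
split_multimappers <- function(mirna_counts, reference) {
  stopifnot(inherits(reference, "smrna_reference"))
  n_loci <- reference$mirnas$n_loci[
    match(mirna_counts$mirna_id, reference$mirnas$mirna_id)]
  if (any(is.na(n_loci))) stop("unknown miRNA in 'mirna_counts'")
  idx <- rep(seq_len(nrow(mirna_counts)), times = n_loci)
  multi <- n_loci[idx] > 1L
  data.frame(
    mirna_id = mirna_counts$mirna_id[idx],
    locus = sequence(n_loci),
    unique_reads = ifelse(multi, 0, mirna_counts$count[idx]),
    multi_reads = ifelse(multi, mirna_counts$count[idx], 0),
    stringsAsFactors = FALSE
  )
}

#' Per-species distortion report
#'
#' Fold-underestimation per miRNA (or isomiR): `raw_reads / dedup_h0`,
#' plus `true_molecules / dedup_h0` when truth is available, and a
#' saturation flag marking species whose de-duplicated count approaches
#' the UMI pool size (`dedup_h0 >= saturation_frac * 4^umi_len`), i.e.
#' species for which the pool itself — not sequencing depth — limits the
#' count. The `raw_reads` vs `dedup_h0` columns are the scatter data for
#' a log-log raw-versus-deduplicated plot.
#'
#' @param counts A `count_table` from [count_isomirs()].
#' @param umi_len Total UMI length in nt (default 8).
#' @param level `"mirna"` or `"isomir"`.
#' @param saturation_frac Fraction of the pool at which a species is
#'   flagged saturated (default 0.5 — the expected unique-UMI count when
#'   molecules number ~0.7x the pool, where undercounting is already
#'   >1.4-fold).
#' @return data.frame with key columns, `raw_reads`, `dedup_h0`,
#'   `fold_vs_raw`, `fold_vs_truth` (NA without truth), `saturated`.
#' @export
distortion_report <- function(counts, umi_len = 8,
                              level = c("mirna", "isomir"),
                              saturation_frac = 0.5) {
  level <- match.arg(level)
  df <- counts[[level]]
  C <- pool_complexity(umi_len)
  out <- df[, setdiff(names(df), c("cpm_raw", "cpm_h0", "cpm_h1",
                                   "fold_underestimate")), drop = FALSE]
  out$fold_vs_raw <- ifelse(df$dedup_h0 > 0, df$raw_reads / df$dedup_h0, NA)
  out$fold_vs_truth <- if (!is.null(df$true_molecules))
    ifelse(df$dedup_h0 > 0, df$true_molecules / df$dedup_h0, NA)
  else NA_real_
  out$saturated <- df$dedup_h0 >= saturation_frac * C
  out[order(-out$raw_reads), , drop = FALSE]
}
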