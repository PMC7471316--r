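#' Trim the 3' sequencing adapter
#'
#' Exact-match 3' adapter removal (error rate 0): the suffix starting at
#' the leftmost full occurrence of the adapter is removed; failing that, an
#' adapter *prefix* of length >= `min_overlap` anchored at the read's 3'
#' end is removed (the read ran out before covering the whole adapter).
#' Reads with no match are flagged by returning `NA` — without the adapter
#' the 3' UMI boundary is unknowable, so such reads are discarded
#' downstream rather than passed through untrimmed.
#'
#' @param sequence Character vector of read sequences.
#' @param adapter Adapter sequence (default the NEXTflex small-RNA 3'
#'   adapter `TGGAATTCTCGGGTGCCAAGG`).
#' @param min_overlap Minimum anchored-prefix match length (default 5).
#' @return Character vector of trimmed sequences; `NA` where no adapter
#'   (or sufficient prefix) was found.
#' @examples
#' trim_adapter(paste0("ACGTACGT", "TGGAATTCTCGGGTGCCAAGG"))  # "ACGTACGT"
#' @export
trim_adapter <- function(sequence, adapter = DEFAULT_ADAPTER, min_overlap = 5) {
  if (!nzchar(adapter)) stop("'adapter' must be non-empty")
  if (min_overlap < 1) stop("'min_overlap' must be >= 1")
  out <- rep(NA_character_, length(sequence))
  pos <- regexpr(adapter, sequence, fixed = TRUE)
  hit <- pos > 0L
  out[hit] <- substr(sequence[hit], 1L, pos[hit] - 1L)
  # anchored prefix matches, longest (= leftmost start) first
  todo <- !hit
  k_max <- min(nchar(adapter) - 1L,
               if (any(todo)) max(nchar(sequence[todo])) else 0L)
  for (k in (if (k_max >= min_overlap) seq(k_max, min_overlap) else integer(0))) {
    if (!any(todo)) break
    pre <- substr(adapter, 1L, k)
    m <- todo & endsWith(sequence, pre)
    out[m] <- substr(sequence[m], 1L, nchar(sequence[m]) - k)
    todo <- todo & !m
  }
  out
}

#' Excise the 5' and 3' UMIs from an adapter-trimmed read
#'
#' The UMI is the first `umi_len_5` bases concatenated with the last
#' `umi_len_3` bases (5' part first, matching the order of the two
#' extraction passes); the insert is the middle. Reads whose insert would
#' be shorter than `min_insert` (18 nt by default, applied both to the
#' trimmed read and to the excised insert) get status `too_short`.
#'
#' @param trimmed Character vector of adapter-trimmed sequences (may
#'   contain `NA` for adapter-less reads, which get status `no_adapter`).
#' @param umi_len_5,umi_len_3 UMI lengths (defaults 4, 4).
#' @param min_insert Minimum insert length retained (default 18).
#' @return data.frame with columns `umi`, `insert`, `status`
#'   (`pass` / `no_adapter` / `too_short`).
#' @export
extract_umis <- function(trimmed, umi_len_5 = 4, umi_len_3 = 4,
                         min_insert = 18) {
  len <- nchar(trimmed)
  status <- rep("pass", length(trimmed))
  status[is.na(trimmed)] <- "no_adapter"
  # length floor applied to the trimmed read and again to the bare insert
  short <- !is.na(trimmed) &
    (len < min_insert | len - umi_len_5 - umi_len_3 < min_insert)
  status[short] <- "too_short"
  ok <- status == "pass"
  umi <- insert <- rep(NA_character_, length(trimmed))
  umi[ok] <- paste0(substr(trimmed[ok], 1L, umi_len_5),
                    substr(trimmed[ok], len[ok] - umi_len_3 + 1L, len[ok]))
  insert[ok] <- substr(trimmed[ok], umi_len_5 + 1L, len[ok] - umi_len_3)
  data.frame(umi = umi, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

# structural 4-line-record validation; names the first offending record
validate_fastq <- function(fastq_path) {
  lines <- readLines(fastq_path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", fastq_path, "': truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(seps, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad) > 0L)
    stop("malformed FASTQ '", fastq_path, "': record ", bad[1L],
         call. = FALSE)
  invisible(TRUE)
}

#' Parse a UMI-tagged small-RNA FASTQ into processed reads
#'
#' Applies [trim_adapter()] then [extract_umis()] to every read, in input
#' order, and tallies the outcome. Deterministic: identical input gives
#' identical output.
#'
#' @param fastq_path Path to a FASTQ file.
#' @param adapter,min_overlap Passed to [trim_adapter()].
#' @param umi_len_5,umi_len_3,min_insert Passed to [extract_umis()].
#' @return List with `reads` (data.frame `read_id`, `umi`, `insert`,
#'   `status`) and `summary` (named counts: `total`, `pass`, `no_adapter`,
#'   `too_short`; the last three always sum to `total`).
#' @export
process_fastq <- function(fastq_path, adapter = DEFAULT_ADAPTER,
                          min_overlap = 5, umi_len_5 = 4, umi_len_3 = 4,
                          min_insert = 18) {
  validate_fastq(fastq_path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(fastq_path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", fastq_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- as.character(x)
  ids <- sub(" .*$", "", names(x))
  parsed <- extract_umis(trim_adapter(seqs, adapter, min_overlap),
                         umi_len_5, umi_len_3, min_insert)
  reads <- data.frame(read_id = ids, parsed, stringsAsFactors = FALSE)
  summary <- c(
    total = nrow(reads),
    pass = sum(reads$status == "pass"),
    no_adapter = sum(reads$status == "no_adapter"),
    too_short = sum(reads$status == "too_short")
  )
  list(reads = reads, summary = summary)
}
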