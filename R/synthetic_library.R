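#' @importFrom stats rbinom rnorm runif
NULL

DNA_BASES <- c("A", "C", "G", "T")
DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Build a synthetic miRNA reference with isomiR repertoire
#'
#' Creates a reference of `n_mirnas` species with random, distinct canonical
#' sequences (22-24 nt, embedded in a longer genomic context so that 5'/3'
#' template extensions exist), heavily skewed relative abundances, and a
#' per-species isomiR repertoire of 5'/3' start/end offsets.
#'
#' Abundances follow deterministic Zipf rank weights, `w_r` proportional to
#' `r^-abundance_skew`: at the default exponent 1.7 the ten most abundant of
#' 100 species carry ~89% of the weight, reproducing the concentration seen
#' in real miRNA libraries where the top 10 species exceed 80% of reads.
#' `abundance_skew = 0` gives uniform weights.
#'
#' The isomiR repertoire assigns the canonical form (offsets 0,0)
#' probability 0.6; the remaining offsets in \{-2..2\}^2 share 0.4 with
#' geometrically decaying probabilities, so each species has one dominant
#' and many minor variants. Negative start offsets extend the 5' end into
#' the context; positive trim it (and symmetrically at the 3' end). All
#' isomiR inserts are at least 18 nt.
#'
#' @param n_mirnas Number of miRNA species (>= 1).
#' @param abundance_skew Zipf exponent (>= 0); 0 means uniform.
#' @param seed Integer seed.
#' @param canonical_only If TRUE the repertoire is only the canonical
#'   (0,0) form — useful for controlled collision experiments where all
#'   molecules of a species must share one de-duplication group.
#' @param multilocus_frac Fraction of species annotated with 2 genomic
#'   loci (multimapping species) rather than 1.
#' @return Object of class `smrna_reference`: list with data.frames
#'   `mirnas` (`mirna_id`, `canonical_seq`, `context_seq`, `n_loci`,
#'   `weight`) and `isomirs` (`mirna_id`, `start_offset`, `end_offset`,
#'   `insert`, `prob` — probabilities conditional on the species).
#' @examples
#' ref <- build_reference(10, seed = 1)
#' sum(ref$mirnas$weight)  # 1
#' @export
build_reference <- function(n_mirnas, abundance_skew = 1.7, seed = 1,
                            canonical_only = FALSE, multilocus_frac = 0.05) {
  if (length(n_mirnas) != 1L || is.na(n_mirnas) || n_mirnas < 1)
    stop("'n_mirnas' must be an integer >= 1")
  if (abundance_skew < 0) stop("'abundance_skew' must be >= 0")
  n_mirnas <- as.integer(n_mirnas)
  set.seed(seed)

  flank <- 5L
  lens <- sample(22:24, n_mirnas, replace = TRUE)
  repeat {
    contexts <- random_dna(n_mirnas, max(lens) + 2L * flank)
    canonical <- substr(contexts, flank + 1L, flank + lens)
    if (!anyDuplicated(canonical)) break
  }
  weight <- seq_len(n_mirnas)^(-abundance_skew)
  weight <- weight / sum(weight)
  n_loci <- rep(1L, n_mirnas)
  n_multi <- floor(multilocus_frac * n_mirnas)
  if (n_multi > 0) n_loci[sample.int(n_mirnas, n_multi)] <- 2L
  mirnas <- data.frame(
    mirna_id = sprintf("mir-%03d", seq_len(n_mirnas)),
    canonical_seq = canonical,
    context_seq = contexts,
    n_loci = n_loci,
    weight = weight,
    stringsAsFactors = FALSE
  )

  if (canonical_only) {
    offsets <- data.frame(start_offset = 0L, end_offset = 0L, prob = 1)
  } else {
    grid <- expand.grid(start_offset = -2:2, end_offset = -2:2)
    grid <- grid[!(grid$start_offset == 0 & grid$end_offset == 0), ]
    ord <- order(abs(grid$start_offset) + abs(grid$end_offset),
                 grid$start_offset, grid$end_offset)
    grid <- grid[ord, ]
    p_minor <- 0.5^seq_len(nrow(grid))
    p_minor <- 0.4 * p_minor / sum(p_minor)
    offsets <- rbind(
      data.frame(start_offset = 0L, end_offset = 0L, prob = 0.6),
      data.frame(start_offset = grid$start_offset,
                 end_offset = grid$end_offset, prob = p_minor)
    )
  }
  iso <- merge(mirnas[, c("mirna_id", "context_seq", "canonical_seq")],
               offsets, by = NULL)
  len0 <- nchar(iso$canonical_seq)
  iso$insert <- substr(iso$context_seq,
                       flank + 1L + iso$start_offset,
                       flank + len0 + iso$end_offset)
  iso <- iso[order(iso$mirna_id, iso$start_offset, iso$end_offset),
             c("mirna_id", "start_offset", "end_offset", "insert", "prob")]
  rownames(iso) <- NULL
  stopifnot(all(nchar(iso$insert) >= 18L))
  # drop cross-species insert clashes (astronomically rare with random 22-24mers)
  iso <- iso[!duplicated(iso$insert), ]

  structure(list(mirnas = mirnas, isomirs = iso),
            class = "smrna_reference")
}

#' @export
print.smrna_reference <- function(x, ...) {
  top10 <- sum(sort(x$mirnas$weight, decreasing = TRUE)[1:min(10, nrow(x$mirnas))])
  cat(sprintf("smrna_reference: %d miRNAs, %d isomiRs, top-10 weight %.3f\n",
              nrow(x$mirnas), nrow(x$isomirs), top10))
  invisible(x)
}

#' Sample ground-truth pre-PCR molecules
#'
#' Draws `total_molecules` molecules from the reference: an isomiR chosen
#' with probability species weight x isomiR probability, and independent
#' uniform-random 5' and 3' UMIs. Each molecule starts with `copies = 1`
#' (pre-amplification).
#'
#' @param reference An `smrna_reference` from [build_reference()].
#' @param total_molecules Number of molecules to draw (>= 0; 0 gives an
#'   empty library).
#' @param umi_len_5,umi_len_3 UMI lengths in nt flanking the insert
#'   (defaults 4 and 4 — the 2 x 4 nt layout).
#' @param seed Integer seed.
#' @return data.frame of class `smrna_molecules` with columns `mol_id`,
#'   `mirna_id`, `start_offset`, `end_offset`, `insert`, `umi5`, `umi3`,
#'   `copies`. The per-isomiR ground truth is recoverable with
#'   [truth_table()].
#' @export
sample_molecules <- function(reference, total_molecules,
                             umi_len_5 = 4, umi_len_3 = 4, seed = 1) {
  stopifnot(inherits(reference, "smrna_reference"))
  if (nrow(reference$isomirs) == 0L) stop("empty reference")
  if (total_molecules < 0) stop("'total_molecules' must be >= 0")
  total_molecules <- as.integer(total_molecules)
  set.seed(seed)
  iso <- reference$isomirs
  w <- reference$mirnas$weight[match(iso$mirna_id, reference$mirnas$mirna_id)]
  p <- w * iso$prob
  idx <- if (total_molecules > 0)
    sample.int(nrow(iso), total_molecules, replace = TRUE, prob = p)
  else integer(0)
  mol <- data.frame(
    mol_id = seq_len(total_molecules),
    mirna_id = iso$mirna_id[idx],
    start_offset = iso$start_offset[idx],
    end_offset = iso$end_offset[idx],
    insert = iso$insert[idx],
    umi5 = random_dna(total_molecules, umi_len_5),
    umi3 = random_dna(total_molecules, umi_len_3),
    copies = rep(1, total_molecules),
    stringsAsFactors = FALSE
  )
  class(mol) <- c("smrna_molecules", "data.frame")
  mol
}

#' Ground-truth molecule counts per isomiR
#'
#' @param molecules Output of [sample_molecules()].
#' @return data.frame `mirna_id`, `start_offset`, `end_offset`,
#'   `true_molecules`; counts sum to the number of molecules.
#' @export
truth_table <- function(molecules) {
  if (nrow(molecules) == 0L)
    return(data.frame(mirna_id = character(0), start_offset = integer(0),
                      end_offset = integer(0), true_molecules = integer(0)))
  agg <- stats::aggregate(
    list(true_molecules = molecules$mol_id),
    by = molecules[, c("mirna_id", "start_offset", "end_offset")],
    FUN = length
  )
  agg[order(agg$mirna_id, agg$start_offset, agg$end_offset), ]
}

#' PCR amplification as a Galton-Watson branching process
#'
#' Each cycle, every existing copy of a molecule duplicates with
#' probability `efficiency * bias`, where efficiency is drawn once per
#' molecule from `Normal(efficiency_mean, efficiency_sd)` and `bias` is a
#' per-species multiplicative factor (e.g. 1.15 to emulate a consistently
#' over-amplified isomiR). Probabilities are clamped to \[0, 1\]. After `k`
#' cycles the expected copy number is `(1 + efficiency)^k`.
#'
#' @param molecules Output of [sample_molecules()].
#' @param cycles Number of PCR cycles (>= 0; 0 leaves copies untouched).
#' @param efficiency_mean,efficiency_sd Per-molecule duplication
#'   probability distribution (defaults 0.9 and 0.05).
#' @param species_bias Named numeric vector `mirna_id -> factor`, or NULL
#'   for no species bias.
#' @param seed Integer seed.
#' @return `molecules` with the `copies` column updated (>= 1 always).
#' @export
pcr_amplify <- function(molecules, cycles = 14,
                        efficiency_mean = 0.9, efficiency_sd = 0.05,
                        species_bias = NULL, seed = 1) {
  if (cycles < 0) stop("'cycles' must be >= 0")
  n <- nrow(molecules)
  if (n == 0L || cycles == 0) return(molecules)
  set.seed(seed)
  eff <- pmin(pmax(rnorm(n, efficiency_mean, efficiency_sd), 0), 1)
  if (!is.null(species_bias)) {
    b <- species_bias[molecules$mirna_id]
    b[is.na(b)] <- 1
    eff <- pmin(pmax(eff * b, 0), 1)
  }
  copies <- molecules$copies
  for (cyc in seq_len(cycles)) {
    copies <- copies + rbinom(n, size = copies, prob = eff)
  }
  molecules$copies <- copies
  molecules
}

#' Write molecules as a NEXTflex-style FASTQ library
#'
#' Emits one read per post-PCR copy with layout
#' `[5' UMI][insert][3' UMI][3' adapter]`, truncated to `read_length`.
#' Per-base substitution errors are applied after assembly at
#' `seq_error_rate` (uniform over the three alternative bases; no indels).
#' Quality strings are constant `'I'` — downstream processing never uses
#' qualities. Read IDs encode the generating molecule
#' (`mol<id>:<copy>`) for test-only truth lookup; the pipeline itself
#' never parses them.
#'
#' @param molecules Output of [sample_molecules()]/[pcr_amplify()].
#' @param path Output FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param read_length Instrument read length (single-end).
#' @param seq_error_rate Per-base substitution probability in \[0, 1\].
#' @param seed Integer seed (errors only).
#' @return `path`, invisibly; the file holds `sum(molecules$copies)` reads.
#' @export
write_fastq <- function(molecules, path, adapter = DEFAULT_ADAPTER,
                        read_length = 75, seq_error_rate = 0, seed = 1) {
  if (seq_error_rate < 0 || seq_error_rate > 1)
    stop("'seq_error_rate' must be in [0, 1]")
  idx <- rep(seq_len(nrow(molecules)), times = molecules$copies)
  seqs <- substr(
    paste0(molecules$umi5[idx], molecules$insert[idx],
           molecules$umi3[idx], adapter),
    1L, read_length
  )
  dup <- sequence(molecules$copies)
  ids <- paste0("mol", molecules$mol_id[idx], ":", dup)
  if (seq_error_rate > 0 && length(seqs) > 0) {
    set.seed(seed)
    seqs <- add_substitution_errors(seqs, seq_error_rate)
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs)))
  )
  invisible(path)
}

# uniform substitutions; RNG state is the caller's responsibility
add_substitution_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), size = lens, prob = rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Write the ground-truth sidecar table
#'
#' @param molecules Output of [sample_molecules()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(molecules, path) {
  utils::write.table(truth_table(molecules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
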