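#' Configuration for the end-to-end distortion demonstration
#'
#' Defaults describe a skewed 100-species library sequenced deep enough
#' that the most abundant species draws more molecules than an 8-nt UMI
#' pool holds (~75,000 molecules against 65,536 UMIs), i.e. the regime in
#' which de-duplication visibly undercounts — while staying small enough
#' to run on a laptop in minutes. Two PCR cycles at modest efficiency
#' exercise the amplification stage without inflating the read count.
#'
#' @param n_mirnas Number of miRNA species.
#' @param abundance_skew Zipf exponent for species weights.
#' @param total_molecules Pre-PCR molecules sampled.
#' @param umi_len_5,umi_len_3 UMI lengths flanking the insert (nt).
#' @param pcr_cycles,pcr_efficiency_mean,pcr_efficiency_sd PCR model.
#' @param species_bias Named per-species amplification factors or NULL.
#' @param seq_error_rate Per-base substitution probability.
#' @param adapter 3' adapter sequence.
#' @param read_length Single-end read length.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A validated list of class `demo_config`.
#' @export
demo_config <- function(n_mirnas = 100, abundance_skew = 1.7,
                        total_molecules = 150000,
                        umi_len_5 = 4, umi_len_3 = 4,
                        pcr_cycles = 2, pcr_efficiency_mean = 0.6,
                        pcr_efficiency_sd = 0.05, species_bias = NULL,
                        seq_error_rate = 0.001,
                        adapter = DEFAULT_ADAPTER, read_length = 75,
                        seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, abundance_skew = abundance_skew,
              total_molecules = total_molecules,
              umi_len_5 = umi_len_5, umi_len_3 = umi_len_3,
              pcr_cycles = pcr_cycles,
              pcr_efficiency_mean = pcr_efficiency_mean,
              pcr_efficiency_sd = pcr_efficiency_sd,
              species_bias = species_bias,
              seq_error_rate = seq_error_rate,
              adapter = adapter, read_length = read_length, seed = seed)
  stopifnot(n_mirnas >= 1, total_molecules >= 0,
            umi_len_5 >= 1, umi_len_3 >= 1, pcr_cycles >= 0,
            pcr_efficiency_mean >= 0, pcr_efficiency_mean <= 1,
            pcr_efficiency_sd >= 0,
            seq_error_rate >= 0, seq_error_rate <= 1,
            nzchar(adapter), read_length >= 1)
  structure(cfg, class = "demo_config")
}

#' Run the full synthetic distortion demonstration
#'
#' Simulate -> write FASTQ -> parse reads -> de-duplicate (Hamming 0 and
#' 1) -> quantify -> distortion report, writing every intermediate table
#' and a run manifest into `out_dir`. All randomness flows from
#' `config$seed`. Stage progress is logged to stderr; data only ever goes
#' to files.
#'
#' @param config A [demo_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `reference`, `counts`
#'   (`count_table`), `distortion` report, `summary` of read statuses and
#'   the `manifest` (also serialised as `manifest.json`).
#' @export
run_demo <- function(config = demo_config(), out_dir = tempfile("umisat_demo_")) {
  stopifnot(inherits(config, "demo_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    message("[umisat] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed

  reference <- stage("simulate/reference",
    build_reference(config$n_mirnas, config$abundance_skew, seed = seed))
  molecules <- stage("simulate/molecules",
    sample_molecules(reference, config$total_molecules,
                     config$umi_len_5, config$umi_len_3, seed = seed + 1))
  molecules <- stage("simulate/pcr",
    pcr_amplify(molecules, config$pcr_cycles, config$pcr_efficiency_mean,
                config$pcr_efficiency_sd, config$species_bias,
                seed = seed + 2))
  stage("simulate/write", {
    write_fastq(molecules, path("reads.fastq"), config$adapter,
                config$read_length, config$seq_error_rate, seed = seed + 3)
    write_truth_table(molecules, path("truth.tsv"))
  })

  processed <- stage("process",
    process_fastq(path("reads.fastq"), config$adapter,
                  umi_len_5 = config$umi_len_5,
                  umi_len_3 = config$umi_len_3))
  stage("process/write", {
    utils::write.table(processed$reads, path("processed.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(processed$summary), path("process_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  truth <- truth_table(molecules)
  counts <- stage("dedup+quantify",
    count_isomirs(processed$reads, reference, truth = truth))
  umi_len <- config$umi_len_5 + config$umi_len_3
  distortion <- stage("distortion",
    distortion_report(counts, umi_len = umi_len, level = "mirna"))
  profile <- stage("duplication-profile",
    duplication_profile(processed$reads, reference))
  stage("quantify/write", {
    utils::write.table(counts$isomir, path("counts_isomir.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(counts$mirna, path("counts_mirna.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(distortion, path("distortion.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(profile$histogram, path("duplication_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  n_reads <- sum(molecules$copies)
  manifest <- list(
    tool = paste0("umisat ", as.character(utils::packageVersion("umisat"))),
    seed = seed,
    config = config[setdiff(names(config), "species_bias")],
    stages = list(
      simulate = list(output = "reads.fastq",
                      molecules = nrow(molecules), reads = n_reads),
      process = list(input_reads = unname(processed$summary["total"]),
                     pass = unname(processed$summary["pass"]),
                     no_adapter = unname(processed$summary["no_adapter"]),
                     too_short = unname(processed$summary["too_short"])),
      dedup = list(groups = nrow(counts$isomir),
                   unmatched_inserts = attr(counts, "unmatched")),
      quantify = list(mirnas = nrow(counts$mirna),
                      saturated_species = sum(distortion$saturated))
    )
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(reference = reference, counts = counts,
                 distortion = distortion, profile = profile,
                 summary = processed$summary, manifest = manifest,
                 out_dir = out_dir))
}
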