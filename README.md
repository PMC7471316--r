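# umisat

Unique molecular identifiers (UMIs) are random barcodes ligated to
molecules before PCR so that read duplicates can be collapsed back to
molecule counts. That arithmetic fails quietly in small RNA sequencing:
miRNA libraries are so low in sequence complexity, and so skewed (the top
ten species can carry over 80% of reads), that the most abundant species
attract more molecules than an 8-nt UMI pool (4^8 = 65,536) can label.
Distinct molecules then share UMIs, de-duplication merges them, and
expression of exactly the most abundant species is under-estimated — by
20-fold and more at realistic depths. `umisat` is for bioinformaticians
designing or auditing UMI-based small-RNA protocols: it quantifies the
effect analytically and demonstrates it end to end on synthetic data with
known ground truth.

## The model

For an L-nt UMI with pool size C = 4^L and n molecules drawing UMIs
uniformly with replacement, the probability that a given UMI tags two or
more molecules is

    P = 1 − ((C−1)/C)^n − n·(1/C)·((C−1)/C)^(n−1)

The expected number of distinct UMIs observed is C·(1 − ((C−1)/C)^n) —
what Hamming-0 de-duplication reports for the group — so a group of n
molecules is undercounted by a factor ≈ n / C(1 − e^(−n/C)), which
approaches n/C once the pool saturates. At L = 8 and n = 10,000 the
expected number of multiply-used UMIs is P·C ≈ 689.5, reproduced by the
package's Monte-Carlo simulation. Allowing a Hamming distance of 1 when
merging UMIs shrinks the usable pool further, to at most 4^(L−1) = 16,384
for L = 8 (the Singleton bound for a 4-ary minimum-distance-2 code, with
a parity-check witness code included).

The package provides: a synthetic library generator (skewed abundances,
isomiRs, 2 × 4 nt UMIs, Galton–Watson PCR with species bias, sequencing
error, FASTQ output plus a ground-truth table), a deterministic
adapter/UMI read parser, UMI de-duplication (`unique`, `cluster` and
count-aware `directional` merging), isomiR/miRNA quantification with CPM
and fold-underestimation reporting, the occupancy mathematics above, and
a one-command demonstration (`run_demo()`).

## Worked example

A single species given 21 × 256 = 5,376 molecules against a 4-nt UMI pool
(C = 256), error-free reads, no PCR:

```r
library(umisat)

collision_stats(8, 10000)[, c("p_multi", "expected_unique", "expected_multi")]
#>      p_multi expected_unique expected_multi
#> 1 0.01052154        9274.495       689.5395

ref <- build_reference(1, abundance_skew = 0, seed = 1, canonical_only = TRUE)
mol <- sample_molecules(ref, 21 * 256, umi_len_5 = 2, umi_len_3 = 2, seed = 2)
fq <- tempfile(fileext = ".fastq")
write_fastq(mol, fq)
reads <- process_fastq(fq, umi_len_5 = 2, umi_len_3 = 2)$reads
ct <- count_isomirs(reads, ref, truth = truth_table(mol))
distortion_report(ct, umi_len = 4)
#>   mirna_id raw_reads dedup_h0 dedup_h1 true_molecules fold_vs_raw fold_vs_truth saturated
#> 1  mir-001      5376      256      231           5376          21            21      TRUE

recommend_umi_length(max_molecules = 1e6, max_distortion = 0.05)
#> [1] 12
```

All 5,376 molecules are real — yet de-duplication reports 256, the entire
exhausted pool: a 21-fold underestimate, exactly the occupancy
prediction n / C(1 − e^(−21)). Merging single-mismatch UMIs (`dedup_h1`)
makes it worse. The last line inverts the formula: to keep the
undercount of a million-molecule species below 5% you need a 12-nt UMI.

`run_demo(demo_config(seed = 1))` runs the full pipeline on a skewed
100-species library (150,000 molecules, 2 × 4 nt UMIs, PCR, sequencing
error) and writes count tables, a duplication-frequency profile, a
distortion report and a reconciling manifest; the top species is flagged
saturated, and rerunning with `umi_len_5 = 6, umi_len_3 = 6` at the same
depth removes the saturation.

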