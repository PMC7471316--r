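test_that("reference weights normalise, skew concentrates, uniform limit holds", {
  expect_error(build_reference(0))
  one <- build_reference(1, seed = 3)
  expect_equal(one$mirnas$weight, 1.0)
  flat <- build_reference(100, abundance_skew = 0, seed = 4)
  expect_equal(flat$mirnas$weight, rep(0.01, 100))
  for (seed in c(1, 19, 404)) {
    ref <- build_reference(100, seed = seed)
    expect_equal(sum(ref$mirnas$weight), 1.0)
    top10 <- sum(sort(ref$mirnas$weight, decreasing = TRUE)[1:10])
    expect_gt(top10, 0.80)
  }
})

test_that("reference sequences are valid DNA with dominant canonical isomiR", {
  ref <- build_reference(20, seed = 8)
  expect_false(anyDuplicated(ref$mirnas$canonical_seq) > 0)
  expect_true(all(grepl("^[ACGT]+$", ref$mirnas$canonical_seq)))
  expect_true(all(nchar(ref$mirnas$canonical_seq) >= 18,
                  nchar(ref$mirnas$canonical_seq) <= 30))
  expect_true(all(nchar(ref$isomirs$insert) >= 18))
  canon <- ref$isomirs[ref$isomirs$start_offset == 0 &
                       ref$isomirs$end_offset == 0, ]
  expect_equal(canon$prob, rep(0.6, nrow(canon)))
  expect_identical(canon$insert,
                   ref$mirnas$canonical_seq[match(canon$mirna_id,
                                                  ref$mirnas$mirna_id)])
  by_mir <- tapply(ref$isomirs$prob, ref$isomirs$mirna_id, sum)
  expect_equal(as.vector(by_mir), rep(1, 20), tolerance = 1e-12)
})

test_that("molecule sampling conserves counts and draws uniform UMIs", {
  ref <- build_reference(10, seed = 2)
  expect_identical(nrow(sample_molecules(ref, 0)), 0L)
  mol <- sample_molecules(ref, 4000, seed = 5)
  tt <- truth_table(mol)
  expect_identical(sum(tt$true_molecules), 4000L)
  expect_true(all(mol$copies == 1))
  expect_true(all(nchar(mol$umi5) == 4, nchar(mol$umi3) == 4))
  # marginal base frequencies of the 8 UMI positions are ~uniform
  bases <- table(unlist(strsplit(paste0(mol$umi5, mol$umi3), "")))
  expect_true(all(abs(bases / sum(bases) - 0.25) < 0.02))
})

test_that("distinct-UMI count of a deep draw matches the occupancy closed form", {
  # 10^5 draws of an 8-nt UMI: E[distinct] = 65536 * (1 - (65535/65536)^1e5)
  ref <- single_group_reference()
  mol <- sample_molecules(ref, 1e5, seed = 21)
  got <- length(unique(paste0(mol$umi5, mol$umi3)))
  expected <- 65536 * (1 - (65535 / 65536)^1e5)
  # SD of the occupancy count is ~100 here; allow a generous 5 sigma
  expect_lt(abs(got - expected), 500)
})

test_that("PCR amplification follows branching-process expectations", {
  ref <- build_reference(5, seed = 1)
  mol <- sample_molecules(ref, 1000, seed = 2)
  expect_identical(pcr_amplify(mol, cycles = 0), mol)
  det <- pcr_amplify(mol, cycles = 3, efficiency_mean = 1,
                     efficiency_sd = 0, seed = 3)
  expect_true(all(det$copies == 8))
  amp <- pcr_amplify(mol, cycles = 14, efficiency_mean = 0.9,
                     efficiency_sd = 0, seed = 4)
  expect_true(all(amp$copies >= 1))
  m <- mean(amp$copies)
  se <- stats::sd(amp$copies) / sqrt(nrow(amp))
  expect_lt(abs(m - 1.9^14), 3 * se)
})

test_that("species bias shifts amplification for the biased species only", {
  ref <- build_reference(2, abundance_skew = 0, seed = 6)
  mol <- sample_molecules(ref, 2000, seed = 7)
  amp <- pcr_amplify(mol, cycles = 6, efficiency_mean = 0.7,
                     efficiency_sd = 0, seed = 8,
                     species_bias = c("mir-001" = 1.15))
  m1 <- mean(amp$copies[amp$mirna_id == "mir-001"])
  m2 <- mean(amp$copies[amp$mirna_id == "mir-002"])
  expect_gt(m1 / m2, (1.805 / 1.7)^6 * 0.9)  # (1+0.7*1.15)^6 / (1+0.7)^6
})

test_that("FASTQ reads are assembled as UMI5|insert|UMI3|adapter", {
  ref <- build_reference(3, seed = 9)
  mol <- sample_molecules(ref, 1, seed = 10)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(mol, f, seq_error_rate = 0)
  lines <- readLines(f)
  expect_length(lines, 4L)
  full <- paste0(mol$umi5, mol$insert, mol$umi3,
                 "TGGAATTCTCGGGTGCCAAGG")
  expect_identical(lines[2], substr(full, 1, 75))
  expect_identical(lines[4], strrep("I", nchar(lines[2])))
  # reads = copies after amplification
  amp <- pcr_amplify(sample_molecules(ref, 50, seed = 11), cycles = 2,
                     efficiency_mean = 0.8, seed = 12)
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(amp, f2)
  expect_identical(length(readLines(f2)) / 4, sum(amp$copies))
})

test_that("substitution errors hit the UMI at the binomial rate", {
  ref <- single_group_reference(2)
  mol <- sample_molecules(ref, 1, seed = 13)
  mol$copies <- 10000
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(mol, f, seq_error_rate = 0.01, seed = 14)
  pr <- process_fastq(f)
  ok <- pr$reads$status == "pass"
  true_umi <- paste0(mol$umi5, mol$umi3)
  frac_mismatch <- mean(pr$reads$umi[ok] != true_umi)
  p <- 1 - 0.99^8
  se <- sqrt(p * (1 - p) / sum(ok))
  expect_lt(abs(frac_mismatch - p), 4 * se)
})

test_that("generation is byte-identical under a fixed seed", {
  ref <- build_reference(10, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  for (f in c(f1, f2)) {
    mol <- sample_molecules(ref, 500, seed = 4)
    mol <- pcr_amplify(mol, cycles = 2, efficiency_mean = 0.7, seed = 5)
    write_fastq(mol, f, seq_error_rate = 0.005, seed = 6)
  }
  expect_identical(readLines(f1), readLines(f2))
})
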