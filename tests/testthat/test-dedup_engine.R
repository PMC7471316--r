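test_that("hamming counts mismatching positions and enforces equal length", {
  expect_identical(hamming("AAAA", "AAAA"), 0L)
  expect_identical(hamming("AAAA", "AAAT"), 1L)
  expect_identical(hamming("ACGT", "TGCA"), 4L)
  expect_identical(hamming(c("AA", "AC"), c("AT", "AC")), c(1L, 0L))
  expect_error(hamming("AAA", "AAAA"), "equal-length")
})

test_that("group collapse follows the threshold and method semantics", {
  expect_identical(dedup_group(c(AAAA = 5), 0), 1L)
  expect_identical(dedup_group(c(AAAA = 5), 1, "cluster"), 1L)
  # distinct UMIs at threshold 0 regardless of counts
  expect_identical(dedup_group(c(AAAA = 5, AAAT = 1, CCCC = 3), 0), 3L)
  # hand adjacency: AAAA-AAAT joined, CCCC isolated
  expect_identical(dedup_group(c(AAAA = 5, AAAT = 1, CCCC = 3), 1,
                               "cluster"), 2L)
  # directional: 2 >= 2*2 - 1 fails in both directions
  expect_identical(dedup_group(c(AAAA = 2, AAAT = 2), 1, "directional"), 2L)
  # ...but a 5:1 satellite is absorbed
  expect_identical(dedup_group(c(AAAA = 5, AAAT = 1), 1, "directional"), 1L)
  # directional chain: 16 absorbs 8 (16 >= 15), 8 absorbs 4 from inside
  expect_identical(dedup_group(c(AAAA = 16, AAAT = 8, AATT = 4), 1,
                               "directional"), 1L)
  expect_error(dedup_group(integer(0)), "empty")
  expect_error(dedup_group(c(AAAA = 2, AAT = 1), 1), "length")
})

test_that("cluster collapse matches exhaustive pairwise brute force", {
  set.seed(77)
  for (case in 1:25) {
    L <- sample(1:2, 1)
    n_reads <- sample(2:50, 1)
    umis <- random_umis(n_reads, L)
    tab <- table(umis)
    counts <- stats::setNames(as.integer(tab), names(tab))
    expect_identical(dedup_group(counts, 1, "cluster"),
                     bf_cluster_count(names(counts)))
  }
})

test_that("dedup counts are monotone: h1 <= h0 <= raw <= pool bound", {
  set.seed(42)
  for (case in 1:20) {
    L <- sample(2:3, 1)
    umis <- random_umis(sample(5:200, 1), L)
    tab <- table(umis)
    counts <- stats::setNames(as.integer(tab), names(tab))
    h0 <- dedup_group(counts, 0)
    h1c <- dedup_group(counts, 1, "cluster")
    h1d <- dedup_group(counts, 1, "directional")
    raw <- sum(counts)
    expect_lte(h1c, h0)
    expect_lte(h1d, h0)
    expect_lte(h0, raw)
    expect_lte(h0, 4^L)
    expect_gte(h1c, 1L)
  }
})

test_that("directional tie-breaking is deterministic", {
  counts <- c(AAAA = 3, AAAT = 3, AATT = 2, TTTT = 4)
  expect_identical(replicate(5, dedup_group(counts, 1, "directional")),
                   rep(dedup_group(counts, 1, "directional"), 5))
})

test_that("library dedup groups reads by isomiR and respects saturation", {
  # 1000 reads, one insert, 1000 distinct UMIs: no collision at threshold 0
  ref <- single_group_reference(51)
  set.seed(51)
  umis <- unique(random_umis(3000, 8))[1:1000]
  reads <- data.frame(
    read_id = paste0("r", 1:1000),
    umi = umis,
    insert = ref$isomirs$insert[1],
    status = "pass", stringsAsFactors = FALSE)
  dd <- dedup_library(reads, ref, threshold = 0)
  expect_identical(nrow(dd), 1L)
  expect_identical(dd$dedup_count, 1000L)
  expect_identical(dd$raw_reads, 1000L)

  # saturation: far more molecules than a 2-nt pool can label
  set.seed(52)
  reads2 <- data.frame(
    read_id = paste0("s", 1:500),
    umi = random_umis(500, 2),
    insert = ref$isomirs$insert[1],
    status = "pass", stringsAsFactors = FALSE)
  dd2 <- dedup_library(reads2, ref, threshold = 0)
  expect_lte(dd2$dedup_count, 16L)
  # unmatched inserts are dropped and counted
  reads3 <- rbind(reads2,
                  data.frame(read_id = "x", umi = "AC",
                             insert = strrep("ACGT", 6), status = "pass"))
  dd3 <- dedup_library(reads3, ref, threshold = 0)
  expect_identical(attr(dd3, "unmatched"), 1L)
  expect_identical(dd3$raw_reads, 500L)
})

test_that("small-instance library dedup matches the brute-force oracle", {
  ref <- single_group_reference(53)
  set.seed(54)
  for (case in 1:10) {
    umis <- random_umis(sample(10:30, 1), 2)
    reads <- data.frame(read_id = seq_along(umis), umi = umis,
                        insert = ref$isomirs$insert[1], status = "pass",
                        stringsAsFactors = FALSE)
    dd <- dedup_library(reads, ref, threshold = 1, method = "cluster")
    expect_identical(dd$dedup_count, bf_cluster_count(unique(umis)))
  }
})

test_that("duplication profile reports UMI multiplicities and median", {
  ref <- single_group_reference(55)
  mk <- function(umis) data.frame(read_id = seq_along(umis), umi = umis,
                                  insert = ref$isomirs$insert[1],
                                  status = "pass", stringsAsFactors = FALSE)
  # all singletons
  p1 <- duplication_profile(mk(unique(random_umis(300, 8))), ref)
  expect_identical(p1$histogram$multiplicity, 1L)
  expect_identical(p1$median_multiplicity, 1)
  # constructed fixture {u1 x 5, u2 x 1}
  p2 <- duplication_profile(mk(c(rep("AAAAAAAA", 5), "CCCCCCCC")), ref)
  expect_identical(p2$histogram,
                   data.frame(multiplicity = c(1L, 5L), n_umis = c(1L, 1L)))
  expect_identical(p2$median_multiplicity, 3)
})

test_that("without PCR and far from saturation the median multiplicity is 1", {
  ref <- build_reference(10, seed = 56)
  mol <- sample_molecules(ref, 3000, seed = 57)  # n << 4^8 per group
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(mol, f)
  pr <- process_fastq(f)
  prof <- duplication_profile(pr$reads, ref)
  expect_identical(prof$median_multiplicity, 1)
})
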