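---
title: "UMI pool complexity and de-duplication distortion in small RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI pool complexity and de-duplication distortion in small RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umisat)
```

## The problem

A unique molecular identifier (UMI) is a random oligonucleotide ligated to
each cDNA molecule before PCR, so that after sequencing, reads sharing both
sequence and UMI can be collapsed to one original molecule. This only works
while the pool of distinct UMIs — $C = 4^L$ for an $L$-nt UMI — comfortably
exceeds the number of molecules competing for it *within one
de-duplication group*. Whole-transcriptome libraries are complex enough
that each distinct insert sequence attracts few molecules, and short UMIs
suffice. Small RNA libraries are different: miRNA biogenesis constrains
the repertoire of possible inserts, abundances are extremely skewed (a
handful of species can carry most of the reads), and millions of
molecules of the *same* sequence may each draw from the same pool of
$4^8 = 65{,}536$ eight-mers. Distinct molecules then collide on the same
UMI, de-duplication merges them, and the most abundant species are
systematically under-counted — the expression profile is compressed
exactly where it matters most.

This package implements every piece needed to study that failure mode on
fully synthetic data: a library generator with known ground truth, the
read parser, the UMI-collapsing engine, quantification, and the analytic
model that predicts the distortion.

## The occupancy model

Assume all $C$ UMIs are equally likely and effectively infinitely
abundant, and let $n$ molecules each draw one. For a fixed UMI,

$$
p_0 = \left(\tfrac{C-1}{C}\right)^n,\qquad
p_1 = n\,\tfrac1C \left(\tfrac{C-1}{C}\right)^{n-1},\qquad
P = 1 - p_0 - p_1 ,
$$

where $P$ is the probability that the UMI tags two or more distinct
molecules. The expected number of distinct UMIs observed is
$C(1-p_0)$ — this is what Hamming-0 de-duplication reports for the group —
and the expected number of multiply-used UMIs is $P\,C$. At $L=8$ and
$n=10^4$ the closed form gives $P \approx 0.01052$ and
$P\,C \approx 689.5$, which `simulate_saturation()` reproduces by direct
Monte Carlo:

```{r occupancy}
collision_stats(L = 8, n = 10000)[, c("p_multi", "expected_unique", "expected_multi")]
simulate_saturation(L = 8, n_grid = 10000, rounds = 100, seed = 1)$summary[
  , c("n", "mean_unique", "mean_multi", "se_multi")]
```

The fold-underestimation of a group with $n$ molecules is
$n / C(1 - e^{-n/C})$ in the Poisson limit: ~1 for $n \ll C$, and
essentially $n/C$ once the pool saturates, where the reported count
pins at $C$ no matter how abundant the species really is.

Powers of $(C-1)/C$ are evaluated in log space (`log1p`/`expm1`), so the
probabilities conserve mass to $10^{-12}$ across $L \le 16$ and
$n \le 10^7$. The simulation draws integer indices in $[0, C)$ and never
materialises the pool, so memory is $O(n)$ at any $L$; round $r$ reseeds
with `seed + r`, making the grid reproducible and order-independent.

### Single-mismatch merging shrinks the pool fourfold

Merging UMIs within Hamming distance 1 (to absorb PCR/sequencing errors)
means two UMIs stay distinguishable only at distance $\ge 2$. The largest
4-ary length-$L$ code with minimum distance 2 has $4^{L-1}$ words — the
Singleton bound, attained by the parity-check construction in
`parity_check_code()` (last symbol = sum of the others mod 4). An 8-nt
UMI therefore offers at worst an effective pool of 16,384, not 65,536.
`effective_pool_hamming1()` returns the bound and the witness code lets
tests verify the pairwise-distance property directly.

`recommend_umi_length()` inverts the occupancy formula: given the largest
group size you expect and a tolerated fractional undercount, it scans
$L$ upward. A group of $10^6$ molecules at 5% tolerated loss needs
$L = 12$, the length adopted by newer small-RNA kits.

## The synthetic generator

`build_reference()` + `sample_molecules()` + `pcr_amplify()` +
`write_fastq()` emulate a NEXTflex-style library:
`[4 nt UMI][insert][4 nt UMI][3' adapter]`, single-end 75-nt reads,
constant quality.

Design choices, and what they do and do not model:

* **Abundance skew.** Species weights are deterministic Zipf rank
  weights $w_r \propto r^{-s}$, default $s = 1.7$, giving the top 10 of
  100 species ~89% of the weight — the concentration regime of real
  miRNA libraries — at *every* seed; $s = 0$ recovers uniform weights. A
  stochastic (e.g. log-normal) weight model was rejected because its
  top-10 share fluctuates far below 0.8 on many seeds, which would make
  the generator's saturation regime seed-dependent.
* **IsomiRs.** Each species carries the canonical form with probability
  0.6 and the 24 offset variants in $\{-2..2\}^2$ sharing 0.4 with
  geometrically decaying probability — one dominant plus minor variants.
  Real isomiR distributions are more structured (templated 3' additions,
  non-templated tailing); only dominance structure matters here. All
  inserts are $\ge 18$ nt by construction (canonical 22–24 nt).
* **PCR.** A Galton–Watson process: each copy duplicates per cycle with
  probability `efficiency * bias`, efficiency drawn once per molecule
  (default $0.9 \pm 0.05$), `bias` an optional per-species factor (1.15
  emulates a consistently over-amplified isomiR). After $k$ cycles the
  expected copy number is $(1+e)^k$. The wet-lab default of 14 cycles is
  honoured as the function default; the demonstration pipeline uses 2
  cycles at efficiency 0.6, since amplification multiplies reads without
  changing the pre-PCR UMI arithmetic that drives saturation.
* **Errors.** Substitutions only, uniform over alternatives, applied
  after read assembly. Indels are deliberately absent: collapsing is
  Hamming-based and fixed-length. No ligation bias, no quality model,
  no paired ends.
* **Truth.** Ground truth is a sidecar TSV (`write_truth_table()`);
  read IDs also encode the generating molecule but only tests use that
  channel.

Consequently, passing tests show that the *mechanism* — pool exhaustion
distorting quantification — behaves exactly as the occupancy model
predicts on data with this statistical shape; they do not certify
adapter-trimming heuristics, aligner behaviour, or isomiR biology on
real reads.

## Read processing

`process_fastq()` re-implements the standard trim-then-excise chain as
one deterministic parser: exact-match 3'-adapter removal (leftmost full
occurrence, else an adapter prefix of $\ge 5$ nt anchored at the read
end), excision of the first `umi_len_5` and last `umi_len_3` bases
(concatenated 5' part first), and an 18-nt minimum applied both to the
trimmed read and to the bare insert. Reads with no adapter evidence are
*discarded* (`no_adapter`), not passed through: without the adapter the
3' UMI boundary is unknowable, and silently keeping such reads would put
adapter bases into the UMI. Statuses always partition the input.

## De-duplication

`dedup_group()` collapses one group's UMI multiset three ways:

* `threshold = 0` / `unique`: distinct UMIs — the pure occupancy count;
* `cluster`: connected components at Hamming distance $\le 1$ —
  worst-case merging, the counterpart of the $4^{L-1}$ effective pool;
* `directional` (default at threshold 1): node $u$ absorbs neighbour $v$
  only if $\mathrm{count}(u) \ge 2\,\mathrm{count}(v) - 1$, clusters
  grown from high-count nodes (descending count, lexicographic
  tie-break — output is deterministic). This count-asymmetry absorbs
  error satellites without merging genuinely distinct molecules of
  similar abundance.

Neighbour search enumerates the $3L$ single-base variants of each UMI
against a hash of the observed set, so cost is linear in distinct UMIs
rather than quadratic. Since genome alignment is out of scope, reads are
assigned to isomiR groups by exact insert match against the expanded
reference; unmatched inserts are dropped and counted.

## Quantification

`count_isomirs()` produces isomiR rows and miRNA rollups with raw reads,
Hamming-0 and Hamming-1 counts, and CPM per column — denominators are
computed within each column, since raw and de-duplicated profiles are
compared side by side. `distortion_report()` adds `raw/dedup` and
`truth/dedup` folds and flags a species *saturated* when its Hamming-0
count reaches half the pool ($n \gtrsim 0.7C$, where the undercount is
already $\ge 1.4$-fold); by the time a count approaches $C$ itself the
fold is unbounded, so the half-pool flag marks the onset rather than the
extreme. Multi-locus species are handled by the unique-sum plus
mean-of-multimappers rule in `aggregate_multimappers()`; the phrasing of
that rule is ambiguous between summing the per-locus means within a
species and other readings — the per-species mean is implemented because
it counts each multimapping molecule exactly once.

`duplication_profile()` reports the multiplicity histogram of
(group, UMI) pairs and its median: a median near 1 demonstrates that a
library is *not* over-sequenced, so any undercounting of abundant
species must come from pool exhaustion instead.

## The demonstration pipeline

```{r demo, eval = FALSE}
res <- run_demo(demo_config(seed = 1))
head(res$distortion)
```

The default configuration is a 100-species library, 150,000 pre-PCR
molecules, 2 x 4 nt UMIs, two PCR cycles, error rate $10^{-3}$ — sized
so the top species (~50% of molecules, ~75,000 against a 65,536 pool)
is clearly saturated while the run stays under half a minute; with
2 x 6 nt UMIs at the same depth no species saturates and the top-species
count returns to within a few percent of truth. Every stage writes its
table plus a manifest whose counts reconcile across stages, and the whole
run is byte-reproducible from the single seed.

## Numerical and degenerate-input choices

* Probabilities are computed in log space; mass conservation is asserted
  at $10^{-12}$.
* `pool_complexity()` returns doubles (exact to $L = 26$); lengths must
  be positive integers.
* Empty UMI groups, empty references, zero totals for CPM, and
  mixed-length UMIs are errors; `total_molecules = 0` and empty FASTQ
  files yield empty, well-formed results.
* PCR with `cycles = 0` is the identity; efficiencies and biases are
  clamped into $[0,1]$ rather than rejected.
* FASTQ structure is validated before parsing so that truncated records
  fail with the offending record index.

## Limitations

The generator's independence assumptions (UMIs uniform and unlimited,
errors i.i.d., no ligation bias) match the analytic model by design;
real libraries violate them in ways that make distortion somewhat worse
(biased UMI usage shrinks the effective pool further). Problem sizes in
the tests are scaled (e.g. the 21-fold-saturation property is exercised
at $C = 256$ rather than $C = 65{,}536$) — the occupancy arithmetic is
scale-free, which is precisely what the closed form shows.
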