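test_that("canonicalization matches explicit enumeration and is invariant", {
  # independent enumeration for a tiny case
  enumerate_min <- function(s) {
    n <- nchar(s)
    rots <- function(x) vapply(0:(n - 1), function(k) rotateSeq(x, k), character(1))
    min(c(rots(s), rots(revComp(s))))
  }
  expect_equal(canonicalizeMonomer("GTAC"), enumerate_min("GTAC"))
  set.seed(1)
  for (i in 1:10) {
    s <- randomDNA(sample(10:60, 1))
    canon <- canonicalizeMonomer(s)
    expect_equal(canonicalizeMonomer(canon), canon)            # idempotent
    expect_equal(canonicalizeMonomer(rotateSeq(s, sample(nchar(s), 1))), canon)
    expect_equal(canonicalizeMonomer(revComp(s)), canon)
    expect_equal(canon, enumerate_min(s))
  }
  expect_error(canonicalizeMonomer("ACGN"), "ACGT")
})

test_that("one mutated family clusters into a single global cluster", {
  set.seed(2)
  m <- randomDNA(171)
  canon <- canonicalizeMonomer(m)
  # simulate detector consensus outputs: random rotations/strands, few errors
  cons <- vapply(1:100, function(i) {
    s <- rotateSeq(m, sample(171, 1))
    if (runif(1) < 0.5) s <- revComp(s)
    .mutate_copies_for_test(s, 0.01)
  }, character(1))
  hits <- fake_hits(sprintf("r%03d", 1:100), start = 0, end = 700,
                    period = 171L, consensus = cons)
  cl <- clusterMonomers(hits, totalReads = 1000)
  glob <- cl[cl$kind == "global", ]
  expect_equal(nrow(glob), 1)
  expect_equal(glob$length, 171)
  expect_equal(glob$consensus, canon)
  expect_equal(glob$supporting_read_fraction, 0.1)
})

test_that("unrelated monomers never share a cluster", {
  set.seed(3)
  a <- randomDNA(150); b <- randomDNA(150)
  hits <- fake_hits(sprintf("r%d", 1:20), start = 0, end = 600, period = 150L,
                    consensus = c(rep(a, 10), rep(b, 10)))
  cl <- clusterMonomers(hits, totalReads = 100)
  expect_equal(sum(cl$kind == "global"), 2)
  expect_equal(sum(cl$kind == "local"), 2)
})

test_that("a 9-bp deletion variant shares the local but not the global cluster", {
  set.seed(4)
  b1 <- randomDNA(171)
  b2 <- paste0(substr(b1, 1, 80), substr(b1, 90, 171))   # 9 bp deleted
  hits <- fake_hits(sprintf("r%d", 1:20), start = 0, end = 700,
                    period = c(rep(171L, 10), rep(162L, 10)),
                    consensus = c(rep(b1, 10), rep(b2, 10)))
  cl <- clusterMonomers(hits, totalReads = 100)
  expect_equal(sum(cl$kind == "local"), 1)    # one variant family
  expect_equal(sum(cl$kind == "global"), 2)   # two length cores
})

test_that("cluster ranking is total and stable", {
  set.seed(5)
  a <- randomDNA(120); b <- randomDNA(200)
  hits <- fake_hits(sprintf("r%d", 1:30), start = 0, end = 600,
                    period = c(rep(120L, 10), rep(200L, 20)),
                    consensus = c(rep(a, 10), rep(b, 20)))
  cl <- clusterMonomers(hits, totalReads = 100)
  glob <- cl[cl$kind == "global", ]
  expect_equal(glob$rank, seq_len(nrow(glob)))
  expect_equal(glob$length[1], 200)  # more supporting reads ranks first
})

test_that("genomic fraction estimation recovers the planted fraction", {
  set.seed(6)
  m <- randomDNA(171)
  g <- makeGenome(90000, arraySpec(m, 60, 0.01), seed = 7)  # 10.26 kb / 100 kb
  reads <- simulateReads(g, readSimSpec("sanger", 400, 0,
                                        substitutionError = 0.005,
                                        nReads = 800, seed = 8))
  est <- estimateGenomicFraction(m, reads)
  truth <- (g$truth$end - g$truth$start) / nchar(g$sequence)
  expect_lt(abs(est - truth), 3 * sqrt(truth * (1 - truth) / 800) + 0.01)
  # no match and all-match extremes
  expect_equal(estimateGenomicFraction(randomDNA(171), reads), 0)
  arr_reads <- simulateReads(list(sequence = strrep(m, 30)),
                             readSimSpec("sanger", 400, 0, nReads = 50, seed = 9))
  expect_equal(estimateGenomicFraction(m, arr_reads), 1)
  expect_error(estimateGenomicFraction(m, character(0)), "no reads")
})

test_that("per-chromosome arithmetic and the low-repeat call behave", {
  expect_equal(perChromosomeAmount(0.005, 2.4e9, 30), 400000)
  expect_equal(perChromosomeAmount(0, 2.4e9, 30), 0)
  expect_equal(perChromosomeAmount(0.01, 1e9, 20),
               perChromosomeAmount(0.01, 1e9, 10) / 2)
  expect_true(is.na(perChromosomeAmount(0.01, NA, 10)))
  prof <- new("RepeatProfile", species = "x", technology = "sanger",
              clusters = S4Vectors::DataFrame(
                cluster_id = "G001", kind = "global", rank = 1L,
                consensus = "ACGT", length = 4L, gc = 0.5, n_hits = 1L,
                n_reads = 1L, supporting_read_fraction = 0.001,
                genomic_fraction = 0.0001),
              genomeSize = NA_real_, chromosomeCount = NA_real_, nReads = 100L)
  expect_true(classifyLowRepeat(prof, 0.001))
  expect_false(classifyLowRepeat(prof, 0.0001))  # strictly lower required
  prof@clusters$genomic_fraction <- 0.02
  expect_false(classifyLowRepeat(prof, 0.001))   # planted high abundance
})
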