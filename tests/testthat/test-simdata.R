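test_that("planted genomes have exact coordinates and unit content", {
  m <- randomDNA(171)
  g <- makeGenome(10000, arraySpec(m, 100), seed = 1)
  expect_equal(nchar(g$sequence), 10000 + 17100)
  expect_equal(nrow(g$truth), 1)
  expect_equal(g$truth$end - g$truth$start, 17100)
  # with no mutation, every planted unit equals the monomer
  arr <- substr(g$sequence, g$truth$start + 1, g$truth$end)
  units <- substring(arr, seq(1, 17100, by = 171), seq(171, 17100, by = 171))
  expect_true(all(units == m))
  expect_error(arraySpec("ACGQ", 10), "non-ACGTN")
})

test_that("HOR patterns plant alternating variant classes", {
  m <- randomDNA(171)
  edits <- make_sub_edits(m, 8, seed = 3)
  g <- makeGenome(0, arraySpec(m, 100, horPattern = c("A", "B"),
                               variantEdits = list(A = list(), B = edits)),
                  seed = 2)
  units <- substring(g$sequence, seq(1, 17100, by = 171),
                     seq(171, 17100, by = 171))
  mc <- strsplit(m, "")[[1]]
  nmis <- vapply(units, function(u) sum(strsplit(u, "")[[1]] != mc), numeric(1))
  expect_equal(unname(nmis), rep(c(0, 8), 50))
})

test_that("array spec validates HOR labels", {
  expect_error(arraySpec("ACGT", 4, horPattern = c("A", "B"),
                         variantEdits = list(A = list())), "B")
})

test_that("read simulation is deterministic and error-free reads are substrings", {
  g <- makeGenome(20000, list(), seed = 5)
  spec <- readSimSpec("sanger", 800, 0, nReads = 100, seed = 11)
  r1 <- simulateReads(g, spec)
  r2 <- simulateReads(g, spec)
  expect_identical(as.character(r1), as.character(r2))
  mc <- S4Vectors::mcols(r1)
  truth <- substring(g$sequence, mc$start + 1, mc$end)
  obs <- as.character(r1)
  obs[mc$strand == "-"] <- revComp(obs[mc$strand == "-"])
  expect_identical(unname(obs), truth)
  expect_error(simulateReads(randomDNA(100),
                             readSimSpec("sanger", 800, 0, nReads = 10)),
               "exceeds genome length")
})

test_that("reads overlap the planted array at the expected rate", {
  m <- randomDNA(200)
  g <- makeGenome(80000, arraySpec(m, 100), seed = 8)   # 20 kb array / 100 kb
  spec <- readSimSpec("sanger", 500, 0, nReads = 2000, seed = 9)
  reads <- simulateReads(g, spec)
  mc <- S4Vectors::mcols(reads)
  ov <- mc$end > g$truth$start & mc$start < g$truth$end
  L <- nchar(g$sequence)
  p <- (g$truth$end - g$truth$start + 500 - 1) / L  # any overlap >= 1 bp
  expect_lt(abs(mean(ov) - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("substitution errors land at the specified rate", {
  g <- makeGenome(50000, list(), seed = 12)
  rate <- 0.02
  spec <- readSimSpec("sanger", 500, 0, substitutionError = rate,
                      nReads = 400, seed = 13)
  reads <- simulateReads(g, spec)
  mc <- S4Vectors::mcols(reads)
  truth <- substring(g$sequence, mc$start + 1, mc$end)
  obs <- as.character(reads)
  obs[mc$strand == "-"] <- revComp(obs[mc$strand == "-"])
  nmis <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 obs, truth)
  total <- sum(nchar(truth))
  # realized substitutions: a fraction 1/4... no - substituted base is always
  # different from the original, so every event is a visible mismatch
  expect_lt(abs(sum(nmis) - total * rate), 3 * sqrt(total * rate * (1 - rate)))
})

test_that("Brownian traits have the closed-form tip variance", {
  tr <- ape::read.tree(text = "(A:50,B:50);")
  diffs <- vapply(1:1000, function(i) {
    x <- simulateBMTrait(tr, sigma2 = 1, seed = i)
    x[["A"]] - x[["B"]]
  }, numeric(1))
  v <- var(diffs)   # expected 2 * sigma2 * t = 100
  expect_gt(v, 100 * 0.85)
  expect_lt(v, 100 * 1.18)
  expect_error(simulateBMTrait(tr, sigma2 = 0), "positive")
})

test_that("star-tree tips are uncorrelated under BM", {
  tr <- ape::read.tree(text = "(A:10,B:10,C:10);")
  xs <- t(vapply(1:800, function(i) simulateBMTrait(tr, 1, seed = 2000 + i),
                 numeric(3)))
  cc <- cor(xs)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.12)
})

test_that("monomer divergence saturates to background and is 100% at rate 0", {
  tr <- ape::read.tree(text = "(A:200,B:200);")
  anc <- randomDNA(200)
  tips0 <- simulateMonomerDivergence(anc, tr, 0)
  expect_identical(unname(tips0[["A"]]), anc)
  expect_equal(globalIdentity(tips0[["A"]], tips0[["B"]])$identity, 100)
  # ~20 substitutions/site on each lineage: memory of the ancestor is gone
  ids <- vapply(1:10, function(i) {
    tt <- simulateMonomerDivergence(anc, tr, 0.1, seed = i)
    globalIdentity(tt[["A"]], tt[["B"]])$identity
  }, numeric(1))
  expect_lt(abs(mean(ids) - 25), 3)
})

test_that("identity decreases with path length in expectation", {
  anc <- randomDNA(300)
  depths <- c(5, 20, 60)
  mean_id <- vapply(depths, function(d) {
    tr <- ape::read.tree(text = sprintf("(A:%d,B:%d);", d, d))
    mean(vapply(1:8, function(i) {
      tt <- simulateMonomerDivergence(anc, tr, 0.01, seed = 100 * d + i)
      globalIdentity(tt[["A"]], tt[["B"]])$identity
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_id) < 0))
})

test_that("simulation files round-trip through FASTA/FASTQ/BED", {
  m <- randomDNA(100)
  g <- makeGenome(5000, arraySpec(m, 20), seed = 30)
  reads <- simulateReads(g, readSimSpec("sanger", 300, 0, nReads = 20, seed = 31))
  pre <- file.path(tempdir(), "simtest")
  files <- writeSimulation(pre, g, reads, fastq = TRUE)
  back <- readShotgun(paste0(pre, ".reads.fq"), technology = "sanger")
  expect_identical(as.character(back), setNames(as.character(reads), names(reads)))
  bed <- read.table(paste0(pre, ".truth.bed"))
  expect_equal(bed$V2, g$truth$start)   # BED is 0-based half-open
  expect_equal(bed$V3, g$truth$end)
  unlink(files)
})
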