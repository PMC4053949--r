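# Shared fixture builders.  Everything is generated in code under fixed seeds.

# a monomer with `nsub` fixed substitutions as an edit list (for HOR variants)
make_sub_edits <- function(monomer, nsub, seed) {
  set.seed(seed)
  pos <- sample(nchar(monomer), nsub)
  lapply(pos, function(p) {
    cur <- substr(monomer, p, p)
    list(op = "sub", pos = p, base = sample(setdiff(c("A", "C", "G", "T"), cur), 1))
  })
}

# a read consisting of `copies` units of an (optionally dimeric) array
make_array_read <- function(monomer, copies, rate = 0, hor = FALSE,
                            nsub = 8, seed = 1) {
  arr <- if (hor) {
    arraySpec(monomer, copies, perCopySubstitutionRate = rate,
              horPattern = c("A", "B"),
              variantEdits = list(A = list(),
                                  B = make_sub_edits(monomer, nsub, seed + 500)))
  } else {
    arraySpec(monomer, copies, perCopySubstitutionRate = rate)
  }
  makeGenome(0, arr, seed = seed)$sequence
}

# synthetic TandemHits rows without running the detector
fake_hits <- function(read_id, start, end, period, score = 1000,
                      identity = 95, consensus = NULL) {
  if (is.null(consensus))
    consensus <- vapply(period, function(p) strrep("A", p), character(1))
  TandemHits(read_id = read_id, start = start, end = end, period = period,
             copy_number = (end - start) / period, identity = identity,
             score = score, consensus = consensus)
}

# independent point-mutator (not the package's internal one)
.mutate_copies_for_test <- function(s, rate) {
  x <- strsplit(s, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (p in hit) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

# fundamental period according to the brute-force oracle: start from the
# best-scoring period and walk down to any divisor whose identity is within
# three points (multimer templates overfit their own copies' mutations, so
# multiples of the true period score at or slightly above it)
oracle_fundamental <- function(read, qs) {
  ids <- vapply(qs, function(q) bruteForcePeriodOracle(read, q)$identity,
                numeric(1))
  p_star <- qs[which.max(ids)]
  repeat {
    cand <- qs[qs < p_star &
                 abs(p_star - round(p_star / qs) * qs) <= 1 &
                 round(p_star / qs) >= 2 &
                 ids >= ids[qs == p_star] - 3]
    if (!length(cand)) break
    p_star <- min(cand)
  }
  p_star
}

# small ultrametric timed tree
fixture_tree <- function(ntip = 20, seed = 7, depth = 50) {
  set.seed(seed)
  tr <- ape::rcoal(ntip)
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  tr
}
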