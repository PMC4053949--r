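#' Build a canonical k-mer graph from short reads
#'
#' Counts canonical k-mers (the smaller of a k-mer and its reverse
#' complement) across the reads and prunes nodes below `minCount`.  Edges are
#' (k-1)-overlaps, queried implicitly during cycle search.
#'
#' @param reads `DNAStringSet` or character vector; reads shorter than `k`
#'   are skipped, and an error is raised if none is at least `k` long.
#' @param k odd k-mer size in 15..31 (default 31; the 2-bit packing used for
#'   speed caps k at 31).
#' @param minCount prune k-mers seen fewer times (default 2, dropping
#'   sequencing-error singletons).
#' @return a [KmerGraph-class].
#' @export
buildKmerGraph <- function(reads, k = 31L, minCount = 2L) {
  seqs <- if (is.character(reads)) reads else as.character(reads)
  if (!any(nchar(seqs) >= k)) stop("k exceeds every read length")
  ptr <- .kgraph_build(seqs, as.integer(k), as.integer(minCount))
  new("KmerGraph", k = as.integer(k), ptr = ptr,
      nNodes = .kgraph_size(ptr),
      medianCoverage = .kgraph_median_coverage(ptr))
}

#' Count of specific k-mers in a graph
#' @param graph a [KmerGraph-class].
#' @param kmers character vector of k-mers (length must equal the graph's k).
#' @return numeric counts (0 for absent; NA for malformed k-mers).
#' @export
kmerCount <- function(graph, kmers) {
  .kgraph_count(graph@ptr, toupper(kmers), graph@k)
}

#' Reconstruct monomer candidates as high-coverage k-mer cycles
#'
#' The assembler role for reads too short to contain two monomer copies:
#' tandem arrays appear in the k-mer graph as cycles whose coverage exceeds
#' the genomic background by the array copy number.  Greedy max-coverage
#' walks over nodes with coverage >= `covFactor` x the graph's median spell
#' candidate cycles (SNP bubbles resolve to the majority branch); each cycle
#' in the length window is re-verified by running the tandem detector on the
#' doubled cycle sequence, which must recover a two-copy hit.  Cycles whose
#' re-detection reveals a shorter sub-period (a HOR multimer cycle) are
#' flagged, not suppressed: downstream shortest-period logic decides.
#'
#' @param graph a [KmerGraph-class] (built with pruning).
#' @param minCycle,maxCycle cycle length window in bp.
#' @param covFactor coverage multiple of the background median required of
#'   cycle nodes.
#' @param maxCycles maximum number of candidate cycles returned.
#' @return `DNAStringSet` of candidate monomers; `mcols()` carries
#'   `coverage`, `length`, `verified` (two-copy re-detection succeeded) and
#'   `multimer_of` (sub-period when the cycle is a multimer, else NA).
#' @export
findRepeatCycles <- function(graph, minCycle = 100L, maxCycle = 2000L,
                             covFactor = 5, maxCycles = 10L) {
  thr <- covFactor * max(1, graph@medianCoverage)
  res <- .kgraph_cycles(graph@ptr, graph@k, thr, as.integer(minCycle),
                        as.integer(maxCycle), as.integer(maxCycles))
  cyc <- res$cycle
  if (!length(cyc)) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      coverage = numeric(), length = integer(), verified = logical(),
      multimer_of = integer())
    return(out)
  }
  verified <- logical(length(cyc))
  multimer_of <- rep(NA_integer_, length(cyc))
  consensus <- character(length(cyc))
  for (i in seq_along(cyc)) {
    doubled <- strrep(cyc[i], 2L)
    h <- detectTandem(doubled, minPeriod = max(10L, as.integer(minCycle / 4)),
                      maxPeriod = nchar(cyc[i]))
    consensus[i] <- cyc[i]
    if (nrow(h)) {
      near <- which(abs(h$period - nchar(cyc[i])) <= 2)
      verified[i] <- length(near) > 0
      sub <- h$period[h$period < 0.75 * nchar(cyc[i])]
      if (length(sub)) {
        m <- nchar(cyc[i]) / min(sub)
        if (abs(m - round(m)) < 0.05 && round(m) >= 2)
          multimer_of[i] <- as.integer(min(sub))
      }
      if (length(near)) consensus[i] <- h$consensus[near[which.max(h$score[near])]]
    }
  }
  out <- Biostrings::DNAStringSet(consensus)
  names(out) <- sprintf("cycle_%03d", seq_along(consensus))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    coverage = res$coverage, length = nchar(consensus),
    verified = verified, multimer_of = multimer_of)
  out
}

#' Short-read monomer reconstruction, end to end
#'
#' Samples reads (200,000 by default, the pipeline's assembly sample size),
#' builds the k-mer graph and extracts verified repeat cycles.  When the
#' reads are long enough for direct detection (mean length >= 2 x
#' `maxCycle`) the stage is skipped with a warning, mirroring the
#' technology routing of the discovery pipeline.
#'
#' @param reads `DNAStringSet` of short reads.
#' @param k,minCount,minCycle,maxCycle,covFactor,maxCycles see
#'   [buildKmerGraph()] and [findRepeatCycles()].
#' @param sampleSize reads sampled before graph construction.
#' @param seed RNG seed for the read sample.
#' @return `DNAStringSet` of candidate monomers (possibly empty), or NULL
#'   when the stage is skipped.
#' @export
reconstructMonomers <- function(reads, k = 31L, minCount = 2L,
                                minCycle = 100L, maxCycle = 2000L,
                                covFactor = 5, maxCycles = 10L,
                                sampleSize = 200000L, seed = 1L) {
  if (mean(Biostrings::width(reads)) >= 2 * maxCycle) {
    warning("reads are long enough for direct detection; reconstruction skipped")
    return(NULL)
  }
  reads <- sampleReads(reads, sampleSize, seed)
  g <- buildKmerGraph(reads, k = k, minCount = minCount)
  findRepeatCycles(g, minCycle = minCycle, maxCycle = maxCycle,
                   covFactor = covFactor, maxCycles = maxCycles)
}
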