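#' Tandem repeat hits within reads
#'
#' A `DataFrame` subclass holding one row per detected tandem repeat.
#' Coordinates are 0-based half-open on the read.  Columns: `read_id`,
#' `start`, `end`, `period` (consensus monomer length, bp), `copy_number`
#' (aligned span / period), `identity` (percent identity of the array against
#' its consensus), `score` (wraparound alignment score) and `consensus`
#' (the monomer consensus sequence, length == `period`).
#'
#' @export
setClass("TandemHits", contains = "DFrame")

.tandemhits_cols <- c("read_id", "start", "end", "period", "copy_number",
                      "identity", "score", "consensus")

setValidity("TandemHits", function(object) {
  miss <- setdiff(.tandemhits_cols, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object)) {
    if (any(object$period != nchar(object$consensus)))
      return("period must equal nchar(consensus)")
    if (any(object$copy_number < 2))
      return("emitted hits require copy_number >= 2")
    if (any(object$end <= object$start))
      return("end must exceed start")
  }
  TRUE
})

#' Construct a TandemHits object
#'
#' @param read_id,start,end,period,copy_number,identity,score,consensus
#'   per-hit vectors; see [TandemHits-class].
#' @return a [TandemHits-class] object.
#' @export
TandemHits <- function(read_id = character(), start = integer(),
                       end = integer(), period = integer(),
                       copy_number = numeric(), identity = numeric(),
                       score = integer(), consensus = character()) {
  new("TandemHits", DataFrame(
    read_id = as.character(read_id), start = as.integer(start),
    end = as.integer(end), period = as.integer(period),
    copy_number = as.numeric(copy_number), identity = as.numeric(identity),
    score = as.integer(score), consensus = as.character(consensus)))
}

#' k-mer graph of a read set
#'
#' Canonical k-mer counts held in native code; the graph's edges are implicit
#' ((k-1)-overlaps queried on demand).  Built by [buildKmerGraph()] and
#' consumed by [findRepeatCycles()].
#'
#' @slot k k-mer size (odd, 15-31).
#' @slot ptr external pointer to the count table.
#' @slot nNodes number of distinct canonical k-mers retained.
#' @slot medianCoverage median k-mer count (the background coverage level).
#' @export
setClass("KmerGraph", representation(
  k = "integer", ptr = "externalptr", nNodes = "numeric",
  medianCoverage = "numeric"))

setMethod("show", "KmerGraph", function(object) {
  cat("KmerGraph: k =", object@k, "|", format(object@nNodes, big.mark = ","),
      "nodes | median coverage", object@medianCoverage, "\n")
})

#' Species-level repeat profile
#'
#' The ranked repeat families of one species, produced by [buildProfile()].
#' The rank-1 cluster is the candidate centromere repeat (the package's
#' central assumption: the most abundant tandem repeat is the centromere
#' repeat).
#'
#' @slot species species label.
#' @slot technology sequencing regime ("sanger", "short" or "long").
#' @slot clusters `DataFrame` of repeat clusters, ranked, rank 1 first.
#' @slot genomeSize genome size in bp (NA if unknown).
#' @slot chromosomeCount haploid chromosome number (NA if unknown).
#' @slot nReads number of sampled reads the profile is based on.
#' @export
setClass("RepeatProfile", representation(
  species = "character", technology = "character", clusters = "DFrame",
  genomeSize = "numeric", chromosomeCount = "numeric", nReads = "integer"))

setValidity("RepeatProfile", function(object) {
  cl <- object@clusters
  if (nrow(cl)) {
    if (!all(c("cluster_id", "kind", "rank", "consensus", "length",
               "supporting_read_fraction") %in% colnames(cl)))
      return("clusters is missing required columns")
    g <- cl[cl$kind == "global", , drop = FALSE]
    if (nrow(g) && g$rank[1] != 1L)
      return("the first global cluster must have rank 1")
  }
  TRUE
})

setMethod("show", "RepeatProfile", function(object) {
  cat("RepeatProfile for", object@species, "(", object@technology, "reads )\n")
  cat(" ", nrow(object@clusters), "clusters from", object@nReads, "sampled reads\n")
  cand <- candidateRepeat(object)
  if (!is.null(cand)) {
    cat("  candidate monomer:", cand$length, "bp, GC", round(cand$gc, 3),
        ", read fraction", signif(cand$supporting_read_fraction, 3))
    if (!is.na(cand$genomic_fraction))
      cat(", genomic fraction", signif(cand$genomic_fraction, 3))
    cat("\n")
  }
})
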