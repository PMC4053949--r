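#' Read shotgun sequences from FASTA or FASTQ
#'
#' Multi-line FASTA is tolerated; FASTQ qualities are assumed Phred+33 and
#' kept in `mcols()$qual`.  A technology tag ("sanger", "short", "long") is
#' attached to every read for downstream routing and QC thresholds.
#'
#' @param path input file; format is taken from the first character
#'   ('>' FASTA, '@' FASTQ).
#' @param technology technology tag for the whole file.
#' @return `DNAStringSet` with `mcols()$technology` (and `qual` for FASTQ).
#' @export
readShotgun <- function(path, technology = c("sanger", "short", "long")) {
  technology <- match.arg(technology)
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (identical(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(technology = technology, qual = qual)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(technology = technology)
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Uniformly sample reads without replacement
#'
#' Deterministic given the seed; input order is preserved in the output.
#' Returns the full set when fewer than `n` reads are available.
#'
#' @param reads `DNAStringSet` (or any subsettable read container).
#' @param n sample size (>= 1).
#' @param seed integer RNG seed.
#' @return the sampled subset.
#' @export
sampleReads <- function(reads, n, seed = 1L) {
  stopifnot(n >= 1)
  if (length(reads) <= n) return(reads)
  set.seed(seed)
  idx <- sort(sample.int(length(reads), n))
  reads[idx]
}

#' Length and N-content pre-filter
#'
#' Drops reads whose fraction of Ns exceeds `maxNFraction` and reads shorter
#' than the per-technology minimum length (Sanger 100 bp, long reads 1,000 bp;
#' 50 bp for the short regime).  Order is preserved and the filter is
#' idempotent.
#'
#' @param reads `DNAStringSet` with `mcols()$technology`, or set `technology`.
#' @param maxNFraction maximum tolerated N fraction (default 0.05; reads with
#'   more than 5% Ns are removed).
#' @param minLen named vector of per-technology minimum lengths (bp).
#' @param technology override the per-read technology tag.
#' @return filtered `DNAStringSet`.
#' @export
qcFilter <- function(reads, maxNFraction = 0.05,
                     minLen = c(sanger = 100, short = 50, long = 1000),
                     technology = NULL) {
  if (length(reads) == 0) return(reads)
  tech <- technology %||% S4Vectors::mcols(reads)$technology
  if (is.null(tech)) stop("reads carry no technology tag; pass `technology`")
  tech <- rep_len(as.character(tech), length(reads))
  unknown <- setdiff(unique(tech), names(minLen))
  if (length(unknown))
    stop("no minimum length configured for technology: ",
         paste(unknown, collapse = ", "))
  nfrac <- as.numeric(Biostrings::letterFrequency(reads, "N")) /
    Biostrings::width(reads)
  keep <- nfrac <= maxNFraction &
    Biostrings::width(reads) >= unname(minLen[tech])
  reads[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DUST-style low-complexity masking
#'
#' Scores 64-bp windows (step 32) by their overlapping-triplet composition,
#' `S = sum c_t (c_t - 1) / 2 / n_triplets`, and flags windows with `S`
#' above the threshold; flagged windows are merged into maximal intervals.
#' The score is invariant to case, so masking an already soft-masked read
#' reproduces the same intervals.
#'
#' @param read one read: a character string, `DNAString`, or a length-1
#'   `DNAStringSet`.
#' @param window window size in bp (>= 3).
#' @param threshold score threshold (classic default 2.0).
#' @param step window step in bp.
#' @return integer matrix with columns `start`,`end`: 0-based half-open
#'   low-complexity intervals (possibly zero rows).
#' @export
dustMask <- function(read, window = 64L, threshold = 2.0, step = 32L) {
  stopifnot(window >= 3)
  s <- if (is.character(read)) read else as.character(read)[1]
  .dust_intervals(s, as.integer(window), threshold, as.integer(step))
}

#' Soft-mask intervals of a sequence
#'
#' Lowercases the given 0-based half-open intervals.  The tandem detector
#' ignores hits whose span is more than half soft-masked.
#'
#' @param seq character DNA string.
#' @param intervals matrix as returned by [dustMask()].
#' @return the soft-masked string.
#' @export
softMask <- function(seq, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(seq)
  for (i in seq_len(nrow(intervals))) {
    a <- intervals[i, 1]; b <- intervals[i, 2]
    substr(seq, a + 1, b) <- tolower(substr(seq, a + 1, b))
  }
  seq
}

#' Apply DUST soft-masking to a whole read set
#'
#' @param reads `DNAStringSet`.
#' @inheritParams dustMask
#' @return character vector of soft-masked read sequences (names preserved).
#' @export
dustMaskSet <- function(reads, window = 64L, threshold = 2.0, step = 32L) {
  seqs <- as.character(reads)
  out <- vapply(seqs, function(s) {
    softMask(s, .dust_intervals(s, as.integer(window), threshold,
                                as.integer(step)))
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(reads)
  out
}

#' Optional fixed-end trimming hook
#'
#' A minimal stand-in for vector/quality clipping of trace reads: trims a
#' fixed number of bases from each end.
#'
#' @param reads `DNAStringSet`.
#' @param left,right bases to trim from each end.
#' @return trimmed `DNAStringSet` (reads shorter than the trim are dropped).
#' @export
trimEnds <- function(reads, left = 0L, right = 0L) {
  keep <- Biostrings::width(reads) > left + right
  reads <- reads[keep]
  if (!length(reads)) return(reads)
  IRanges::narrow(reads, start = left + 1L,
                  end = Biostrings::width(reads) - right)
}
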