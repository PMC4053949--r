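#' Specification of a planted tandem array
#'
#' Describes one tandem array to plant in a synthetic genome: a base monomer,
#' a copy count, an independent per-base substitution rate applied to every
#' copy, and optionally a higher-order repeat pattern (an ordered cycle of
#' variant labels, e.g. `c("A","B")` for a dimeric HOR) with per-variant edits
#' relative to the base monomer.
#'
#' @param monomer DNA string over ACGTN, length >= 1.
#' @param copies number of monomer copies (>= 1).
#' @param perCopySubstitutionRate per-base substitution probability applied
#'   independently in every copy, in \[0,1\].
#' @param horPattern optional character vector of variant labels; copies cycle
#'   through the pattern (so `c("A","B")` yields A,B,A,B,...).
#' @param variantEdits named list (one entry per label in `horPattern`); each
#'   entry is a list of edits, each edit a list with `op` ("sub", "ins" or
#'   "del"), `pos` (1-based position in the base monomer) and, for sub/ins,
#'   `base`.
#' @return an `array_spec` object.
#' @export
arraySpec <- function(monomer, copies, perCopySubstitutionRate = 0,
                      horPattern = NULL, variantEdits = NULL) {
  monomer <- toupper(monomer)
  if (nchar(monomer) < 1) stop("monomer length must be >= 1")
  if (grepl("[^ACGTN]", monomer)) stop("monomer contains non-ACGTN characters")
  if (copies < 1) stop("copies must be >= 1")
  if (perCopySubstitutionRate < 0 || perCopySubstitutionRate > 1)
    stop("perCopySubstitutionRate must be in [0,1]")
  if (!is.null(horPattern)) {
    miss <- setdiff(unique(horPattern), names(variantEdits))
    if (length(miss))
      stop("horPattern labels without variantEdits entry: ",
           paste(miss, collapse = ", "))
  }
  structure(list(monomer = monomer, copies = as.integer(copies),
                 perCopySubstitutionRate = perCopySubstitutionRate,
                 horPattern = horPattern, variantEdits = variantEdits),
            class = "array_spec")
}

# apply an edit list to a monomer string
.apply_edits <- function(monomer, edits) {
  s <- strsplit(monomer, "", fixed = TRUE)[[1]]
  # apply from right to left so positions stay valid under indels
  ord <- order(vapply(edits, function(e) e$pos, numeric(1)), decreasing = TRUE)
  for (e in edits[ord]) {
    if (e$op == "sub") s[e$pos] <- toupper(e$base)
    else if (e$op == "ins") s <- append(s, toupper(e$base), after = e$pos)
    else if (e$op == "del") s <- s[-e$pos]
    else stop("unknown edit op: ", e$op)
  }
  paste(s, collapse = "")
}

.mutate_copies <- function(units, rate) {
  if (rate <= 0) return(units)
  lens <- nchar(units)
  joined <- paste(units, collapse = "")
  raw <- charToRaw(joined)
  n <- length(raw)
  nmut <- rbinom(1L, n, rate)
  if (nmut > 0) {
    pos <- sample.int(n, nmut)
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    cur <- rawToChar(raw[pos], multiple = TRUE)
    new <- vapply(cur, function(b) {
      a <- alt[[b]]
      if (is.null(a)) b else sample(a, 1)
    }, character(1))
    raw[pos] <- charToRaw(paste(new, collapse = ""))
  }
  joined <- rawToChar(raw)
  ends <- cumsum(lens)
  substring(joined, c(1L, head(ends, -1) + 1L), ends)
}

#' Build a synthetic genome with planted tandem arrays
#'
#' Background sequence is i.i.d. uniform ACGT; each array is the concatenation
#' of its (mutated) monomer copies, and arrays are placed at evenly spaced
#' offsets within the background.  Coordinates of planted arrays are returned
#' both 0-based half-open and as a `GRanges` for export.
#'
#' @param backgroundLength background bp (>= 0).
#' @param arrays list of [arraySpec()] objects.
#' @param seed integer RNG seed; the generator is a pure function of its
#'   inputs and this seed.
#' @return list with `sequence` (character), `truth` (data.frame with 0-based
#'   half-open `start`,`end`, monomer, unit length, copies) and `granges`
#'   (the same intervals as a `GRanges` on seqname "genome").
#' @export
makeGenome <- function(backgroundLength, arrays, seed = 1L) {
  stopifnot(backgroundLength >= 0)
  if (inherits(arrays, "array_spec")) arrays <- list(arrays)
  set.seed(seed)
  units_per_array <- lapply(arrays, function(a) {
    labels <- if (is.null(a$horPattern)) NULL
              else rep_len(a$horPattern, a$copies)
    base_units <- if (is.null(labels)) rep(a$monomer, a$copies)
                  else vapply(labels, function(l) {
                    ed <- a$variantEdits[[l]]
                    if (length(ed)) .apply_edits(a$monomer, ed) else a$monomer
                  }, character(1))
    .mutate_copies(unname(base_units), a$perCopySubstitutionRate)
  })
  array_seqs <- vapply(units_per_array, paste, character(1), collapse = "")
  k <- length(arrays)
  bg_chunk_sizes <- if (k == 0) backgroundLength else {
    sizes <- rep(backgroundLength %/% (k + 1), k + 1)
    sizes[k + 1] <- sizes[k + 1] + backgroundLength %% (k + 1)
    sizes
  }
  pieces <- character(0)
  truth <- data.frame(start = integer(0), end = integer(0),
                      monomer = character(0), unit_length = integer(0),
                      copies = integer(0))
  pos <- 0L
  for (i in seq_len(k)) {
    bg <- randomDNA(bg_chunk_sizes[i])
    pieces <- c(pieces, bg)
    pos <- pos + nchar(bg)
    pieces <- c(pieces, array_seqs[i])
    truth <- rbind(truth, data.frame(
      start = pos, end = pos + nchar(array_seqs[i]),
      monomer = arrays[[i]]$monomer,
      unit_length = nchar(arrays[[i]]$monomer),
      copies = arrays[[i]]$copies))
    pos <- pos + nchar(array_seqs[i])
  }
  pieces <- c(pieces, randomDNA(bg_chunk_sizes[length(bg_chunk_sizes)]))
  genome <- paste(pieces, collapse = "")
  gr <- if (nrow(truth))
    GenomicRanges::GRanges("genome",
                           IRanges::IRanges(start = truth$start + 1L, end = truth$end),
                           unit_length = truth$unit_length, copies = truth$copies)
  else GenomicRanges::GRanges()
  list(sequence = genome, truth = truth, granges = gr)
}

#' Read simulation specification
#'
#' @param technology one of "sanger", "short", "long".
#' @param readLengthMean,readLengthSd read length distribution (bp); lengths
#'   are drawn normal and rounded, floored at 30 bp.
#' @param substitutionError,indelError per-base error rates in \[0, 0.2\].
#' @param nReads number of reads (>= 1).
#' @param seed integer RNG seed.
#' @return a `read_sim_spec` object.
#' @export
readSimSpec <- function(technology = c("sanger", "short", "long"),
                        readLengthMean = 800, readLengthSd = 0,
                        substitutionError = 0, indelError = 0,
                        nReads = 1000, seed = 1L) {
  technology <- match.arg(technology)
  if (nReads < 1) stop("nReads must be >= 1")
  if (substitutionError < 0 || substitutionError > 0.2 ||
      indelError < 0 || indelError > 0.2)
    stop("error rates must be in [0, 0.2]")
  structure(list(technology = technology, readLengthMean = readLengthMean,
                 readLengthSd = readLengthSd,
                 substitutionError = substitutionError,
                 indelError = indelError, nReads = as.integer(nReads),
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

.inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  .mutate_copies(seqs, rate)
}

# 1-bp indels; insertions 60% / deletions 40% (crude long-read chemistry mix)
.inject_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_events <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_events > 0)
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (e in seq_len(n_events[i])) {
      p <- sample.int(length(s), 1)
      if (runif(1) < 0.6) s <- append(s, sample(c("A", "C", "G", "T"), 1), after = p)
      else if (length(s) > 1) s <- s[-p]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate shotgun reads from a genome
#'
#' Reads are uniform substrings of the genome; each read is reverse
#' complemented with probability 0.5, then substitution and 1-bp indel errors
#' are injected at the spec's rates.  Deterministic given the spec seed.
#'
#' @param genome character genome string, or the list from [makeGenome()].
#' @param spec a [readSimSpec()].
#' @return a `DNAStringSet`; `mcols()` carries `start`, `end` (0-based
#'   half-open on the forward genome), `strand` and `technology`.
#' @export
simulateReads <- function(genome, spec) {
  if (is.list(genome)) genome <- genome$sequence
  L <- nchar(genome)
  if (L < spec$readLengthMean)
    stop("mean read length exceeds genome length")
  set.seed(spec$seed)
  n <- spec$nReads
  lens <- if (spec$readLengthSd > 0)
    pmax(30L, pmin(L, as.integer(round(rnorm(n, spec$readLengthMean,
                                             spec$readLengthSd)))))
  else rep(as.integer(spec$readLengthMean), n)
  starts <- as.integer(floor(runif(n) * (L - lens + 1)))  # 0-based
  seqs <- substring(genome, starts + 1L, starts + lens)
  is_rc <- runif(n) < 0.5
  if (any(is_rc)) seqs[is_rc] <- revComp(seqs[is_rc])
  seqs <- .inject_substitutions(seqs, spec$substitutionError)
  seqs <- .inject_indels(seqs, spec$indelError)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("read_%06d", seq_len(n))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    start = starts, end = starts + lens,
    strand = ifelse(is_rc, "-", "+"), technology = spec$technology)
  out
}

#' Simulate a trait under Brownian motion on a timed tree
#'
#' Tip values accumulate independent normal increments along each branch with
#' variance `sigma2` per million years (branch-length unit).
#'
#' @param tree an `ape::phylo` with branch lengths in MY.
#' @param sigma2 Brownian rate (variance per MY), > 0.
#' @param seed integer RNG seed.
#' @return named numeric vector of tip values (root value 0).
#' @export
simulateBMTrait <- function(tree, sigma2, seed = 1L) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0)
}

#' Evolve a monomer along a timed tree by Jukes-Cantor substitutions
#'
#' Each tip receives the ancestor sequence evolved along its root-to-tip path
#' with `subsPerBpPerMY * branch length` expected substitutions per site
#' (Jukes-Cantor model, so identity saturates at the 25% background).
#'
#' @param ancestor DNA string at the root.
#' @param tree timed `phylo` (branch lengths in MY).
#' @param subsPerBpPerMY substitution rate, > 0 (0 is accepted and returns
#'   identical tips).
#' @param seed integer RNG seed.
#' @return named character vector of tip monomers.
#' @export
simulateMonomerDivergence <- function(ancestor, tree, subsPerBpPerMY,
                                      seed = 1L) {
  if (subsPerBpPerMY < 0) stop("rate must be >= 0")
  ancestor <- toupper(ancestor)
  if (subsPerBpPerMY == 0) {
    out <- rep(ancestor, ape::Ntip(tree))
    names(out) <- tree$tip.label
    return(out)
  }
  set.seed(seed)
  rootseq <- tolower(strsplit(ancestor, "", fixed = TRUE)[[1]])
  sim <- phangorn::simSeq(tree, l = nchar(ancestor), rootseq = rootseq,
                          type = "DNA", rate = subsPerBpPerMY)
  m <- toupper(as.character(sim))
  out <- apply(m, 1, paste, collapse = "")
  out[tree$tip.label]
}

#' Write a simulated data set to disk
#'
#' FASTA (or FASTQ with flat Phred 30 qualities) for the reads, FASTA for the
#' genome, and a BED file of the planted array coordinates for truth tracking.
#'
#' @param prefix output path prefix.
#' @param genome list from [makeGenome()].
#' @param reads `DNAStringSet` from [simulateReads()].
#' @param fastq write reads as FASTQ instead of FASTA.
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(prefix, genome, reads, fastq = FALSE) {
  gfa <- paste0(prefix, ".genome.fa")
  gseq <- Biostrings::DNAStringSet(genome$sequence)
  names(gseq) <- "genome"
  Biostrings::writeXStringSet(gseq, gfa)
  rfile <- paste0(prefix, if (fastq) ".reads.fq" else ".reads.fa")
  if (fastq) {
    q <- Biostrings::PhredQuality(vapply(Biostrings::width(reads),
                                         function(w) paste(rep("?", w), collapse = ""),
                                         character(1)))
    Biostrings::writeXStringSet(reads, rfile, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(reads, rfile)
  }
  bed <- paste0(prefix, ".truth.bed")
  rtracklayer::export(genome$granges, bed, format = "BED")
  invisible(c(gfa, rfile, bed))
}
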