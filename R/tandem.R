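#' Tandem detector options
#'
#' Scoring follows the classic tandem-repeat finder defaults: match +2,
#' mismatch -7, indel -7, minimum reported alignment score 50.  Period
#' candidates come from the distance histogram of exact k-mer re-occurrences
#' within the read (k = 12 for reads >= 500 bp, 8 otherwise), requiring at
#' least `minSupport` re-occurrences at a given distance.
#'
#' @param match,mismatch,indel wraparound alignment scores.
#' @param minScore minimum alignment score for an emitted hit.
#' @param minSupport minimum k-mer re-occurrence support for a candidate
#'   period.
#' @param maxCandidates number of candidate periods examined per read (by
#'   support, descending).
#' @param maxMaskedFraction hits whose span is more than this fraction
#'   soft-masked are dropped.
#' @return list of detector options.
#' @export
tandemOpts <- function(match = 2L, mismatch = -7L, indel = -7L,
                       minScore = 50L, minSupport = 3L, maxCandidates = 6L,
                       maxMaskedFraction = 0.5) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       indel = as.integer(indel), minScore = as.integer(minScore),
       minSupport = as.integer(minSupport),
       maxCandidates = as.integer(maxCandidates),
       maxMaskedFraction = maxMaskedFraction)
}

#' Detect tandem repeats within a single read
#'
#' The detector (i) proposes candidate periods from the distance histogram of
#' exact k-mer re-occurrences, (ii) builds an initial consensus by stacking
#' period-length windows and taking the column majority, (iii) refines unit
#' boundaries and the consensus by wraparound dynamic programming of the read
#' against the circular consensus, and (iv) reports period, span, copy
#' number (= aligned span / period), percent identity of the array against
#' the consensus, and the alignment score.  Hits with fewer than two copies
#' are suppressed, so reads shorter than `2 * minPeriod` yield no hits.
#'
#' Multimer periods (2x, 3x the basic monomer) are reported as separate hits
#' when supported; the shortest-period rule of [filterHits()] removes them
#' for abundance profiling while [detectHOR()] consumes them.
#'
#' @param read one read: character string (may be soft-masked lowercase) or
#'   `DNAString`/length-1 `DNAStringSet`.
#' @param minPeriod,maxPeriod period search range (bp); `maxPeriod` is capped
#'   at half the read length (two-copy requirement) and at 2,000 bp unless
#'   `Inf` is passed, in which case only the read-length cap applies.
#' @param readId read identifier for the output.
#' @param opts detector options from [tandemOpts()].
#' @return a [TandemHits-class] object (zero rows when nothing is found).
#' @export
detectTandem <- function(read, minPeriod = 1L, maxPeriod = 2000L,
                         readId = "read", opts = tandemOpts()) {
  s <- if (is.character(read)) read else as.character(read)[1]
  rows <- .detect_core(s, minPeriod, maxPeriod, opts)
  .hits_from_rows(rows, readId)
}

# plain-list detector core; returns NULL or a list of per-hit lists
.detect_core <- function(s, minPeriod, maxPeriod, opts) {
  n <- nchar(s)
  hard_cap <- floor(n / 2)
  maxp <- if (is.finite(maxPeriod)) min(as.integer(maxPeriod), hard_cap) else hard_cap
  if (n < 2 * minPeriod || maxp < minPeriod) return(NULL)
  k <- if (n >= 500) 12L else 8L
  cand <- .period_candidates(s, k, as.integer(minPeriod), as.integer(maxp),
                             opts$minSupport)
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(-cand[, "support"]), , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), opts$maxCandidates)), , drop = FALSE]
  cand <- cand[order(cand[, "period"]), , drop = FALSE]

  hits <- list()
  cons_by_period <- list()
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, "period"]
    reg_a <- cand[r, "region_start"]; reg_b <- cand[r, "region_end"]
    if (reg_b - reg_a < 2 * p) {  # widen to the read if support region is tight
      reg_a <- max(0L, reg_a - p); reg_b <- min(n, reg_b + p)
      if (reg_b - reg_a < 2 * p) next
    }
    # tie-break reference: the consensus of a detected sub-period, repeated
    tie_ref <- NULL
    for (q in names(cons_by_period)) {
      pq <- as.integer(q)
      m <- round(p / pq)
      if (m >= 2 && abs(p - m * pq) <= 2) {
        tie_ref <- substr(strrep(cons_by_period[[q]], m + 1L), 1L, p)
        break
      }
    }
    # align only the support region plus one period of margin on each side;
    # the k-mer pairs bracket the array, and skipping the non-repetitive
    # remainder of the read leaves the alignment unchanged
    win_a <- max(0L, reg_a - p); win_b <- min(n, reg_b + p)
    sub <- substr(s, win_a + 1, win_b)
    # seed with the single unit anchored at the support region start (a
    # global window stack desynchronizes when the array carries indels or
    # truncated units); wraparound DP iterations refine it to the majority
    cons <- toupper(substr(s, reg_a + 1, reg_a + p))
    aln <- .wraparound_align(sub, cons, opts$match, opts$mismatch, opts$indel)
    for (iter in 1:4) {
      cons2 <- .consensus_from_counts(aln$counts, tie_ref %||% cons)
      if (identical(cons2, cons)) break
      cons <- cons2
      aln <- .wraparound_align(sub, cons, opts$match, opts$mismatch, opts$indel)
    }
    copy_number <- (aln$end - aln$start) / p
    if (copy_number < 2 || aln$score < opts$minScore) next
    if (.soft_masked_fraction(s, win_a + aln$start, win_a + aln$end) >
        opts$maxMaskedFraction) next
    cons_by_period[[as.character(p)]] <- cons
    hits[[length(hits) + 1L]] <- list(
      start = win_a + aln$start, end = win_a + aln$end, period = p,
      copy_number = copy_number,
      identity = 100 * aln$matches / max(1L, aln$cols),
      score = aln$score, consensus = cons)
  }
  if (!length(hits)) return(NULL)
  # collapse near-identical periods (+-2 bp): keep the best-scoring one
  periods <- vapply(hits, `[[`, numeric(1), "period")
  scores <- vapply(hits, `[[`, numeric(1), "score")
  keep <- rep(TRUE, length(hits))
  taken <- integer(0)
  for (i in order(-scores)) {
    if (any(abs(periods[i] - periods[taken]) <= 2)) keep[i] <- FALSE
    else taken <- c(taken, i)
  }
  hits <- hits[keep]
  # drop shadowed artifacts: a hit whose span is occupied by another hit
  # with clearly higher identity at an unrelated (non-multiple) period -
  # typically a compressed-period alignment stretched over the array by
  # indels, seeded from internal monomer structure
  if (length(hits) > 1) {
    keep <- rep(TRUE, length(hits))
    for (i in seq_along(hits)) for (j in seq_along(hits)) {
      if (i == j || !keep[i]) next
      hi <- hits[[i]]; hj <- hits[[j]]
      inter <- min(hi$end, hj$end) - max(hi$start, hj$start)
      if (inter <= 0) next
      same_span <- inter / (hi$end - hi$start) >= 0.9 &&
        inter / (hj$end - hj$start) >= 0.9
      if (!same_span) next
      long_p <- max(hi$period, hj$period); short_p <- min(hi$period, hj$period)
      r <- long_p / short_p
      tau <- long_p - floor(r) * short_p
      multiple_related <- abs(r - round(r)) <= 0.03 * round(r) ||
        (tau >= 0.2 * short_p && tau <= 0.8 * short_p)  # truncated-unit HOR
      if (!multiple_related && hj$identity >= hi$identity + 5)
        keep[i] <- FALSE
    }
    hits <- hits[keep]
  }
  hits
}

.hits_from_rows <- function(rows, read_ids) {
  if (is.null(rows) || !length(rows)) return(TandemHits())
  TandemHits(
    read_id = read_ids,
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    period = vapply(rows, `[[`, numeric(1), "period"),
    copy_number = vapply(rows, `[[`, numeric(1), "copy_number"),
    identity = vapply(rows, `[[`, numeric(1), "identity"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    consensus = vapply(rows, `[[`, character(1), "consensus"))
}

#' Detect tandem repeats across a read set
#'
#' @param reads named character vector (possibly soft-masked, see
#'   [dustMaskSet()]) or `DNAStringSet`.
#' @inheritParams detectTandem
#' @return a [TandemHits-class] with one row per hit across all reads.
#' @export
detectTandemSet <- function(reads, minPeriod = 1L, maxPeriod = 2000L,
                            opts = tandemOpts()) {
  seqs <- if (is.character(reads)) reads else as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  rows <- list()
  row_ids <- character(0)
  for (i in seq_along(seqs)) {
    r <- .detect_core(seqs[[i]], minPeriod, maxPeriod, opts)
    if (!is.null(r)) {
      rows <- c(rows, r)
      row_ids <- c(row_ids, rep(ids[i], length(r)))
    }
  }
  .hits_from_rows(rows, row_ids)
}

#' Brute-force period oracle
#'
#' Independent reference for the detector: for a fixed period `p`, every
#' phase offset in `[0, p)` is evaluated by scoring the read against the
#' tandem extension of its own unit at that phase; the maximum column
#' agreement is returned.  The template unit's own positions are excluded
#' from the score (they match trivially), so random sequence scores near the
#' 25% background for every period.  Exhaustive and alignment-free, so
#' useful as a test oracle but insensitive to indels.
#'
#' @param read character read (uppercased internally).
#' @param p period to evaluate; requires `2p <= nchar(read)`.
#' @return list with `identity` (percent, best over phases) and `phase`.
#' @export
bruteForcePeriodOracle <- function(read, p) {
  s <- toupper(if (is.character(read)) read else as.character(read)[1])
  n <- nchar(s)
  stopifnot(2 * p <= n)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- -1; best_phase <- 0L
  for (phase in 0:(p - 1)) {
    if (phase + p > n) break
    unit <- x[(phase + 1):(phase + p)]
    pred <- unit[((seq_len(n) - 1 - phase) %% p) + 1]
    after <- if (phase + p < n) (phase + p + 1):n else integer(0)
    outside <- c(seq_len(phase), after)
    ident <- 100 * mean(pred[outside] == x[outside])
    if (ident > best) { best <- ident; best_phase <- phase }
  }
  list(identity = best, phase = best_phase)
}

#' Candidate filters on tandem hits
#'
#' Applies the pipeline's candidate rules: hits spanning less than
#' `minSpanFraction` of their read are removed (default 80%), hits with
#' period below `minPeriod` (default 50 bp) are removed, and among hits of
#' one read occupying approximately the same span (reciprocal overlap >= 0.9)
#' only the shortest period is retained.
#'
#' @param hits a [TandemHits-class].
#' @param readLengths named integer vector of read lengths (bp), names
#'   matching `read_id`.
#' @param minSpanFraction minimum fraction of the read the array must cover.
#' @param minPeriod minimum monomer length (bp).
#' @param reciprocalOverlap overlap fraction defining "the same span".
#' @return filtered [TandemHits-class].
#' @export
filterHits <- function(hits, readLengths, minSpanFraction = 0.8,
                       minPeriod = 50L, reciprocalOverlap = 0.9) {
  if (nrow(hits) == 0) return(hits)
  rl <- readLengths[hits$read_id]
  if (any(is.na(rl))) stop("readLengths missing for some read_id")
  span_ok <- (hits$end - hits$start) / rl >= minSpanFraction
  period_ok <- hits$period >= minPeriod
  hits <- hits[span_ok & period_ok, ]
  if (nrow(hits) <= 1) return(hits)
  keep <- logical(nrow(hits))
  for (id in unique(hits$read_id)) {
    idx <- which(hits$read_id == id)
    # shortest period first; ties by higher score
    ord <- idx[order(hits$period[idx], -hits$score[idx])]
    taken <- integer(0)
    for (i in ord) {
      ov <- FALSE
      for (j in taken) {
        inter <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
        if (inter > 0 &&
            inter / (hits$end[i] - hits$start[i]) >= reciprocalOverlap &&
            inter / (hits$end[j] - hits$start[j]) >= reciprocalOverlap) {
          ov <- TRUE; break
        }
      }
      if (!ov) { keep[i] <- TRUE; taken <- c(taken, i) }
    }
  }
  hits[keep, ]
}

#' Write hits as TSV
#' @param hits a [TandemHits-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeHits <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
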