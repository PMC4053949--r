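#' Random DNA sequence
#'
#' Uniform i.i.d. sequence over ACGT, the background model used throughout the
#' package (it is what makes 25% the expected identity of unrelated sequence).
#'
#' @param n sequence length in bp.
#' @return A character scalar of length-`n` DNA.
#' @export
randomDNA <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of character DNA
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rotate a circular sequence
#'
#' @param s DNA string.
#' @param k left rotation offset (0 <= k < nchar(s)).
#' @return rotated string: `s[k+1..n] s[1..k]`.
#' @export
rotateSeq <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

#' GC content of a DNA string
#' @param s DNA string (character).
#' @return fraction of G+C among A/C/G/T bases.
#' @export
gcContent <- function(s) {
  x <- Biostrings::DNAStringSet(toupper(s))
  f <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  as.numeric((f[, "G"] + f[, "C"]) / pmax(1, rowSums(f)))
}

# fraction of lowercase (soft-masked) characters within [start, end) 0-based
.soft_masked_fraction <- function(seq, start, end) {
  span <- substr(seq, start + 1, end)
  chars <- strsplit(span, "", fixed = TRUE)[[1]]
  mean(chars %in% c("a", "c", "g", "t", "n"))
}

# column-majority consensus of equal-length unit strings; ties resolved toward
# tie_ref (if given and among the tied bases) else alphabetically
.majority_consensus <- function(units, tie_ref = NULL) {
  p <- nchar(units[1])
  stopifnot(all(nchar(units) == p))
  m <- matrix(unlist(strsplit(toupper(units), "", fixed = TRUE), use.names = FALSE),
              ncol = p, byrow = TRUE)
  ref <- if (!is.null(tie_ref)) strsplit(toupper(tie_ref), "", fixed = TRUE)[[1]] else NULL
  bases <- c("A", "C", "G", "T")
  out <- character(p)
  for (j in seq_len(p)) {
    cnt <- tabulate(match(m[, j], bases), nbins = 4L)
    mx <- max(cnt)
    tied <- bases[cnt == mx]
    if (length(tied) > 1L && !is.null(ref) && ref[j] %in% tied) out[j] <- ref[j]
    else out[j] <- tied[1L]
  }
  paste(out, collapse = "")
}

# consensus from a 4 x p count matrix (rows A,C,G,T), ties toward tie_ref
.consensus_from_counts <- function(counts, tie_ref = NULL) {
  bases <- c("A", "C", "G", "T")
  p <- ncol(counts)
  ref <- if (!is.null(tie_ref)) strsplit(toupper(tie_ref), "", fixed = TRUE)[[1]] else NULL
  out <- character(p)
  for (j in seq_len(p)) {
    cj <- counts[, j]
    mx <- max(cj)
    if (mx == 0L) { out[j] <- if (!is.null(ref)) ref[j] else "A"; next }
    tied <- bases[cj == mx]
    if (length(tied) > 1L && !is.null(ref) && ref[j] %in% tied) out[j] <- ref[j]
    else out[j] <- tied[1L]
  }
  paste(out, collapse = "")
}

# stable sub-seeds derived from one master seed (kept < 2^31)
.subseed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483629L
}
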