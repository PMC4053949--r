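#' Canonical form of a monomer
#'
#' Tandem repeat boundaries are arbitrary, so a monomer is only defined up to
#' rotation and strand.  The canonical form is the lexicographic minimum over
#' the 2L strings (rotations of the sequence and of its reverse complement);
#' canonicalization is idempotent, and two monomers are rotations/strand
#' flips of each other iff their canonical forms are equal.
#'
#' @param monomer non-empty ACGT string (no Ns; resolve Ns upstream).
#' @return the canonical monomer (character scalar).
#' @export
canonicalizeMonomer <- function(monomer) {
  s <- toupper(if (is.character(monomer)) monomer else as.character(monomer))
  if (nchar(s) == 0) stop("empty monomer")
  if (grepl("[^ACGT]", s)) stop("monomer must contain only ACGT")
  n <- nchar(s)
  dd <- paste0(s, s)
  rc <- revComp(s)
  ddrc <- paste0(rc, rc)
  cand <- c(substring(dd, 1:n, n:(2 * n - 1)),
            substring(ddrc, 1:n, n:(2 * n - 1)))
  min(cand)
}

# rotation of `member` best matching `ref` (equal lengths; Hamming distance)
.best_rotation <- function(member, ref) {
  n <- nchar(member)
  dd <- paste0(member, member)
  rots <- substring(dd, 1:n, n:(2 * n - 1))
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  dists <- vapply(rots, function(r) {
    sum(strsplit(r, "", fixed = TRUE)[[1]] != ref_chars)
  }, numeric(1))
  rots[which.min(dists)]
}

# consensus of a cluster: among members of modal length, rotate each onto the
# best-supported member and take the support-weighted column majority
.cluster_consensus <- function(seqs, support) {
  lens <- nchar(seqs)
  tab <- tapply(support, lens, sum)
  modal_len <- as.integer(names(tab)[which.max(tab)])
  sel <- which(lens == modal_len)
  rep_seq <- seqs[sel[which.max(support[sel])]]
  aligned <- vapply(seqs[sel], function(s) {
    if (identical(s, rep_seq)) s else .best_rotation(s, rep_seq)
  }, character(1))
  expanded <- rep(aligned, times = pmax(1L, support[sel]))
  canonicalizeMonomer(.majority_consensus(expanded, rep_seq))
}

#' Cluster monomers into repeat families
#'
#' Clusters the canonical monomers of the hits' consensus sequences by
#' rotation-tolerant within-species identity.  Membership is built greedily
#' against cluster representatives (processing order: support, then length,
#' then sequence - deterministic), followed by a representative merge pass,
#' which reproduces the connected components of the pairwise identity graph
#' whenever clusters are separated by clear identity gaps - the situation
#' this threshold is chosen for - at a linear instead of quadratic number of
#' alignments.  "Local" clusters require identity >= the threshold; "global"
#' clusters additionally require near-identical lengths (ratio >=
#' `lengthRatioThreshold`).  Each cluster's consensus is the support-weighted
#' column majority of a rotation-aligned member stack, in canonical form.
#'
#' @param hits a [TandemHits-class] (typically after [filterHits()]).
#' @param totalReads number of sampled reads the hits came from (denominator
#'   of `supporting_read_fraction`).
#' @param identityThreshold fraction in (0,1\]; edge when identity >=
#'   100 * threshold.
#' @param lengthRatioThreshold minimum pairwise length ratio inside a global
#'   cluster.
#' @param sampleSize at most this many hits are clustered (uniform sample).
#' @param seed RNG seed for the hit sample.
#' @param model within-species alignment model.
#' @return `DataFrame` of clusters: `cluster_id`, `kind` ("global"/"local"),
#'   `rank` (global clusters only, 1 = most abundant), `consensus`
#'   (canonical), `length`, `gc`, `n_hits`, `n_reads`,
#'   `supporting_read_fraction`, `genomic_fraction` (NA; see
#'   [estimateGenomicFraction()]).
#' @export
clusterMonomers <- function(hits, totalReads, identityThreshold = 0.80,
                            lengthRatioThreshold = 0.95, sampleSize = 5000L,
                            seed = 1L, model = identityModelWithin()) {
  empty <- DataFrame(cluster_id = character(), kind = character(),
                     rank = integer(), consensus = character(),
                     length = integer(), gc = numeric(), n_hits = integer(),
                     n_reads = integer(),
                     supporting_read_fraction = numeric(),
                     genomic_fraction = numeric())
  if (nrow(hits) == 0) return(empty)
  if (nrow(hits) > sampleSize) {
    set.seed(seed)
    hits <- hits[sort(sample.int(nrow(hits), sampleSize)), ]
  }
  canon <- vapply(hits$consensus, canonicalizeMonomer, character(1),
                  USE.NAMES = FALSE)
  uniq <- unique(canon)
  grp <- match(canon, uniq)
  support <- tabulate(grp, nbins = length(uniq))
  lens <- nchar(uniq)
  thr <- 100 * identityThreshold
  # identity can only reach thr when the shorter/longer length ratio allows it
  min_ratio <- max(0, (identityThreshold - model$backgroundRate) /
                        (1 - model$backgroundRate))
  nu <- length(uniq)
  pair_id <- function(i, j) {
    ord <- if (lens[i] >= lens[j]) c(i, j) else c(j, i)
    globalIdentity(uniq[ord[1]], uniq[ord[2]], model)$identity
  }
  # greedy assignment to cluster representatives, then merge representatives
  greedy_membership <- function(need_len_ratio) {
    ord <- order(-support, -lens, uniq)
    member <- integer(nu)
    reps <- integer(0)
    for (i in ord) {
      joined <- FALSE
      for (ci in seq_along(reps)) {
        r <- reps[ci]
        ratio <- min(lens[i], lens[r]) / max(lens[i], lens[r])
        if (ratio < min_ratio) next
        if (need_len_ratio && ratio < lengthRatioThreshold) next
        if (pair_id(i, r) >= thr) { member[i] <- ci; joined <- TRUE; break }
      }
      if (!joined) { reps <- c(reps, i); member[i] <- length(reps) }
    }
    if (length(reps) > 1) {   # merge clusters whose representatives match
      g <- igraph::make_empty_graph(length(reps), directed = FALSE)
      for (a in seq_len(length(reps) - 1)) for (b in (a + 1):length(reps)) {
        ra <- reps[a]; rb <- reps[b]
        ratio <- min(lens[ra], lens[rb]) / max(lens[ra], lens[rb])
        if (ratio < min_ratio) next
        if (need_len_ratio && ratio < lengthRatioThreshold) next
        if (pair_id(ra, rb) >= thr) g <- igraph::add_edges(g, c(a, b))
      }
      comp <- igraph::components(g)$membership
      member <- comp[member]
    }
    member
  }
  local_m <- greedy_membership(FALSE)
  global_m <- greedy_membership(TRUE)

  build_rows <- function(membership, kind) {
    out <- list()
    for (cid in unique(membership)) {
      sel <- which(membership == cid)
      hsel <- which(grp %in% sel)
      n_reads <- length(unique(hits$read_id[hsel]))
      cons <- .cluster_consensus(uniq[sel], support[sel])
      out[[length(out) + 1L]] <- DataFrame(
        kind = kind, consensus = cons, length = nchar(cons),
        gc = gcContent(cons), n_hits = length(hsel), n_reads = n_reads,
        supporting_read_fraction = n_reads / totalReads,
        genomic_fraction = NA_real_)
    }
    do.call(rbind, out)
  }
  glob <- build_rows(global_m, "global")
  loc <- build_rows(local_m, "local")
  # total, stable ranking of the global clusters
  ord <- order(-glob$supporting_read_fraction, -glob$length, glob$consensus)
  glob <- glob[ord, ]
  glob$rank <- seq_len(nrow(glob))
  glob$cluster_id <- sprintf("G%03d", glob$rank)
  loc <- loc[order(-loc$supporting_read_fraction, -loc$length, loc$consensus), ]
  loc$rank <- NA_integer_
  loc$cluster_id <- sprintf("L%03d", seq_len(nrow(loc)))
  cols <- c("cluster_id", "kind", "rank", "consensus", "length", "gc",
            "n_hits", "n_reads", "supporting_read_fraction",
            "genomic_fraction")
  rbind(glob[, cols], loc[, cols])
}

#' Genomic fraction of a repeat family from read alignment
#'
#' The proportion of sampled reads matching the monomer: a read counts when
#' its best local alignment against the doubled consensus (either strand)
#' reaches `minIdentity` over at least `minCoverage` of the shorter of read
#' and monomer.  Read-count abundance follows the pipeline's definition and
#' is subject to the usual library and sampling biases.
#'
#' @param consensus monomer (canonical or not).
#' @param reads `DNAStringSet` or character vector of sampled reads (an
#'   unbiased sample of the genome).
#' @param minIdentity minimum alignment identity (fraction).
#' @param minCoverage minimum aligned fraction of `min(read, monomer)`.
#' @param model within-species alignment model.
#' @param prefilterK reads are pre-screened for an exact shared k-mer with
#'   the doubled consensus (strand-aware); only those are aligned.
#' @return fraction of matching reads in \[0,1\].
#' @export
estimateGenomicFraction <- function(consensus, reads, minIdentity = 0.70,
                                    minCoverage = 0.50,
                                    model = identityModelWithin(),
                                    prefilterK = 12L) {
  seqs <- toupper(if (is.character(reads)) reads else as.character(reads))
  if (!length(seqs)) stop("no reads given")
  cons <- toupper(if (is.character(consensus)) consensus
                  else as.character(consensus))
  dd <- paste0(cons, cons)
  cand <- which(.reads_sharing_kmer(seqs, dd, as.integer(prefilterK)))
  if (!length(cand)) return(0)
  n_match <- 0L
  for (i in cand) {
    lmin <- min(nchar(seqs[i]), nchar(cons))
    st <- .sw_stats(seqs[i], dd, model$match, model$mismatch, model$gapOpen,
                    model$gapExtend)
    rc <- .sw_stats(revComp(seqs[i]), dd, model$match, model$mismatch,
                    model$gapOpen, model$gapExtend)
    if (rc$score > st$score) st <- rc
    if (st$cols >= minCoverage * lmin &&
        st$matches >= minIdentity * st$cols) n_match <- n_match + 1L
  }
  n_match / length(seqs)
}

#' Average amount of repeat per chromosome
#'
#' @param fraction genomic fraction of the repeat.
#' @param genomeSize genome size in bp.
#' @param chromosomes haploid chromosome count.
#' @return bp of repeat per chromosome, or NA when metadata is missing.
#' @export
perChromosomeAmount <- function(fraction, genomeSize, chromosomes) {
  if (is.na(genomeSize) || is.na(chromosomes)) return(NA_real_)
  stopifnot(fraction >= 0, genomeSize > 0, chromosomes > 0)
  fraction * genomeSize / chromosomes
}

#' Does a species lack high-copy tandem repeats?
#'
#' Compares the candidate repeat's genomic fraction against that of a
#' designated low-repeat control (the holocentric nematode C. elegans in the
#' original analysis); strictly lower means the species can be assumed to
#' lack a high-copy centromere tandem repeat.
#'
#' @param profile a [RepeatProfile-class].
#' @param controlFraction genomic fraction of the control species.
#' @return TRUE iff the candidate fraction is strictly below the control.
#' @export
classifyLowRepeat <- function(profile, controlFraction) {
  cand <- candidateRepeat(profile)
  if (is.null(cand)) return(TRUE)
  frac <- cand$genomic_fraction
  if (is.na(frac)) stop("candidate has no genomic fraction estimate")
  frac < controlFraction
}

#' Build a species-level repeat profile
#'
#' Clusters the (filtered) hits, ranks families by supporting-read fraction,
#' and optionally estimates genomic fractions for the top global clusters.
#'
#' @param hits filtered [TandemHits-class].
#' @param reads the sampled reads the hits came from.
#' @param species species label.
#' @param technology sequencing regime.
#' @param genomeSize,chromosomeCount optional metadata (bp / count).
#' @param estimateFractionsTop estimate genomic fraction for this many
#'   top-ranked global clusters (0 to skip).
#' @param ... passed to [clusterMonomers()].
#' @return a [RepeatProfile-class].
#' @export
buildProfile <- function(hits, reads, species = "species",
                         technology = "sanger", genomeSize = NA_real_,
                         chromosomeCount = NA_real_,
                         estimateFractionsTop = 1L, ...) {
  cl <- clusterMonomers(hits, totalReads = length(reads), ...)
  if (estimateFractionsTop > 0 && nrow(cl)) {
    top <- which(cl$kind == "global" & cl$rank <= estimateFractionsTop)
    for (i in top) {
      cl$genomic_fraction[i] <- estimateGenomicFraction(cl$consensus[i], reads)
    }
  }
  new("RepeatProfile", species = species, technology = technology,
      clusters = cl, genomeSize = as.numeric(genomeSize),
      chromosomeCount = as.numeric(chromosomeCount),
      nReads = length(reads))
}

#' Write a profile to JSON (and its clusters to TSV)
#'
#' @param profile a [RepeatProfile-class].
#' @param path output JSON path; a sibling `.clusters.tsv` is written too.
#' @return invisibly, `path`.
#' @export
writeProfile <- function(profile, path) {
  cl <- as.data.frame(clusters(profile))
  obj <- list(species = profile@species, technology = profile@technology,
              genome_size = profile@genomeSize,
              chromosome_count = profile@chromosomeCount,
              n_reads = profile@nReads, clusters = cl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  write.table(cl, sub("\\.json$", ".clusters.tsv", path), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
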