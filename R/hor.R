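#' Detect higher-order repeat structure from overlapping hits
#'
#' Works on the unfiltered hits of a read (HOR detection needs exactly the
#' multimer hits the shortest-period rule discards).  Hit pairs occupying
#' approximately the same span (reciprocal overlap >= `overlapThreshold`)
#' are tested for a multimer relationship: the longer period is close to an
#' integer multiple of the shorter (tolerance `periodTol` of m*p), or fits a
#' truncated-unit model (m full units plus one truncated unit of 20-80% of
#' the monomer).  A call is emitted only when the multimer's identity AND
#' score strictly exceed the monomer's - the signature that the multimer,
#' not the monomer, is the true repeating unit.
#'
#' Two guards keep the caller quiet on homogeneous (variant-free) arrays: a
#' pair whose periods are both multiples of a shorter detected period is
#' skipped (the pair is already explained by that sub-period), and the
#' identity gain must clear `minIdentityGain` - a multimer consensus is fit
#' on fewer units per column, which by itself yields fraction-of-a-point
#' gains on homogeneous arrays, an order of magnitude below the gain from
#' genuine variant structure.
#'
#' @param hits a [TandemHits-class], unfiltered, one or more reads.
#' @param overlapThreshold reciprocal span overlap required of a pair.
#' @param periodTol multimer period tolerance as a fraction of m*p.
#' @param minIdentityGain minimum identity gain in percentage points.
#' @return `DataFrame` of HOR calls: `read_id`, `monomer_period`,
#'   `multimer_period`, `multiplicity`, `identity_gain`, `score_gain`,
#'   `truncated_unit_len` (NA for exact multimers).
#' @export
detectHOR <- function(hits, overlapThreshold = 0.9, periodTol = 0.03,
                      minIdentityGain = 0.5) {
  empty <- DataFrame(read_id = character(), monomer_period = integer(),
                     multimer_period = integer(), multiplicity = integer(),
                     identity_gain = numeric(), score_gain = numeric(),
                     truncated_unit_len = integer())
  if (nrow(hits) < 2) return(empty)
  out <- list()
  for (id in unique(hits$read_id)) {
    h <- hits[hits$read_id == id, ]
    if (nrow(h) < 2) next
    ord <- order(h$period)
    for (a in seq_len(nrow(h) - 1)) for (b in (a + 1):nrow(h)) {
      i <- ord[a]; j <- ord[b]           # i = shorter period (monomer)
      p <- h$period[i]; P <- h$period[j]
      inter <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
      if (inter <= 0) next
      if (inter / (h$end[i] - h$start[i]) < overlapThreshold ||
          inter / (h$end[j] - h$start[j]) < overlapThreshold) next
      # both periods multiples of a shorter detected period spanning the
      # same region? then that sub-period explains the pair
      sub <- which(h$period < p)
      sub <- sub[vapply(sub, function(s2) {
        ov <- min(h$end[i], h$end[s2]) - max(h$start[i], h$start[s2])
        ov > 0 && ov / (h$end[i] - h$start[i]) >= overlapThreshold &&
          ov / (h$end[s2] - h$start[s2]) >= overlapThreshold
      }, logical(1))]
      explained <- any(vapply(h$period[sub], function(q) {
        mp <- round(p / q); mP <- round(P / q)
        mp >= 2 && mP >= 2 && abs(p - mp * q) <= periodTol * p &&
          abs(P - mP * q) <= periodTol * P
      }, logical(1)))
      if (explained) next
      m <- round(P / p)
      trunc_len <- NA_integer_
      mult <- NA_integer_
      if (m >= 2 && abs(P - m * p) <= periodTol * m * p) {
        mult <- m
      } else {
        m_full <- floor(P / p)
        tau <- P - m_full * p
        if (m_full >= 1 && tau >= 0.2 * p && tau <= 0.8 * p) {
          mult <- m_full + 1L
          trunc_len <- as.integer(tau)
        }
      }
      if (is.na(mult) || mult < 2) next
      id_gain <- h$identity[j] - h$identity[i]
      sc_gain <- h$score[j] - h$score[i]
      if (id_gain < minIdentityGain || sc_gain <= 0) next
      out[[length(out) + 1L]] <- DataFrame(
        read_id = id, monomer_period = p, multimer_period = P,
        multiplicity = as.integer(mult), identity_gain = id_gain,
        score_gain = as.numeric(sc_gain), truncated_unit_len = trunc_len)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Cut a tandem array into its monomer instances
#'
#' Re-aligns the read against the hit's circular consensus and cuts at the
#' consensus-aligned unit boundaries; boundaries tile the hit span without
#' gaps or overlaps, and partial first/last units are discarded.  Instances
#' outside +-20% of the period are dropped (indel-broken units).
#'
#' @param read the read sequence (character or `DNAString`).
#' @param hit one row of a [TandemHits-class].
#' @param opts detector options (alignment scores).
#' @return list with `instances` (character vector of unit sequences, in
#'   read order), `boundaries` (0-based cut points) and `period`.
#' @export
extractInstances <- function(read, hit, opts = tandemOpts()) {
  s <- toupper(if (is.character(read)) read else as.character(read)[1])
  stopifnot(nrow(hit) == 1)
  aln <- .wraparound_align(s, hit$consensus, opts$match, opts$mismatch,
                           opts$indel)
  b <- aln$boundaries
  if (length(b) < 2)
    return(list(instances = character(0), boundaries = b,
                period = hit$period))
  inst <- substring(s, head(b, -1) + 1, b[-1])
  p <- hit$period
  keep <- nchar(inst) >= 0.8 * p & nchar(inst) <= 1.2 * p
  list(instances = inst[keep], boundaries = b, period = p)
}

#' Cluster monomer instances from one read
#'
#' Distances are 1 - identity over aligned columns (instances are already in
#' phase, so no rotation is needed); a neighbor-joining tree is built, cut in
#' two at its deepest internal edge, and the split's support estimated by
#' bootstrap over alignment columns.  For a dimeric HOR, the two classes
#' alternate along the read.
#'
#' @param instances character vector of >= 4 unit sequences (from
#'   [extractInstances()]).
#' @param nBoot bootstrap replicates over columns.
#' @param seed RNG seed for the bootstrap.
#' @return list: `labels` (integer class per instance), `tree` (`phylo`, or
#'   NULL when all instances are identical), `support` (percent bootstrap
#'   support of the two-class split).
#' @export
clusterInstances <- function(instances, nBoot = 100L, seed = 1L) {
  n <- length(instances)
  if (n < 4) stop("instance clustering needs at least 4 full units")
  L <- min(nchar(instances))
  m <- t(vapply(substr(instances, 1, L),
                function(s) strsplit(s, "", fixed = TRUE)[[1]],
                character(L), USE.NAMES = FALSE))
  rownames(m) <- sprintf("unit_%02d", seq_len(n))
  if (all(apply(m, 2, function(col) length(unique(col)) == 1)))
    return(list(labels = rep(1L, n), tree = NULL, support = NA_real_))
  dist_from <- function(mat) {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
    }
    rownames(d) <- colnames(d) <- rownames(mat)
    stats::as.dist(d)
  }
  deepest_split <- function(d) {
    tr <- ape::nj(d)
    internal <- which(tr$edge[, 2] > n)
    if (!length(internal)) return(list(tree = tr, split = NULL))
    e <- internal[which.max(tr$edge.length[internal])]
    child <- tr$edge[e, 2]
    tips <- .clade_tips(tr)[[child - n]]
    side <- sort(tr$tip.label[tips])
    # canonical representation: the side containing the first tip
    if (!(tr$tip.label[1] %in% side))
      side <- sort(setdiff(tr$tip.label, side))
    list(tree = tr, split = side)
  }
  obs <- deepest_split(dist_from(m))
  labels <- ifelse(rownames(m) %in% obs$split, 1L, 2L)
  if (is.null(obs$split)) labels <- rep(1L, n)
  set.seed(seed)
  hits <- 0L
  for (bi in seq_len(nBoot)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    bs <- tryCatch(deepest_split(dist_from(m[, cols, drop = FALSE])),
                   error = function(e) NULL)
    if (!is.null(bs) && !is.null(bs$split) && identical(bs$split, obs$split))
      hits <- hits + 1L
  }
  list(labels = labels, tree = obs$tree, support = 100 * hits / nBoot)
}

#' Half-alignment test for dimer-origin monomers
#'
#' Tests whether a long monomer is a doubled (HOR-derived) version of a
#' short one: the long monomer is split at its midpoint and each half is
#' compared to the short monomer with the rotation-tolerant global identity.
#' Both halves aligning well - each with its own specific polymorphisms -
#' is the signature of a dimer origin.
#'
#' @param longMonomer,shortMonomer DNA strings with length ratio in
#'   \[1.8, 2.2\] (otherwise the test refuses).
#' @param model an [identityModel()].
#' @return list: `identity_first`, `identity_second` (percent), and
#'   `diff_columns` (positions of the short monomer mismatching in exactly
#'   one half; NA when half and monomer lengths differ).
#' @export
halfAlignmentTest <- function(longMonomer, shortMonomer,
                              model = identityModel()) {
  lng <- toupper(as.character(longMonomer))
  sht <- toupper(as.character(shortMonomer))
  ratio <- nchar(lng) / nchar(sht)
  if (ratio < 1.8 || ratio > 2.2)
    stop("length ratio ", round(ratio, 2),
         " outside [1.8, 2.2]: not a candidate doubled monomer")
  mid <- nchar(lng) %/% 2
  h1 <- substr(lng, 1, mid)
  h2 <- substr(lng, mid + 1, nchar(lng))
  id1 <- globalIdentity(h1, sht, model)
  id2 <- globalIdentity(h2, sht, model)
  diff_cols <- NA
  if (nchar(h1) == nchar(sht) && nchar(h2) == nchar(sht)) {
    r1 <- .best_rotation(h1, sht)
    r2 <- .best_rotation(h2, sht)
    sc <- strsplit(sht, "", fixed = TRUE)[[1]]
    mm1 <- which(strsplit(r1, "", fixed = TRUE)[[1]] != sc)
    mm2 <- which(strsplit(r2, "", fixed = TRUE)[[1]] != sc)
    diff_cols <- sort(union(setdiff(mm1, mm2), setdiff(mm2, mm1)))
  }
  list(identity_first = id1$identity, identity_second = id2$identity,
       diff_columns = diff_cols)
}
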