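#' Alignment model for monomer identity
#'
#' Cross-species comparisons use match +1, mismatch -1, gap open 2, gap
#' extend 2, word size 8; within-species clustering uses the alternative gap
#' open/extend 3 with word size 10 (see [identityModelWithin()]).  Unaligned
#' regions are credited at the 25% background match rate.  `minHSPScore`
#' plays the role of the aligner's significance cutoff: a best local
#' alignment below it (or lacking an exact `wordSize` match run, the seed
#' requirement) counts as "no alignment", leaving the pair at background
#' identity.
#'
#' @param match,mismatch,gapOpen,gapExtend local alignment scores (a gap of
#'   length g costs `gapOpen + g * gapExtend`).
#' @param wordSize minimum exact match run the accepted alignment must
#'   contain.
#' @param backgroundRate expected identity of unrelated sequence (0.25).
#' @param minHSPScore minimum accepted local alignment score.
#' @return an identity model (list).
#' @export
identityModel <- function(match = 1L, mismatch = -1L, gapOpen = 2L,
                          gapExtend = 2L, wordSize = 8L,
                          backgroundRate = 0.25, minHSPScore = 16L) {
  stopifnot(backgroundRate >= 0, backgroundRate <= 1)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
       wordSize = as.integer(wordSize), backgroundRate = backgroundRate,
       minHSPScore = as.integer(minHSPScore))
}

#' @rdname identityModel
#' @export
identityModelWithin <- function() {
  identityModel(gapOpen = 3L, gapExtend = 3L, wordSize = 10L)
}

# best local alignment of a against doubled b, both strands; returns stats
.pair_align <- function(a, b, model) {
  bb <- paste0(b, b)
  f <- .sw_stats(a, bb, model$match, model$mismatch, model$gapOpen,
                 model$gapExtend)
  r <- .sw_stats(revComp(a), bb, model$match, model$mismatch, model$gapOpen,
                 model$gapExtend)
  if (r$score > f$score) r else f
}

#' Circular-permutation-tolerant global identity of two monomers
#'
#' Tandem repeat boundaries are arbitrary, so related monomers can align in a
#' staggered fashion.  The best local alignment of `a` (either strand) is
#' therefore computed against the doubled partner `b+b`, which makes rotation
#' transparent.  A global percent identity is then formed by crediting the
#' unaligned remainder at the background match rate: with `L = max(len a,
#' len b)`,
#' `identity = 100 * (matches + backgroundRate * (L - aligned_cols_on_a)) / L`.
#' Pairs with no accepted alignment sit at `100 * backgroundRate`.
#'
#' @param a,b DNA strings (monomers; canonical form not required).
#' @param model an [identityModel()].
#' @return list: `identity` (percent), `alignedLen` (alignment columns),
#'   `matches`, `score`, `aligned` (logical: did an accepted HSP exist).
#' @export
globalIdentity <- function(a, b, model = identityModel()) {
  a <- toupper(if (is.character(a)) a else as.character(a))
  b <- toupper(if (is.character(b)) b else as.character(b))
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  L <- max(nchar(a), nchar(b))
  best <- .pair_align(a, b, model)
  accepted <- best$score >= model$minHSPScore && best$max_run >= model$wordSize
  if (!accepted)
    return(list(identity = 100 * model$backgroundRate, alignedLen = 0L,
                matches = 0L, score = best$score, aligned = FALSE))
  cols_a <- min(best$cols_a, L)
  ident <- 100 * (best$matches + model$backgroundRate * (L - cols_a)) / L
  list(identity = max(0, min(100, ident)), alignedLen = best$cols,
       matches = best$matches, score = best$score, aligned = TRUE)
}

#' All-vs-all identity matrix
#'
#' Each unordered pair is computed once (query = the longer monomer, ties by
#' name) so the matrix is exactly symmetric.
#'
#' @param monomers named character vector or `DNAStringSet` (names =
#'   species).
#' @param model an [identityModel()].
#' @return symmetric numeric matrix of percent identities (diagonal 100).
#' @export
identityMatrix <- function(monomers, model = identityModel()) {
  seqs <- toupper(if (is.character(monomers)) monomers else as.character(monomers))
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ord <- order(c(nchar(seqs[i]), nchar(seqs[j])), decreasing = TRUE)
    pair <- c(i, j)[ord]
    id <- globalIdentity(seqs[pair[1]], seqs[pair[2]], model)$identity
    m[i, j] <- m[j, i] <- id
  }
  m
}

#' Similarity groups of species
#'
#' Connected components of the graph whose edges join species with monomer
#' identity at or above the threshold; singletons are omitted.
#'
#' @param mat identity matrix from [identityMatrix()].
#' @param threshold percent identity defining an edge.
#' @return list of character vectors (species groups of size >= 2).
#' @export
similarityGroups <- function(mat, threshold) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  adj <- mat >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  unname(lapply(groups, sort))
}

#' Randomly resolve polytomies of a timed tree
#'
#' Multifurcations are replaced by random binary subtrees with zero-length
#' internal branches, so pairwise tip path lengths are unchanged.
#' Deterministic given the seed; already-binary trees are returned as-is.
#'
#' @param tree `ape::phylo`.
#' @param seed integer RNG seed.
#' @return binary `phylo`.
#' @export
resolvePolytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  ape::multi2di(tree, random = TRUE)
}

# node ages: for ultrametric trees the classic branching times; otherwise the
# mean root-to-tip distance of the node's clade minus the node depth
.node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ages <- numeric(nnode)
  tipsets <- .clade_tips(tree)
  for (i in seq_len(nnode)) {
    node <- ntip + i
    tips <- tipsets[[i]]
    ages[i] <- mean(depth[tips]) - depth[node]
  }
  names(ages) <- as.character(ntip + seq_len(nnode))
  ages
}

# tip indices below each internal node; node order in phylo is not guaranteed
# postorder, so accumulate until stable
.clade_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  sets <- vector("list", tree$Nnode)
  get_set <- function(v) if (v <= ntip) v else sets[[v - ntip]]
  remaining <- rep(TRUE, tree$Nnode)
  while (any(remaining)) {
    progressed <- FALSE
    for (i in which(remaining)) {
      ch <- tree$edge[tree$edge[, 1] == ntip + i, 2]
      ready <- all(vapply(ch, function(v) v <= ntip || !remaining[v - ntip],
                          logical(1)))
      if (ready) {
        sets[[i]] <- sort(unique(unlist(lapply(ch, get_set))))
        remaining[i] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("malformed tree edges")
  }
  sets
}

#' Node-averaged identity contrasts
#'
#' For each internal node of a binary timed tree, averages the pairwise
#' identity over exactly the tip pairs whose most recent common ancestor is
#' that node, yielding one value H per node at the node's age t.  Pairs
#' partition: summed over nodes, `n_pairs` equals `choose(n_tips, 2)`.
#'
#' @param tree binary `phylo` with branch lengths in MY.
#' @param mat identity matrix over the tree's tips (names must match).
#' @return `DataFrame` with `node`, `age`, `mean_identity`, `n_pairs`.
#' @export
nodeAverage <- function(tree, mat) {
  stopifnot(ape::is.binary(tree))
  miss <- setdiff(tree$tip.label, rownames(mat))
  if (length(miss))
    stop("identity matrix missing tips: ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  tipsets <- .clade_tips(tree)
  ages <- .node_ages(tree)
  rows <- lapply(seq_len(tree$Nnode), function(i) {
    node <- ntip + i
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    sets <- lapply(ch, function(v) if (v <= ntip) v else tipsets[[v - ntip]])
    ids <- numeric(0)
    for (a in seq_len(length(sets) - 1)) for (b in (a + 1):length(sets)) {
      la <- tree$tip.label[sets[[a]]]; lb <- tree$tip.label[sets[[b]]]
      ids <- c(ids, as.numeric(mat[la, lb, drop = FALSE]))
    }
    DataFrame(node = node, age = unname(ages[as.character(node)]),
              mean_identity = mean(ids), n_pairs = length(ids))
  })
  do.call(rbind, rows)
}

#' Fit the identity-decay model H ~ alpha * t^lambda
#'
#' Nonlinear least squares (Gaussian residuals) on the node-averaged
#' contrasts, started from the log-log linear fit.  `t_background` is the
#' smallest age at which the fitted curve reaches the background identity
#' (Inf when it never does).
#'
#' @param contrasts `DataFrame`/data.frame from [nodeAverage()] (columns
#'   `age`, `mean_identity`); only points with age > 0 enter the fit.
#' @param model an [identityModel()] (supplies the background rate).
#' @return list: `alpha`, `lambda`, `residual_sd`, `t_background`, `fit`
#'   (the `nls` object).
#' @export
fitDecay <- function(contrasts, model = identityModel()) {
  d <- as.data.frame(contrasts)
  d <- d[d$age > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 contrasts with age > 0")
  if (length(unique(d$age)) < 2) stop("degenerate input: constant age")
  H <- pmax(d$mean_identity, 1e-6)
  t <- d$age
  start_fit <- lm(log(H) ~ log(t))
  start <- list(a = unname(exp(coef(start_fit)[1])),
                l = unname(coef(start_fit)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(H ~ a * t^l, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)   # e.g. an exactly flat curve: lm start is exact
  if (is.null(fit)) {
    a <- start$a; l <- start$l
    rsd <- sqrt(sum((H - a * t^l)^2) / max(1, nrow(d) - 2))
  } else {
    a <- coef(fit)[["a"]]; l <- coef(fit)[["l"]]
    rsd <- sqrt(sum(residuals(fit)^2) / max(1, nrow(d) - 2))
  }
  B <- 100 * model$backgroundRate
  t_bg <- if (a <= B && l >= 0) min(t)
          else if (l < 0) (B / a)^(1 / l)
          else Inf
  list(alpha = a, lambda = l, residual_sd = rsd,
       t_background = t_bg, fit = fit)
}

#' Blomberg's K and its permutation test
#'
#' Phylogenetic signal of a tip trait: the observed ratio MSE0/MSE (mean
#' squared deviation from the phylogenetically corrected mean over the GLS
#' mean squared error under the tree's Brownian covariance) divided by its
#' analytic Brownian expectation.  K is about 1 for traits evolved by
#' Brownian motion, < 1 when relatives resemble each other less than that
#' expectation, > 1 when more.  Significance comes from permuting trait
#' values across tips (one-tailed, greater).
#'
#' @param tree binary `phylo` with branch lengths.
#' @param trait named numeric vector over the tips.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return list: `K`, `observedRatio`, `expectedRatio`, `p`, `nPerm`.
#' @export
blombergK <- function(tree, trait, nPerm = 999L, seed = 1L) {
  x <- trait[tree$tip.label]
  if (any(is.na(x))) stop("trait values missing for some tips")
  if (var(x) == 0) stop("zero-variance trait")
  n <- length(x)
  stopifnot(nPerm >= 99)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  ones <- rep(1, n)
  sum_cinv <- sum(Cinv)
  cinv_rowsum <- Cinv %*% ones
  expected <- (sum(diag(C)) - n / sum_cinv) / (n - 1)
  ratio <- function(v) {
    ahat <- sum(cinv_rowsum * v) / sum_cinv
    dev <- v - ahat
    mse0 <- sum(dev^2) / (n - 1)
    mse <- as.numeric(crossprod(dev, Cinv %*% dev)) / (n - 1)
    mse0 / mse
  }
  obs <- ratio(x)
  K <- obs / expected
  set.seed(seed)
  perm_k <- vapply(seq_len(nPerm), function(i) ratio(sample(x)) / expected,
                   numeric(1))
  p <- (1 + sum(perm_k >= K)) / (nPerm + 1)
  list(K = K, observedRatio = obs, expectedRatio = expected, p = p,
       nPerm = as.integer(nPerm))
}

#' Non-phylogenetic rank correlations among repeat traits
#'
#' Pairwise Spearman correlations among monomer length, GC content and log2
#' genomic fraction (plus genome size and chromosome number when present).
#'
#' @param traits data.frame with a `species` column and numeric trait
#'   columns among `length`, `gc`, `fraction`, `genome_size`, `chromosomes`;
#'   or a list of [RepeatProfile-class] objects.
#' @return `DataFrame` with `trait_a`, `trait_b`, `rho`, `p`, `n`.
#' @export
traitCorrelations <- function(traits) {
  if (is.list(traits) && length(traits) && inherits(traits[[1]], "RepeatProfile")) {
    traits <- do.call(rbind, lapply(traits, function(p) {
      cand <- candidateRepeat(p)
      data.frame(species = p@species, length = cand$length, gc = cand$gc,
                 fraction = cand$genomic_fraction,
                 genome_size = p@genomeSize, chromosomes = p@chromosomeCount)
    }))
  }
  stopifnot(nrow(traits) >= 3)
  d <- traits
  if (!is.null(d$fraction)) d$fraction <- log2(pmax(d$fraction, 1e-12))
  vars <- intersect(c("length", "gc", "fraction", "genome_size", "chromosomes"),
                    colnames(d))
  vars <- vars[vapply(vars, function(v) !all(is.na(d[[v]])), logical(1))]
  rows <- list()
  for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
    ok <- stats::complete.cases(d[, c(vars[i], vars[j])])
    if (sum(ok) < 3) { warning("pair dropped: ", vars[i], "/", vars[j]); next }
    ct <- suppressWarnings(cor.test(d[[vars[i]]][ok], d[[vars[j]]][ok],
                                    method = "spearman"))
    rows[[length(rows) + 1L]] <- DataFrame(
      trait_a = vars[i], trait_b = vars[j],
      rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  if (!length(rows)) return(DataFrame(trait_a = character(), trait_b = character(),
                                      rho = numeric(), p = numeric(), n = integer()))
  do.call(rbind, rows)
}
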