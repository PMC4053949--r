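#' Repeat clusters of a profile
#' @param x a [RepeatProfile-class].
#' @return a `DataFrame` of clusters, rank 1 first.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname clusters
#' @export
setMethod("clusters", "RepeatProfile", function(x) x@clusters)

#' Candidate centromere repeat of a profile
#'
#' The rank-1 global cluster, i.e. the most abundant tandem repeat family.
#'
#' @param x a [RepeatProfile-class].
#' @return a one-row `DataFrame`, or NULL when the profile has no clusters.
#' @export
setGeneric("candidateRepeat", function(x) standardGeneric("candidateRepeat"))

#' @rdname candidateRepeat
#' @export
setMethod("candidateRepeat", "RepeatProfile", function(x) {
  g <- x@clusters[x@clusters$kind == "global", , drop = FALSE]
  if (!nrow(g)) return(NULL)
  g[g$rank == 1L, , drop = FALSE][1, , drop = FALSE]
})
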