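#' Pipeline run configuration
#'
#' All tunable parameters of the discovery pipeline in one nested list, with
#' the defaults used throughout the package.  Serializing the returned list
#' (e.g. to YAML/JSON) and reloading it reproduces the identical run.
#'
#' @param seed global seed; every stage derives its own sub-seed from it.
#' @param maxPeriod largest monomer length searched for (bp).
#' @param routeMinLength technology routing threshold: reads tagged "short",
#'   or with mean length below this, go through k-mer reconstruction; longer
#'   reads are scanned directly.  The default (300 bp) is twice the typical
#'   monomer scale, the point below which a read rarely holds two copies.
#' @param sampleReads reads sampled for detection.
#' @param ... per-stage overrides merged over the defaults (`qc`, `dust`,
#'   `detect`, `filter`, `cluster`, `recon` blocks).
#' @return a named list.
#' @export
runConfig <- function(seed = 1L, maxPeriod = 2000L, routeMinLength = 300L,
                      sampleReads = 200000L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    maxPeriod = as.integer(maxPeriod),
    routeMinLength = as.integer(routeMinLength),
    sampleReads = as.integer(sampleReads),
    qc = list(maxNFraction = 0.05,
              minLen = c(sanger = 100, short = 50, long = 1000)),
    dust = list(window = 64L, threshold = 2.0, step = 32L),
    detect = list(minPeriod = 1L, opts = tandemOpts()),
    filter = list(minSpanFraction = 0.8, minPeriod = 50L,
                  reciprocalOverlap = 0.9),
    cluster = list(identityThreshold = 0.80, lengthRatioThreshold = 0.95,
                   sampleSize = 5000L),
    recon = list(k = 31L, minCount = 2L, minCycle = 100L, covFactor = 5,
                 maxCycles = 10L))
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(cfg[[nm]]) && is.list(override[[nm]]))
      cfg[[nm]][names(override[[nm]])] <- override[[nm]]
    else cfg[[nm]] <- override[[nm]]
  }
  cfg
}

#' Run the discovery pipeline end to end
#'
#' Technology routing, QC, DUST soft-masking, tandem detection (directly for
#' long/Sanger reads; through k-mer cycle reconstruction for short reads),
#' candidate filtering and profiling.  Deterministic given the config seed.
#'
#' @param reads `DNAStringSet` with a technology tag in `mcols()`, or pass
#'   `technology`.
#' @param config list from [runConfig()].
#' @param species species label for the profile.
#' @param technology override the reads' technology tag (one value).
#' @param genomeSize,chromosomeCount optional metadata.
#' @param outDir when given, hits TSV, clusters TSV, profile JSON, consensus
#'   FASTA and a run manifest JSON are written there.
#' @return a [RepeatProfile-class]; the (unfiltered) hits are attached in
#'   `metadata(clusters(profile))$hits` for HOR analysis.
#' @export
runDiscovery <- function(reads, config = runConfig(), species = "species",
                         technology = NULL,
                         genomeSize = NA_real_, chromosomeCount = NA_real_,
                         outDir = NULL) {
  if (length(reads) == 0) stop("empty read set")
  tech <- technology %||% unique(S4Vectors::mcols(reads)$technology)
  if (is.null(tech)) stop("reads carry no technology tag; pass `technology`")
  if (length(tech) != 1)
    stop("mixed-technology input: split by technology and run per regime")
  reads <- sampleReads(reads, config$sampleReads,
                       seed = .subseed(config$seed, 1L))
  reads <- qcFilter(reads, maxNFraction = config$qc$maxNFraction,
                    minLen = config$qc$minLen, technology = tech)
  if (length(reads) == 0) stop("no reads left after QC")
  mean_len <- mean(Biostrings::width(reads))

  if (identical(tech, "short") || mean_len < config$routeMinLength) {
    # short-read route: monomers longer than the read must be reconstructed
    message("routing through k-mer cycle reconstruction (", tech,
            " reads, mean ", round(mean_len), " bp)")
    cand <- reconstructMonomers(
      reads, k = config$recon$k, minCount = config$recon$minCount,
      minCycle = config$recon$minCycle, maxCycle = config$maxPeriod,
      covFactor = config$recon$covFactor, maxCycles = config$recon$maxCycles,
      sampleSize = config$sampleReads, seed = .subseed(config$seed, 2L))
    cand <- cand[S4Vectors::mcols(cand)$verified]
    if (length(cand) == 0) {
      hits <- TandemHits()
    } else {
      # each verified cycle stands in as a detected monomer; abundance comes
      # from read matching rather than per-read hits
      hits <- TandemHits(
        read_id = names(cand), start = 0L,
        end = 2L * Biostrings::width(cand),
        period = Biostrings::width(cand), copy_number = 2,
        identity = 100, score = 2L * Biostrings::width(cand),
        consensus = as.character(cand))
    }
    profile <- buildProfile(
      hits, reads, species = species, technology = tech,
      genomeSize = genomeSize, chromosomeCount = chromosomeCount,
      estimateFractionsTop = max(1L, length(cand)),
      identityThreshold = config$cluster$identityThreshold,
      lengthRatioThreshold = config$cluster$lengthRatioThreshold,
      sampleSize = config$cluster$sampleSize,
      seed = .subseed(config$seed, 3L))
    # short-route ranking: supporting reads are unknown per cycle, so rank
    # by estimated genomic fraction
    cl <- profile@clusters
    if (nrow(cl) > 1) {
      g <- which(cl$kind == "global")
      need <- g[is.na(cl$genomic_fraction[g])]
      for (i in need)
        cl$genomic_fraction[i] <- estimateGenomicFraction(cl$consensus[i], reads)
      ord <- order(-cl$genomic_fraction[g])
      cl[g, ] <- cl[g[ord], ]
      cl$rank[g] <- seq_along(g)
      cl$cluster_id[g] <- sprintf("G%03d", seq_along(g))
      profile@clusters <- cl
    }
    hits_all <- hits
  } else {
    masked <- dustMaskSet(reads, window = config$dust$window,
                          threshold = config$dust$threshold,
                          step = config$dust$step)
    hits_all <- detectTandemSet(masked, minPeriod = config$detect$minPeriod,
                                maxPeriod = config$maxPeriod,
                                opts = config$detect$opts)
    rl <- setNames(Biostrings::width(reads), names(reads))
    hits <- filterHits(hits_all, rl,
                       minSpanFraction = config$filter$minSpanFraction,
                       minPeriod = config$filter$minPeriod,
                       reciprocalOverlap = config$filter$reciprocalOverlap)
    profile <- buildProfile(
      hits, reads, species = species, technology = tech,
      genomeSize = genomeSize, chromosomeCount = chromosomeCount,
      identityThreshold = config$cluster$identityThreshold,
      lengthRatioThreshold = config$cluster$lengthRatioThreshold,
      sampleSize = config$cluster$sampleSize,
      seed = .subseed(config$seed, 3L))
  }
  S4Vectors::metadata(profile@clusters)$hits <- hits_all

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeHits(hits_all, file.path(outDir, "hits.tsv"))
    writeProfile(profile, file.path(outDir, "profile.json"))
    cl <- clusters(profile)
    if (nrow(cl)) {
      fa <- Biostrings::DNAStringSet(cl$consensus)
      names(fa) <- cl$cluster_id
      Biostrings::writeXStringSet(fa, file.path(outDir, "consensus.fa"))
    }
    manifest <- list(package_version = as.character(utils::packageVersion("satmine")),
                     config = config, species = species, technology = tech,
                     n_reads_in = length(reads))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  profile
}
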