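#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

.SAMPLE_GROUPS <- c("early", "mid", "mid_late", "late", "extraembryonic",
                    "limb", "aortic_smc", "hepatocyte", "msc", "other")

#' Pipeline configuration
#'
#' Holds every numeric threshold used by the analysis: the CTSS clustering
#' gap, the super-cluster merge distance, the gene-association window, the
#' permissive (>= 3 tags) and robust (> 10 tags, >= 1 TPM) peak support
#' thresholds, the expressed (> 3 TPM), group-specific (> 10 TPM, > 10-fold)
#' and housekeeping (> 10 TPM in every sample, sd(log2 TPM) < 1) rules, the
#' sharp/broad shape-index boundary (-1), and the promoter motif window
#' (-300, +100) around the representative TSS.
#'
#' @slot gapBp integer, maximum distance (bp) between consecutive CTSS in
#'   one tag cluster.
#' @slot superclusterGapBp integer, merge distance for super clusters.
#' @slot annotationWindowBp integer, gene-association window.
#' @slot permissiveMinCount integer, minimum single-CTSS single-sample tag
#'   count for the permissive tier.
#' @slot robustMinCount integer, minimum single-CTSS single-sample tag count
#'   for the robust tier ("more than 10" = 11).
#' @slot robustMinTpm numeric, TPM that same CTSS/sample must reach.
#' @slot expressedTpm numeric, strict lower bound for "expressed".
#' @slot specificTpm numeric, group-mean TPM cutoff for group enrichment.
#' @slot specificFold numeric, fold-enrichment cutoff over the cross-sample
#'   reference.
#' @slot housekeepingMinTpm numeric, per-sample TPM floor for housekeeping.
#' @slot housekeepingMaxSdLog2 numeric, sd(log2 TPM) ceiling.
#' @slot siBoundary numeric, shape-index boundary between sharp and broad.
#' @slot maxUnsplitBp integer, clusters spanning at most this many bp are
#'   never decomposed.
#' @slot splitSigma numeric, Gaussian smoothing bandwidth (bp) used before
#'   valley splitting.
#' @slot valleyFrac numeric, a smoothed local minimum splits a cluster when
#'   it is below this fraction of the smaller flanking maximum.
#' @slot motifWindow integer(2), (upstream, downstream) promoter window
#'   relative to the representative TSS; upstream <= 0 <= downstream.
#' @slot noiseRate numeric, fraction of each simulated library scattered as
#'   uniform background tags.
#' @slot seed integer, base random seed.
#' @export
setClass("PipelineConfig",
  representation(
    gapBp = "integer",
    superclusterGapBp = "integer",
    annotationWindowBp = "integer",
    permissiveMinCount = "integer",
    robustMinCount = "integer",
    robustMinTpm = "numeric",
    expressedTpm = "numeric",
    specificTpm = "numeric",
    specificFold = "numeric",
    housekeepingMinTpm = "numeric",
    housekeepingMaxSdLog2 = "numeric",
    siBoundary = "numeric",
    maxUnsplitBp = "integer",
    splitSigma = "numeric",
    valleyFrac = "numeric",
    motifWindow = "integer",
    noiseRate = "numeric",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  pos <- c(gapBp = object@gapBp, superclusterGapBp = object@superclusterGapBp,
           annotationWindowBp = object@annotationWindowBp,
           permissiveMinCount = object@permissiveMinCount,
           robustMinCount = object@robustMinCount,
           maxUnsplitBp = object@maxUnsplitBp)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  posn <- c(robustMinTpm = object@robustMinTpm,
            expressedTpm = object@expressedTpm,
            specificTpm = object@specificTpm,
            specificFold = object@specificFold,
            housekeepingMinTpm = object@housekeepingMinTpm,
            housekeepingMaxSdLog2 = object@housekeepingMaxSdLog2,
            splitSigma = object@splitSigma, valleyFrac = object@valleyFrac)
  bad <- names(posn)[!is.finite(posn) | posn <= 0]
  if (length(bad))
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  if (length(object@motifWindow) != 2L)
    msg <- c(msg, "motifWindow must have length 2")
  else if (!(object@motifWindow[1L] <= 0L && 0L <= object@motifWindow[2L]))
    msg <- c(msg, "motifWindow must satisfy upstream <= 0 <= downstream")
  if (object@noiseRate < 0 || object@noiseRate >= 1)
    msg <- c(msg, "noiseRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A per-sample CTSS tag count table
#'
#' One record per (chromosome, position, strand): the 5' end of a mapped
#' CAGE read and the number of tags observed there in one sample library.
#' Positions are width-1 GRanges; the BED readers/writers translate the
#' 0-based half-open file convention at the boundary.
#'
#' @slot ranges width-1 [GenomicRanges::GRanges] with an integer metadata
#'   column \code{count} (>= 1), unique (seqnames, start, strand) keys.
#' @slot sampleId character scalar.
#' @slot totalMappedTags numeric scalar, library size used for TPM.
#' @export
setClass("CTSSTable",
  representation(
    ranges = "GRanges",
    sampleId = "character",
    totalMappedTags = "numeric"
  )
)

setValidity("CTSSTable", function(object) {
  msg <- character()
  gr <- object@ranges
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@totalMappedTags) != 1L || object@totalMappedTags <= 0)
    msg <- c(msg, "totalMappedTags must be a single positive number")
  if (length(gr)) {
    if (!all(width(gr) == 1L))
      msg <- c(msg, "all CTSS ranges must have width 1")
    cnt <- mcols(gr)$count
    if (is.null(cnt) || !is.numeric(cnt))
      msg <- c(msg, "ranges must carry an integer 'count' column")
    else {
      if (any(cnt < 1 | cnt != round(cnt)))
        msg <- c(msg, "counts must be positive integers")
      if (sum(cnt) > object@totalMappedTags)
        msg <- c(msg, "sum of counts exceeds totalMappedTags")
    }
    if (any(strand(gr) == "*"))
      msg <- c(msg, "CTSS must be stranded (+ or -)")
    key <- paste(seqnames(gr), start(gr), strand(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos, strand) keys")
  }
  if (length(msg)) msg else TRUE
})

#' Called TSS peaks with per-sample expression
#'
#' Extends RangedSummarizedExperiment: rows are TSS peaks (strand-specific
#' intervals of clustered CTSS) carrying \code{peak_id}, the representative
#' position (the member CTSS with highest pooled count) and the support
#' tier (\code{"permissive"} or \code{"robust"}); assays \code{counts} and
#' \code{tpm} hold per-sample tag counts and tags-per-million; colData
#' carries the sample library table.
#'
#' @export
setClass("TSSPeaks", contains = "RangedSummarizedExperiment")

setValidity("TSSPeaks", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  need <- c("peak_id", "rep_pos", "tier")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData must contain: ", paste(miss, collapse = ", ")))
  if (!all(c("counts", "tpm") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'counts' and 'tpm' are required")
  if (!length(miss) && length(object)) {
    gr <- SummarizedExperiment::rowRanges(object)
    rp <- rd$rep_pos
    if (any(rp < start(gr) | rp > end(gr)))
      msg <- c(msg, "representative positions must lie inside their peak")
    if (!all(rd$tier %in% c("permissive", "robust")))
      msg <- c(msg, "tier must be 'permissive' or 'robust'")
  }
  if (length(msg)) msg else TRUE
})
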