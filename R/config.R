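#' Construct a pipeline configuration
#'
#' All thresholds default to the values used throughout the analysis:
#' 20-bp CTSS clustering gap, 100-bp super-cluster merge, 500-bp gene
#' association, permissive support at >= 3 tags, robust support at > 10
#' tags with >= 1 TPM at the same CTSS/sample, expressed at > 3 TPM,
#' group-specific at > 10 TPM and > 10-fold over the cross-sample
#' reference, housekeeping at > 10 TPM in every sample with
#' sd(log2 TPM) < 1, sharp/broad boundary at SI = -1, and a
#' (-300, +100) promoter motif window.
#'
#' @param gapBp CTSS clustering gap in bp.
#' @param superclusterGapBp super-cluster merge distance in bp.
#' @param annotationWindowBp gene association window in bp.
#' @param permissiveMinCount minimum tag count for permissive support.
#' @param robustMinCount minimum tag count for robust support ("more than
#'   10 tag counts" read strictly, hence 11).
#' @param robustMinTpm TPM the robust-supporting CTSS must reach in the
#'   same sample.
#' @param expressedTpm strict TPM bound for "expressed".
#' @param specificTpm group-mean TPM cutoff for group enrichment.
#' @param specificFold fold cutoff over the cross-sample reference.
#' @param housekeepingMinTpm per-sample TPM floor for housekeeping calls.
#' @param housekeepingMaxSdLog2 sd(log2 TPM) ceiling for housekeeping.
#' @param siBoundary shape-index boundary; SI > boundary is sharp.
#' @param maxUnsplitBp clusters spanning at most this many bp pass through
#'   peak decomposition unsplit.
#' @param splitSigma Gaussian smoothing sigma (bp) for valley splitting.
#' @param valleyFrac relative depth below which a smoothed local minimum
#'   cuts a cluster.
#' @param motifWindow integer(2): (upstream, downstream) of the promoter
#'   window, upstream <= 0 <= downstream.
#' @param noiseRate simulated uniform background fraction of each library.
#' @param seed base random seed.
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(gapBp = 20L, superclusterGapBp = 100L,
                           annotationWindowBp = 500L,
                           permissiveMinCount = 3L, robustMinCount = 11L,
                           robustMinTpm = 1.0, expressedTpm = 3.0,
                           specificTpm = 10.0, specificFold = 10.0,
                           housekeepingMinTpm = 10.0,
                           housekeepingMaxSdLog2 = 1.0,
                           siBoundary = -1.0, maxUnsplitBp = 49L,
                           splitSigma = 5, valleyFrac = 0.1,
                           motifWindow = c(-300L, 100L),
                           noiseRate = 0.02, seed = 1L) {
  new("PipelineConfig",
      gapBp = as.integer(gapBp),
      superclusterGapBp = as.integer(superclusterGapBp),
      annotationWindowBp = as.integer(annotationWindowBp),
      permissiveMinCount = as.integer(permissiveMinCount),
      robustMinCount = as.integer(robustMinCount),
      robustMinTpm = as.numeric(robustMinTpm),
      expressedTpm = as.numeric(expressedTpm),
      specificTpm = as.numeric(specificTpm),
      specificFold = as.numeric(specificFold),
      housekeepingMinTpm = as.numeric(housekeepingMinTpm),
      housekeepingMaxSdLog2 = as.numeric(housekeepingMaxSdLog2),
      siBoundary = as.numeric(siBoundary),
      maxUnsplitBp = as.integer(maxUnsplitBp),
      splitSigma = as.numeric(splitSigma),
      valleyFrac = as.numeric(valleyFrac),
      motifWindow = as.integer(motifWindow),
      noiseRate = as.numeric(noiseRate),
      seed = as.integer(seed))
}

#' Read a pipeline configuration from a flat YAML key-value file
#'
#' The file mirrors the arguments of [pipelineConfig()]; keys present in
#' \code{overrides} take precedence over file values, so a run is fully
#' reproducible from (file, overrides, seed).
#'
#' @param path path to a YAML file of scalar keys.
#' @param overrides named list overriding file values.
#' @return A [PipelineConfig-class] object.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(vals))
    stop("config file must be a flat key-value document: ", path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a [PipelineConfig-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  sl <- slotNames(config)
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  clustering gap:", object@gapBp, "bp;  supercluster gap:",
      object@superclusterGapBp, "bp;  annotation window:",
      object@annotationWindowBp, "bp\n")
  cat("  permissive >=", object@permissiveMinCount, "tags;  robust >=",
      object@robustMinCount, "tags &", object@robustMinTpm, "TPM\n")
  cat("  expressed >", object@expressedTpm, "TPM;  specific >",
      object@specificTpm, "TPM &", object@specificFold, "fold\n")
  cat("  housekeeping >", object@housekeepingMinTpm,
      "TPM all samples & sd(log2) <", object@housekeepingMaxSdLog2, "\n")
  cat("  SI boundary:", object@siBoundary, ";  motif window: (",
      object@motifWindow[1L], ",", object@motifWindow[2L], ")\n")
  cat("  seed:", object@seed, "\n")
})
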