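#' Run the full analysis chain on a set of CTSS tables
#'
#' Pools the per-sample CTSS tables, calls tiered TSS peaks, computes
#' shape indices and super clusters, expression specificity
#' (expressed/ubiquity/housekeeping/group-enriched) and the sample
#' PCoA; optionally annotates peaks against gene models and interval
#' sets and runs promoter motif enrichment when a genome and PWMs are
#' supplied. Fully deterministic given identical inputs and
#' configuration.
#'
#' @param ctss named list of [CTSSTable-class].
#' @param samples sample library table.
#' @param config a [PipelineConfig-class].
#' @param genome optional [Biostrings::DNAStringSet] for GC content and
#'   motif windows.
#' @param genes optional gene TSS GRanges from [readGeneModels()].
#' @param intervals optional named list of GRanges (e.g. cpg, hce) for
#'   overlap flags.
#' @param pwms optional list of [MotifPWM-class] for motif enrichment of
#'   sharp versus broad promoter windows.
#' @param outdir optional directory; when given, peak BED, peak TPM,
#'   super-cluster BED and result TSVs are written there.
#' @return A list with \code{pooled}, \code{peaks}, \code{shape},
#'   \code{superclusters}, \code{stats}, \code{tiers},
#'   \code{housekeeping}, \code{group_enriched}, \code{pcoa} and, when
#'   inputs allow, \code{annotation}, \code{gc}, \code{overlaps} and
#'   \code{motifs}.
#' @export
runCagePipeline <- function(ctss, samples, config = pipelineConfig(),
                            genome = NULL, genes = NULL,
                            intervals = NULL, pwms = NULL,
                            outdir = NULL) {
  pooled <- poolCTSS(ctss, samples)
  peaks <- callPeaks(pooled, config)
  rob <- robustPeaks(peaks)
  shape <- peakShape(rob, pooled, config)
  sc <- superClusters(rob, min_tpm = config@robustMinTpm,
                      gap = config@superclusterGapBp)
  m <- peakTpm(rob)
  stats <- expressionStats(m)
  tiers <- ubiquityTiers(m)
  groups <- sampleGroups(samples)
  enriched <- groupEnriched(m, groups, min_tpm = config@specificTpm,
                            fold = config@specificFold)
  hk <- housekeepingSet(m, min_tpm = config@housekeepingMinTpm,
                        max_sd_log2 = config@housekeepingMaxSdLog2)
  ord <- pcoaSamples(m)
  res <- list(pooled = pooled, peaks = peaks, shape = shape,
              superclusters = sc, stats = stats, tiers = tiers,
              housekeeping = hk, group_enriched = enriched, pcoa = ord)
  if (!is.null(genes)) {
    res$annotation <- associateGenes(rob, genes,
                                     window_bp = config@annotationWindowBp)
  }
  if (!is.null(genome)) {
    res$gc <- gcContent(genome, rob)
    if (!is.null(pwms)) {
      win <- promoterWindows(rob, genome, window = config@motifWindow)
      sharp <- shape$shape_class == "sharp" & !is.na(shape$shape_class)
      broad <- shape$shape_class == "broad" & !is.na(shape$shape_class)
      if (any(sharp) && any(broad)) {
        res$motifs <- list(
          sharp_vs_broad = motifEnrichment(win[sharp], win[broad], pwms),
          broad_vs_sharp = motifEnrichment(win[broad], win[sharp], pwms))
      }
    }
  }
  if (!is.null(intervals)) {
    res$overlaps <- vapply(intervals, function(iv)
      intervalOverlap(rob, iv), logical(length(rob)))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writePeakBed(peaks, file.path(outdir, "peaks.bed"))
    writePeakTpm(rob, file.path(outdir, "peaks_robust_tpm.tsv"))
    writeIntervalBed(sc, file.path(outdir, "superclusters.bed"),
                     names = mcols(sc)$cluster_id)
    data.table::fwrite(shape, file.path(outdir, "peak_shape.tsv"),
                       sep = "\t")
    data.table::fwrite(stats, file.path(outdir, "expression_stats.tsv"),
                       sep = "\t")
    data.table::fwrite(hk, file.path(outdir, "housekeeping.tsv"),
                       sep = "\t")
    pco <- data.frame(sample_id = rownames(ord$points), ord$points)
    data.table::fwrite(pco, file.path(outdir, "pcoa.tsv"), sep = "\t")
  }
  res
}

#' Simulate a synthetic study and analyse it end to end
#'
#' Runs [simulateCageStudy()] and then [runCagePipeline()] on its
#' output, with the toy PWM set and the simulated gene-model-free
#' annotation inputs (CpG islands). Deterministic given (config, seed).
#'
#' @param config a [PipelineConfig-class].
#' @param seed random seed for the simulation.
#' @param outdir optional output directory passed to the pipeline.
#' @param ... further arguments to [simulateCageStudy()].
#' @return A list with \code{study} (the simulation) and \code{result}
#'   (the pipeline output).
#' @export
runSyntheticStudy <- function(config = pipelineConfig(), seed = 1L,
                              outdir = NULL, ...) {
  study <- simulateCageStudy(config = config, seed = seed, ...)
  result <- runCagePipeline(study$ctss, study$samples, config,
                            genome = study$genome,
                            intervals = list(cpg = study$islands),
                            pwms = toyPWMs(), outdir = outdir)
  list(study = study, result = result)
}

#' Match called peaks to planted promoters
#'
#' A peak matches a planted promoter when it lies on the same
#' chromosome and strand and its interval (extended by \code{slop} bp)
#' contains the planted anchor. Used to score synthetic recovery.
#'
#' @param peaks a [TSSPeaks-class].
#' @param truth truth data.frame from [simulateCTSS()].
#' @param slop interval extension in bp (default 10).
#' @return Integer vector: for each truth row, the index of the
#'   matching peak (NA when unrecovered). Multiple candidate peaks
#'   resolve to the one whose representative position is closest to
#'   the anchor.
#' @export
matchPeaksToTruth <- function(peaks, truth, slop = 10L) {
  gr <- SummarizedExperiment::rowRanges(peaks)
  anchors <- GRanges(truth$chrom, IRanges(truth$anchor, width = 1L),
                     strand = truth$strand)
  ov <- GenomicRanges::findOverlaps(
    anchors, GenomicRanges::resize(gr, width(gr) + 2L * slop,
                                   fix = "center"),
    ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  res <- rep(NA_integer_, nrow(truth))
  if (length(qh)) {
    d <- abs(mcols(gr)$rep_pos[sh] - truth$anchor[qh])
    o <- order(qh, d)
    first <- !duplicated(qh[o])
    res[qh[o][first]] <- sh[o][first]
  }
  res
}
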