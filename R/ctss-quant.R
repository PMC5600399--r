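#' Extract CTSS from aligned 5'-end reads
#'
#' The CTSS of a read is the first transcribed base: the leftmost aligned
#' base for \code{+} reads, the rightmost for \code{-} reads. Counts are
#' accumulated per (chromosome, position, strand). Reads without strand
#' are skipped (reported via a message); when a \code{mapq} metadata
#' column is present, reads below \code{min_quality} are skipped too.
#' BAM input is read with GenomicAlignments (unmapped, secondary and
#' supplementary records excluded by flag); BED12 is read with
#' rtracklayer.
#'
#' @param alignments a [GenomicRanges::GRanges] of aligned reads, or a
#'   path to a BAM or BED12 file.
#' @param sample_id sample identifier.
#' @param total_mapped_tags library size; defaults to the number of
#'   accepted reads.
#' @param min_quality minimum mapping quality (default 10), applied when
#'   quality information is available.
#' @return A [CTSSTable-class].
#' @export
extractCTSS <- function(alignments, sample_id, total_mapped_tags = NULL,
                        min_quality = 10L) {
  if (is.character(alignments)) {
    ext <- tolower(tools::file_ext(alignments))
    if (ext == "bam") {
      if (!requireNamespace("GenomicAlignments", quietly = TRUE))
        stop("BAM input requires the GenomicAlignments package")
      flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE)
      ga <- GenomicAlignments::readGAlignments(
        alignments,
        param = Rsamtools::ScanBamParam(flag = flags, what = "mapq"))
      gr <- GRanges(GenomicAlignments::seqnames(ga),
                    IRanges(GenomicAlignments::start(ga),
                            GenomicAlignments::end(ga)),
                    strand = GenomicAlignments::strand(ga),
                    mapq = mcols(ga)$mapq)
      alignments <- gr
    } else if (ext %in% c("bed", "bed12")) {
      alignments <- rtracklayer::import(alignments, format = "BED")
    } else {
      stop("unknown alignment format '.", ext, "'")
    }
  }
  gr <- alignments
  n0 <- length(gr)
  keep <- as.character(strand(gr)) %in% c("+", "-")
  mq <- mcols(gr)$mapq
  if (!is.null(mq))
    keep <- keep & (is.na(mq) | mq >= min_quality)
  skipped <- n0 - sum(keep)
  if (skipped > 0L)
    message(skipped, " read(s) skipped (no strand or low quality)")
  gr <- gr[keep]
  ctss <- GenomicRanges::resize(gr, width = 1L, fix = "start")
  mcols(ctss) <- NULL
  mcols(ctss)$count <- 1L
  CTSSTable(ctss, sample_id,
            if (is.null(total_mapped_tags)) length(ctss)
            else total_mapped_tags)
}

#' Tags-per-million normalization of a CTSS table
#'
#' TPM = count x 1e6 / total mapped tags of the library, so 10 counts in
#' a 10-million-tag library equal exactly 1 TPM.
#'
#' @param x a [CTSSTable-class].
#' @return The CTSS GRanges with an added numeric \code{tpm} column.
#' @export
tpmNormalize <- function(x) {
  total <- totalMappedTags(x)
  if (total <= 0) stop("totalMappedTags must be positive")
  gr <- ctssRanges(x)
  mcols(gr)$tpm <- mcols(gr)$count * 1e6 / total
  gr
}

#' Tags-per-million from raw counts
#' @param counts numeric vector or matrix of tag counts.
#' @param total_mapped_tags library size(s); recycled across matrix
#'   columns.
#' @return counts x 1e6 / total.
#' @export
tpm <- function(counts, total_mapped_tags) {
  if (any(total_mapped_tags <= 0)) stop("library sizes must be positive")
  if (is.matrix(counts))
    sweep(counts, 2L, total_mapped_tags, "/") * 1e6
  else counts * 1e6 / total_mapped_tags
}

#' Relative log expression (RLE) size factors
#'
#' Median-of-ratios size factors: the reference for each feature is its
#' geometric mean across samples (features with any zero are excluded
#' from the reference, the standard RLE convention, unless a pseudocount
#' is requested); each sample's factor is the median across features of
#' count/reference, rescaled so the factors' geometric mean is 1.
#'
#' @param counts feature x sample numeric matrix (>= 2 samples).
#' @param pseudocount optional value (e.g. 0.5) added to all counts
#'   before computing ratios, for matrices with no all-positive feature.
#' @return Named numeric vector of per-sample size factors.
#' @export
rleSizeFactors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("RLE needs at least 2 samples")
  if (pseudocount > 0) counts <- counts + pseudocount
  allpos <- rowSums(counts <= 0) == 0L
  if (!any(allpos))
    stop("no feature is positive in all samples; consider ",
         "pseudocount = 0.5")
  lx <- log(counts[allpos, , drop = FALSE])
  ref <- rowMeans(lx)
  f <- apply(exp(lx - ref), 2L, stats::median)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Pool CTSS tables across samples
#'
#' Unions the (chromosome, position, strand) keys of all tables and
#' retains the per-sample counts as a sparse matrix, so that peak
#' calling can operate on pooled signal while support thresholds are
#' checked per sample.
#'
#' @param tables named list of [CTSSTable-class] (names = sample ids; or
#'   sample ids taken from the tables).
#' @param samples optional sample library table; defaults to one built
#'   from the tables (group \code{"other"}).
#' @return A [SummarizedExperiment::RangedSummarizedExperiment] with
#'   width-1 rowRanges, a sparse \code{counts} assay and a
#'   \code{pooled} rowData column holding the cross-sample sums.
#' @export
poolCTSS <- function(tables, samples = NULL) {
  ids <- vapply(tables, sampleId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate sample ids in tables")
  names(tables) <- ids
  if (is.null(samples))
    samples <- sampleLibraries(ids, rep("other", length(ids)),
                               vapply(tables, totalMappedTags, numeric(1L)))
  else {
    miss <- setdiff(ids, samples$sample_id)
    if (length(miss))
      stop("samples table lacks: ", paste(miss, collapse = ", "))
    samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  }
  dts <- lapply(seq_along(tables), function(i) {
    gr <- ctssRanges(tables[[i]])
    data.table::data.table(chrom = as.character(seqnames(gr)),
                           pos = start(gr),
                           strand = as.character(strand(gr)),
                           count = mcols(gr)$count, sample = i)
  })
  dt <- data.table::rbindlist(dts)
  data.table::setkey(dt, chrom, strand, pos)
  keys <- unique(dt[, .(chrom, strand, pos)])
  keys[, row := .I]
  dt <- keys[dt, on = c("chrom", "strand", "pos")]
  mat <- Matrix::sparseMatrix(i = dt$row, j = dt$sample, x = dt$count,
                              dims = c(nrow(keys), length(tables)),
                              dimnames = list(NULL, ids))
  gr <- GRanges(keys$chrom, IRanges(keys$pos, width = 1L),
                strand = keys$strand)
  mcols(gr)$pooled <- Matrix::rowSums(mat)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat), rowRanges = gr, colData = samples)
  se
}
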