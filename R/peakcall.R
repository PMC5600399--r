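#' Strand-specific single-linkage clustering of pooled CTSS
#'
#' Consecutive CTSS on the same chromosome and strand join one tag
#' cluster when their positions differ by at most \code{gap_bp}. The
#' result is a partition: every CTSS belongs to exactly one cluster and
#' clusters on one strand never overlap.
#'
#' @param pooled a pooled CTSS experiment from [poolCTSS()], or a width-1
#'   stranded GRanges.
#' @param gap_bp maximum joining distance in bp.
#' @return A [GenomicRanges::GRanges] of clusters with an
#'   \code{n_ctss} metadata column.
#' @export
clusterCTSS <- function(pooled, gap_bp = 20L) {
  gr <- if (is(pooled, "SummarizedExperiment"))
    SummarizedExperiment::rowRanges(pooled) else pooled
  cl <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(gap_bp),
                              ignore.strand = FALSE, with.revmap = TRUE)
  mcols(cl)$n_ctss <- lengths(mcols(cl)$revmap)
  mcols(cl)$revmap <- NULL
  sort(cl, ignore.strand = FALSE)
}

.gaussSmooth <- function(x, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(r), x, numeric(r))
  y <- stats::filter(xp, k, sides = 2L)
  as.numeric(y[r + seq_len(n)])
}

# valley cut offsets (dense 1..n indices) of a smoothed profile: a local
# minimum cuts when its value is below valley_frac times the smaller of
# the two flanking maxima, where the flanks run to the nearest already
# accepted cut (or the profile end). Minima are visited deepest-first so
# a rippled valley floor between two tall modes yields exactly one cut
# at its deepest point rather than shadowing the modes. Deterministic;
# positions > cut fall in the right-hand segment.
.valleyCuts <- function(y, valley_frac) {
  n <- length(y)
  if (n < 3L) return(integer())
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  if (m < 3L) return(integer())
  is_min <- c(FALSE, v[2:(m - 1L)] < v[1:(m - 2L)] &
                     v[2:(m - 1L)] < v[3:m], FALSE)
  mins <- which(is_min)
  if (!length(mins)) return(integer())
  ord <- mins[order(v[mins], starts[mins])]  # deepest first, ties left
  cuts <- integer()
  for (mi in ord) {
    pos <- starts[mi]
    bl <- c(0L, cuts)
    br <- c(cuts, n)
    lo <- max(bl[bl < pos]) + 1L
    hi <- min(br[br >= ends[mi]])
    left_max <- max(y[lo:starts[mi]])
    right_max <- max(y[ends[mi]:hi])
    if (v[mi] < valley_frac * min(left_max, right_max))
      cuts <- sort(c(cuts, pos))
  }
  cuts
}

#' Decompose a wide tag cluster at smoothed valleys
#'
#' Clusters spanning at most \code{maxUnsplitBp} pass through unsplit.
#' Wider clusters are smoothed with a Gaussian kernel (sd
#' \code{splitSigma} bp, truncated at 3 sd) and cut at local minima
#' whose smoothed depth is below \code{valleyFrac} times the smaller
#' flanking maximum. Entirely deterministic; pooled counts are conserved
#' across the emitted segments.
#'
#' @param positions integer vector of member CTSS positions (one strand).
#' @param counts pooled counts at those positions.
#' @param config a [PipelineConfig-class].
#' @return Integer vector assigning each member CTSS to a segment
#'   (1, 2, ...), non-decreasing along sorted positions.
#' @export
splitCluster <- function(positions, counts, config = pipelineConfig()) {
  o <- order(positions)
  positions <- positions[o]
  counts <- counts[o]
  res <- rep(1L, length(positions))
  span <- positions[length(positions)] - positions[1L] + 1L
  if (span > config@maxUnsplitBp) {
    dense <- numeric(span)
    dense[positions - positions[1L] + 1L] <- counts
    y <- .gaussSmooth(dense, config@splitSigma)
    cuts <- .valleyCuts(y, config@valleyFrac)
    if (length(cuts)) {
      seg <- findInterval(positions - positions[1L] + 1L, cuts + 0.5) + 1L
      res <- match(seg, sort(unique(seg)))  # drop empty segments
    }
  }
  res[order(o)]
}

#' Representative position of a peak
#'
#' The member position with the highest pooled count; ties are broken
#' toward the 5' end of the peak's strand (smallest position on
#' \code{+}, largest on \code{-}).
#'
#' @param positions member CTSS positions.
#' @param counts pooled counts at those positions.
#' @param strand \code{"+"} or \code{"-"}.
#' @return The representative position (scalar).
#' @export
representativePosition <- function(positions, counts, strand) {
  mx <- max(counts)
  cand <- positions[counts == mx]
  if (strand == "-") max(cand) else min(cand)
}

#' Call TSS peaks from pooled CTSS signal
#'
#' Runs the full peak-calling chain: strand-specific clustering at
#' \code{gapBp}, deterministic valley decomposition of wide clusters,
#' support-threshold tiering and representative-position selection.
#' A peak is \emph{permissive} when at least one member CTSS reaches
#' \code{permissiveMinCount} tags in at least one sample; it is
#' \emph{robust} when one member CTSS in one sample reaches
#' \code{robustMinCount} tags ("more than 10") and that same CTSS/sample
#' is at or above \code{robustMinTpm}. Peaks failing the permissive
#' threshold are dropped.
#'
#' @param pooled pooled CTSS experiment from [poolCTSS()].
#' @param config a [PipelineConfig-class].
#' @return A [TSSPeaks-class] object.
#' @export
callPeaks <- function(pooled, config = pipelineConfig()) {
  gr <- SummarizedExperiment::rowRanges(pooled)
  mat <- SummarizedExperiment::assay(pooled, "counts")
  samples <- SummarizedExperiment::colData(pooled)
  totals <- samples$total_mapped_tags
  pooled_cnt <- mcols(gr)$pooled
  if (is.null(pooled_cnt)) pooled_cnt <- Matrix::rowSums(mat)

  clusters <- GenomicRanges::reduce(gr, min.gapwidth = config@gapBp,
                                    ignore.strand = FALSE,
                                    with.revmap = TRUE)
  revmap <- mcols(clusters)$revmap
  pos <- start(gr)
  cstr <- as.character(strand(clusters))

  # decompose wide clusters only; narrow ones pass through unsplit
  segs <- rep(1L, length(gr))
  nseg <- rep(1L, length(clusters))
  wide <- which(width(clusters) > config@maxUnsplitBp)
  for (ci in wide) {
    idx <- revmap[[ci]]
    sg <- splitCluster(pos[idx], pooled_cnt[idx], config)
    segs[idx] <- sg
    nseg[ci] <- max(sg)
  }
  offset <- cumsum(c(0L, nseg))
  cluster_of <- integer(length(gr))
  cluster_of[unlist(revmap)] <- rep(seq_along(clusters), lengths(revmap))
  peak_of <- offset[cluster_of] + segs
  n_peaks <- offset[length(offset)]

  dt <- data.table::data.table(peak = peak_of, pos = pos,
                               pooled = pooled_cnt, row = seq_along(gr))
  pk <- dt[, .(start = min(pos), end = max(pos), total = sum(pooled)),
           by = peak]
  data.table::setkey(pk, peak)
  chrom <- rep(as.character(seqnames(clusters)), nseg)
  pstr <- rep(cstr, nseg)
  # representative: max pooled count, tie toward the strand's 5' end
  dt[, str := pstr[peak]]
  rep_dt <- dt[order(peak, -pooled,
                     data.table::fifelse(str == "-", -pos, pos))]
  rep_dt <- rep_dt[!duplicated(peak)][order(peak)]

  # per-sample support: permissive / robust at the CTSS x sample level
  tmat <- as(mat, "TsparseMatrix")
  tri <- data.table::data.table(row = tmat@i + 1L, col = tmat@j + 1L,
                                x = tmat@x)
  tri[, peak := peak_of[row]]
  tri[, tpm := x * 1e6 / totals[col]]
  supp <- tri[, .(max_count = max(x),
                  robust = any(x >= config@robustMinCount &
                               tpm >= config@robustMinTpm)), by = peak]
  data.table::setkey(supp, peak)
  permissive <- supp[pk, on = "peak"]$max_count >= config@permissiveMinCount
  robust <- supp[pk, on = "peak"]$robust

  keep <- which(permissive)
  if (!length(keep))
    stop("no peak passes the permissive threshold")
  old2new <- integer(n_peaks)
  old2new[keep] <- seq_along(keep)

  peaks <- GRanges(chrom[keep], IRanges(pk$start[keep], pk$end[keep]),
                   strand = pstr[keep])
  tier <- ifelse(robust[keep], "robust", "permissive")
  rep_pos <- rep_dt$pos[keep]

  # per-sample peak counts via indicator-matrix aggregation
  in_keep <- old2new[peak_of]
  nz <- which(in_keep > 0L)
  ind <- Matrix::sparseMatrix(i = in_keep[nz], j = nz, x = 1,
                              dims = c(length(keep), length(gr)))
  cnt <- as.matrix(ind %*% mat)
  colnames(cnt) <- colnames(mat)
  tpm_mat <- tpm(cnt, totals)

  peak_id <- sprintf("%s:%d..%d,%s", chrom[keep], pk$start[keep] - 1L,
                     pk$end[keep], pstr[keep])
  mcols(peaks) <- DataFrame(peak_id = peak_id, rep_pos = rep_pos,
                            tier = tier,
                            pooled_count = pk$total[keep])
  rownames(cnt) <- peak_id
  rownames(tpm_mat) <- peak_id
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, tpm = tpm_mat), rowRanges = peaks,
    colData = samples)
  ord <- GenomicRanges::order(peaks)
  new("TSSPeaks", out[ord, ])
}

#' @describeIn TSSPeaks-class representative positions (1-based).
#' @export
setGeneric("representativePos", function(x) standardGeneric("representativePos"))

#' @export
setMethod("representativePos", "TSSPeaks", function(x)
  SummarizedExperiment::rowData(x)$rep_pos)

#' @describeIn TSSPeaks-class support tier of every peak.
#' @export
setGeneric("peakTier", function(x) standardGeneric("peakTier"))

#' @export
setMethod("peakTier", "TSSPeaks", function(x)
  SummarizedExperiment::rowData(x)$tier)

#' @describeIn TSSPeaks-class per-sample TPM matrix.
#' @export
setGeneric("peakTpm", function(x) standardGeneric("peakTpm"))

#' @export
setMethod("peakTpm", "TSSPeaks", function(x)
  SummarizedExperiment::assay(x, "tpm"))

#' @describeIn TSSPeaks-class subset to robust peaks.
#' @export
setGeneric("robustPeaks", function(x) standardGeneric("robustPeaks"))

#' @export
setMethod("robustPeaks", "TSSPeaks", function(x) x[peakTier(x) == "robust", ])

setMethod("show", "TSSPeaks", function(object) {
  tier <- peakTier(object)
  cat("TSSPeaks: ", length(object), " peaks (", sum(tier == "robust"),
      " robust) x ", ncol(object), " samples\n", sep = "")
  callNextMethod()
})

#' Write peaks as extended BED
#'
#' BED6 (name = peak_id, score = round of the maximum pooled TPM,
#' capped at 1000) plus thickStart/thickEnd carrying the representative
#' position as a 0-based single-base interval, and the tier in column 9.
#'
#' @param peaks a [TSSPeaks-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePeakBed <- function(peaks, path) {
  gr <- SummarizedExperiment::rowRanges(peaks)
  tpm_max <- apply(peakTpm(peaks), 1L, max)
  dt <- data.table::data.table(
    chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
    end = end(gr), name = mcols(gr)$peak_id,
    score = pmin(1000L, round(tpm_max)),
    strand = as.character(strand(gr)),
    thickStart = mcols(gr)$rep_pos - 1L, thickEnd = mcols(gr)$rep_pos,
    tier = mcols(gr)$tier)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write the per-sample peak TPM matrix as TSV
#' @param peaks a [TSSPeaks-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePeakTpm <- function(peaks, path) {
  m <- peakTpm(peaks)
  dt <- data.table::data.table(peak_id = rownames(m))
  for (cn in colnames(m)) dt[[cn]] <- m[, cn]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
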