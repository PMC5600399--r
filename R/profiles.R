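#' Shape index of a within-peak tag profile
#'
#' SI = 2 + sum_i p_i log2 p_i, where p_i are the positional tag
#' fractions of the peak. The maximum of 2 is attained when all tags map
#' to a single base; a uniform spread over 2^k positions gives 2 - k.
#' Terms with p_i = 0 contribute 0. Invariant under count scaling.
#'
#' @param counts numeric vector of per-position pooled tag counts (or
#'   fractions) of one peak.
#' @return The shape index (bits scale, <= 2).
#' @export
shapeIndex <- function(counts) {
  if (length(counts) == 0L || sum(counts) <= 0)
    stop("shape index needs a profile with positive total count")
  p <- counts / sum(counts)
  p <- p[p > 0]
  2 + sum(p * log2(p))
}

#' Classify a shape index as sharp or broad
#'
#' Sharp when SI is strictly above the boundary (-1 by default); the
#' boundary itself is assigned broad so that the classification is
#' total.
#'
#' @param si numeric vector of shape indices.
#' @param boundary the sharp/broad boundary (default -1).
#' @return Character vector, \code{"sharp"} or \code{"broad"}.
#' @export
classifyShape <- function(si, boundary = -1) {
  ifelse(si > boundary, "sharp", "broad")
}

#' Shape index and class for every peak
#'
#' Profiles are the pooled per-position counts of each peak's member
#' CTSS over the in-scope samples (all samples by default).
#'
#' @param peaks a [TSSPeaks-class].
#' @param pooled the pooled CTSS experiment the peaks were called from.
#' @param config a [PipelineConfig-class] (supplies \code{siBoundary}).
#' @param scope optional character vector of sample ids; profiles are
#'   then pooled over those samples only.
#' @return A \code{data.frame} with \code{peak_id}, \code{si},
#'   \code{shape_class} and \code{n_positions}.
#' @export
peakShape <- function(peaks, pooled, config = pipelineConfig(),
                      scope = NULL) {
  gr <- SummarizedExperiment::rowRanges(peaks)
  ctss <- SummarizedExperiment::rowRanges(pooled)
  cnt <- if (is.null(scope)) {
    pc <- mcols(ctss)$pooled
    if (is.null(pc))
      pc <- Matrix::rowSums(SummarizedExperiment::assay(pooled, "counts"))
    pc
  } else {
    m <- SummarizedExperiment::assay(pooled, "counts")
    miss <- setdiff(scope, colnames(m))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    Matrix::rowSums(m[, scope, drop = FALSE])
  }
  ov <- GenomicRanges::findOverlaps(ctss, gr, ignore.strand = FALSE)
  dt <- data.table::data.table(peak = S4Vectors::subjectHits(ov),
                               cnt = cnt[S4Vectors::queryHits(ov)])
  dt <- dt[cnt > 0]
  res <- dt[, .(si = shapeIndex(cnt), n_positions = .N), by = peak]
  out <- data.frame(peak_id = mcols(gr)$peak_id, si = NA_real_,
                    shape_class = NA_character_,
                    n_positions = 0L, stringsAsFactors = FALSE)
  out$si[res$peak] <- res$si
  out$n_positions[res$peak] <- res$n_positions
  out$shape_class <- ifelse(is.na(out$si), NA_character_,
                            classifyShape(out$si, config@siBoundary))
  out
}

#' Merge expressed peaks into super clusters
#'
#' Peaks whose maximum TPM over the in-scope samples reaches
#' \code{min_tpm} are merged, strand-aware, whenever the gap between
#' consecutive peaks (next start minus previous end) is at most
#' \code{gap} bp; singletons remain singleton clusters. Per-group super
#' clusters are obtained by passing the group's sample ids as
#' \code{scope}.
#'
#' @param peaks a [TSSPeaks-class].
#' @param min_tpm inclusion threshold (default 1 TPM, inclusive).
#' @param gap merge distance in bp (default 100).
#' @param scope optional sample ids restricting the TPM maximum.
#' @param ignore_strand merge across strands (default FALSE).
#' @return A [GenomicRanges::GRanges] of super clusters with
#'   \code{cluster_id}, \code{n_members} and a \code{members}
#'   CharacterList of member peak ids.
#' @export
superClusters <- function(peaks, min_tpm = 1, gap = 100L, scope = NULL,
                          ignore_strand = FALSE) {
  m <- peakTpm(peaks)
  if (!is.null(scope)) {
    miss <- setdiff(scope, colnames(m))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    m <- m[, scope, drop = FALSE]
  }
  keep <- apply(m, 1L, max) >= min_tpm
  gr <- SummarizedExperiment::rowRanges(peaks)[keep]
  cl <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(gap) + 1L,
                              ignore.strand = ignore_strand,
                              with.revmap = TRUE)
  rv <- mcols(cl)$revmap
  mcols(cl) <- DataFrame(
    cluster_id = sprintf("sc_%05d", seq_along(cl)),
    n_members = lengths(rv),
    members = IRanges::CharacterList(
      lapply(rv, function(i) mcols(gr)$peak_id[i])))
  sort(cl, ignore.strand = TRUE)
}

#' Super-cluster size distribution
#'
#' @param clusters super clusters from [superClusters()].
#' @return A list with \code{by_members} (table of member counts) and
#'   \code{spans_bp} (numeric vector of cluster widths).
#' @export
sizeDistribution <- function(clusters) {
  list(by_members = table(mcols(clusters)$n_members),
       spans_bp = width(clusters))
}
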