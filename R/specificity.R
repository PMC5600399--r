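#' Expressed calls at a strict TPM threshold
#'
#' A feature is "expressed" in a sample when its TPM is strictly greater
#' than the threshold (3 TPM by default, roughly one transcript per
#' cell).
#'
#' @param m TPM matrix (features x samples) or a [TSSPeaks-class].
#' @param threshold strict TPM bound (default 3).
#' @return Logical matrix of the same shape.
#' @export
expressedCalls <- function(m, threshold = 3) {
  if (is(m, "TSSPeaks")) m <- peakTpm(m)
  m > threshold
}

#' Log10 enrichment over a cross-sample reference
#'
#' score = log10((x + eps) / (ref + eps)) with ref the per-feature
#' median (default) or mean over samples. The pseudocount eps (0.1 TPM)
#' keeps zeros finite and makes the score 0 when both value and
#' reference are 0.
#'
#' @param m TPM matrix or [TSSPeaks-class].
#' @param reference \code{"median"} or \code{"mean"}.
#' @param eps pseudocount in TPM.
#' @return Matrix of enrichment scores, same shape as \code{m}.
#' @export
enrichmentScore <- function(m, reference = c("median", "mean"),
                            eps = 0.1) {
  if (is(m, "TSSPeaks")) m <- peakTpm(m)
  reference <- match.arg(reference)
  ref <- if (reference == "median") apply(m, 1L, stats::median)
         else rowMeans(m)
  log10((m + eps) / (ref + eps))
}

#' Group-enriched features
#'
#' A feature is enriched in a group when its mean TPM over the group's
#' samples exceeds \code{min_tpm} (10) and exceeds \code{fold} (10)
#' times the cross-sample reference (mean over all samples by default;
#' the median variant is also available).
#'
#' @param m TPM matrix or [TSSPeaks-class].
#' @param groups named list mapping group labels to sample ids (see
#'   [sampleGroups()]).
#' @param min_tpm group-mean activity cutoff.
#' @param fold fold-enrichment cutoff.
#' @param reference \code{"mean"} or \code{"median"} across all samples.
#' @return Named list: for each group, the character vector of enriched
#'   feature ids (rownames of \code{m}).
#' @export
groupEnriched <- function(m, groups, min_tpm = 10, fold = 10,
                          reference = c("mean", "median")) {
  if (is(m, "TSSPeaks")) m <- peakTpm(m)
  reference <- match.arg(reference)
  ref <- if (reference == "mean") rowMeans(m)
         else apply(m, 1L, stats::median)
  lapply(groups, function(ids) {
    miss <- setdiff(ids, colnames(m))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    gm <- rowMeans(m[, ids, drop = FALSE])
    rownames(m)[gm > min_tpm & gm > fold * ref]
  })
}

#' Per-feature expression statistics
#'
#' @param m TPM matrix or [TSSPeaks-class].
#' @return data.frame with mean, median, min, max TPM, fold (max/min;
#'   NA when min = 0) and sd of log2 TPM (NA when any value is 0).
#' @export
expressionStats <- function(m) {
  if (is(m, "TSSPeaks")) m <- peakTpm(m)
  mn <- apply(m, 1L, min)
  mx <- apply(m, 1L, max)
  sd_log2 <- apply(m, 1L, function(v)
    if (any(v <= 0)) NA_real_ else stats::sd(log2(v)))
  data.frame(feature_id = rownames(m), mean_tpm = rowMeans(m),
             median_tpm = apply(m, 1L, stats::median), min_tpm = mn,
             max_tpm = mx, fold = ifelse(mn > 0, mx / mn, NA_real_),
             sd_log2 = sd_log2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Housekeeping features: ubiquitous and stable
#'
#' A feature qualifies when its TPM exceeds \code{min_tpm} (10) in every
#' sample and the sample standard deviation of its log2 TPM is below
#' \code{max_sd_log2} (1). The result is ranked by ascending sd, i.e.
#' most stable first. When annotations are supplied, qualifying peaks
#' are collapsed to the gene level (a gene is housekeeping when at
#' least one associated peak qualifies).
#'
#' @param m TPM matrix or [TSSPeaks-class].
#' @param min_tpm strict per-sample TPM floor.
#' @param max_sd_log2 strict sd(log2 TPM) ceiling.
#' @param annotations optional data.frame from [associateGenes()] (rows
#'   matching \code{m}).
#' @return data.frame of qualifying features (feature_id, sd_log2,
#'   mean_tpm, and gene_id when annotations are given), ranked by
#'   sd_log2.
#' @export
housekeepingSet <- function(m, min_tpm = 10, max_sd_log2 = 1,
                            annotations = NULL) {
  if (is(m, "TSSPeaks")) m <- peakTpm(m)
  ubiq <- apply(m, 1L, min) > min_tpm
  sd_log2 <- rep(NA_real_, nrow(m))
  sd_log2[ubiq] <- apply(log2(m[ubiq, , drop = FALSE]), 1L, stats::sd)
  hk <- ubiq & !is.na(sd_log2) & sd_log2 < max_sd_log2
  out <- data.frame(feature_id = rownames(m)[hk], sd_log2 = sd_log2[hk],
                    mean_tpm = rowMeans(m[hk, , drop = FALSE]),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations))
    out$gene_id <- annotations$gene_id[match(out$feature_id,
                                             annotations$peak_id)]
  out[order(out$sd_log2), , drop = FALSE]
}

#' Ubiquity tiers of expression
#'
#' Nested tiers over all samples: \code{ubiquitous} when the minimum
#' TPM exceeds 3; \code{high} when it exceeds 100; \code{extreme} when
#' it exceeds 300 and the cross-sample mean exceeds 700.
#'
#' @param m TPM matrix or [TSSPeaks-class].
#' @return Character vector per feature: \code{"extreme"},
#'   \code{"high"}, \code{"ubiquitous"} or \code{"none"}.
#' @export
ubiquityTiers <- function(m) {
  if (is(m, "TSSPeaks")) m <- peakTpm(m)
  mn <- apply(m, 1L, min)
  mean_tpm <- rowMeans(m)
  ifelse(mn > 300 & mean_tpm > 700, "extreme",
         ifelse(mn > 100, "high",
                ifelse(mn > 3, "ubiquitous", "none")))
}

#' Principal coordinates analysis of samples
#'
#' Classical multidimensional scaling of a sample-by-sample distance
#' matrix: double centering of -D^2/2 followed by eigendecomposition,
#' keeping axes with positive eigenvalues ordered by eigenvalue. The
#' default distance is 1 - Spearman correlation of log2(TPM + 1)
#' profiles (rank-based, sequencing-depth robust); Euclidean distance
#' on log2(TPM + 1) is also available. For Euclidean-embeddable
#' distances the recovered coordinates reproduce the input distances
#' exactly. Axis signs follow the convention that the first nonzero
#' loading of each axis is positive.
#'
#' @param m TPM matrix (features x samples), [TSSPeaks-class], or a
#'   \code{dist} object.
#' @param distance \code{"one_minus_spearman"} or \code{"euclidean_log"};
#'   ignored when \code{m} is already a \code{dist}.
#' @param k number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return A list with \code{points} (samples x axes), \code{eig}
#'   (eigenvalues, non-increasing) and \code{distance}.
#' @export
pcoaSamples <- function(m, distance = c("one_minus_spearman",
                                        "euclidean_log"), k = NULL) {
  distance <- match.arg(distance)
  if (inherits(m, "dist")) {
    d <- m
  } else {
    if (is(m, "TSSPeaks")) m <- peakTpm(m)
    if (ncol(m) < 3L) stop("PCoA needs at least 3 samples")
    lm <- log2(m + 1)
    d <- if (distance == "one_minus_spearman")
      stats::as.dist(1 - stats::cor(lm, method = "spearman"))
    else stats::dist(t(lm))
  }
  n <- attr(d, "Size")
  if (all(d == 0)) {
    pts <- matrix(0, n, 1L,
                  dimnames = list(attr(d, "Labels"), "Axis1"))
    return(list(points = pts, eig = rep(0, n), distance = distance))
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig[seq_len(ncol(fit$points))] > 1e-9 * max(abs(eig)))
  if (!is.null(k)) pos <- pos[seq_len(min(k, length(pos)))]
  pts <- fit$points[, pos, drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  list(points = pts, eig = sort(eig, decreasing = TRUE),
       distance = distance)
}
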