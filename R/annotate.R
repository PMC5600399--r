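#' Associate peaks with the closest annotated gene TSS
#'
#' A peak is associated with the gene whose annotated TSS is closest to
#' the peak's representative position, among same-strand genes within
#' \code{window_bp} (inclusive). Ties on absolute distance are broken by
#' gene-model source priority (\code{refseq} > \code{ensembl} > others)
#' and then lexicographically on \code{gene_id}, so the result does not
#' depend on gene-list order. The reported distance is signed and
#' strand-oriented: positive when the peak lies downstream of the gene
#' TSS in the direction of transcription.
#'
#' @param peaks a [TSSPeaks-class] or a GRanges with \code{peak_id} and
#'   \code{rep_pos} metadata columns.
#' @param genes width-1 gene TSS GRanges from [readGeneModels()].
#' @param window_bp association window (default 500).
#' @param ignore_strand associate across strands (default FALSE).
#' @return A \code{data.frame} keyed by \code{peak_id} with
#'   \code{gene_id} (NA when unassociated), \code{symbol},
#'   \code{distance_bp} and \code{source}.
#' @export
associateGenes <- function(peaks, genes, window_bp = 500L,
                           ignore_strand = FALSE) {
  gr <- if (is(peaks, "TSSPeaks"))
    SummarizedExperiment::rowRanges(peaks) else peaks
  rep_gr <- GRanges(seqnames(gr), IRanges(mcols(gr)$rep_pos, width = 1L),
                    strand = strand(gr))
  ov <- GenomicRanges::findOverlaps(
    rep_gr, GenomicRanges::resize(genes, 2L * window_bp + 1L,
                                  fix = "center"),
    ignore.strand = ignore_strand)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (length(qh)) {
    d_raw <- start(rep_gr)[qh] - start(genes)[sh]
    gstr <- as.character(strand(genes))[sh]
    dist <- ifelse(gstr == "-", -d_raw, d_raw)
    src <- as.character(mcols(genes)$source)[sh]
    prio <- match(src, c("refseq", "ensembl"), nomatch = 3L)
    dt <- data.table::data.table(
      q = qh, gene_id = mcols(genes)$gene_id[sh],
      symbol = mcols(genes)$symbol[sh], dist = dist, src = src,
      prio = prio)
    dt <- dt[abs(dist) <= window_bp]
    dt <- dt[order(q, abs(dist), prio, gene_id)]
    best <- dt[!duplicated(q)]
  } else {
    best <- data.table::data.table(q = integer(), gene_id = character(),
                                   symbol = character(), dist = integer(),
                                   src = character())
  }
  out <- data.frame(peak_id = mcols(gr)$peak_id,
                    gene_id = NA_character_, symbol = NA_character_,
                    distance_bp = NA_integer_, source = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(best)) {
    out$gene_id[best$q] <- best$gene_id
    out$symbol[best$q] <- best$symbol
    out$distance_bp[best$q] <- best$dist
    out$source[best$q] <- best$src
  }
  out
}

#' Flag peaks overlapping an interval set
#'
#' Strand-blind, half-open overlap of at least 1 bp (the intersectBed
#' convention).
#'
#' @param peaks a [TSSPeaks-class] or GRanges.
#' @param intervals a GRanges (e.g. CpG islands, HCE, ASHCE from
#'   [readIntervalBed()]).
#' @return Logical vector, one flag per peak.
#' @export
intervalOverlap <- function(peaks, intervals) {
  gr <- if (is(peaks, "TSSPeaks"))
    SummarizedExperiment::rowRanges(peaks) else peaks
  IRanges::overlapsAny(gr, intervals, ignore.strand = TRUE)
}

#' GC content around representative positions
#'
#' Fraction (G+C)/(A+C+G+T) in the window \code{[rep - flank, rep +
#' flank)} (100 bp at the default flank of 50), clipped at chromosome
#' bounds. Ambiguous bases are excluded from numerator and denominator;
#' a window with no unambiguous base yields NA.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param peaks a [TSSPeaks-class] or GRanges with \code{rep_pos}.
#' @param flank half-window in bp (default 50).
#' @return Numeric vector of GC fractions (NA where undefined).
#' @export
gcContent <- function(genome, peaks, flank = 50L) {
  gr <- if (is(peaks, "TSSPeaks"))
    SummarizedExperiment::rowRanges(peaks) else peaks
  rep_pos <- mcols(gr)$rep_pos
  chrom <- as.character(seqnames(gr))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  lo <- pmax(1L, rep_pos - as.integer(flank))
  hi <- pmin(lens[chrom], rep_pos + as.integer(flank) - 1L)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], lo[i], hi[i])),
    character(1L)))
  f <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  tot <- rowSums(f)
  gc <- (f[, "C"] + f[, "G"]) / tot
  gc[tot == 0] <- NA_real_
  unname(gc)
}

#' Robust TSS peaks per associated gene
#'
#' Counts, for every gene, the number of associated peaks passing a
#' caller-supplied TPM filter — the basis of the single- versus
#' multi-TSS gene summary.
#'
#' @param annotations data.frame from [associateGenes()].
#' @param peaks the matching [TSSPeaks-class] (same row order as
#'   \code{annotations}).
#' @param min_tpm keep peaks whose maximum TPM over samples exceeds this
#'   (strict; default 3, the "expressed" rule). Use 0 to keep all.
#' @return Named integer vector: associated robust-peak count per gene.
#' @export
tssPerGene <- function(annotations, peaks, min_tpm = 3) {
  keep <- !is.na(annotations$gene_id)
  if (!is.null(peaks)) {
    mx <- apply(peakTpm(peaks), 1L, max)
    keep <- keep & mx > min_tpm
  }
  tab <- table(annotations$gene_id[keep])
  stats::setNames(as.integer(tab), names(tab))
}
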