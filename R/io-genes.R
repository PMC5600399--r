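#' Read gene models and derive annotated TSSs
#'
#' Accepts GTF/GFF (1-based closed, converted on read) or BED6 (0-based
#' half-open). For GTF/GFF, every gene's annotated TSS is the 5'-most
#' transcript start on its strand (minimum start on \code{+}, maximum end
#' on \code{-}); for BED6 each record is taken as one gene whose TSS is
#' the 5' end of the interval. Records without a strand are skipped with
#' a warning.
#'
#' @param path file path ending in .gtf, .gff, .gff3 or .bed.
#' @param source gene-model source label attached to every record; used
#'   by [associateGenes()] for tie-breaking (\code{refseq} beats
#'   \code{ensembl} beats others).
#' @return A width-1 [GenomicRanges::GRanges] of annotated TSSs with
#'   metadata columns \code{gene_id}, \code{symbol} and \code{source}.
#' @export
readGeneModels <- function(path, source = c("ensembl", "refseq",
                                            "noncode", "other")) {
  source <- match.arg(source)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    keep <- strand(gr) %in% c("+", "-")
    if (!all(keep)) {
      warning(sum(!keep), " record(s) without strand skipped")
      gr <- gr[keep]
    }
    gid <- mcols(gr)$gene_id
    if (is.null(gid))
      stop("GTF/GFF lacks gene_id attributes: ", path)
    sym <- mcols(gr)$gene_name
    if (is.null(sym)) sym <- gid
    tss5 <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
    dt <- data.table::data.table(
      gene_id = gid, symbol = sym,
      chrom = as.character(seqnames(gr)),
      strand = as.character(strand(gr)), pos = tss5)
    # 5'-most over all features of the gene
    res <- dt[, .(chrom = chrom[1L], strand = strand[1L],
                  symbol = symbol[1L],
                  tss = if (strand[1L] == "+") min(pos) else max(pos)),
              by = gene_id]
    out <- GRanges(res$chrom, IRanges(res$tss, width = 1L),
                   strand = res$strand, gene_id = res$gene_id,
                   symbol = res$symbol, source = source)
  } else if (ext == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6L)
      stop("BED gene models need 6 columns: ", path)
    str <- dt[[6L]]
    keep <- str %in% c("+", "-")
    if (!all(keep)) {
      warning(sum(!keep), " record(s) without strand skipped")
      dt <- dt[keep]
      str <- str[keep]
    }
    tss <- ifelse(str == "+", dt[[2L]] + 1L, dt[[3L]])  # 0-based -> 1-based
    out <- GRanges(dt[[1L]], IRanges(tss, width = 1L), strand = str,
                   gene_id = as.character(dt[[4L]]),
                   symbol = as.character(dt[[4L]]), source = source)
  } else {
    stop("unknown gene-model extension '.", ext, "' (need gtf/gff/gff3/bed)")
  }
  GenomicRanges::sort(out, ignore.strand = FALSE)
}

#' Read a BED file of plain intervals (CpG islands, HCE, ASHCE)
#'
#' @param path BED path (at least 3 columns, 0-based half-open).
#' @return A [GenomicRanges::GRanges] (unstranded).
#' @export
readIntervalBed <- function(path) {
  if (file.size(path) == 0L) return(GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED needs >= 3 columns: ", path)
  GRanges(dt[[1L]], IRanges(as.integer(dt[[2L]]) + 1L,
                            as.integer(dt[[3L]])))
}

#' Write intervals as BED
#' @param gr a [GenomicRanges::GRanges].
#' @param path output file.
#' @param names optional name column.
#' @return \code{path}, invisibly.
#' @export
writeIntervalBed <- function(gr, path, names = NULL) {
  if (is.null(names))
    names <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
             else paste0("iv_", seq_along(gr))
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
    end = end(gr), name = names, score = 0L, strand = str)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
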