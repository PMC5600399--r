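#' Construct a CTSSTable from a GRanges of single-base positions
#'
#' Duplicate (chrom, pos, strand) keys are summed, so per-lane tables can
#' be concatenated before construction.
#'
#' @param ranges width-1 stranded [GenomicRanges::GRanges] with a numeric
#'   \code{count} metadata column.
#' @param sample_id sample identifier.
#' @param total_mapped_tags library size; defaults to \code{sum(count)}.
#' @return A [CTSSTable-class].
#' @export
CTSSTable <- function(ranges, sample_id,
                      total_mapped_tags = sum(mcols(ranges)$count)) {
  if (length(ranges)) {
    key <- paste(seqnames(ranges), start(ranges), strand(ranges))
    if (anyDuplicated(key)) {
      cnt <- rowsum(as.numeric(mcols(ranges)$count), key, reorder = FALSE)
      keep <- !duplicated(key)
      gr <- ranges[keep]
      mcols(gr)$count <- as.integer(cnt[match(key[keep], rownames(cnt)), 1L])
      ranges <- gr
    }
    ranges <- GenomicRanges::sort(ranges, ignore.strand = FALSE)
    mcols(ranges)$count <- as.integer(mcols(ranges)$count)
  }
  new("CTSSTable", ranges = ranges, sampleId = as.character(sample_id),
      totalMappedTags = as.numeric(total_mapped_tags))
}

#' @describeIn CTSSTable-class the CTSS positions and counts as GRanges.
#' @param x,object a \code{CTSSTable}.
#' @export
setGeneric("ctssRanges", function(x) standardGeneric("ctssRanges"))

#' @export
setMethod("ctssRanges", "CTSSTable", function(x) x@ranges)

#' @describeIn CTSSTable-class the sample identifier.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setMethod("sampleId", "CTSSTable", function(x) x@sampleId)

#' @describeIn CTSSTable-class the library size (mapped tags).
#' @export
setGeneric("totalMappedTags", function(x) standardGeneric("totalMappedTags"))

#' @export
setMethod("totalMappedTags", "CTSSTable", function(x) x@totalMappedTags)

setMethod("show", "CTSSTable", function(object) {
  gr <- object@ranges
  cat("CTSSTable for sample '", object@sampleId, "': ", length(gr),
      " CTSS, ", sum(mcols(gr)$count), " tags of ",
      format(object@totalMappedTags, big.mark = ","), " mapped\n", sep = "")
})

#' Read a per-sample CTSS BED file
#'
#' Expects BED6 with single-base intervals (0-based half-open), tag count
#' in column 5 and strand in column 6. Duplicate (chrom, pos, strand)
#' lines (e.g. from per-lane files) are summed.
#'
#' @param path BED file path.
#' @param sample_id sample identifier to attach.
#' @param total_mapped_tags library size; defaults to the file's tag sum.
#' @return A [CTSSTable-class].
#' @export
readCTSS <- function(path, sample_id, total_mapped_tags = NULL) {
  if (!file.exists(path))
    stop("CTSS BED file not found: ", path)
  if (file.size(path) == 0L) {
    gr <- GRanges()
    mcols(gr)$count <- integer()
    return(CTSSTable(gr, sample_id,
                     if (is.null(total_mapped_tags)) 1 else total_mapped_tags))
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = c(1L, 4L, 6L))),
    error = function(e) stop("cannot read CTSS BED '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) < 6L)
    stop("CTSS BED needs 6 columns, found ", ncol(dt), ": ", path)
  chrom <- dt[[1L]]
  s <- suppressWarnings(as.integer(dt[[2L]]))
  e <- suppressWarnings(as.integer(dt[[3L]]))
  cnt <- suppressWarnings(as.numeric(dt[[5L]]))
  str <- dt[[6L]]
  bad <- which(is.na(s) | is.na(e) | is.na(cnt) | cnt <= 0 |
               !(str %in% c("+", "-")))
  if (length(bad))
    stop("malformed CTSS BED line ", bad[1L], " in '", path, "'")
  bad <- which(e - s != 1L)
  if (length(bad))
    stop("CTSS interval length != 1 at line ", bad[1L], " in '", path, "'")
  gr <- GRanges(chrom, IRanges(s + 1L, width = 1L), strand = str,
                count = as.integer(cnt))
  CTSSTable(gr, sample_id,
            if (is.null(total_mapped_tags)) sum(cnt) else total_mapped_tags)
}

#' Write a CTSSTable as BED6
#'
#' Single-base 0-based half-open intervals; column 5 carries the tag
#' count. Reading the file back with [readCTSS()] reproduces the table.
#'
#' @param x a [CTSSTable-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCTSS <- function(x, path) {
  gr <- ctssRanges(x)
  dt <- data.table::data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = start(gr),
    name = paste0(sampleId(x), "_", seq_along(gr)),
    score = mcols(gr)$count,
    strand = as.character(strand(gr)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
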