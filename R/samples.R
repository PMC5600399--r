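#' Build a sample library table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group sample group labels; one of \code{early}, \code{mid},
#'   \code{mid_late}, \code{late}, \code{extraembryonic}, \code{limb},
#'   \code{aortic_smc}, \code{hepatocyte}, \code{msc}, \code{other}.
#' @param total_mapped_tags positive library sizes (mapped tags).
#' @return A [S4Vectors::DataFrame] with one row per sample.
#' @export
sampleLibraries <- function(sample_id, group, total_mapped_tags) {
  if (anyDuplicated(sample_id))
    stop("sample_id values must be unique")
  group <- as.character(group)
  bad <- setdiff(unique(group), .SAMPLE_GROUPS)
  if (length(bad))
    stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  if (any(total_mapped_tags <= 0))
    stop("total_mapped_tags must be > 0")
  DataFrame(sample_id = as.character(sample_id), group = group,
            total_mapped_tags = as.numeric(total_mapped_tags),
            row.names = as.character(sample_id))
}

#' The default 26-library developmental design
#'
#' Sixteen whole-embryo libraries ordered along development (five early,
#' four mid, four mid-late, three late) plus ten cell/tissue libraries
#' (two extraembryonic, two limb bud, three aortic smooth muscle, two
#' hepatocyte, one mesenchymal stem cell), mirroring a full prehatching
#' developmental CAGE series. A \code{stage_index} column (1..16, NA for
#' non-developmental samples) orders the embryo series.
#'
#' @param total_mapped_tags library size applied to every sample
#'   (default 1e6 tags).
#' @return A [S4Vectors::DataFrame] of 26 sample libraries.
#' @export
defaultSampleLibraries <- function(total_mapped_tags = 1e6) {
  dev_groups <- rep(c("early", "mid", "mid_late", "late"), c(5L, 4L, 4L, 3L))
  ids <- c(sprintf("dev_%02d", seq_len(16L)),
           sprintf("extraembryonic_%d", 1:2), sprintf("limb_%d", 1:2),
           sprintf("aortic_smc_%d", 1:3), sprintf("hepatocyte_%d", 1:2),
           "msc_1")
  grp <- c(dev_groups, rep("extraembryonic", 2L), rep("limb", 2L),
           rep("aortic_smc", 3L), rep("hepatocyte", 2L), "msc")
  df <- sampleLibraries(ids, grp, rep(total_mapped_tags, length(ids)))
  df$stage_index <- c(seq_len(16L), rep(NA_integer_, 10L))
  df
}

#' Sample groups as a named list of sample ids
#' @param samples a sample library table from [sampleLibraries()].
#' @return Named list mapping each group label to its member sample ids.
#' @export
sampleGroups <- function(samples) {
  split(samples$sample_id, factor(samples$group, levels = .SAMPLE_GROUPS),
        drop = TRUE)
}
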