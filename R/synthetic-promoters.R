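#' Default planted-promoter class counts
#'
#' The panel emulates the promoter composition the analysis is designed
#' around: a stable housekeeping program (broad, CpG-island promoters
#' plus a sharper TATA subset), developmentally ramped early- and
#' late-specific programs, strongly group-restricted promoters for every
#' sample group, low-abundance lineage-restricted promoters below the
#' robust detection scale, silent decoys, and a few "ballast" ultra-high
#' expression housekeeping promoters (ribosomal-protein-like) that carry
#' the bulk of the library so that planted expectations sum to
#' (1 - noiseRate) of each library.
#'
#' @return Named integer vector of promoter counts per class.
#' @export
defaultPromoterCounts <- function() {
  c(housekeeping_broad = 50L, housekeeping_sharp = 30L,
    early_specific = 30L, late_specific = 30L,
    group_specific = 108L, low_abundance = 30L,
    silent = 20L, ballast = 10L)
}

#' Positional tag-emission profile of a planted promoter
#'
#' Sharp promoters concentrate 85% of emission at the anchor base with
#' the remainder on its four neighbours (>= 80% within 5 bp of the
#' anchor). Broad promoters place a 15% anchor spike (broad promoters in
#' real CAGE data retain one preferred CTSS) on top of an 85% discrete
#' Gaussian of sd = width/4 truncated at +/- width/2, so no position
#' carries more than 20% of the mass.
#'
#' @param shape_class \code{"sharp"} or \code{"broad"}.
#' @param width_bp promoter width (sharp: 5; broad: 30-120).
#' @return Named numeric vector of emission probabilities; names are
#'   offsets relative to the anchor.
#' @export
emissionProfile <- function(shape_class, width_bp) {
  if (shape_class == "sharp") {
    p <- c(0.04, 0.06, 0.85, 0.03, 0.02)
    names(p) <- -2:2
    return(p)
  }
  half <- floor(width_bp / 2)
  off <- seq(-half, half)
  sigma <- width_bp / 4
  g <- exp(-off^2 / (2 * sigma^2))
  g <- g / sum(g)
  p <- 0.85 * g
  p[off == 0] <- p[off == 0] + 0.15
  names(p) <- off
  p
}

#' Plant promoter architectures into a synthetic genome
#'
#' Chooses anchor positions at least 2 kb apart, assigns each promoter a
#' shape class, an expression program and a strand, writes a TATAAA box
#' at positions -31..-26 (0-based, strand-aware) upstream of every
#' TATA-bearing sharp anchor, and places CpG-flagged broad promoters at
#' the centres of the genome's CpG islands.
#'
#' @param gen a list with \code{genome} and \code{islands} as returned by
#'   [generateGenome()].
#' @param nPerClass named integer vector of promoter counts per class
#'   (see [defaultPromoterCounts()]); unknown names are an error.
#' @param config a [PipelineConfig-class] (supplies the seed offset only
#'   through \code{seed}).
#' @param seed random seed.
#' @return A list with \code{specs} (width-1 anchor
#'   [GenomicRanges::GRanges] with metadata \code{promoter_id},
#'   \code{class}, \code{shape_class}, \code{width_bp},
#'   \code{program_kind}, \code{base_tpm}, \code{target_group},
#'   \code{has_tata}, \code{has_cpg}, \code{detectable}) and
#'   \code{genome} (the edited [Biostrings::DNAStringSet]).
#' @export
plantPromoters <- function(gen, nPerClass = defaultPromoterCounts(),
                           config = pipelineConfig(), seed = 1L) {
  known <- names(defaultPromoterCounts())
  bad <- setdiff(names(nPerClass), known)
  if (length(bad)) stop("unknown promoter classes: ",
                        paste(bad, collapse = ", "))
  full <- defaultPromoterCounts() * 0L
  full[names(nPerClass)] <- as.integer(nPerClass)
  n_total <- sum(full)
  genome <- gen$genome
  islands <- gen$islands
  if (n_total == 0L) {
    specs <- GRanges()
    mcols(specs) <- DataFrame(promoter_id = character(),
                              class = character(),
                              shape_class = character(),
                              width_bp = integer(),
                              program_kind = character(),
                              base_tpm = numeric(),
                              target_group = character(),
                              has_tata = logical(),
                              has_cpg = logical(),
                              detectable = logical())
    return(list(specs = specs, genome = genome))
  }
  set.seed(as.integer(seed))

  broad_classes <- c("housekeeping_broad", "ballast")
  n_broad <- sum(full[broad_classes])
  n_sharp <- n_total - n_broad
  if (n_broad > length(islands))
    stop("need ", n_broad, " CpG islands for broad promoters, genome has ",
         length(islands))

  # broad anchors: island centres (islands are >= 2 kb apart by
  # construction); sharp anchors: jittered 2-kb grid away from islands
  isl_pick <- sort(sample(seq_along(islands), n_broad))
  broad_anchor <- GRanges(seqnames(islands)[isl_pick],
                          IRanges(start(islands)[isl_pick] +
                                  floor(width(islands)[isl_pick] / 2),
                                  width = 1L))
  lens <- Biostrings::width(genome)
  slots <- list()
  for (i in seq_along(genome)) {
    gs <- seq(2500L, lens[i] - 2500L, by = 2500L)
    slots[[i]] <- GRanges(names(genome)[i], IRanges(gs, width = 1L))
  }
  slots <- suppressWarnings(do.call(c, slots))
  near_isl <- IRanges::overlapsAny(
    slots, GenomicRanges::resize(islands, width(islands) + 4000L,
                                 fix = "center"))
  slots <- slots[!near_isl]
  if (length(slots) < n_sharp)
    stop("genome too short: need ", n_sharp, " sharp promoter slots at ",
         "2.5-kb spacing, have ", length(slots),
         " (grow the genome to at least ",
         (n_sharp - length(slots) + 1L) * 2500L + sum(lens), " bp)")
  sharp_anchor <- slots[sort(sample(seq_along(slots), n_sharp))]
  jit <- sample(seq(-200L, 200L), n_sharp, replace = TRUE)
  sharp_anchor <- GenomicRanges::shift(sharp_anchor, jit)

  cls <- rep(known, full[known])
  is_broad_cls <- cls %in% broad_classes
  combined <- suppressWarnings(c(broad_anchor, sharp_anchor))
  perm <- integer(n_total)
  perm[which(is_broad_cls)] <- seq_len(n_broad)
  perm[which(!is_broad_cls)] <- n_broad + seq_len(n_sharp)
  anchors <- combined[perm]
  strand(anchors) <- sample(c("+", "-"), n_total, replace = TRUE)

  shape <- ifelse(is_broad_cls, "broad", "sharp")
  width_bp <- ifelse(shape == "sharp", 5L,
                     sample(seq(30L, 120L), n_total, replace = TRUE))
  kind <- c(housekeeping_broad = "housekeeping",
            housekeeping_sharp = "housekeeping",
            early_specific = "early_specific",
            late_specific = "late_specific",
            group_specific = "group_specific",
            low_abundance = "group_specific",
            silent = "silent", ballast = "housekeeping")[cls]

  # expression levels: log-uniform housekeeping, fixed specific targets
  base <- numeric(n_total)
  base[cls == "housekeeping_broad"] <-
    10^stats::runif(full["housekeeping_broad"], 2, log10(2e4))
  base[cls == "housekeeping_sharp"] <-
    10^stats::runif(full["housekeeping_sharp"], log10(40), log10(2e3))
  base[cls %in% c("early_specific", "late_specific")] <- 150
  base[cls == "group_specific"] <- 120
  base[cls == "low_abundance"] <- 3
  base[cls == "silent"] <- 0
  base[cls == "ballast"] <- NA_real_  # sized against the library later

  groups <- setdiff(.SAMPLE_GROUPS, "other")
  target <- rep(NA_character_, n_total)
  gs <- cls == "group_specific"
  target[gs] <- rep_len(groups, sum(gs))
  la <- cls == "low_abundance"
  target[la] <- sample(groups, sum(la), replace = TRUE)

  specs <- anchors
  mcols(specs) <- DataFrame(
    promoter_id = sprintf("prom_%03d", seq_len(n_total)),
    class = cls, shape_class = shape, width_bp = as.integer(width_bp),
    program_kind = unname(kind), base_tpm = base, target_group = target,
    has_tata = shape == "sharp", has_cpg = shape == "broad",
    detectable = cls != "low_abundance" & cls != "silent")

  # write TATAAA at -31..-26 (0-based) relative to TATA-bearing anchors
  tata <- which(mcols(specs)$has_tata)
  for (j in tata) {
    ch <- as.character(seqnames(specs)[j])
    a <- start(specs)[j]
    if (as.character(strand(specs)[j]) == "+") {
      Biostrings::subseq(genome[[ch]], a - 31L, a - 26L) <-
        Biostrings::DNAString("TATAAA")
    } else {
      Biostrings::subseq(genome[[ch]], a + 26L, a + 31L) <-
        Biostrings::DNAString("TTTATA")
    }
  }
  ord <- GenomicRanges::order(specs)
  list(specs = specs[ord], genome = genome)
}
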