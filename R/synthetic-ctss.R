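#' Expected TPM of every planted promoter in every sample
#'
#' Housekeeping promoters are constant across samples (ballast promoters
#' are sized so that the planted expectations average
#' \code{(1 - noiseRate) * 1e6} TPM per sample, the remainder being
#' uniform background). Early-/late-specific programs ramp geometrically
#' across the ordered developmental series from their 150-TPM peak down
#' to 0.5 TPM (0.2 TPM in non-developmental samples). Group-specific
#' programs emit their target TPM in the target group's samples and 0.2
#' TPM elsewhere (0.1 TPM for the low-abundance class). Silent promoters
#' emit nothing.
#'
#' @param specs planted promoter specs from [plantPromoters()].
#' @param samples sample library table; needs a \code{stage_index}
#'   column for the developmental ramps (see [defaultSampleLibraries()]).
#' @param config a [PipelineConfig-class]; supplies \code{noiseRate}.
#' @return Numeric matrix, promoters x samples, of expected TPM.
#' @export
expectedTpmMatrix <- function(specs, samples, config = pipelineConfig()) {
  n <- length(specs)
  ids <- samples$sample_id
  m <- matrix(0, n, length(ids),
              dimnames = list(mcols(specs)$promoter_id, ids))
  if (n == 0L) return(m)
  md <- mcols(specs)
  stage <- samples$stage_index
  if (is.null(stage)) stage <- rep(NA_integer_, length(ids))
  is_dev <- !is.na(stage)
  n_stage <- if (any(is_dev)) max(stage[is_dev]) else 0L

  ramp <- function(peak, floor_tpm, reversed) {
    v <- rep(0.2, length(ids))
    if (n_stage > 1L) {
      r <- (peak / floor_tpm)^(1 / (n_stage - 1L))
      expo <- if (reversed) stage[is_dev] - 1L else n_stage - stage[is_dev]
      v[is_dev] <- floor_tpm * r^expo
    }
    v
  }

  grp <- samples$group
  for (i in seq_len(n)) {
    kind <- md$program_kind[i]
    cls <- md$class[i]
    if (kind == "silent") next
    if (kind == "housekeeping") {
      m[i, ] <- md$base_tpm[i]  # ballast NA resolved below
    } else if (kind == "early_specific") {
      m[i, ] <- ramp(md$base_tpm[i], 0.5, reversed = FALSE)
    } else if (kind == "late_specific") {
      m[i, ] <- ramp(md$base_tpm[i], 0.5, reversed = TRUE)
    } else if (kind == "group_specific") {
      off <- if (cls == "low_abundance") 0.1 else 0.2
      m[i, ] <- ifelse(grp == md$target_group[i], md$base_tpm[i], off)
    }
  }
  ballast <- which(md$class == "ballast")
  if (length(ballast)) {
    planted <- mean(colSums(m[-ballast, , drop = FALSE]))
    leftover <- (1 - config@noiseRate) * 1e6 - planted
    if (leftover <= 0)
      stop("planted programs already exceed (1 - noiseRate) of the ",
           "library; reduce promoter expression or counts")
    m[ballast, ] <- leftover / length(ballast)
  }
  m
}

#' Simulate per-sample CTSS tag counts from planted promoters
#'
#' For each sample, each promoter's tag total is drawn as Poisson with
#' mean \code{expected TPM x total_mapped_tags / 1e6}; tags are then
#' spread over positions by a multinomial draw from the promoter's
#' positional emission profile ([emissionProfile()]). The remainder of
#' the library is scattered as uniform background over both strands of
#' the genome, so each sample's simulated tag total equals its
#' \code{total_mapped_tags} exactly.
#'
#' @param specs planted promoter specs from [plantPromoters()].
#' @param genome the (edited) [Biostrings::DNAStringSet].
#' @param samples sample library table.
#' @param config a [PipelineConfig-class].
#' @param seed random seed.
#' @return A list with \code{ctss} (named list of [CTSSTable-class], one
#'   per sample) and \code{truth} (a \code{data.frame} with one row per
#'   planted promoter: id, position, strand, shape class, program kind,
#'   detectability, and per-sample expected TPM in \code{etpm.*}
#'   columns).
#' @export
simulateCTSS <- function(specs, genome, samples,
                         config = pipelineConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  etpm <- expectedTpmMatrix(specs, samples, config)
  md <- mcols(specs)
  n_prom <- length(specs)
  lens <- Biostrings::width(genome)
  chroms <- names(genome)
  cum <- cumsum(as.numeric(lens))
  total_len <- cum[length(cum)]

  profiles <- lapply(seq_len(n_prom), function(i)
    emissionProfile(md$shape_class[i], md$width_bp[i]))
  offsets <- lapply(profiles, function(p) as.integer(names(p)))

  out <- vector("list", nrow(samples))
  names(out) <- samples$sample_id
  for (s in seq_len(nrow(samples))) {
    total <- samples$total_mapped_tags[s]
    lambda <- etpm[, s] * total / 1e6
    n_tags <- stats::rpois(n_prom, lambda)
    excess <- sum(n_tags) - total
    while (excess > 0) {  # measure-zero guard: trim the largest promoter
      j <- which.max(n_tags)
      take <- min(excess, n_tags[j])
      n_tags[j] <- n_tags[j] - take
      excess <- excess - take
    }
    parts <- vector("list", n_prom + 1L)
    for (i in which(n_tags > 0L)) {
      k <- stats::rmultinom(1L, n_tags[i], profiles[[i]])[, 1L]
      nz <- which(k > 0L)
      parts[[i]] <- data.table::data.table(
        chrom = as.character(seqnames(specs)[i]),
        pos = start(specs)[i] + offsets[[i]][nz],
        strand = as.character(strand(specs)[i]),
        count = k[nz])
    }
    n_bg <- total - sum(n_tags)
    if (n_bg > 0L) {
      u <- ceiling(stats::runif(n_bg) * total_len)
      ci <- findInterval(u - 0.5, c(0, cum)) # chromosome index
      pos <- as.integer(u - c(0, cum)[ci])
      parts[[n_prom + 1L]] <- data.table::data.table(
        chrom = chroms[ci], pos = pos,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        count = 1L)
    }
    dt <- data.table::rbindlist(parts)
    dt <- dt[, .(count = sum(count)), by = .(chrom, pos, strand)]
    gr <- GRanges(dt$chrom, IRanges(dt$pos, width = 1L),
                  strand = dt$strand, count = dt$count)
    out[[s]] <- CTSSTable(gr, samples$sample_id[s],
                          total_mapped_tags = total)
  }
  truth <- data.frame(
    promoter_id = md$promoter_id,
    chrom = as.character(seqnames(specs)),
    anchor = start(specs),
    strand = as.character(strand(specs)),
    class = md$class,
    shape_class = md$shape_class,
    width_bp = md$width_bp,
    program_kind = md$program_kind,
    target_group = md$target_group,
    detectable = md$detectable,
    stringsAsFactors = FALSE)
  colnames(etpm) <- paste0("etpm.", colnames(etpm))
  truth <- cbind(truth, as.data.frame(etpm, row.names = NULL))
  list(ctss = out, truth = truth)
}

#' Write a simulation truth table as TSV
#'
#' The \code{anchor} position is written 0-based (BED convention) as
#' \code{anchor0}, alongside the 1-based \code{anchor}.
#'
#' @param truth truth data.frame from [simulateCTSS()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  truth$anchor0 <- truth$anchor - 1L
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' Generate a complete synthetic CAGE study
#'
#' Convenience wrapper: genome with CpG islands, planted promoter panel,
#' and per-sample CTSS tables with the ground-truth table. The defaults
#' emulate the study design the analysis targets: 26 libraries (16
#' ordered developmental + 10 cell/tissue samples), ~300 planted
#' promoters over a 20-Mb two-chromosome genome at 52% GC with 80 CpG
#' islands.
#'
#' @param samples sample library table (default
#'   [defaultSampleLibraries()]).
#' @param config a [PipelineConfig-class].
#' @param seed random seed; sub-steps derive their own fixed offsets.
#' @param n_chrom,length_bp,gc,n_islands genome parameters.
#' @param nPerClass promoter class counts.
#' @return A list: \code{genome}, \code{islands}, \code{specs},
#'   \code{ctss}, \code{truth}, \code{samples}, \code{config}.
#' @export
simulateCageStudy <- function(samples = defaultSampleLibraries(),
                              config = pipelineConfig(), seed = 1L,
                              n_chrom = 2L, length_bp = 1e7, gc = 0.52,
                              n_islands = 80L,
                              nPerClass = defaultPromoterCounts()) {
  seed <- as.integer(seed)
  gen <- generateGenome(n_chrom, length_bp, gc, seed = seed,
                        n_islands = n_islands)
  planted <- plantPromoters(gen, nPerClass, config, seed = seed + 1000L)
  sim <- simulateCTSS(planted$specs, planted$genome, samples, config,
                      seed = seed + 2000L)
  list(genome = planted$genome, islands = gen$islands,
       specs = planted$specs, ctss = sim$ctss, truth = sim$truth,
       samples = samples, config = config)
}
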