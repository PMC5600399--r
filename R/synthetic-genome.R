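#' Generate a random genome with designated CpG islands
#'
#' Sequence is i.i.d. at the requested GC content except inside the
#' designated islands, which are drawn at \code{island_gc} (so their GC
#' is >= 0.65 and, bases being independent, their observed/expected CpG
#' ratio sits near 1, comfortably above the 0.6 island rule). Islands are
#' placed non-overlapping, at least 2 kb from each other and from
#' chromosome ends, at jittered grid positions.
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp length of every chromosome (>= 10 kb).
#' @param gc genome-wide GC fraction, in (0, 1).
#' @param seed random seed.
#' @param n_islands total number of CpG islands across the genome.
#' @param island_bp island width in bp.
#' @param island_gc GC fraction inside islands (>= 0.65).
#' @return A list with \code{genome} (a [Biostrings::DNAStringSet]) and
#'   \code{islands} (a [GenomicRanges::GRanges]).
#' @examples
#' gen <- generateGenome(2, 2e4, 0.5, seed = 1, n_islands = 2)
#' gen$genome
#' @export
generateGenome <- function(n_chrom, length_bp, gc, seed = 1L,
                           n_islands = 0L, island_bp = 1000L,
                           island_gc = 0.72) {
  if (!(gc > 0 && gc < 1)) stop("gc must lie strictly inside (0, 1)")
  if (length_bp < 1e4) stop("length_bp must be at least 10 kb")
  if (island_gc < 0.65) stop("island_gc must be >= 0.65")
  set.seed(as.integer(seed))
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  isl_prob <- c(A = (1 - island_gc) / 2, C = island_gc / 2,
                G = island_gc / 2, T = (1 - island_gc) / 2)
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(n_chrom))

  seqs <- vapply(chroms, function(ch) {
    paste(sample(bases, length_bp, replace = TRUE, prob = base_prob),
          collapse = "")
  }, character(1L))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  islands <- GRanges()
  if (n_islands > 0L) {
    per_chrom <- diff(round(seq(0, n_islands, length.out = n_chrom + 1L)))
    isl <- list()
    for (i in seq_len(n_chrom)) {
      k <- per_chrom[i]
      if (k == 0L) next
      lo <- 2000L
      hi <- length_bp - 2000L - island_bp
      if (hi - lo < k * (island_bp + 2000L))
        stop("chromosome too short for ", k, " islands; need at least ",
             lo + k * (island_bp + 2000L) + island_bp + 2000L, " bp")
      grid <- round(seq(lo, hi, length.out = k))
      jitter <- sample(seq(-500L, 500L), k, replace = TRUE)
      starts <- pmin(pmax(grid + jitter, lo), hi)
      isl[[i]] <- GRanges(chroms[i],
                          IRanges(starts + 1L, width = island_bp))
    }
    islands <- sort(suppressWarnings(do.call(c, isl)))
    # overwrite island sequence with GC-rich composition
    for (j in seq_along(islands)) {
      ch <- as.character(seqnames(islands)[j])
      s <- paste(sample(bases, island_bp, replace = TRUE, prob = isl_prob),
                 collapse = "")
      Biostrings::subseq(genome[[ch]], start(islands)[j],
                         end(islands)[j]) <- Biostrings::DNAString(s)
    }
  }
  list(genome = genome, islands = islands)
}

#' GC fraction of a DNA sequence set or character vector
#' @param x a [Biostrings::DNAStringSet] or character vector.
#' @return Overall (G+C)/(A+C+G+T) fraction, ambiguity codes excluded.
#' @export
gcFraction <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  f <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  unname((f["C"] + f["G"]) / sum(f))
}

#' Observed/expected CpG ratio of a sequence
#' @param x a [Biostrings::DNAString], DNAStringSet element or character.
#' @return n(CG) * L / (n(C) * n(G)).
#' @export
cpgObsExp <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAString(x)
  n <- length(x)
  f <- Biostrings::letterFrequency(x, c("C", "G"))
  cg <- Biostrings::countPattern("CG", x)
  unname(cg * n / (f[1L] * f[2L]))
}
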