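suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
  library(Biostrings)
})

# CTSSTable from a plain data.frame of (chrom, pos [1-based], strand, count)
makeCTSS <- function(df, sample_id, total = sum(df$count)) {
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand,
                count = as.integer(df$count))
  CTSSTable(gr, sample_id, total)
}

# pooled experiment from a position table and a positions x samples count
# matrix (zeros dropped per sample)
makePooled <- function(df, counts, totals,
                       groups = rep("other", ncol(counts))) {
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(counts)))
  tabs <- lapply(seq_along(ids), function(j) {
    nz <- counts[, j] > 0
    makeCTSS(df[nz, , drop = FALSE][, c("chrom", "pos", "strand")] |>
               cbind(count = counts[nz, j]), ids[j], totals[j])
  })
  samples <- sampleLibraries(ids, groups, totals)
  poolCTSS(tabs, samples)
}

# a TSSPeaks object built directly (for super-cluster / specificity tests)
makeToyPeaks <- function(chrom, start, end, strand, tpm_mat,
                         rep_pos = start, tier = "robust") {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  n <- length(gr)
  tpm_mat <- matrix(tpm_mat, nrow = n)
  ids <- sprintf("%s:%d..%d,%s", chrom, start - 1L, end, strand)
  if (is.null(colnames(tpm_mat)))
    colnames(tpm_mat) <- paste0("s", seq_len(ncol(tpm_mat)))
  rownames(tpm_mat) <- ids
  mcols(gr) <- DataFrame(peak_id = ids, rep_pos = rep_pos,
                         tier = rep(tier, length.out = n),
                         pooled_count = rowSums(tpm_mat))
  samples <- sampleLibraries(colnames(tpm_mat),
                             rep("other", ncol(tpm_mat)),
                             rep(1e6, ncol(tpm_mat)))
  se <- SummarizedExperiment(assays = list(counts = tpm_mat,
                                           tpm = tpm_mat),
                             rowRanges = gr, colData = samples)
  new("TSSPeaks", se)
}

# brute-force O(n^2) fixpoint merge oracle for super clustering
bruteMerge <- function(start, end, strand, gap) {
  n <- length(start)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] == grp[j] || strand[i] != strand[j]) next
      g <- max(start[i], start[j]) - min(end[i], end[j]) - 1L
      if (g <= gap) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# one full-scale synthetic study, computed once per test session
.study_cache <- new.env(parent = emptyenv())
getSyntheticRun <- function() {
  if (is.null(.study_cache$run)) {
    .study_cache$run <- runSyntheticStudy(pipelineConfig(), seed = 7L)
  }
  .study_cache$run
}

# expected TPM matrix of a truth table, samples as columns
truthEtpm <- function(truth) {
  et <- as.matrix(truth[, grep("^etpm\\.", names(truth)), drop = FALSE])
  colnames(et) <- sub("^etpm\\.", "", colnames(et))
  rownames(et) <- truth$promoter_id
  et
}
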