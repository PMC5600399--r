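test_that("generated genomes hit the requested composition", {
  gen <- generateGenome(1L, 1e5, 0.5, seed = 5L)
  s <- as.character(gen$genome[[1L]])
  # independent oracle: direct character count
  tab <- table(strsplit(s, "")[[1L]])
  gc_direct <- sum(tab[c("C", "G")]) / sum(tab)
  expect_lt(abs(gc_direct - 0.5), 0.02)
  expect_equal(gcFraction(gen$genome), gc_direct)
  expect_error(generateGenome(1L, 1e5, 1.5, seed = 1L), "gc must lie")
  expect_error(generateGenome(1L, 5e3, 0.5, seed = 1L), "10 kb")
})

test_that("genome generation is seed-deterministic with distinct records", {
  g1 <- generateGenome(2L, 2e4, 0.4, seed = 9L, n_islands = 2L)
  g2 <- generateGenome(2L, 2e4, 0.4, seed = 9L, n_islands = 2L)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_equal(names(g1$genome), c("chr1", "chr2"))
  g3 <- generateGenome(2L, 2e4, 0.4, seed = 10L, n_islands = 2L)
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
})

test_that("CpG islands satisfy the GC and observed/expected rules", {
  gen <- generateGenome(1L, 2e5, 0.45, seed = 3L, n_islands = 8L)
  expect_equal(length(gen$islands), 8L)
  for (j in seq_along(gen$islands)) {
    isl_seq <- Biostrings::subseq(gen$genome[[1L]],
                                  start(gen$islands)[j],
                                  end(gen$islands)[j])
    expect_gte(gcFraction(as.character(isl_seq)), 0.65)
    expect_gte(cpgObsExp(isl_seq), 0.6)
  }
})

test_that("TATA boxes are written at -31..-26 strand-aware", {
  gen <- generateGenome(1L, 1e6, 0.5, seed = 2L, n_islands = 10L)
  pl <- plantPromoters(gen, c(housekeeping_sharp = 20L), seed = 4L)
  sp <- pl$specs
  for (j in seq_along(sp)) {
    a <- start(sp)[j]
    ch <- as.character(seqnames(sp))[j]
    if (as.character(strand(sp))[j] == "+") {
      # 0-based window [a0-31, a0-26+1) == 1-based [a-31, a-26]
      expect_equal(as.character(
        Biostrings::subseq(pl$genome[[ch]], a - 31L, a - 26L)), "TATAAA")
    } else {
      expect_equal(as.character(
        Biostrings::subseq(pl$genome[[ch]], a + 26L, a + 31L)), "TTTATA")
    }
  }
})

test_that("broad promoters sit inside CpG islands; spacing holds", {
  gen <- generateGenome(2L, 1e6, 0.5, seed = 6L, n_islands = 20L)
  pl <- plantPromoters(gen, c(housekeeping_broad = 15L,
                              group_specific = 18L), seed = 8L)
  sp <- pl$specs
  broad <- sp[mcols(sp)$has_cpg]
  expect_equal(length(broad), 15L)
  expect_true(all(IRanges::overlapsAny(broad, gen$islands)))
  # anchors at least 2 kb apart
  d <- GenomicRanges::distanceToNearest(sp, ignore.strand = TRUE)
  expect_true(all(mcols(d)$distance >= 2000L - 1L))
})

test_that("empty promoter request leaves the genome unchanged", {
  gen <- generateGenome(1L, 2e4, 0.5, seed = 1L)
  pl <- plantPromoters(gen, c(silent = 0L), seed = 1L)
  expect_equal(length(pl$specs), 0L)
  expect_identical(as.character(pl$genome), as.character(gen$genome))
})

test_that("emission profiles satisfy the shape-class mass constraints", {
  sharp <- emissionProfile("sharp", 5L)
  expect_equal(sum(sharp), 1)
  off <- as.integer(names(sharp))
  expect_gte(sum(sharp[abs(off) <= 5L]), 0.8)
  for (w in c(30L, 60L, 120L)) {
    broad <- emissionProfile("broad", w)
    expect_equal(sum(broad), 1, tolerance = 1e-12)
    expect_lt(max(broad), 0.2)
    expect_equal(length(broad), 2L * floor(w / 2) + 1L)
  }
})

test_that("simulated libraries conserve tag totals exactly", {
  samples <- defaultSampleLibraries(5e4)
  cfg <- pipelineConfig()
  study <- simulateCageStudy(samples, cfg, seed = 2L, n_chrom = 1L,
                             length_bp = 1e6, n_islands = 62L,
                             nPerClass = c(housekeeping_broad = 30L,
                                           housekeeping_sharp = 20L,
                                           group_specific = 27L,
                                           silent = 5L, ballast = 5L))
  for (tab in study$ctss)
    expect_identical(sum(mcols(ctssRanges(tab))$count), 50000L)
  expect_equal(nrow(study$truth), 87L)
})

# two-promoter spec set: the promoter under test plus a far-away ballast
# that absorbs the rest of the library (so uniform background stays at
# the 2% noise level rather than swamping the locus under test)
.testSpecs <- function(pos, strand, base_tpm, shape = "sharp",
                       width = 5L) {
  specs <- GRanges("chr1", IRanges(c(pos, 5000L), width = 1L),
                   strand = c(strand, "+"))
  mcols(specs) <- DataFrame(
    promoter_id = c("p1", "fill"),
    class = c("housekeeping_sharp", "ballast"),
    shape_class = c(shape, "broad"), width_bp = c(width, 60L),
    program_kind = "housekeeping", base_tpm = c(base_tpm, NA_real_),
    target_group = NA_character_, has_tata = FALSE, has_cpg = FALSE,
    detectable = TRUE)
  specs
}

test_that("promoter tag totals match the analytic Poisson mean", {
  # a housekeeping promoter at 50 TPM in a 1e6-tag library: over 20
  # replicate seeds the mean observed tag count should sit within 50 +/- 3
  gen <- generateGenome(1L, 5e4, 0.5, seed = 1L)
  specs <- .testSpecs(25000L, "+", 50)
  samples <- sampleLibraries("s1", "other", 1e6)
  totals <- vapply(1:20, function(sd) {
    sim <- simulateCTSS(specs, gen$genome, samples, pipelineConfig(),
                        seed = 100L + sd)
    gr <- ctssRanges(sim$ctss[[1L]])
    near <- abs(start(gr) - 25000L) <= 2L & as.logical(strand(gr) == "+")
    sum(mcols(gr)$count[near])
  }, numeric(1L))
  expect_lt(abs(mean(totals) - 50), 3)
})

test_that("sharp promoters emit >= 80% of tags within 5 bp of the anchor", {
  gen <- generateGenome(1L, 5e4, 0.5, seed = 1L)
  specs <- .testSpecs(30000L, "-", 1e4)
  samples <- sampleLibraries("s1", "other", 1e6)
  sim <- simulateCTSS(specs, gen$genome, samples, pipelineConfig(),
                      seed = 31L)
  gr <- ctssRanges(sim$ctss[[1L]])
  near <- abs(start(gr) - 30000L) <= 5L & as.logical(strand(gr) == "-")
  expect_gte(sum(mcols(gr)$count[near]) / 1e4, 0.8)
})

test_that("silent programs emit no promoter tags and seeds matter", {
  gen <- generateGenome(1L, 5e4, 0.5, seed = 1L)
  specs <- GRanges("chr1", IRanges(c(20000L, 40000L), width = 1L),
                   strand = "+")
  mcols(specs) <- DataFrame(
    promoter_id = c("p1", "p2"), class = c("silent", "housekeeping_sharp"),
    shape_class = "sharp", width_bp = 5L,
    program_kind = c("silent", "housekeeping"), base_tpm = c(0, 1000),
    target_group = NA_character_, has_tata = FALSE, has_cpg = FALSE,
    detectable = c(FALSE, TRUE))
  samples <- sampleLibraries("s1", "other", 1e5)
  cfg <- pipelineConfig(noiseRate = 0.001)
  sim1 <- simulateCTSS(specs, gen$genome, samples, cfg, seed = 1L)
  et <- truthEtpm(sim1$truth)
  expect_equal(unname(et["p1", "s1"]), 0)
  sim2 <- simulateCTSS(specs, gen$genome, samples, cfg, seed = 2L)
  t1 <- ctssRanges(sim1$ctss[[1L]])
  t2 <- ctssRanges(sim2$ctss[[1L]])
  expect_false(identical(start(t1), start(t2)) &&
               identical(mcols(t1)$count, mcols(t2)$count))
})

test_that("ballast promoters fill the library to the noise target", {
  samples <- defaultSampleLibraries(1e6)
  cfg <- pipelineConfig(noiseRate = 0.02)
  gen <- generateGenome(1L, 2e6, 0.5, seed = 1L, n_islands = 40L)
  pl <- plantPromoters(gen, c(housekeeping_broad = 10L, ballast = 4L),
                       seed = 2L)
  et <- expectedTpmMatrix(pl$specs, samples, cfg)
  expect_equal(mean(colSums(et)), 0.98e6, tolerance = 1e-9)
})
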