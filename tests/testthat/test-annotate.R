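.genes <- function(pos, strand, ids, src = "ensembl") {
  GRanges("chr1", IRanges(pos, width = 1L), strand = strand,
          gene_id = ids, symbol = ids,
          source = rep(src, length.out = length(pos)))
}

test_that("gene association respects the 500-bp window and closeness", {
  pk <- makeToyPeaks("chr1", 995L, 1005L, "+", matrix(10), rep_pos = 1000L)
  a1 <- associateGenes(pk, .genes(1400L, "+", "gA"))
  expect_equal(a1$gene_id, "gA")
  expect_equal(a1$distance_bp, -400L)  # peak upstream of the gene TSS
  # 700 bp away: unassociated
  a2 <- associateGenes(pk, .genes(1700L, "+", "gA"))
  expect_true(is.na(a2$gene_id))
  # two candidates at 100 and 300 bp: the closest wins
  a3 <- associateGenes(pk, .genes(c(1100L, 1300L), "+", c("gB", "gC")))
  expect_equal(a3$gene_id, "gB")
  # exactly 500 bp: inclusive window
  a4 <- associateGenes(pk, .genes(1500L, "+", "gD"))
  expect_equal(a4$gene_id, "gD")
})

test_that("gene association is strand-aware with signed distances", {
  pk <- makeToyPeaks("chr1", 995L, 1005L, "-", matrix(10), rep_pos = 1000L)
  # same position, wrong strand
  expect_true(is.na(associateGenes(pk, .genes(1000L, "+", "gA"))$gene_id))
  a <- associateGenes(pk, .genes(900L, "-", "gB"))
  expect_equal(a$gene_id, "gB")
  # on the minus strand a peak right of the TSS is upstream: negative
  expect_equal(a$distance_bp, -100L)
  expect_equal(associateGenes(pk, .genes(1000L, "+", "gA"),
                              ignore_strand = TRUE)$gene_id, "gA")
})

test_that("association tie-breaks are a total order over sources and ids", {
  pk <- makeToyPeaks("chr1", 995L, 1005L, "+", matrix(10), rep_pos = 1000L)
  g_ens <- .genes(1100L, "+", "gEns", src = "ensembl")
  g_ref <- .genes(900L, "+", "gRef", src = "refseq")
  both <- suppressWarnings(c(g_ens, g_ref))
  # equal |distance|: refseq wins, in either input order
  expect_equal(associateGenes(pk, both)$gene_id, "gRef")
  expect_equal(associateGenes(pk, rev(both))$gene_id, "gRef")
  # same source: lexicographic gene id
  g2 <- .genes(c(900L, 1100L), "+", c("zzz", "aaa"))
  expect_equal(associateGenes(pk, g2)$gene_id, "aaa")
  expect_equal(associateGenes(pk, rev(g2))$gene_id, "aaa")
})

test_that("interval overlap uses >= 1 bp half-open logic", {
  # peak 0-based [100,105) = 1-based 101..105
  pk <- GRanges("chr1", IRanges(101L, 105L), strand = "+",
                peak_id = "p1", rep_pos = 101L)
  isl_touch <- GRanges("chr1", IRanges(105L, 200L))  # 0-based [104,200)
  isl_abut <- GRanges("chr1", IRanges(106L, 200L))   # 0-based [105,200)
  expect_true(intervalOverlap(pk, isl_touch))
  expect_false(intervalOverlap(pk, isl_abut))
})

test_that("interval overlap equals the quadratic brute-force oracle", {
  set.seed(13)
  for (rep in 1:5) {
    ps <- sample.int(1000L, 100L, TRUE)
    pk <- GRanges("chr1", IRanges(ps, ps + sample.int(20L, 100L, TRUE)),
                  strand = sample(c("+", "-"), 100L, TRUE))
    is_ <- sample.int(1000L, 30L, TRUE)
    iv <- GRanges("chr1", IRanges(is_, is_ + sample.int(50L, 30L, TRUE)))
    got <- intervalOverlap(pk, iv)
    want <- vapply(seq_along(pk), function(i)
      any(start(pk)[i] <= end(iv) & start(iv) <= end(pk)[i]),
      logical(1L))
    expect_identical(got, want)
  }
})

test_that("GC content handles pure, mixed and ambiguous windows", {
  g100 <- paste(rep("G", 200L), collapse = "")
  acgt <- paste(rep("ACGT", 50L), collapse = "")
  nmix <- paste(c(rep("N", 10L), rep("G", 45L), rep("A", 45L),
                  rep("C", 100L)), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrG = g100, chrM = acgt,
                                       chrN = nmix))
  pk <- GRanges(c("chrG", "chrM", "chrN"),
                IRanges(c(100L, 100L, 50L), width = 1L), strand = "+",
                peak_id = c("a", "b", "c"),
                rep_pos = c(100L, 100L, 51L))
  gc <- gcContent(genome, pk, flank = 50L)
  expect_equal(gc[1L], 1.0)
  expect_equal(gc[2L], 0.5)
  # window chrN[1..100]: 10 N excluded, 45 G + 45 A -> 45/90
  expect_equal(gc[3L], 0.5)
  # fully ambiguous window is NA
  genomeN <- Biostrings::DNAStringSet(c(chrZ = paste(rep("N", 200L),
                                                     collapse = "")))
  pkZ <- GRanges("chrZ", IRanges(100L, width = 1L), strand = "+",
                 peak_id = "z", rep_pos = 100L)
  expect_true(is.na(gcContent(genomeN, pkZ)))
})

test_that("TSS-per-gene counts follow annotation and the TPM filter", {
  pk <- makeToyPeaks("chr1", c(600L, 1300L, 5000L), c(610L, 1310L, 5010L),
                     "+", matrix(c(10, 10, 2), ncol = 1),
                     rep_pos = c(605L, 1305L, 5005L))
  genes <- .genes(c(1000L, 5000L), "+", c("gA", "gB"))
  ann <- associateGenes(pk, genes)
  # gA gets peaks at -395 and +305; gB's peak fails the 3-TPM filter
  counts <- tssPerGene(ann, pk, min_tpm = 3)
  expect_equal(unname(counts["gA"]), 2L)
  expect_false("gB" %in% names(counts))
  counts0 <- tssPerGene(ann, pk, min_tpm = 0)
  expect_equal(unname(counts0["gB"]), 1L)
})
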