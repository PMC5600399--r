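test_that("CTSS clustering follows the gap rule and strand separation", {
  gr <- GRanges("chr1", IRanges(c(100L, 105L, 200L), width = 1L),
                strand = "+", count = 1L)
  cl <- clusterCTSS(gr, gap_bp = 20L)
  expect_equal(length(cl), 2L)
  expect_equal(start(cl), c(100L, 200L))
  expect_equal(end(cl), c(105L, 200L))
  # same position, opposite strands -> two clusters
  gr2 <- GRanges("chr1", IRanges(c(100L, 100L), width = 1L),
                 strand = c("+", "-"), count = 1L)
  expect_equal(length(clusterCTSS(gr2, 20L)), 2L)
  # singleton
  expect_equal(length(clusterCTSS(gr2[1L], 20L)), 1L)
})

test_that("clustering matches a brute-force gap oracle and is monotone", {
  set.seed(21)
  for (rep in 1:25) {
    pos <- sort(sample.int(500L, 40L))
    gr <- GRanges("chr1", IRanges(pos, width = 1L), strand = "+",
                  count = 1L)
    for (gap in c(1L, 5L, 20L)) {
      cl <- clusterCTSS(gr, gap)
      # oracle: split sorted positions where the step exceeds the gap
      brk <- c(0L, which(diff(pos) > gap), length(pos))
      expect_equal(length(cl), length(brk) - 1L)
      expect_equal(start(cl), pos[head(brk, -1L) + 1L])
      expect_equal(end(cl), pos[brk[-1L]])
    }
    # monotonicity: larger gap never increases the cluster count
    n_by_gap <- vapply(c(1L, 5L, 20L, 100L), function(g)
      length(clusterCTSS(gr, g)), integer(1L))
    expect_true(all(diff(n_by_gap) <= 0L))
  }
})

test_that("valley decomposition splits bimodal but not flat clusters", {
  cfg <- pipelineConfig()
  # two modes 80 bp apart bridged by 1-count positions (zero-depth valley)
  pos <- c(100:104, seq(105L, 179L, by = 10L), 180:184)
  cnt <- c(c(5, 20, 60, 20, 5), rep(1, 8), c(5, 25, 70, 25, 5))
  seg <- splitCluster(pos, cnt, cfg)
  expect_equal(max(seg), 2L)
  expect_true(all(diff(seg[order(pos)]) >= 0L))
  # counts conserved across segments
  expect_equal(sum(tapply(cnt, seg, sum)), sum(cnt))
  # unimodal 40-bp cluster is below maxUnsplitBp: untouched
  pos2 <- 200:239
  cnt2 <- dnorm(seq(-2, 2, length.out = 40L)) * 100
  expect_equal(max(splitCluster(pos2, cnt2, cfg)), 1L)
  # flat 200-bp profile: no qualifying valley
  pos3 <- 300:499
  cnt3 <- rep(7, 200L)
  expect_equal(max(splitCluster(pos3, cnt3, cfg)), 1L)
})

test_that("representative positions break ties toward the 5' end", {
  expect_equal(representativePosition(c(100L, 101L), c(5, 9), "+"), 101L)
  expect_equal(representativePosition(c(100L, 102L), c(5, 5), "+"), 100L)
  expect_equal(representativePosition(c(100L, 102L), c(5, 5), "-"), 102L)
})

test_that("support thresholds assign permissive and robust tiers", {
  df <- data.frame(chrom = "chr1",
                   pos = c(100L, 500L, 900L, 1300L),
                   strand = "+")
  # columns: two samples with 1e6 and 2e7 mapped tags
  counts <- cbind(s1 = c(3L, 11L, 2L, 0L), s2 = c(0L, 0L, 2L, 11L))
  se <- makePooled(df, counts, totals = c(1e6, 2e7))
  peaks <- callPeaks(se, pipelineConfig())
  rd <- rowData(peaks)
  # peak at 100: max count 3 -> permissive only
  expect_equal(rd$tier[start(rowRanges(peaks)) == 100L], "permissive")
  # peak at 500: count 11 in the 1e6 library -> 11 TPM -> robust
  expect_equal(rd$tier[start(rowRanges(peaks)) == 500L], "robust")
  # peak at 900: count 2 everywhere -> dropped
  expect_false(900L %in% start(rowRanges(peaks)))
  # peak at 1300: count 11 but TPM 0.55 < 1 -> permissive only
  expect_equal(rd$tier[start(rowRanges(peaks)) == 1300L], "permissive")
  expect_equal(length(peaks), 3L)
})

test_that("called peaks partition their CTSS and conserve pooled counts", {
  set.seed(5)
  pos <- sort(sample.int(2000L, 120L))
  df <- data.frame(chrom = "chr1", pos = pos,
                   strand = sample(c("+", "-"), 120L, TRUE))
  counts <- cbind(s1 = sample(3:40, 120L, TRUE),
                  s2 = sample(3:40, 120L, TRUE))
  se <- makePooled(df, counts, totals = c(1e6, 1e6))
  peaks <- callPeaks(se, pipelineConfig())
  # conservation: pooled counts over peaks equal the pooled input total
  expect_equal(sum(rowData(peaks)$pooled_count), sum(counts))
  # peaks within a strand are disjoint
  for (s in c("+", "-")) {
    p <- rowRanges(peaks)[strand(rowRanges(peaks)) == s]
    expect_equal(length(IRanges::reduce(ranges(p), min.gapwidth = 0L)),
                 length(p))
  }
  # representative position lies inside its peak and is the pooled argmax
  rr <- rowRanges(peaks)
  expect_true(all(rowData(peaks)$rep_pos >= start(rr) &
                  rowData(peaks)$rep_pos <= end(rr)))
})

test_that("peak BED output round-trips coordinates 0-based", {
  df <- data.frame(chrom = "chr1", pos = c(100L, 101L, 102L),
                   strand = "+")
  counts <- cbind(s1 = c(4L, 12L, 3L))
  se <- makePooled(df, counts, totals = 1e6)
  peaks <- callPeaks(se, pipelineConfig())
  f <- withr::local_tempfile(fileext = ".bed")
  writePeakBed(peaks, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 99L)    # 1-based 100 -> 0-based 99
  expect_equal(bed$V3, 102L)
  expect_equal(bed$V7, 100L)   # representative 101 -> 0-based 100
  expect_equal(bed$V9, "robust")
})
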