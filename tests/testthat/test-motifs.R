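test_that("promoter windows follow the strand-aware (-300,+100) rule", {
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 2000L, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  # plus peak, representative at 0-based 1000 (1-based 1001)
  pk <- GRanges("chr1", IRanges(995L, 1010L), strand = "+",
                peak_id = "p", rep_pos = 1001L)
  w <- promoterWindows(pk, genome)
  # genomic 0-based [700, 1100) == 1-based 701..1100
  expect_equal(as.character(w[[1L]]), substr(s, 701L, 1100L))
  expect_equal(Biostrings::width(w), 400L)
  expect_false(mcols(w)$clipped)
  # TSS base sits at offset 300 (0-based)
  expect_equal(substr(as.character(w[[1L]]), 301L, 301L),
               substr(s, 1001L, 1001L))

  mk <- GRanges("chr1", IRanges(995L, 1010L), strand = "-",
                peak_id = "m", rep_pos = 1001L)
  wm <- promoterWindows(mk, genome)
  # reverse complement of 0-based [901, 1301) == 1-based 902..1301
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 902L, 1301L))))
  expect_equal(as.character(wm[[1L]]), rc)
  tssbase <- chartr("ACGT", "TGCA", substr(s, 1001L, 1001L))
  expect_equal(substr(as.character(wm[[1L]]), 301L, 301L), tssbase)

  # near the chromosome start the window is clipped and flagged
  ck <- GRanges("chr1", IRanges(45L, 55L), strand = "+",
                peak_id = "c", rep_pos = 51L)
  wc <- promoterWindows(ck, genome)
  expect_true(mcols(wc)$clipped)
  expect_lt(Biostrings::width(wc), 400L)
})

test_that("PWM construction regularizes counts into probabilities", {
  pwms <- toyPWMs()
  for (p in pwms) {
    expect_true(all(abs(colSums(p@mat) - 1) < 1e-6))
    expect_true(all(p@mat > 0))
  }
  expect_error(pwmFromCounts(matrix(1, 3, 4), "bad"), "4 rows")
})

test_that("JASPAR-style matrices parse with and without brackets", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">MA0001.1 test",
               "A [ 10  0 90 ]",
               "C [ 10  0  0 ]",
               "G [ 70 95  5 ]",
               "T [ 10  5  5 ]",
               ">MA0002.1 plain",
               "1 2 3",
               "4 5 6",
               "7 8 9",
               "10 11 12"), f)
  pw <- readJASPAR(f)
  expect_equal(names(pw), c("MA0001.1", "MA0002.1"))
  expect_equal(ncol(pw$MA0001.1@mat), 3L)
  expect_equal(unname(which.max(pw$MA0001.1@mat[, 2L])), 3L)  # G dominates
})

test_that("PWM scanning finds the consensus and rejects all-N", {
  pwms <- toyPWMs()
  tata <- pwms$TATA_box
  hit <- paste0(strrep("C", 50L), "TATAAA", strrep("C", 50L))
  expect_gte(pwmScan(hit, tata), 1L)
  expect_equal(pwmScan(strrep("N", 100L), tata), 0L)
  # reverse-complement hits found only when both_strands
  rc <- paste0(strrep("C", 50L), "TTTATA", strrep("C", 50L))
  expect_equal(pwmScan(rc, tata, both_strands = FALSE), 0L)
  expect_gte(pwmScan(rc, tata, both_strands = TRUE), 1L)
})

test_that("PWM scan counts equal the brute-force enumeration oracle", {
  set.seed(43)
  pwms <- toyPWMs()
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 400L, TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    for (pwm in pwms[c("TATA_box", "rand_1")]) {
      # oracle: explicit per-offset scoring on both strands
      oracle_count <- function(str) {
        ch <- strsplit(str, "")[[1L]]
        L <- ncol(pwm@mat)
        n <- 0L
        for (o in seq_len(length(ch) - L + 1L)) {
          sc <- 0
          for (i in seq_len(L)) {
            b <- match(ch[o + i - 1L], c("A", "C", "G", "T"))
            sc <- sc + if (is.na(b)) -Inf else
              log2(pwm@mat[b, i] / pwm@background[b])
          }
          mx <- sum(apply(log2(pwm@mat / pwm@background), 2L, max))
          if (sc >= pwm@threshold_frac * mx) n <- n + 1L
        }
        n
      }
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
      expect_identical(pwmScan(s, pwm, both_strands = TRUE),
                       oracle_count(s) + oracle_count(rc))
    }
  }
})

test_that("motif enrichment reproduces the exact hypergeometric tail", {
  pwms <- toyPWMs()["GC_box"]
  hit <- paste0(strrep("A", 40L), "GGGCGG", strrep("A", 40L))
  miss <- strrep("A", 86L)
  fg <- setNames(rep(hit, 10L), paste0("f", 1:10))
  bg <- setNames(rep(miss, 10L), paste0("b", 1:10))
  res <- motifEnrichment(fg, bg, pwms)
  expect_equal(res$fg_hits, 10L)
  expect_equal(res$bg_hits, 0L)
  # all 10 hits drawn into the foreground: p = 1/C(20,10)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # single motif: BH leaves the p-value untouched
  expect_equal(res$adjusted_p, res$p_value)
  # identical rates: odds ratio 1 and p >= 0.5
  res2 <- motifEnrichment(setNames(rep(hit, 5L), paste0("f", 1:5)),
                          setNames(rep(hit, 5L), paste0("b", 1:5)), pwms)
  expect_equal(res2$odds_ratio, 1)
  expect_gte(res2$p_value, 0.5)
  expect_error(motifEnrichment(fg, fg, pwms), "overlap")
})

test_that("exact-test p-values match a choose() oracle on random tables", {
  pwms <- toyPWMs()["TATA_box"]
  hit <- paste0(strrep("G", 20L), "TATAAA", strrep("G", 20L))
  miss <- strrep("G", 46L)
  set.seed(47)
  for (rep in 1:8) {
    nf <- sample(3:25, 1L); nb <- sample(3:25, 1L)
    fh <- sample(0:nf, 1L); bh <- sample(0:nb, 1L)
    fg <- setNames(c(rep(hit, fh), rep(miss, nf - fh)),
                   paste0("f", seq_len(nf)))
    bg <- setNames(c(rep(hit, bh), rep(miss, nb - bh)),
                   paste0("b", seq_len(nb)))
    res <- motifEnrichment(fg, bg, pwms)
    K <- fh + bh; N <- nf + nb
    ks <- seq(fh, min(K, nf))
    oracle <- sum(choose(K, ks) * choose(N - K, nf - ks)) / choose(N, nf)
    expect_lt(abs(res$p_value - oracle), 1e-10)
  }
})

test_that("top-k overlap counts shared and unique motifs", {
  mkset <- function(ids) data.frame(motif_id = ids,
                                    adjusted_p = 1e-6,
                                    stringsAsFactors = FALSE)
  a <- mkset(paste0("m", 1:50))
  b <- mkset(paste0("m", 26:75))
  ov <- topKOverlap(list(A = a, B = b), k = 50L)
  expect_equal(ov$overlap["A", "B"], 25L)
  expect_equal(ov$overlap["A", "A"], 50L)
  expect_setequal(ov$unique$A, paste0("m", 1:25))
  # identical rankings overlap completely; disjoint sets not at all
  ov2 <- topKOverlap(list(A = a, B = a), k = 50L)
  expect_equal(ov2$overlap["A", "B"], 50L)
  ov3 <- topKOverlap(list(A = a, B = mkset(paste0("x", 1:50))))
  expect_equal(ov3$overlap["A", "B"], 0L)
  # non-enriched motifs never enter the top list
  weak <- mkset("m99"); weak$adjusted_p <- 0.2
  ov4 <- topKOverlap(list(A = rbind(a, weak), B = b), k = 60L)
  expect_false("m99" %in% ov4$top$A)
})
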