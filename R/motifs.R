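#' A position weight matrix for motif scanning
#'
#' Column-stochastic 4 x L base probability matrix (rows A, C, G, T)
#' with its background base frequencies and a log-odds hit threshold
#' expressed as a fraction of the maximum attainable score.
#'
#' @slot motif_id character scalar.
#' @slot mat 4 x L probability matrix, columns summing to 1.
#' @slot background length-4 base frequencies (A, C, G, T).
#' @slot threshold_frac hit threshold as a fraction of the maximum
#'   log-odds score (default 0.8).
#' @export
setClass("MotifPWM",
  representation(motif_id = "character", mat = "matrix",
                 background = "numeric", threshold_frac = "numeric"))

setValidity("MotifPWM", function(object) {
  msg <- character()
  if (nrow(object@mat) != 4L) msg <- c(msg, "mat must have 4 rows (ACGT)")
  if (any(abs(colSums(object@mat) - 1) > 1e-6))
    msg <- c(msg, "mat columns must sum to 1 (within 1e-6)")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (object@threshold_frac <= 0 || object@threshold_frac > 1)
    msg <- c(msg, "threshold_frac must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifPWM", function(object) {
  cons <- paste(c("A", "C", "G", "T")[apply(object@mat, 2L, which.max)],
                collapse = "")
  cat("MotifPWM '", object@motif_id, "' (", ncol(object@mat),
      " bp, consensus ", cons, ")\n", sep = "")
})

#' Build a PWM from a base count matrix
#'
#' Counts are regularized with a +0.01 pseudocount per cell and
#' normalized column-wise.
#'
#' @param counts 4 x L numeric count matrix (rows A, C, G, T).
#' @param motif_id motif identifier.
#' @param background base frequencies (default uniform).
#' @param threshold_frac log-odds hit threshold as a fraction of the
#'   maximum score (default 0.8).
#' @return A [MotifPWM-class].
#' @export
pwmFromCounts <- function(counts, motif_id,
                          background = rep(0.25, 4),
                          threshold_frac = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("count matrix must have 4 rows (A, C, G, T)")
  counts <- counts + 0.01
  mat <- sweep(counts, 2L, colSums(counts), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  new("MotifPWM", motif_id = as.character(motif_id), mat = mat,
      background = background, threshold_frac = threshold_frac)
}

#' Read PWMs from JASPAR-style 4-row count matrix text
#'
#' Accepts the JASPAR 2016 format: a \code{>ID name} header followed by
#' four rows (A, C, G, T), with or without the base letter and square
#' brackets.
#'
#' @param path matrix file.
#' @param background base frequencies applied to every motif.
#' @param threshold_frac hit threshold fraction.
#' @return Named list of [MotifPWM-class].
#' @export
readJASPAR <- function(path, background = rep(0.25, 4),
                       threshold_frac = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' motif headers in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    lo <- hdr[i] + 1L
    hi <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    rows <- lines[lo:hi]
    if (length(rows) != 4L)
      stop("motif at line ", hdr[i], " does not have 4 count rows")
    nums <- lapply(rows, function(r) {
      r <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", r)
      r <- gsub("\\[|\\]", "", r)
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1L]])
    })
    L <- unique(lengths(nums))
    if (length(L) != 1L)
      stop("ragged count rows for motif at line ", hdr[i])
    id <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1L]][1L]
    out[[id]] <- pwmFromCounts(do.call(rbind, nums), id, background,
                               threshold_frac)
  }
  out
}

#' Bundled toy PWM set
#'
#' Five small motifs for testing and synthetic-data analysis: a strong
#' TATA-box (consensus TATAAA), a GC-box (consensus GGGCGG, Sp1-like)
#' and three unrelated mixed-composition motifs.
#'
#' @param threshold_frac hit threshold fraction (default 0.8).
#' @return Named list of [MotifPWM-class].
#' @export
toyPWMs <- function(threshold_frac = 0.8) {
  strong <- function(consensus) {
    idx <- match(strsplit(consensus, "")[[1L]], c("A", "C", "G", "T"))
    m <- matrix(1, 4L, length(idx))
    m[cbind(idx, seq_along(idx))] <- 97
    m
  }
  moderate <- function(consensus) {
    idx <- match(strsplit(consensus, "")[[1L]], c("A", "C", "G", "T"))
    m <- matrix(10, 4L, length(idx))
    m[cbind(idx, seq_along(idx))] <- 70
    m
  }
  list(
    TATA_box = pwmFromCounts(strong("TATAAA"), "TATA_box",
                             threshold_frac = threshold_frac),
    GC_box = pwmFromCounts(strong("GGGCGG"), "GC_box",
                           threshold_frac = threshold_frac),
    rand_1 = pwmFromCounts(moderate("ACGTCA"), "rand_1",
                           threshold_frac = threshold_frac),
    rand_2 = pwmFromCounts(moderate("CTAGGA"), "rand_2",
                           threshold_frac = threshold_frac),
    rand_3 = pwmFromCounts(moderate("TGCCAT"), "rand_3",
                           threshold_frac = threshold_frac))
}

#' Extract strand-aware promoter windows
#'
#' For the default window (-300, +100): plus-strand peaks yield the
#' genomic interval [rep - 300, rep + 100) and minus-strand peaks the
#' reverse complement of [rep - 99, rep + 301) (0-based half-open), so
#' every output runs 5' to 3' with the TSS at offset 300. Windows are
#' clipped at chromosome edges and flagged \code{clipped} when short.
#'
#' @param peaks a [TSSPeaks-class] or GRanges with \code{peak_id} and
#'   \code{rep_pos}.
#' @param genome a [Biostrings::DNAStringSet].
#' @param window integer(2): (upstream, downstream), upstream <= 0 <=
#'   downstream.
#' @return A [Biostrings::DNAStringSet] named by peak_id, with a
#'   \code{clipped} logical metadata column.
#' @export
promoterWindows <- function(peaks, genome, window = c(-300L, 100L)) {
  if (!(window[1L] <= 0L && 0L <= window[2L]))
    stop("window must satisfy upstream <= 0 <= downstream")
  gr <- if (is(peaks, "TSSPeaks"))
    SummarizedExperiment::rowRanges(peaks) else peaks
  rep_pos <- mcols(gr)$rep_pos
  chrom <- as.character(seqnames(gr))
  str <- as.character(strand(gr))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  lo <- ifelse(str == "-", rep_pos - window[2L] + 1L, rep_pos + window[1L])
  hi <- ifelse(str == "-", rep_pos - window[1L], rep_pos + window[2L] - 1L)
  clo <- pmax(1L, lo)
  chi <- pmin(lens[chrom], hi)
  seqs <- vapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(genome[[chrom[i]]], clo[i], chi[i])
    if (str[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1L))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- mcols(gr)$peak_id
  mcols(out)$clipped <- clo != lo | chi != hi
  out
}

.BASES <- c("A", "C", "G", "T")

#' Count PWM hits in a sequence by sliding log-odds scan
#'
#' Scores every offset as sum_i log2(p_i(base) / bg(base)); offsets
#' covering an ambiguous base score -Inf. A hit is an offset whose
#' score reaches \code{threshold_frac} of the maximum attainable score.
#' With \code{both_strands} the reverse complement is scanned too.
#'
#' @param sequence a [Biostrings::DNAString], one-element DNAStringSet
#'   or character scalar over A, C, G, T, N.
#' @param pwm a [MotifPWM-class].
#' @param both_strands scan both strands (default TRUE).
#' @return Integer hit count (>= 0).
#' @export
pwmScan <- function(sequence, pwm, both_strands = TRUE) {
  s <- if (is.character(sequence)) sequence
       else as.character(sequence)[1L]
  slog <- rbind(log2(pwm@mat / pwm@background), -Inf)  # row 5 = N/other
  thr <- pwm@threshold_frac * sum(apply(slog[1:4, , drop = FALSE], 2L, max))
  count_one <- function(chars) {
    code <- match(chars, .BASES, nomatch = 5L)
    L <- ncol(slog)
    n <- length(code) - L + 1L
    if (n < 1L) return(0L)
    sc <- numeric(n)
    for (i in seq_len(L))
      sc <- sc + slog[cbind(code[i:(i + n - 1L)], i)]
    sum(sc >= thr)
  }
  chars <- strsplit(toupper(s), "")[[1L]]
  hits <- count_one(chars)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste(chars, collapse = ""))))
    hits <- hits + count_one(strsplit(rc, "")[[1L]])
  }
  hits
}

#' Motif enrichment of a foreground against a background sequence set
#'
#' For each PWM, sequences are reduced to hit/no-hit (>= 1 scan hit)
#' and the resulting 2 x 2 table is tested one-sided for foreground
#' over-representation with the hypergeometric (Fisher) exact test;
#' p-values are Benjamini-Hochberg adjusted across motifs. Rows are
#' ranked by adjusted p, then descending odds ratio. "Enriched" means
#' adjusted p <= 0.05.
#'
#' @param fg,bg foreground / background [Biostrings::DNAStringSet] (or
#'   character vectors); names must not overlap between the two sets.
#' @param pwms list of [MotifPWM-class].
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame: motif_id, fg_hits, fg_total, bg_hits, bg_total,
#'   odds_ratio, p_value, adjusted_p, enriched.
#' @export
motifEnrichment <- function(fg, bg, pwms, both_strands = TRUE) {
  if (!length(fg) || !length(bg))
    stop("foreground and background must be non-empty")
  if (!is.null(names(fg)) && !is.null(names(bg))) {
    shared <- intersect(names(fg), names(bg))
    if (length(shared))
      stop("foreground and background overlap: ",
           paste(utils::head(shared, 3L), collapse = ", "))
  }
  fg_chr <- as.character(fg)
  bg_chr <- as.character(bg)
  rows <- lapply(pwms, function(pwm) {
    fh <- sum(vapply(fg_chr, pwmScan, integer(1L), pwm = pwm,
                     both_strands = both_strands) > 0L)
    bh <- sum(vapply(bg_chr, pwmScan, integer(1L), pwm = pwm,
                     both_strands = both_strands) > 0L)
    nf <- length(fg_chr); nb <- length(bg_chr)
    # one-sided hypergeometric tail: P(X >= fh) drawing nf from nf+nb
    p <- stats::phyper(fh - 1L, fh + bh, nf + nb - fh - bh, nf,
                       lower.tail = FALSE)
    or_num <- fh * (nb - bh)
    or_den <- (nf - fh) * bh
    or <- if (or_den == 0) {
      if (or_num == 0) 1 else Inf
    } else or_num / or_den
    data.frame(motif_id = pwm@motif_id, fg_hits = fh, fg_total = nf,
               bg_hits = bh, bg_total = nb, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$adjusted_p <= 0.05
  out <- out[order(out$adjusted_p, -out$odds_ratio, out$motif_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k overlap between ranked motif enrichment results
#'
#' Takes the top \code{k} enriched motifs (adjusted p <= \code{alpha})
#' of each result set and reports all pairwise intersection sizes and
#' the motifs unique to each set.
#'
#' @param rowsets named list of data.frames from [motifEnrichment()].
#' @param k top-list size (default 50).
#' @param alpha adjusted-p cutoff for "enriched" (default 0.05).
#' @return A list with \code{top} (named list of motif id vectors),
#'   \code{overlap} (pairwise count matrix) and \code{unique} (named
#'   list of motifs found in exactly one set).
#' @export
topKOverlap <- function(rowsets, k = 50L, alpha = 0.05) {
  top <- lapply(rowsets, function(df) {
    df <- df[df$adjusted_p <= alpha, , drop = FALSE]
    utils::head(df$motif_id, k)
  })
  n <- length(top)
  ov <- matrix(0L, n, n, dimnames = list(names(top), names(top)))
  for (i in seq_len(n)) for (j in seq_len(n))
    ov[i, j] <- length(intersect(top[[i]], top[[j]]))
  all_ids <- unlist(top, use.names = FALSE)
  uniq <- lapply(seq_len(n), function(i) {
    others <- unlist(top[-i], use.names = FALSE)
    setdiff(top[[i]], others)
  })
  names(uniq) <- names(top)
  list(top = top, overlap = ov, unique = uniq)
}
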