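SCORE_GRID <- 1000L # integer score units per bit

# log2-odds score matrix (width x 4, bits); pseudocount added per cell and
# rows renormalised; cells with zero probability at pseudocount 0 score -Inf
logOddsMatrix <- function(pwm) {
  p <- (pwm@matrix + pwm@pseudocount) / (1 + 4 * pwm@pseudocount)
  log2(sweep(p, 2L, pwm@background, "/"))
}

# integer score matrix on the 1/SCORE_GRID-bit grid; -Inf cells are floored
# far below the achievable range so they can never reach any threshold
integerScoreMatrix <- function(S) {
  Si <- round(S * SCORE_GRID)
  if (any(!is.finite(Si))) {
    finiteMin <- min(Si[is.finite(Si)])
    Si[!is.finite(Si)] <- finiteMin - 100L * SCORE_GRID
  }
  Si
}

#' Log-odds score of a motif on one sequence window
#'
#' Sum over columns of `log2((p_ij + pseudocount) / background_j)` with
#' the pseudocount-adjusted probabilities renormalised. A window
#' containing a non-ACGT letter scores `-Inf` when `nPolicy = "skip"`,
#' otherwise it is an error.
#'
#' @param pwm A [MotifMatrix-class].
#' @param sequence A character string of exactly the motif width.
#' @param nPolicy `"error"` (default) or `"skip"` for non-ACGT letters.
#' @return The score in bits.
#' @examples
#' m <- matrix(rep(c(1, 0, 0, 0), 5), ncol = 4, byrow = TRUE)
#' pwm <- motifMatrix("A5", m, pseudocount = 0)
#' scoreWindow(pwm, "AAAAA") # 5 columns x 2 bits
#' @export
scoreWindow <- function(pwm, sequence, nPolicy = c("error", "skip")) {
  nPolicy <- match.arg(nPolicy)
  w <- motifWidth(pwm)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) != w)
    stop("sequence length ", length(chars), " != motif width ", w)
  code <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(code))) {
    if (nPolicy == "skip") return(-Inf)
    stop("non-ACGT letter in sequence")
  }
  S <- logOddsMatrix(pwm)
  sum(S[cbind(seq_len(w), code)])
}

# exact null distribution of the discretised score for a background-drawn
# width-mer: returns integer offset (minimum achievable integer score) and
# the tail vector tail[i] = P(S_int >= offset + i - 1)
scoreTailDistribution <- function(pwm) {
  Si <- integerScoreMatrix(logOddsMatrix(pwm))
  bg <- pwm@background
  rowMin <- apply(Si, 1L, min)
  rowMax <- apply(Si, 1L, max)
  offset <- sum(rowMin)
  dist <- 1
  base <- 0
  for (i in seq_len(nrow(Si))) {
    span <- rowMax[i] - rowMin[i]
    nd <- numeric(length(dist) + span)
    for (j in 1:4) {
      sh <- Si[i, j] - rowMin[i]
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * bg[j]
    }
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))
  list(offset = offset, tail = tail, dist = dist)
}

#' Exact p-value of a motif score under the background model
#'
#' Tail probability `P(S >= score)` for a random width-mer drawn from the
#' motif's background frequencies. Computed exactly by dynamic programming
#' over column scores discretised to a 1/1000-bit grid (the observed score
#' is rounded to the same grid). Scores at or below the minimum achievable
#' return 1; scores above the maximum achievable return the probability
#' mass of the top grid cell, the smallest value the discretisation can
#' resolve.
#'
#' @param pwm A [MotifMatrix-class].
#' @param score Observed score in bits (vectorised).
#' @return P-values in (0, 1].
#' @export
scorePvalue <- function(pwm, score) {
  td <- scoreTailDistribution(pwm)
  si <- round(score * SCORE_GRID)
  idx <- si - td$offset + 1
  n <- length(td$tail)
  vapply(idx, function(i) {
    if (i <= 1) return(1)
    if (i > n) return(max(td$tail[n], .Machine$double.xmin))
    max(td$tail[i], .Machine$double.xmin)
  }, 0)
}

# integer code vector (A=1..T=4, NA otherwise) for one chromosome
sequenceCodes <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1L]], c("A", "C", "G", "T"))
}

# per-position integer window scores for a code vector (NA where the
# window contains a non-ACGT base)
slideScores <- function(Si, code) {
  w <- nrow(Si)
  L <- length(code)
  if (L < w) return(integer(0))
  n <- L - w + 1L
  sc <- numeric(n)
  for (i in seq_len(w)) {
    sc <- sc + Si[i, ][code[seq.int(i, i + n - 1L)]]
  }
  sc
}

#' Scan sequences for motif occurrences
#'
#' FIMO-style occurrence finding: every window of the motif width on both
#' strands is scored with the log-odds matrix and reported as a hit when
#' its exact background p-value (see [scorePvalue()]) is below
#' `pvalueCutoff`. The reverse strand is scanned by scoring the
#' reverse-complemented motif on the forward sequence, so reported
#' intervals are always in forward-strand coordinates. When `regions` is
#' given, only windows fully contained in a region are reported (identical
#' to filtering a whole-genome scan to those windows).
#'
#' @param pwm A [MotifMatrix-class].
#' @param genome A named [Biostrings::DNAStringSet].
#' @param regions Optional `GRanges` restricting the scan.
#' @param pvalueCutoff Report hits with p-value strictly below this
#'   (default 1e-4, a conventional occurrence threshold).
#' @return A sorted `GRanges` of hits with metadata columns `motif`,
#'   `score` (bits) and `pvalue`.
#' @export
scanMotif <- function(pwm, genome, regions = NULL, pvalueCutoff = 1e-4) {
  w <- motifWidth(pwm)
  if (!is.null(regions)) {
    bad <- !(as.character(seqnames(regions)) %in% names(genome))
    if (any(bad)) stop("region on unknown sequence")
    lens <- Biostrings::width(genome)[match(as.character(seqnames(regions)),
                                            names(genome))]
    if (any(start(regions) < 1 | end(regions) > lens))
      stop("region outside sequence bounds")
  }
  td <- scoreTailDistribution(pwm)
  # smallest integer score whose tail is below the cutoff
  ok <- which(td$tail < pvalueCutoff)
  minInt <- if (length(ok)) td$offset + ok[1L] - 1L else Inf
  SiF <- integerScoreMatrix(logOddsMatrix(pwm))
  SiR <- integerScoreMatrix(logOddsMatrix(motifReverseComplement(pwm)))
  hits <- list()
  for (ch in names(genome)) {
    code <- sequenceCodes(genome[[ch]])
    for (strandChar in c("+", "-")) {
      Si <- if (strandChar == "+") SiF else SiR
      sc <- slideScores(Si, code)
      pos <- which(!is.na(sc) & sc >= minInt)
      if (length(pos) == 0L) next
      idx <- pmin(pmax(sc[pos] - td$offset + 1, 1), length(td$tail))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = pos + w - 1L, strand = strandChar,
        score = sc[pos] / SCORE_GRID,
        pvalue = pmax(td$tail[idx], .Machine$double.xmin))
    }
  }
  if (length(hits) == 0L) {
    gr <- GRanges()
  } else {
    df <- do.call(rbind, hits)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    mcols(gr)$score <- df$score
    mcols(gr)$pvalue <- df$pvalue
  }
  mcols(gr)$motif <- rep(motifName(pwm), length(gr))
  if (!is.null(regions) && length(gr))
    gr <- gr[countOverlaps(gr, regions, type = "within",
                           ignore.strand = TRUE) > 0]
  sort(gr, ignore.strand = TRUE)
}

#' Number of scannable motif window starts
#'
#' The sampling units of the motif enrichment test: window start positions
#' on both strands, `2 * sum(L - w + 1)` over sequences of length `L` for
#' a motif of width `w`.
#'
#' @param lengths Numeric vector of sequence (or interval) lengths.
#' @param width Motif width.
#' @return Total number of scannable window starts.
#' @export
scannablePositions <- function(lengths, width) {
  2 * sum(pmax(lengths - width + 1, 0))
}

#' Hypergeometric enrichment of motif occurrences in peaks
#'
#' Tests whether motif occurrences are over-represented among the
#' scannable window positions inside peaks relative to the whole genome.
#' For each motif, `k` hits among `n` peak positions are compared with `K`
#' hits among `N` genome positions by the hypergeometric upper tail;
#' q-values are Benjamini-Hochberg adjusted across all motifs tested and
#' flagged significant at `alpha` (default 0.05).
#'
#' @param k,n,K,N Integer vectors (one element per motif): hits in peaks,
#'   scannable positions in peaks, hits in the genome, scannable positions
#'   in the genome.
#' @param motif Motif names.
#' @param alpha Significance threshold on the q-value.
#' @return A data frame: `motif`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, in input order.
#' @export
motifEnrichment <- function(k, n, K, N, motif = names(k), alpha = 0.05) {
  if (any(k > pmin(K, n)) || any(n > N) || any(K > N) || any(k < 0))
    stop("invalid counts: need k <= min(K, n), n <= N, K <= N")
  if (is.null(motif)) motif <- paste0("motif", seq_along(k))
  p <- mapply(hypergeomUpperTail, k, K, n, N)
  q <- bhAdjust(p)
  data.frame(motif = motif, k = k, K = K, n = n, N = N, p = p, q = q,
             significant = q < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full motif enrichment of a peak set against the genome
#'
#' Convenience wrapper: scans each motif over the whole genome, counts
#' hits fully inside the peaks versus everywhere, forms the
#' position-level hypergeometric contingency (see [motifEnrichment()]),
#' and adjusts across motifs.
#'
#' @param motifs Named list of [MotifMatrix-class] objects.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param peaks A `GRanges` of peaks (within genome bounds).
#' @param pvalueCutoff Occurrence p-value cutoff passed to [scanMotif()].
#' @param alpha Significance threshold on the q-value.
#' @return A list with `table` (the enrichment data frame) and `hits`
#'   (named list of per-motif hit `GRanges`).
#' @export
motifEnrichmentScan <- function(motifs, genome, peaks,
                                pvalueCutoff = 1e-4, alpha = 0.05) {
  peaks <- reduce(peaks, min.gapwidth = 0L, ignore.strand = TRUE)
  res <- lapply(motifs, function(pwm) {
    w <- motifWidth(pwm)
    hg <- scanMotif(pwm, genome, pvalueCutoff = pvalueCutoff)
    inPk <- if (length(hg)) countOverlaps(hg, peaks, type = "within",
                                          ignore.strand = TRUE) > 0
            else logical(0)
    list(hits = hg,
         k = sum(inPk), K = length(hg),
         n = scannablePositions(width(peaks), w),
         N = scannablePositions(Biostrings::width(genome), w))
  })
  tab <- motifEnrichment(vapply(res, `[[`, 0, "k"),
                         vapply(res, `[[`, 0, "n"),
                         vapply(res, `[[`, 0, "K"),
                         vapply(res, `[[`, 0, "N"),
                         motif = names(motifs), alpha = alpha)
  list(table = tab, hits = lapply(res, `[[`, "hits"))
}

#' TSS-distance distribution of motif-bearing peaks
#'
#' Restricts a peak set to peaks containing at least one hit of the motif
#' and profiles their midpoint distances to the nearest TSS (delegating to
#' [tssProfile()]), up to `window` bases either side (default 20 kb).
#'
#' @param peaks A `GRanges` of peaks.
#' @param hits A `GRanges` of motif hits (e.g. from [scanMotif()]).
#' @param genes A stranded gene `GRanges`.
#' @param window,bin Histogram half-width and bin size in bases.
#' @return As [tssProfile()], plus `nPeaksWithMotif`; when no peak
#'   contains the motif, an empty histogram with zero counts.
#' @export
motifTssDistribution <- function(peaks, hits, genes, window = 20000,
                                 bin = 500) {
  contained <- if (length(hits))
    countOverlaps(hits, peaks, type = "within", ignore.strand = TRUE) > 0 else
    logical(0)
  keep <- if (any(contained))
    countOverlaps(peaks, hits[contained], ignore.strand = TRUE) > 0 else
    rep(FALSE, length(peaks))
  sel <- peaks[keep]
  if (length(sel) == 0L) {
    breaks <- seq(-window, window, by = bin)
    return(list(histogram = data.frame(lower = head(breaks, -1),
                                       upper = tail(breaks, -1),
                                       mid = (head(breaks, -1) +
                                              tail(breaks, -1)) / 2,
                                       count = 0L),
                distances = numeric(0), nTotal = 0L, nWithin1kb = 0L,
                nWithin500 = 0L, pctWithin1kb = NaN, pctWithin500 = NaN,
                nPeaksWithMotif = 0L))
  }
  out <- tssProfile(sel, genes, window = window, bin = bin)
  out$nPeaksWithMotif <- length(sel)
  out
}
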