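categoryLevels <- c("intragenic", "promoter_5kb", "downstream_5kb",
                    "within_100kb_upstream", "within_100kb_downstream",
                    "gene_desert")

# strand-aware category windows for one category over all genes; windows
# clipped at chromosome starts may become empty (width 0) and then match
# nothing
categoryWindows <- function(genes, category, promoterWindow = 5000,
                            flankWindow = 100000) {
  plus <- as.character(strand(genes)) == "+"
  gs <- start(genes); ge <- end(genes)
  lim <- switch(category,
    intragenic = list(s = gs, e = ge),
    promoter_5kb = list(s = ifelse(plus, gs - promoterWindow, ge + 1),
                        e = ifelse(plus, gs - 1, ge + promoterWindow)),
    downstream_5kb = list(s = ifelse(plus, ge + 1, gs - promoterWindow),
                          e = ifelse(plus, ge + promoterWindow, gs - 1)),
    within_100kb_upstream = list(s = ifelse(plus, gs - flankWindow, ge + 1),
                                 e = ifelse(plus, gs - 1, ge + flankWindow)),
    within_100kb_downstream = list(s = ifelse(plus, ge + 1, gs - flankWindow),
                                   e = ifelse(plus, ge + flankWindow, gs - 1)),
    stop("unknown category ", category))
  s <- pmax(lim$s, 1)
  e <- pmax(lim$e, s - 1) # clipped-away windows collapse to width 0
  IRanges(s, e)
}

#' Categorise peaks relative to gene models
#'
#' Assigns each peak exactly one location category by testing, in fixed
#' precedence order, for at least one base of overlap with strand-aware
#' gene windows: `intragenic` (gene body, TSS to transcript end),
#' `promoter_5kb` (5 kb upstream of a TSS), `downstream_5kb` (5 kb
#' downstream of the transcript end), `within_100kb_upstream` /
#' `within_100kb_downstream` (up to 100 kb from the 5' / 3' gene end), and
#' `gene_desert` (more than 100 kb from any gene). When several genes
#' qualify for the winning category, the gene whose TSS is nearest the
#' peak midpoint is assigned (ties toward the smaller TSS coordinate).
#'
#' @param peaks A `GRanges` of peaks.
#' @param genes A stranded gene `GRanges` (see [readGeneTable()]).
#' @param promoterWindow Promoter / downstream window size in bases
#'   (default 5000).
#' @param flankWindow Distal flank size in bases (default 100000).
#' @return A data frame with one row per peak: `category`, `gene` (NA for
#'   gene deserts) and `tssDistance` (signed, strand-aware; NA for gene
#'   deserts).
#' @export
categorizePeaks <- function(peaks, genes, promoterWindow = 5000,
                            flankWindow = 100000) {
  n <- length(peaks)
  res <- data.frame(category = rep("gene_desert", n),
                    gene = rep(NA_character_, n),
                    tssDistance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (length(genes) == 0L) {
    warning("empty gene list: all peaks categorised as gene_desert")
    res$category <- factor(res$category, levels = categoryLevels)
    return(res)
  }
  genes <- addTssTes(genes)
  mid <- floor((start(peaks) + end(peaks)) / 2)
  unassigned <- rep(TRUE, n)
  for (cat in setdiff(categoryLevels, "gene_desert")) {
    if (!any(unassigned)) break
    win <- GRanges(seqnames(genes),
                   categoryWindows(genes, cat, promoterWindow, flankWindow))
    keepWin <- width(win) >= 1
    hits <- findOverlaps(peaks, win[keepWin], ignore.strand = TRUE)
    geneIdx <- which(keepWin)[subjectHits(hits)]
    q <- queryHits(hits)
    use <- unassigned[q]
    if (!any(use)) next
    q <- q[use]; geneIdx <- geneIdx[use]
    # nearest qualifying gene by |midpoint - TSS|, ties toward smaller TSS
    dd <- abs(mid[q] - mcols(genes)$tss[geneIdx])
    o <- order(q, dd, mcols(genes)$tss[geneIdx], geneIdx)
    first <- !duplicated(q[o])
    pick <- o[first]
    pq <- q[pick]; pg <- geneIdx[pick]
    res$category[pq] <- cat
    res$gene[pq] <- mcols(genes)$name[pg]
    plus <- as.character(strand(genes))[pg] == "+"
    res$tssDistance[pq] <- ifelse(plus, mid[pq] - mcols(genes)$tss[pg],
                                  mcols(genes)$tss[pg] - mid[pq])
    unassigned[pq] <- FALSE
  }
  res$category <- factor(res$category, levels = categoryLevels)
  res
}

#' Category fractions over a peak set
#'
#' Fractions of peaks in each of the six location categories (summing to
#' 1), plus the combined fraction within 100 kb of a gene (everything but
#' gene deserts).
#'
#' @inheritParams categorizePeaks
#' @return A list with `fractions` (named numeric over the six
#'   categories), `counts`, and `within100kb` (scalar fraction).
#' @export
categoryFractions <- function(peaks, genes, promoterWindow = 5000,
                              flankWindow = 100000) {
  if (length(peaks) == 0L) stop("empty peak list")
  ann <- categorizePeaks(peaks, genes, promoterWindow, flankWindow)
  counts <- table(ann$category)
  fr <- as.numeric(counts) / length(peaks)
  names(fr) <- names(counts)
  list(fractions = fr, counts = counts,
       within100kb = 1 - fr[["gene_desert"]])
}

#' Distance profile of peaks around transcription start sites
#'
#' Each peak contributes the signed distance from its midpoint to the
#' nearest TSS, oriented by the gene's strand (negative = upstream of the
#' TSS, positive = downstream). Distances are histogrammed over
#' `[-window, +window]` in `bin`-sized bins; peaks beyond the window are
#' excluded from the histogram but counted in the total, and counts within
#' +/- 1 kb and +/- 500 b of a TSS are reported for all peaks.
#'
#' @param peaks A `GRanges` of peaks.
#' @param genes A stranded gene `GRanges`.
#' @param window Half-width of the histogram range (multiple of `bin`).
#' @param bin Bin width in bases.
#' @return A list: `histogram` (data frame with `lower`, `upper`, `mid`,
#'   `count`), `distances` (per-peak signed distance), `nTotal`,
#'   `nWithin1kb`, `nWithin500`, `pctWithin1kb`, `pctWithin500`.
#' @export
tssProfile <- function(peaks, genes, window = 10000, bin = 500) {
  if (window %% bin != 0) stop("window must be a multiple of bin")
  if (length(genes) == 0L) stop("no genes supplied")
  genes <- addTssTes(genes)
  mid <- floor((start(peaks) + end(peaks)) / 2)
  np <- nearestPoint(as.character(seqnames(peaks)), mid,
                     as.character(seqnames(genes)), mcols(genes)$tss)
  plus <- as.character(strand(genes))[np$index] == "+"
  dist <- ifelse(plus, np$distance, -np$distance)
  breaks <- seq(-window, window, by = bin)
  inWin <- dist >= -window & dist <= window
  h <- hist(dist[inWin], breaks = breaks, plot = FALSE, right = FALSE)
  histogram <- data.frame(lower = head(breaks, -1), upper = tail(breaks, -1),
                          mid = h$mids, count = h$counts)
  n1k <- sum(abs(dist) <= 1000)
  n500 <- sum(abs(dist) <= 500)
  list(histogram = histogram, distances = dist, nTotal = length(peaks),
       nWithin1kb = n1k, nWithin500 = n500,
       pctWithin1kb = 100 * n1k / length(peaks),
       pctWithin500 = 100 * n500 / length(peaks))
}

#' Per-chromosome peak counts, densities and length correlation
#'
#' Counts peaks per chromosome, computes density (count per base) and the
#' Pearson correlation between chromosome length and peak count, which is
#' near 1 when occupancy is proportional to chromosome length.
#'
#' @param peaks A `GRanges` of peaks.
#' @param chromSizes Named chromosome lengths.
#' @return A list with `table` (chrom, length, count, density) and `r`
#'   (Pearson correlation; NA with fewer than 3 chromosomes).
#' @export
chromosomeDensity <- function(peaks, chromSizes) {
  chroms <- names(chromSizes)
  cnt <- vapply(chroms, function(ch)
    sum(as.character(seqnames(peaks)) == ch), 0L)
  tab <- data.frame(chrom = chroms, length = unname(chromSizes),
                    count = unname(cnt),
                    density = unname(cnt / chromSizes))
  r <- if (length(chroms) >= 3L) {
    if (stats::sd(tab$length) == 0 || stats::sd(tab$count) == 0) NA_real_
    else cor(tab$length, tab$count)
  } else NA_real_
  list(table = tab, r = r)
}
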