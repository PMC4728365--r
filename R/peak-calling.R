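#' CallerParams: shared peak-caller parameters
#'
#' @slot fragmentShift Estimated fragment length d in bases (tags are
#'   shifted by d/2 toward their 3' end, or extended to d, depending on
#'   the caller).
#' @slot window Sliding-window width in bases for the Poisson and
#'   threshold callers.
#' @slot transitionWindow Net-count window width in bases for the
#'   strand-transition caller.
#' @slot pvalueCutoff Poisson upper-tail significance cutoff.
#' @slot foldCutoff Minimum fold enrichment E over the depth-scaled
#'   control.
#' @slot minTags Minimum tag count R supporting a strand-transition
#'   candidate.
#' @slot minRun Minimum run length m, in bases, above threshold for the
#'   coverage-threshold caller.
#' @export
setClass("CallerParams",
  representation(fragmentShift = "numeric", window = "numeric",
                 transitionWindow = "numeric", pvalueCutoff = "numeric",
                 foldCutoff = "numeric", minTags = "numeric",
                 minRun = "numeric"))

setValidity("CallerParams", function(object) {
  v <- c(object@fragmentShift, object@window, object@transitionWindow,
         object@foldCutoff, object@minTags, object@minRun)
  if (any(v <= 0)) return("all parameters must be positive")
  if (object@pvalueCutoff <= 0 || object@pvalueCutoff >= 1)
    return("pvalueCutoff must lie in (0, 1)")
  TRUE
})

#' Construct caller parameters
#'
#' Defaults follow the published defaults of the tools the three callers
#' are modelled on: 300 bp windows for Poisson/threshold calling, 20 bp
#' net-count granularity for the strand-transition caller, Poisson cutoff
#' 1e-5, fold cutoff 2, at least 10 supporting tags and 50 bp minimum
#' run length. The fragment shift default of 150 bp is a fallback; in the
#' pipeline it is replaced by [estimateFragmentShift()].
#'
#' @param fragmentShift,window,transitionWindow,pvalueCutoff,foldCutoff,minTags,minRun
#'   See [CallerParams-class].
#' @return A [CallerParams-class] object.
#' @export
callerParams <- function(fragmentShift = 150, window = 300,
                         transitionWindow = 20, pvalueCutoff = 1e-5,
                         foldCutoff = 2, minTags = 10, minRun = 50) {
  new("CallerParams", fragmentShift = fragmentShift, window = window,
      transitionWindow = transitionWindow, pvalueCutoff = pvalueCutoff,
      foldCutoff = foldCutoff, minTags = minTags, minRun = minRun)
}

setMethod("show", "CallerParams", function(object) {
  cat("CallerParams: d =", object@fragmentShift, "| w =", object@window,
      "| wt =", object@transitionWindow, "| p <", object@pvalueCutoff,
      "| E =", object@foldCutoff, "| R =", object@minTags,
      "| m =", object@minRun, "\n")
})

# 5' end of each tag (start for +, end for -)
tagFivePrime <- function(tags) {
  ifelse(as.character(strand(tags)) == "+", start(tags), end(tags))
}

#' Estimate the fragment length by strand cross-correlation
#'
#' Computes the Pearson correlation between the density of forward-tag 5'
#' ends and the density of reverse-tag 5' ends shifted left by s, over a
#' grid of candidate shifts, and returns the shift that maximises it.
#' Because the forward 5' end marks a fragment's start and the reverse 5'
#' end marks its end, the optimal shift estimates the fragment length d.
#' Densities are counted in `binWidth`-base bins before correlating, which
#' sets the shift resolution and keeps single-base sparsity from drowning
#' the signal at realistic depths.
#'
#' @param tags Stranded tag `GRanges` (treatment sample).
#' @param chromSizes Named chromosome lengths.
#' @param maxShift Largest shift considered, in bases.
#' @param binWidth Density bin width in bases (default 5; also the shift
#'   resolution).
#' @return A list with `d` (the shift), `cor` (the correlation at `d`) and
#'   `lowCorrelation` (TRUE when the best correlation is below 0.1,
#'   indicating data with no strand structure). A warning is emitted in
#'   the low-correlation case.
#' @export
estimateFragmentShift <- function(tags, chromSizes, maxShift = 1000,
                                  binWidth = 5) {
  str <- as.character(strand(tags))
  if (!any(str == "+") || !any(str == "-"))
    stop("both strands must be represented to estimate the fragment shift")
  if (length(tags) < 1000)
    warning("fewer than 1000 tags; fragment-shift estimate may be unstable")
  p5 <- tagFivePrime(tags)
  chroms <- intersect(names(chromSizes), unique(as.character(seqnames(tags))))
  dens <- lapply(chroms, function(ch) {
    on <- as.character(seqnames(tags)) == ch
    L <- chromSizes[[ch]]
    nb <- ceiling(L / binWidth)
    bin <- pmin(pmax(ceiling(p5[on] / binWidth), 1L), nb)
    list(f = tabulate(bin[str[on] == "+"], nbins = nb),
         r = tabulate(bin[str[on] == "-"], nbins = nb))
  })
  corAt <- function(sb) { # shift in bins
    acc <- c(n = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0)
    for (d in dens) {
      nb <- length(d$f)
      if (sb >= nb) next
      x <- d$f[seq_len(nb - sb)]
      y <- d$r[seq.int(1L + sb, nb)]
      acc <- acc + c(length(x), sum(x), sum(y), sum(x * x), sum(y * y),
                     sum(x * y))
    }
    num <- acc["sxy"] - acc["sx"] * acc["sy"] / acc["n"]
    den <- sqrt((acc["sxx"] - acc["sx"]^2 / acc["n"]) *
                (acc["syy"] - acc["sy"]^2 / acc["n"]))
    if (!is.finite(den) || den == 0) 0 else unname(num / den)
  }
  grid <- seq(0L, floor(maxShift / binWidth))
  cc <- vapply(grid, corAt, 0)
  d <- grid[which.max(cc)] * binWidth
  low <- max(cc) < 0.1
  if (low)
    warning("strand cross-correlation below 0.1; fragment-shift estimate unreliable")
  list(d = d, cor = max(cc), lowCorrelation = low)
}

# shifted single-base positions (tag 5' moved d/2 toward the 3' end)
shiftedPositions <- function(tags, d, chromSizes) {
  str <- as.character(strand(tags))
  p <- tagFivePrime(tags) + ifelse(str == "+", 1, -1) * round(d / 2)
  L <- chromSizes[as.character(seqnames(tags))]
  pmin(pmax(p, 1), L)
}

# count sorted positions falling in [lo, hi] (vectorised over windows)
countInWindows <- function(sortedPos, lo, hi) {
  findInterval(hi, sortedPos) - findInterval(lo - 1L, sortedPos)
}

emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr)$caller <- character(0)
  mcols(gr)$score <- numeric(0)
  mcols(gr)$summit <- numeric(0)
  gr
}

#' Poisson sliding-window peak caller
#'
#' A simplified model-based caller: tags are shifted by half the fragment
#' length toward their 3' end, counted in sliding windows of width `window`
#' (step `window/2`), and a window is called significant when its count
#' exceeds a local Poisson background at `pvalueCutoff`. The local rate is
#' the maximum of the genome-wide rate and rates computed from control tag
#' counts in 5 kb and 10 kb windows centred on the window, all scaled by
#' the treatment/control depth ratio; the local windows protect against
#' copy-number artefacts present in both samples. Overlapping significant
#' windows are merged into peaks.
#'
#' @param treatment,control Stranded tag `GRanges`.
#' @param chromSizes Named chromosome lengths.
#' @param params A [CallerParams-class] object.
#' @return A sorted `GRanges` of peaks with metadata columns `caller`
#'   (`"poisson"`), `score` (-log10 of the best window p-value) and
#'   `summit` (position of maximum shifted-tag coverage).
#' @export
callPeaksPoisson <- function(treatment, control, chromSizes,
                             params = callerParams()) {
  if (length(control) == 0L) stop("control tag set must be non-empty")
  if (length(treatment) == 0L) return(emptyPeaks())
  w <- params@window
  d <- params@fragmentShift
  ratio <- length(treatment) / length(control)
  genomeLen <- sum(chromSizes)
  tPos <- shiftedPositions(treatment, d, chromSizes)
  cPos <- shiftedPositions(control, d, chromSizes)
  tChr <- as.character(seqnames(treatment))
  cChr <- as.character(seqnames(control))
  lambdaBg <- length(control) * ratio * w / genomeLen
  out <- list()
  for (ch in names(chromSizes)) {
    L <- chromSizes[[ch]]
    if (L <= 0) stop("zero-length chromosome: ", ch)
    tp <- sort(tPos[tChr == ch])
    if (length(tp) == 0L) next
    cp <- sort(cPos[cChr == ch])
    starts <- seq(1, L, by = max(1, floor(w / 2)))
    ends <- pmin(starts + w - 1, L)
    cnt <- countInWindows(tp, starts, ends)
    centers <- (starts + ends) / 2
    c5 <- countInWindows(cp, pmax(centers - 2500, 1), pmin(centers + 2499, L))
    c10 <- countInWindows(cp, pmax(centers - 5000, 1), pmin(centers + 4999, L))
    lambda <- pmax(lambdaBg, c5 * ratio * w / 5000, c10 * ratio * w / 10000)
    pv <- ppois(cnt - 1, lambda, lower.tail = FALSE)
    sig <- which(pv < params@pvalueCutoff & cnt > 0)
    if (length(sig) == 0L) next
    # merge overlapping/adjacent significant windows into peak regions
    grp <- cumsum(c(TRUE, starts[sig][-1] > ends[sig][-length(sig)] + 1))
    covRle <- shiftedTagCoverage(treatment, tChr == ch, d, L)
    for (g in unique(grp)) {
      win <- sig[grp == g]
      ps <- min(starts[win]); pe <- max(ends[win])
      score <- max(-log10(pmax(pv[win], .Machine$double.xmin)))
      v <- as.numeric(S4Vectors::window(covRle, ps, pe))
      summit <- ps + which.max(v) - 1L
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = ps, end = pe,
                                            score = score, summit = summit)
    }
  }
  peaksFromFrames(out, "poisson")
}

# coverage Rle of tag intervals shifted d/2 toward 3', one chromosome
shiftedTagCoverage <- function(tags, sel, d, L) {
  tg <- tags[sel]
  if (length(tg) == 0L) return(Rle(0, L))
  sh <- ifelse(as.character(strand(tg)) == "+", 1, -1) * round(d / 2)
  s <- pmin(pmax(start(tg) + sh, 1), L)
  e <- pmin(pmax(end(tg) + sh, 1), L)
  coverage(IRanges(s, e), width = L)
}

peaksFromFrames <- function(frames, caller) {
  if (length(frames) == 0L) return(emptyPeaks())
  df <- do.call(rbind, frames)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$caller <- caller
  mcols(gr)$score <- df$score
  mcols(gr)$summit <- df$summit
  sort(gr, ignore.strand = TRUE)
}

#' Strand-transition peak caller
#'
#' Exploits the strand asymmetry of ChIP fragments around a protein
#' binding site: forward tags accumulate upstream and reverse tags
#' downstream of the true site. Net counts (forward minus reverse) are
#' computed in `transitionWindow`-wide bins and each sign transition from
#' positive to negative between successive tag-bearing bins yields a
#' candidate site at the midpoint between the two bins. A candidate is
#' retained when at least `minTags` treatment tags fall within +/- flank of
#' it and the count is at least `foldCutoff` times the depth-scaled control
#' expectation, where flank = max(transitionWindow, fragmentShift/2) so the
#' counting region scales with the sonication fragment size. Candidates
#' closer than `transitionWindow` merge (keeping the one with more tags)
#' and remaining overlaps are resolved toward the stronger candidate.
#'
#' @inheritParams callPeaksPoisson
#' @return A sorted `GRanges` of peaks (`caller = "strand_transition"`,
#'   `score` = fold enrichment over the scaled control, `summit` = the
#'   transition position).
#' @export
callPeaksStrandTransition <- function(treatment, control, chromSizes,
                                      params = callerParams()) {
  if (length(treatment) == 0L) return(emptyPeaks())
  w <- params@transitionWindow
  flank <- max(w, round(params@fragmentShift / 2))
  ratio <- if (length(control) > 0) length(treatment) / length(control) else 1
  genomeLen <- sum(chromSizes)
  p5 <- tagFivePrime(treatment)
  str <- as.character(strand(treatment))
  tChr <- as.character(seqnames(treatment))
  cp5 <- if (length(control)) tagFivePrime(control) else numeric(0)
  cChr <- if (length(control)) as.character(seqnames(control)) else character(0)
  out <- list()
  for (ch in names(chromSizes)) {
    L <- chromSizes[[ch]]
    on <- tChr == ch
    if (!any(on)) next
    nw <- ceiling(L / w)
    bin <- pmin(pmax(ceiling(p5[on] / w), 1L), nw)
    fwd <- tabulate(bin[str[on] == "+"], nbins = nw)
    rev <- tabulate(bin[str[on] == "-"], nbins = nw)
    net <- fwd - rev
    # windows with tags but zero net carry no strand direction; skip them
    # (as well as empty windows) when pairing consecutive windows
    nz <- which(net != 0)
    if (length(nz) < 2L) next
    prev <- nz[-length(nz)]
    nxt <- nz[-1L]
    trans <- which(net[prev] > 0 & net[nxt] < 0)
    if (length(trans) == 0L) next
    tpos <- floor((prev[trans] * w + (nxt[trans] - 1L) * w + 1) / 2)
    tpF <- sort(p5[on][str[on] == "+"])
    tpR <- sort(p5[on][str[on] == "-"])
    lo <- pmax(tpos - flank, 1); hi <- pmin(tpos + flank, L)
    cntF <- countInWindows(tpF, lo, hi)
    cntR <- countInWindows(tpR, lo, hi)
    cnt <- cntF + cntR
    # local control rate estimated over a window wide enough for the
    # (sparse) control to carry signal, then rescaled to the flank width;
    # a raw count in the flank window alone would be dominated by Poisson
    # noise once multiplied by the depth ratio
    ctlWin <- max(flank, 2500)
    ctl <- if (length(cp5)) {
      cs <- sort(cp5[cChr == ch])
      countInWindows(cs, pmax(tpos - ctlWin, 1), pmin(tpos + ctlWin, L))
    } else rep(0, length(tpos))
    ctlEst <- ctl * (2 * flank + 1) / (2 * ctlWin + 1) * ratio
    expBg <- length(cp5) * ratio * (2 * flank + 1) / genomeLen
    fold <- cnt / pmax(ctlEst, expBg, 1e-9)
    keep <- cnt >= params@minTags & fold >= params@foldCutoff
    if (!any(keep)) next
    cand <- data.frame(pos = tpos[keep], cnt = cnt[keep],
                       bal = pmin(cntF, cntR)[keep], fold = fold[keep])
    # merge candidates closer than w, keeping the higher-tag one
    cand <- cand[order(cand$pos), , drop = FALSE]
    repeat {
      close <- which(diff(cand$pos) < w)
      if (length(close) == 0L) break
      i <- close[1L]
      drop <- if (cand$cnt[i] >= cand$cnt[i + 1L]) i + 1L else i
      cand <- cand[-drop, , drop = FALSE]
    }
    # resolve residual overlaps of the +/- flank intervals; prefer the
    # candidate with the stronger bidirectional (min-strand) support, as a
    # true site has tags on both sides, then the higher total
    cand <- cand[order(-cand$bal, -cand$cnt, cand$pos), , drop = FALSE]
    acc <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (all(abs(cand$pos[acc] - cand$pos[i]) > 2 * flank))
        acc <- c(acc, i)
    }
    cand <- cand[sort(acc), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = max(cand$pos[i] - flank, 1),
        end = min(cand$pos[i] + flank - 1, L),
        score = cand$fold[i], summit = cand$pos[i])
    }
  }
  peaksFromFrames(out, "strand_transition")
}

#' Coverage-threshold peak caller
#'
#' A deterministic surrogate for manual inspection of pileups: tags are
#' extended to the fragment length from their 5' end, and maximal runs of
#' at least `minRun` consecutive bases whose extended-tag coverage reaches
#' `foldCutoff` times the genome-mean coverage become peaks, provided the
#' depth-scaled treatment/control coverage ratio over the run also reaches
#' `foldCutoff`. Sparse control coverage is floored at the control
#' genome-mean so the ratio is always defined.
#'
#' @inheritParams callPeaksPoisson
#' @return A sorted `GRanges` of peaks (`caller = "threshold"`, `score` =
#'   mean run coverage over genome-mean coverage, `summit` = position of
#'   maximum coverage in the run).
#' @export
callPeaksThreshold <- function(treatment, control, chromSizes,
                               params = callerParams()) {
  if (length(treatment) == 0L) return(emptyPeaks())
  d <- params@fragmentShift
  ratio <- if (length(control) > 0) length(treatment) / length(control) else 1
  genomeLen <- sum(chromSizes)
  tChr <- as.character(seqnames(treatment))
  cChr <- if (length(control)) as.character(seqnames(control)) else character(0)
  genomeMean <- length(treatment) * d / genomeLen
  ctrlMean <- if (length(control)) length(control) * d / genomeLen else 0
  thresh <- params@foldCutoff * genomeMean
  out <- list()
  for (ch in names(chromSizes)) {
    L <- chromSizes[[ch]]
    cov <- extendedTagCoverage(treatment, tChr == ch, d, L)
    ctlCov <- extendedTagCoverage(control, cChr == ch, d, L)
    runs <- IRanges::slice(cov, lower = thresh, includeLower = TRUE)
    runs <- runs[BiocGenerics::width(runs) >= params@minRun]
    if (length(runs) == 0L) next
    for (i in seq_along(runs)) {
      s <- start(runs)[i]; e <- end(runs)[i]
      v <- as.numeric(S4Vectors::window(cov, s, e))
      cv <- as.numeric(S4Vectors::window(ctlCov, s, e))
      ctrlRun <- max(mean(cv), ctrlMean) * ratio
      if (mean(v) / max(ctrlRun, 1e-9) < params@foldCutoff) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, score = mean(v) / genomeMean,
        summit = s + which.max(v) - 1L)
    }
  }
  peaksFromFrames(out, "threshold")
}

# coverage Rle of tags extended to length d from their 5' end
extendedTagCoverage <- function(tags, sel, d, L) {
  tg <- tags[sel]
  if (length(tg) == 0L) return(Rle(0, L))
  plus <- as.character(strand(tg)) == "+"
  s <- ifelse(plus, start(tg), end(tg) - d + 1)
  e <- ifelse(plus, start(tg) + d - 1, end(tg))
  coverage(IRanges(pmax(s, 1), pmin(e, L)), width = L)
}
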