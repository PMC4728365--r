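#' Bidirectional coincidence between peaks and a feature track
#'
#' A peak coincides with the track when it shares at least one base with
#' any track interval; a peak overlapping several track intervals counts
#' once (the reported statistic is peak-level, mirroring percentages of
#' peaks). The converse direction (track features overlapped by at least
#' one peak) is computed the same way, and the track's base coverage as a
#' fraction of the genome is reported so observed coincidence can be
#' compared with the genomic expectation.
#'
#' @param peaks A `GRanges` of peaks (non-empty).
#' @param track A `GRanges` of feature intervals.
#' @param genomeLength Total genome length in bases.
#' @param trackName Feature label carried into the result.
#' @return A one-row data frame: `track`, `nPeaks`, `nOverlapping`,
#'   `fractionPeaks`, `nFeatures`, `nFeaturesOverlapping`,
#'   `fractionFeatures`, `genomeFractionTrack`.
#' @examples
#' pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), width = 100))
#' tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 120))
#' peakTrackCoincidence(pk, tr, 1e4, "CpG")
#' @export
peakTrackCoincidence <- function(peaks, track, genomeLength,
                                 trackName = "track") {
  if (length(peaks) == 0L) stop("empty peak list")
  trackCov <- sum(width(reduce(track, ignore.strand = TRUE)))
  if (genomeLength < trackCov)
    stop("genomeLength smaller than track coverage")
  if (length(track) == 0L)
    warning("empty track '", trackName, "': fractions are 0")
  nOv <- sum(countOverlaps(peaks, track, ignore.strand = TRUE) > 0)
  nFt <- sum(countOverlaps(track, peaks, ignore.strand = TRUE) > 0)
  data.frame(track = trackName,
             nPeaks = length(peaks), nOverlapping = nOv,
             fractionPeaks = nOv / length(peaks),
             nFeatures = length(track), nFeaturesOverlapping = nFt,
             fractionFeatures = if (length(track)) nFt / length(track) else 0,
             genomeFractionTrack = trackCov / genomeLength,
             stringsAsFactors = FALSE)
}

#' Compare coincidence between two conditions
#'
#' Fold change and difference of the peak-level coincidence fraction for
#' the same feature track measured in two conditions (e.g. untreated
#' versus ligand-treated).
#'
#' @param resultA,resultB One-row data frames from
#'   [peakTrackCoincidence()] for the same track.
#' @return A one-row data frame: `track`, `fractionA`, `fractionB`,
#'   `fold` (A/B; NA with `foldUndefined = TRUE` when B's fraction is 0)
#'   and `difference` (A - B).
#' @export
conditionCompare <- function(resultA, resultB) {
  if (resultA$track != resultB$track)
    stop("track names differ: ", resultA$track, " vs ", resultB$track)
  fa <- resultA$fractionPeaks
  fb <- resultB$fractionPeaks
  data.frame(track = resultA$track, fractionA = fa, fractionB = fb,
             fold = if (fb > 0) fa / fb else NA_real_,
             foldUndefined = fb == 0,
             difference = fa - fb, stringsAsFactors = FALSE)
}

#' Over/under-representation of a track in a peak set
#'
#' Ratio of the observed peak coincidence fraction to the track's genomic
#' coverage fraction: above 1 the feature is over-represented among
#' peaks, below 1 under-represented (e.g. CpG islands cover roughly 1.5%
#' of the human genome, so a 4.6% peak coincidence is a ~3-fold
#' over-representation).
#'
#' @param result A one-row data frame from [peakTrackCoincidence()].
#' @return A list with `ratio` and `direction`
#'   (`"over-represented"`, `"under-represented"` or `"neutral"`).
#' @export
enrichmentVsGenome <- function(result) {
  if (result$genomeFractionTrack <= 0)
    stop("track covers no genomic bases; ratio undefined")
  ratio <- result$fractionPeaks / result$genomeFractionTrack
  list(ratio = ratio,
       direction = if (ratio > 1) "over-represented"
                   else if (ratio < 1) "under-represented" else "neutral")
}
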