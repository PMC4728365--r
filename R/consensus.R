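#' ConsensusSet: clustered peaks from multiple callers
#'
#' The result of single-linkage clustering of the peak sets produced by
#' independent callers. Each cluster is represented by the union span of
#' its mutually overlapping member peaks, together with the set of callers
#' supporting it.
#'
#' @slot peaks A `GRanges` with metadata columns `support` (comma-joined
#'   caller labels) and `nSupport` (integer, number of supporting callers).
#' @slot callers Character vector of all caller labels that contributed.
#' @export
setClass("ConsensusSet",
  representation(peaks = "GRanges", callers = "character"))

setValidity("ConsensusSet", function(object) {
  mc <- mcols(object@peaks)
  if (is.null(mc$support) || is.null(mc$nSupport))
    return("peaks must carry 'support' and 'nSupport' metadata columns")
  ns <- lengths(strsplit(mc$support, ",", fixed = TRUE))
  if (length(ns) && any(ns != mc$nSupport))
    return("nSupport must equal the number of supporting callers")
  if (length(mc$nSupport) && any(mc$nSupport < 1))
    return("every cluster needs at least one supporting caller")
  TRUE
})

setMethod("show", "ConsensusSet", function(object) {
  ns <- mcols(object@peaks)$nSupport
  cat("ConsensusSet with", length(object@peaks), "clusters from callers:",
      paste(object@callers, collapse = ", "), "\n")
  if (length(ns))
    cat("  support 1/2/3:", sum(ns == 1), "/", sum(ns == 2), "/",
        sum(ns >= 3), "\n")
})

#' @describeIn ConsensusSet-class The cluster `GRanges` (accessor).
#' @param x A `ConsensusSet`.
#' @export
consensusPeaks <- function(x) x@peaks

#' @describeIn ConsensusSet-class Caller labels (accessor).
#' @export
callerLabels <- function(x) x@callers

#' Cluster peak sets from independent callers
#'
#' Single-linkage clustering across callers: any two peaks sharing at
#' least one base belong to the same cluster, and membership is closed
#' transitively, so a chain of pairwise-overlapping peaks forms one
#' cluster. Each cluster's interval is the union span of its members and
#' its support records the contributing callers. Every input peak belongs
#' to exactly one cluster.
#'
#' @param peaksets Named list of `GRanges`, one per caller, each
#'   internally non-overlapping.
#' @return A [ConsensusSet-class].
#' @export
clusterPeaks <- function(peaksets) {
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets))))
    stop("peaksets must be a named list (one entry per caller)")
  callers <- names(peaksets)
  all <- unlist(GenomicRanges::GRangesList(lapply(peaksets, function(g) {
    mcols(g) <- NULL
    strand(g) <- "*"
    g
  })), use.names = FALSE)
  if (length(all) == 0L) {
    pk <- GRanges()
    mcols(pk)$support <- character(0)
    mcols(pk)$nSupport <- integer(0)
    return(new("ConsensusSet", peaks = pk, callers = callers))
  }
  # min.gapwidth = 0: only ranges sharing >= 1 base merge (book-ended
  # peaks stay separate); reduce performs the transitive closure
  clusters <- reduce(all, min.gapwidth = 0L, ignore.strand = TRUE)
  support <- matrix(FALSE, length(clusters), length(callers),
                    dimnames = list(NULL, callers))
  for (cl in callers) {
    hits <- findOverlaps(clusters, peaksets[[cl]], ignore.strand = TRUE)
    support[unique(queryHits(hits)), cl] <- TRUE
  }
  mcols(clusters)$support <- apply(support, 1L, function(r)
    paste(callers[r], collapse = ","))
  mcols(clusters)$nSupport <- as.integer(rowSums(support))
  new("ConsensusSet", peaks = clusters, callers = callers)
}

#' @rdname selectConsensus
#' @export
setGeneric("selectConsensus", function(x, minSupport = 2L)
  standardGeneric("selectConsensus"))

#' Filter a consensus set by caller support
#'
#' `minSupport = 1` returns the merged set, `2` the at-least-two-of-three
#' set used for the main analyses, `3` the stringent set found by all
#' callers. The sets are nested: each tier's coverage contains the next.
#'
#' @param x A [ConsensusSet-class].
#' @param minSupport Minimum number of supporting callers (1-3).
#' @return A `ConsensusSet` containing only clusters with at least
#'   `minSupport` supporting callers.
#' @export
setMethod("selectConsensus", "ConsensusSet", function(x, minSupport = 2L) {
  if (minSupport < 1 || minSupport > length(x@callers))
    stop("minSupport must lie between 1 and the number of callers")
  new("ConsensusSet",
      peaks = sort(x@peaks[mcols(x@peaks)$nSupport >= minSupport],
                   ignore.strand = TRUE),
      callers = x@callers)
})

#' @rdname vennCounts
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' Venn partition of a three-caller consensus set
#'
#' Tabulates clusters by their exact support set: the seven regions of the
#' three-set Venn diagram, plus per-caller totals. Region counts sum to
#' the number of clusters.
#'
#' @param x A [ConsensusSet-class] built from three callers.
#' @return A list with `regions` (named integer vector, keys are
#'   comma-joined support sets) and `totals` (per-caller cluster counts).
#' @export
setMethod("vennCounts", "ConsensusSet", function(x) {
  callers <- x@callers
  keys <- unlist(lapply(seq_along(callers), function(sz)
    utils::combn(callers, sz, paste, collapse = ",")))
  regions <- setNames(integer(length(keys)), keys)
  supp <- mcols(x@peaks)$support
  tab <- table(supp)
  regions[names(tab)] <- as.integer(tab)
  totals <- vapply(callers, function(cl)
    sum(vapply(strsplit(supp, ",", fixed = TRUE), function(s) cl %in% s,
               NA)), 0L)
  list(regions = regions, totals = totals)
})

#' Write a consensus tier as BED6 plus a Venn table
#' @param x A [ConsensusSet-class].
#' @param bedPath Output BED path (name = support set, score = nSupport).
#' @param vennPath Optional TSV path for the Venn region table.
#' @return `bedPath`, invisibly.
#' @export
writeConsensus <- function(x, bedPath, vennPath = NULL) {
  pk <- x@peaks
  gr <- pk
  mcols(gr) <- NULL
  mcols(gr)$name <- gsub(",", "+", mcols(pk)$support, fixed = TRUE)
  mcols(gr)$score <- mcols(pk)$nSupport
  writeBed(gr, bedPath)
  if (!is.null(vennPath)) {
    vc <- vennCounts(x)
    write.table(data.frame(region = names(vc$regions),
                           count = unname(vc$regions)),
                vennPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bedPath)
}
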