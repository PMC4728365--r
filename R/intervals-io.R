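#' @import methods
#' @importFrom stats ppois rnorm runif rpois cor phyper dhyper sd na.omit
#'   setNames
#' @importFrom graphics hist
#' @importFrom utils read.table write.table head tail
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue
#' @importFrom IRanges IRanges Views viewApply coverage
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce sort.GenomicRanges
#' @importFrom BiocGenerics sort "strand<-"
NULL

# Internal convention: all GRanges are 1-based closed (Bioconductor).
# BED files are 0-based half-open; conversion happens only in readers/writers.

#' Read genomic intervals from a BED3 or BED6 file
#'
#' Parses a tab-separated BED file into a `GRanges`. Coordinates are
#' converted from BED's 0-based half-open convention to the 1-based closed
#' convention used throughout the package. Strand is taken from column 6
#' when present (`bed6`), otherwise set to `*`.
#'
#' @param path Path to an uncompressed BED file.
#' @param format One of `"auto"`, `"bed3"`, `"bed6"`. With `"auto"` the
#'   format is inferred from the number of columns on the first line.
#' @return A `GRanges`, in file order, with `name` and `score` metadata
#'   columns when a BED6 file is read.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tpk1\t5\t+", "chr1\t400\t450\tpk2\t3\t-"), bed)
#' readBed(bed)
#' @export
readBed <- function(path, format = c("auto", "bed3", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L)
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", which(nf < 3L)[1L], ": fewer than 3 tab-separated fields")
  want6 <- switch(format, auto = all(nf >= 6L), bed3 = FALSE, bed6 = TRUE)
  if (want6 && any(nf < 6L))
    stop("line ", which(nf < 6L)[1L], ": bed6 requested but fewer than 6 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("line ", bad[1L], ": unparsable coordinate")
  bad <- which(e <= s | s < 0)
  if (length(bad))
    stop("line ", bad[1L], ": invalid interval (end <= start or negative start)")
  if (want6) {
    str <- vapply(fields, `[[`, "", 6L)
    if (!all(str %in% c("+", "-", ".")))
      stop("line ", which(!str %in% c("+", "-", "."))[1L], ": bad strand field")
    str[str == "."] <- "*"
    gr <- GRanges(chrom, IRanges(s + 1L, e), strand = str)
    mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
  } else {
    gr <- GRanges(chrom, IRanges(s + 1L, e))
  }
  gr
}

#' Write genomic intervals to a BED file
#'
#' Writes a `GRanges` as BED6 (or BED3 with `bed3 = TRUE`), converting back
#' to 0-based half-open coordinates. `name` and `score` metadata columns are
#' used when present; strand `*` is written as `.`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param bed3 Write only the first three columns.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, bed3 = FALSE) {
  chrom <- as.character(seqnames(gr))
  s <- start(gr) - 1L
  e <- end(gr)
  if (bed3) {
    df <- data.frame(chrom, s, e)
  } else {
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
      paste0("iv", seq_along(gr))
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    df <- data.frame(chrom, s, e, nm, sc, str)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome sizes file
#'
#' Two tab-separated columns: chromosome name and length in bases.
#'
#' @param path Path to the sizes file.
#' @return A named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("non-positive chromosome length")
  setNames(df$length, df$chrom)
}

#' Write a chromosome sizes file
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), unname(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene model table
#'
#' Six tab-separated columns: chrom, txStart, txEnd (0-based half-open),
#' strand (+/-), name, and an optional secondary id. The transcription
#' start site (TSS) is the 5' end in the gene's orientation and the
#' transcription end site (TES) the 3' end.
#'
#' @param path Path to the gene table.
#' @return A `GRanges` with strand, `name`, and computed `tss`/`tes`
#'   metadata columns (1-based positions).
#' @export
readGeneTable <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character"))[, 1:5]
  names(df) <- c("chrom", "start", "end", "strand", "name")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (any(df$end <= df$start))
    stop("gene with end <= start")
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
  mcols(gr)$name <- df$name
  addTssTes(gr)
}

# annotate tss/tes positions (1-based) onto a stranded gene GRanges
addTssTes <- function(genes) {
  plus <- as.character(strand(genes)) == "+"
  mcols(genes)$tss <- ifelse(plus, start(genes), end(genes))
  mcols(genes)$tes <- ifelse(plus, end(genes), start(genes))
  genes
}

#' Write a gene model table (inverse of [readGeneTable()])
#' @param genes Stranded `GRanges` with a `name` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  df <- data.frame(as.character(seqnames(genes)), start(genes) - 1L,
                   end(genes), as.character(strand(genes)),
                   mcols(genes)$name)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge genomic intervals
#'
#' Collapses a set of (possibly unsorted, possibly overlapping) intervals
#' into sorted, pairwise non-overlapping intervals. Two intervals merge
#' when separated by at most `gap` bases; with `gap = 0` book-ended
#' intervals (zero bases apart) merge, matching the default behaviour of
#' common interval-merge tools. Base coverage is preserved when `gap = 0`.
#'
#' @param gr A `GRanges`.
#' @param gap Maximum separation, in bases, for two intervals to merge.
#' @return A sorted, disjoint `GRanges`.
#' @export
mergeIntervals <- function(gr, gap = 0L) {
  stopifnot(gap >= 0)
  reduce(gr, min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' Find overlapping interval pairs between two sets
#'
#' Reports every pair `(i, j)` such that `a[i]` and `b[j]` are on the same
#' chromosome and share at least `minOverlap` bases. Strand is ignored.
#'
#' @param a,b `GRanges` objects.
#' @param minOverlap Minimum number of shared bases (default 1).
#' @return A two-column data frame (`query`, `subject`) of indices into
#'   `a` and `b`.
#' @export
overlapPairs <- function(a, b, minOverlap = 1L) {
  stopifnot(minOverlap >= 1)
  hits <- findOverlaps(a, b, minoverlap = minOverlap, ignore.strand = TRUE)
  data.frame(query = queryHits(hits), subject = subjectHits(hits))
}

#' Nearest point to a set of query positions
#'
#' For each query position, finds the point on the same chromosome that
#' minimises the absolute distance. Ties are broken toward the smaller
#' genomic coordinate, so results are reproducible.
#'
#' @param chrom,pos Character and numeric vectors: query chromosome and
#'   position (1-based) per query.
#' @param pointChrom,pointPos The candidate points.
#' @return A data frame with columns `index` (into the point vectors) and
#'   `distance` (signed, `pos - pointPos`).
#' @export
nearestPoint <- function(chrom, pos, pointChrom, pointPos) {
  stopifnot(length(chrom) == length(pos),
            length(pointChrom) == length(pointPos))
  idx <- integer(length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    pi <- which(pointChrom == ch)
    if (length(pi) == 0L)
      stop("no point on chromosome ", ch)
    # sort points; ties toward smaller coordinate resolved by taking the
    # left candidate when distances are equal
    o <- order(pointPos[pi], pi)
    ps <- pointPos[pi][o]
    right <- findInterval(pos[qi], ps) # index of rightmost point <= pos
    left <- pmax(right, 1L)
    nxt <- pmin(right + 1L, length(ps))
    dl <- abs(pos[qi] - ps[left])
    dn <- abs(pos[qi] - ps[nxt])
    useLeft <- right >= 1L & (dl <= dn | nxt == left)
    pick <- ifelse(useLeft, left, nxt)
    idx[qi] <- pi[o][pick]
  }
  data.frame(index = idx, distance = pos - pointPos[idx])
}

#' Read a multi-record FASTA file
#' @param path Path to an uncompressed FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write sequences as FASTA
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
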