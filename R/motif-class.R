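#' MotifMatrix: a position weight matrix with background
#'
#' Holds per-column base probabilities for a transcription-factor binding
#' motif, the background base frequencies used for log-odds scoring, and
#' the pseudocount added to each cell before scoring.
#'
#' @slot name Motif identifier.
#' @slot matrix Numeric matrix, width x 4, columns named A, C, G, T; each
#'   row sums to 1.
#' @slot background Numeric length-4 probability vector (A, C, G, T).
#' @slot pseudocount Probability mass added per matrix cell at scoring time.
#' @export
setClass("MotifMatrix",
  representation(name = "character", matrix = "matrix",
                 background = "numeric", pseudocount = "numeric"),
  prototype(background = rep(0.25, 4), pseudocount = 1e-4))

setValidity("MotifMatrix", function(object) {
  m <- object@matrix
  if (ncol(m) != 4L) return("matrix must have 4 columns (A, C, G, T)")
  if (nrow(m) < 4L) return("motif width must be >= 4")
  if (any(m < 0)) return("negative probabilities")
  if (any(abs(rowSums(m) - 1) > 1e-6)) return("matrix rows must sum to 1")
  if (length(object@background) != 4L) return("background must have length 4")
  if (abs(sum(object@background) - 1) > 1e-6) return("background must sum to 1")
  if (object@pseudocount < 0) return("negative pseudocount")
  TRUE
})

#' Construct a MotifMatrix
#' @param name Motif identifier.
#' @param matrix Width x 4 probability matrix (columns A, C, G, T).
#' @param background Background base frequencies (A, C, G, T).
#' @param pseudocount Pseudocount added per cell when scoring.
#' @return A [MotifMatrix-class] object.
#' @examples
#' m <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 6), ncol = 4, byrow = TRUE)
#' motifMatrix("polyA", m)
#' @export
motifMatrix <- function(name, matrix, background = rep(0.25, 4),
                        pseudocount = 1e-4) {
  colnames(matrix) <- c("A", "C", "G", "T")
  new("MotifMatrix", name = name, matrix = matrix,
      background = background, pseudocount = pseudocount)
}

#' @describeIn MotifMatrix-class Motif width in bases.
#' @param x A `MotifMatrix`.
#' @export
motifWidth <- function(x) nrow(x@matrix)

#' @describeIn MotifMatrix-class Motif name.
#' @export
motifName <- function(x) x@name

#' @describeIn MotifMatrix-class Consensus sequence (column-wise argmax).
#' @export
motifConsensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x@matrix, 1L, which.max)], collapse = "")
}

#' Reverse-complement a MotifMatrix
#' @param x A `MotifMatrix`.
#' @return A `MotifMatrix` describing the motif on the opposite strand.
#' @export
motifReverseComplement <- function(x) {
  m <- x@matrix[rev(seq_len(nrow(x@matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  bg <- x@background[c(4, 3, 2, 1)]
  motifMatrix(x@name, m, background = bg, pseudocount = x@pseudocount)
}

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix", object@name, "| width", motifWidth(object),
      "| consensus", motifConsensus(object), "\n")
})

#' Read motifs from a MEME minimal format file
#'
#' Parses MOTIF blocks with their letter-probability matrices. A
#' `Background letter frequencies` section, when present, supplies the
#' background; otherwise a uniform background is used (it can be replaced
#' later, e.g. by the scanned genome's base composition).
#'
#' @param path Path to a MEME minimal format file.
#' @param pseudocount Pseudocount stored on each returned motif.
#' @return A named list of [MotifMatrix-class] objects.
#' @export
readMeme <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
    freq <- as.numeric(toks[c(FALSE, TRUE)])
    names(freq) <- toks[c(TRUE, FALSE)]
    bg <- unname(freq[c("A", "C", "G", "T")])
  }
  starts <- grep("^MOTIF", lines)
  motifs <- list()
  for (s in starts) {
    nm <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines[seq(s, length(lines))])[1L]
    hdr <- s + hdr - 1L
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])
    w <- as.integer(w)
    rows <- lines[seq(hdr + 1L, hdr + w)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    if (ncol(m) != 4L) stop("motif ", nm, ": expected 4 columns")
    motifs[[nm]] <- motifMatrix(nm, m, background = bg,
                                pseudocount = pseudocount)
  }
  motifs
}

#' Write motifs in MEME minimal format
#' @param motifs A list of [MotifMatrix-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMeme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  bg <- motifs[[1L]]@background
  writeLines(c("Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3],
                       bg[4]), ""), con)
  for (mo in motifs) {
    writeLines(sprintf("MOTIF %s", mo@name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       motifWidth(mo)), con)
    writeLines(apply(mo@matrix, 1L, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}
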