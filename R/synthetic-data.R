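#' SimConfig: parameters of the synthetic ChIP-seq dataset generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' an i.i.d. genome, non-overlapping gene models, planted protein binding
#' sites producing strand-asymmetric tag pileups (forward tags upstream,
#' reverse tags downstream, as sonicated-fragment ends are sequenced),
#' uniform background tags, an input control with optional copy-number
#' segments affecting both samples, feature tracks with controlled
#' site-overlap rates, a CpG track covering ~1.5% of the genome, and
#' planted motif instances. Everything is deterministic under `seed`.
#'
#' @slot seed RNG seed.
#' @slot nChroms,chromLength Number of chromosomes and length of each, in
#'   bases.
#' @slot nGenes,nSites Total gene and planted-site counts.
#' @slot tagsPerSite Mean tag (fragment) count per planted site.
#' @slot backgroundRate Background tags per kilobase (per sample).
#' @slot controlRate Control tags per kilobase.
#' @slot fragmentRange Sonicated fragment length range in bases
#'   (default 500-1000, the conventional sonication range).
#' @slot readLength Tag length in bases (default 36).
#' @slot gc Genome GC content (default 0.41).
#' @slot siteJitterSd SD of the fragment-centre jitter around a site.
#' @slot motifPlantFraction Fraction of sites receiving a planted motif
#'   instance.
#' @slot cpgFraction Target CpG-island genome coverage (default 0.015).
#' @slot trackOverlapProbs Named per-track probabilities that a planted
#'   site carries the mark.
#' @slot cnvSegments Data frame (chrom, start, end, fold) of copy-number
#'   segments modulating background density in both samples.
#' @export
setClass("SimConfig",
  representation(seed = "numeric", nChroms = "numeric",
                 chromLength = "numeric", nGenes = "numeric",
                 nSites = "numeric", tagsPerSite = "numeric",
                 backgroundRate = "numeric", controlRate = "numeric",
                 fragmentRange = "numeric", readLength = "numeric",
                 gc = "numeric", siteJitterSd = "numeric",
                 motifPlantFraction = "numeric", cpgFraction = "numeric",
                 trackOverlapProbs = "numeric", cnvSegments = "data.frame"))

setValidity("SimConfig", function(object) {
  if (any(c(object@nChroms, object@chromLength, object@nGenes,
            object@nSites, object@tagsPerSite) < 0))
    return("counts must be non-negative")
  if (length(object@fragmentRange) != 2L ||
      object@fragmentRange[1L] > object@fragmentRange[2L])
    return("fragmentRange must be (min, max)")
  if (object@fragmentRange[1L] <= object@readLength)
    return("fragments must be longer than the read length")
  if (object@fragmentRange[2L] >= object@chromLength)
    return("fragments must be shorter than a chromosome")
  probs <- c(object@motifPlantFraction, object@cpgFraction, object@gc,
             object@trackOverlapProbs)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  TRUE
})

#' Construct a simulation configuration
#'
#' @param seed RNG seed (all generator functions derive their streams from
#'   it, so a config maps to one byte-identical dataset).
#' @param nChroms,chromLength,nGenes,nSites,tagsPerSite,backgroundRate,controlRate,fragmentRange,readLength,gc,siteJitterSd,motifPlantFraction,cpgFraction,trackOverlapProbs,cnvSegments
#'   See [SimConfig-class].
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1L, nChroms = 3, chromLength = 3e5,
                      nGenes = 45, nSites = 60, tagsPerSite = 60,
                      backgroundRate = 0.5, controlRate = 0.5,
                      fragmentRange = c(500, 1000), readLength = 36,
                      gc = 0.41, siteJitterSd = 50,
                      motifPlantFraction = 0.5, cpgFraction = 0.015,
                      trackOverlapProbs = c(H3K4me3 = 0.6, RNAPII = 0.5,
                                            FAIRE = 0.4),
                      cnvSegments = data.frame(chrom = character(0),
                                               start = numeric(0),
                                               end = numeric(0),
                                               fold = numeric(0))) {
  new("SimConfig", seed = seed, nChroms = nChroms,
      chromLength = chromLength, nGenes = nGenes, nSites = nSites,
      tagsPerSite = tagsPerSite, backgroundRate = backgroundRate,
      controlRate = controlRate, fragmentRange = fragmentRange,
      readLength = readLength, gc = gc, siteJitterSd = siteJitterSd,
      motifPlantFraction = motifPlantFraction, cpgFraction = cpgFraction,
      trackOverlapProbs = trackOverlapProbs, cnvSegments = cnvSegments)
}

#' Named simulation presets
#'
#' `"strong"`: high signal-to-noise study conditions — 60 planted sites
#' with a mean of 60 tags each over a 0.5 tags/kb background, fragments
#' drawn from the 500-1000 bp sonication range. `"short"`: the same but
#' with 140-160 bp fragments, the conventional easy case for
#' strand-shift-based callers.
#'
#' @param name `"strong"` or `"short"`.
#' @param seed RNG seed.
#' @param ... Overrides passed to [simConfig()].
#' @return A [SimConfig-class] object.
#' @export
simPreset <- function(name = c("strong", "short"), seed = 1L, ...) {
  name <- match.arg(name)
  switch(name,
    strong = simConfig(seed = seed, ...),
    short = simConfig(seed = seed, fragmentRange = c(140, 160), ...))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", object@nChroms, "x",
      object@chromLength, "bp |", object@nSites, "sites x",
      object@tagsPerSite, "tags | bg", object@backgroundRate,
      "/kb | fragments", paste(object@fragmentRange, collapse = "-"), "\n")
})

simChromSizes <- function(config) {
  setNames(rep(config@chromLength, config@nChroms),
           paste0("chr", seq_len(config@nChroms)))
}

# each generator op seeds its own offset stream from the config seed so
# every op is individually deterministic and composition stays so
opSeed <- function(config, offset) {
  set.seed((as.integer(config@seed) + offset) %% .Machine$integer.max)
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC content.
#'
#' @param config A [SimConfig-class].
#' @return A named [Biostrings::DNAStringSet] (chr1..chrN).
#' @export
generateGenome <- function(config) {
  opSeed(config, 11L)
  sizes <- simChromSizes(config)
  probs <- c(A = (1 - config@gc) / 2, C = config@gc / 2,
             G = config@gc / 2, T = (1 - config@gc) / 2)
  seqs <- Biostrings::DNAStringSet(vapply(sizes, function(L)
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = ""), ""))
  names(seqs) <- names(sizes)
  seqs
}

#' Plant binding sites
#'
#' Places `nSites` site positions uniformly over the chromosomes with a
#' minimum separation (3 kb) and an edge margin, so peaks from distinct
#' sites cannot merge.
#'
#' @param config A [SimConfig-class].
#' @return A `GRanges` of single-base site positions with a `site` id
#'   column.
#' @export
generateSites <- function(config) {
  opSeed(config, 23L)
  sizes <- simChromSizes(config)
  margin <- 3000
  minSep <- 3000
  perChrom <- diff(round(seq(0, config@nSites,
                             length.out = config@nChroms + 1L)))
  pos <- list()
  for (i in seq_along(sizes)) {
    k <- perChrom[i]
    if (k == 0L) next
    L <- sizes[[i]]
    p <- numeric(0)
    attempts <- 0L
    while (length(p) < k && attempts < 10000L) {
      cand <- round(runif(1, margin, L - margin))
      if (all(abs(cand - p) >= minSep)) p <- c(p, cand)
      attempts <- attempts + 1L
    }
    if (length(p) < k) stop("could not place sites with required separation")
    pos[[names(sizes)[i]]] <- sort(p)
  }
  p <- unlist(pos, use.names = FALSE)
  if (is.null(p)) p <- numeric(0)
  gr <- GRanges(factor(rep(names(pos), lengths(pos)),
                       levels = names(sizes)),
                IRanges(p, width = 1L))
  mcols(gr)$site <- if (length(gr)) paste0("site", seq_along(gr)) else
    character(0)
  gr
}

#' Generate gene models and feature tracks
#'
#' Genes are rejection-sampled non-overlapping bodies (2-20 kb, random
#' strand, at least one per chromosome). The CpG track places islands at
#' a subset of TSSs plus random background islands until the genome CpG
#' coverage is close to `cpgFraction` (~1.5%). Each mark track covers the
#' +/- 500 b neighbourhood of a planted site with its configured
#' `trackOverlapProbs` probability, plus random background intervals.
#'
#' @param config A [SimConfig-class].
#' @param sites A site `GRanges` from [generateSites()].
#' @return A list with `genes` (stranded `GRanges` with `name`, `tss`,
#'   `tes`) and `tracks` (named list of `GRanges`, including `CpG`).
#' @export
generateAnnotation <- function(config, sites) {
  opSeed(config, 37L)
  sizes <- simChromSizes(config)
  nG <- config@nGenes
  if (nG == 0L) {
    warning("zero genes requested: empty gene table")
    genes <- GRanges()
  } else {
    perChrom <- diff(round(seq(0, nG, length.out = config@nChroms + 1L)))
    perChrom <- pmax(perChrom, 1L)
    out <- list()
    for (i in seq_along(sizes)) {
      L <- sizes[[i]]
      placed <- IRanges()
      attempts <- 0L
      while (length(placed) < perChrom[i] && attempts < 20000L) {
        len <- round(runif(1, 2000, 20000))
        s <- round(runif(1, 1000, L - len - 1000))
        cand <- IRanges(s, s + len - 1L)
        if (length(placed) == 0L ||
            sum(countOverlaps(cand, placed)) == 0L)
          placed <- c(placed, cand)
        attempts <- attempts + 1L
      }
      if (length(placed) < perChrom[i])
        stop("could not place genes without overlap (density too high)")
      out[[names(sizes)[i]]] <- BiocGenerics::sort(placed)
    }
    genes <- GRanges(factor(rep(names(out), lengths(out)),
                            levels = names(sizes)),
                     unlist(IRanges::IRangesList(out), use.names = FALSE),
                     strand = sample(c("+", "-"), sum(lengths(out)),
                                     replace = TRUE))
    mcols(genes)$name <- paste0("gene", seq_along(genes))
    genes <- addTssTes(genes)
  }
  genomeLen <- sum(sizes)
  # CpG islands: TSS-associated islands first, then random background
  # islands until coverage reaches the target fraction; island placement
  # stops as soon as the target is met so the final coverage sits just
  # above cpgFraction
  tracks <- list()
  cpg <- GRanges()
  target <- config@cpgFraction * genomeLen
  if (length(genes)) {
    atTss <- which(runif(length(genes)) < 0.35)
    for (i in atTss) {
      if (sum(width(reduce(cpg))) >= 0.7 * target) break
      ctr <- mcols(genes)$tss[i]
      wd <- round(runif(1, 300, 900))
      ch <- as.character(seqnames(genes))[i]
      cpg <- c(cpg, GRanges(factor(ch, levels = names(sizes)),
                            IRanges(pmax(round(ctr - wd / 2), 1),
                                        pmin(round(ctr + wd / 2),
                                             sizes[[ch]]))))
    }
  }
  guard <- 0L
  while (sum(width(reduce(cpg))) < target && guard < 10000L) {
    ch <- sample(names(sizes), 1L)
    wd <- round(runif(1, 300, 900))
    s <- round(runif(1, 1, sizes[[ch]] - wd))
    cpg <- c(cpg, GRanges(factor(ch, levels = names(sizes)),
                          IRanges(s, s + wd - 1L)))
    guard <- guard + 1L
  }
  tracks$CpG <- BiocGenerics::sort(reduce(cpg))
  for (mark in names(config@trackOverlapProbs)) {
    p <- config@trackOverlapProbs[[mark]]
    covered <- if (length(sites))
      sites[runif(length(sites)) < p] else GRanges()
    gr <- if (length(covered))
      GRanges(seqnames(covered),
              IRanges(pmax(start(covered) - 500, 1),
                      pmin(start(covered) + 500,
                           sizes[as.character(seqnames(covered))])))
      else GRanges()
    nBg <- 30L
    bgCh <- sample(names(sizes), nBg, replace = TRUE)
    bgW <- round(runif(nBg, 500, 2000))
    bgS <- round(runif(nBg, 1, sizes[bgCh] - bgW))
    gr <- c(gr, GRanges(factor(bgCh, levels = names(sizes)),
                        IRanges(bgS, bgS + bgW - 1L)))
    tracks[[mark]] <- BiocGenerics::sort(reduce(gr))
  }
  list(genes = genes, tracks = tracks)
}

# uniform background tag positions honouring copy-number segments: base
# rate everywhere plus (fold - 1) extra density inside each segment
backgroundTags <- function(config, sizes, ratePerKb, seedOffset) {
  opSeed(config, seedOffset)
  rl <- config@readLength
  mk <- function(ch, n, lo, hi) {
    if (n == 0L) return(NULL)
    p5 <- round(runif(n, lo, hi))
    str <- sample(c("+", "-"), n, replace = TRUE)
    data.frame(chrom = ch, p5 = p5, strand = str)
  }
  out <- list()
  for (ch in names(sizes)) {
    L <- sizes[[ch]]
    n <- rpois(1, ratePerKb * L / 1000)
    out[[length(out) + 1L]] <- mk(ch, n, 1 + rl, L - rl)
  }
  cnv <- config@cnvSegments
  if (nrow(cnv)) {
    for (i in seq_len(nrow(cnv))) {
      segLen <- cnv$end[i] - cnv$start[i]
      extra <- rpois(1, (cnv$fold[i] - 1) * ratePerKb * segLen / 1000)
      out[[length(out) + 1L]] <- mk(cnv$chrom[i], extra,
                                    cnv$start[i] + 1, cnv$end[i])
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(GRanges())
  plus <- df$strand == "+"
  GRanges(factor(df$chrom, levels = names(sizes)),
          IRanges(ifelse(plus, df$p5, df$p5 - rl + 1L),
                  ifelse(plus, df$p5 + rl - 1L, df$p5)),
          strand = df$strand)
}

#' Simulate treatment and control tag sets
#'
#' Per planted site, a Poisson(`tagsPerSite`) number of fragments is
#' drawn; each fragment has length Uniform(`fragmentRange`), centre at the
#' site plus Normal(0, `siteJitterSd`) jitter, and is sequenced from one
#' randomly chosen end: a forward tag of `readLength` bases at the
#' fragment 5' start, or a reverse tag ending at the fragment 3' end —
#' producing the forward-upstream / reverse-downstream asymmetry real
#' ChIP-seq pileups show. Background tags are uniform on both strands at
#' `backgroundRate` per kb; the control contains only uniform background
#' at `controlRate` per kb. Copy-number segments multiply background
#' density in both samples.
#'
#' @param config A [SimConfig-class].
#' @param sites A site `GRanges` from [generateSites()].
#' @return A list with `treatment` and `control` tag `GRanges` (strand +/-)
#'   and `siteTagCounts` (tags drawn per site).
#' @export
simulateTags <- function(config, sites) {
  sizes <- simChromSizes(config)
  opSeed(config, 51L)
  rl <- config@readLength
  frames <- list()
  nTags <- integer(length(sites))
  for (i in seq_along(sites)) {
    n <- rpois(1, config@tagsPerSite)
    nTags[i] <- n
    if (n == 0L) next
    ch <- as.character(seqnames(sites))[i]
    L <- sizes[[ch]]
    fl <- round(runif(n, config@fragmentRange[1L], config@fragmentRange[2L]))
    ctr <- start(sites)[i] + round(rnorm(n, 0, config@siteJitterSd))
    fs <- pmax(round(ctr - fl / 2), 1)
    fe <- pmin(fs + fl - 1, L)
    fwd <- runif(n) < 0.5
    s <- ifelse(fwd, fs, fe - rl + 1L)
    e <- ifelse(fwd, fs + rl - 1L, fe)
    frames[[length(frames) + 1L]] <- data.frame(
      chrom = ch, start = pmax(s, 1), end = pmin(e, L),
      strand = ifelse(fwd, "+", "-"))
  }
  siteTags <- if (length(frames)) {
    df <- do.call(rbind, frames)
    GRanges(factor(df$chrom, levels = names(sizes)),
            IRanges(df$start, df$end), strand = df$strand)
  } else GRanges()
  treatment <- c(siteTags,
                 backgroundTags(config, sizes, config@backgroundRate, 63L))
  control <- backgroundTags(config, sizes, config@controlRate, 77L)
  list(treatment = sort(treatment, ignore.strand = TRUE),
       control = sort(control, ignore.strand = TRUE),
       siteTagCounts = setNames(nTags, mcols(sites)$site))
}

#' Plant motif instances near binding sites
#'
#' Writes the motif consensus into the genome within +/- 50 bp of a
#' `motifPlantFraction` share of the planted sites.
#'
#' @param config A [SimConfig-class].
#' @param genome A named [Biostrings::DNAStringSet] (modified copy
#'   returned).
#' @param sites A site `GRanges`.
#' @param pwm A [MotifMatrix-class].
#' @return A list with `genome` (modified) and `planted` (`GRanges` of
#'   inserted instances, with a `site` column; empty when the fraction
#'   is 0).
#' @export
plantMotifs <- function(config, genome, sites, pwm) {
  opSeed(config, 91L)
  w <- motifWidth(pwm)
  stopifnot(w < 100)
  cons <- motifConsensus(pwm)
  sel <- which(runif(length(sites)) < config@motifPlantFraction)
  planted <- list()
  for (i in sel) {
    ch <- as.character(seqnames(sites))[i]
    off <- round(runif(1, -50, 50 - w))
    s <- start(sites)[i] + off
    s <- max(1, min(s, Biostrings::width(genome)[[match(ch, names(genome))]] - w + 1))
    Biostrings::subseq(genome[[ch]], s, s + w - 1L) <- Biostrings::DNAString(cons)
    planted[[length(planted) + 1L]] <- data.frame(
      chrom = ch, start = s, end = s + w - 1L,
      site = mcols(sites)$site[i])
  }
  if (length(planted)) {
    df <- do.call(rbind, planted)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr)$site <- df$site
  } else gr <- GRanges()
  list(genome = genome, planted = gr)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full generator — genome, sites, gene models, tracks, tags,
#' planted motifs — and writes every pipeline input as plain text: a
#' FASTA genome, a chrom.sizes file, treatment and control tag BED6
#' files, a gene table, one BED per feature track, a MEME motif file and
#' a machine-readable truth table (per-site position, tag budget, motif
#' and per-track mark flags). The same config always produces the same
#' bytes.
#'
#' @param config A [SimConfig-class].
#' @param outdir Output directory (created if needed).
#' @param pwm Optional [MotifMatrix-class] to plant; default plants
#'   nothing.
#' @return A list with the in-memory objects (`genome`, `sites`, `genes`,
#'   `tracks`, `treatment`, `control`, `planted`, `truth`) and `paths`
#'   (named file paths).
#' @export
simulateDataset <- function(config, outdir, pwm = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sizes <- simChromSizes(config)
  genome <- generateGenome(config)
  sites <- generateSites(config)
  ann <- generateAnnotation(config, sites)
  tags <- simulateTags(config, sites)
  planted <- GRanges()
  if (!is.null(pwm) && config@motifPlantFraction > 0) {
    pm <- plantMotifs(config, genome, sites, pwm)
    genome <- pm$genome
    planted <- pm$planted
  }
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    chromSizes = file.path(outdir, "chrom.sizes"),
    treatment = file.path(outdir, "treatment.bed"),
    control = file.path(outdir, "control.bed"),
    genes = file.path(outdir, "genes.tsv"),
    truth = file.path(outdir, "truth_sites.tsv"))
  writeGenome(genome, paths$genome)
  writeChromSizes(sizes, paths$chromSizes)
  tagBed <- function(gr, label, path) {
    out <- gr
    mcols(out)$name <- rep(label, length(gr))
    mcols(out)$score <- rep(0, length(gr))
    writeBed(out, path)
  }
  tagBed(tags$treatment, "treatment", paths$treatment)
  tagBed(tags$control, "control", paths$control)
  writeGeneTable(ann$genes, paths$genes)
  for (tn in names(ann$tracks)) {
    p <- file.path(outdir, paste0("track_", tn, ".bed"))
    writeBed(ann$tracks[[tn]], p, bed3 = TRUE)
    paths[[paste0("track_", tn)]] <- p
  }
  if (!is.null(pwm)) {
    paths$motifs <- file.path(outdir, "motifs.meme")
    writeMeme(list(pwm), paths$motifs)
  }
  siteMarks <- vapply(names(ann$tracks), function(tn)
    countOverlaps(sites, ann$tracks[[tn]], ignore.strand = TRUE) > 0,
    logical(length(sites)))
  if (length(sites) == 1L) siteMarks <- matrix(siteMarks, nrow = 1L,
                                               dimnames = list(NULL,
                                                 names(ann$tracks)))
  truth <- data.frame(site = mcols(sites)$site,
                      chrom = as.character(seqnames(sites)),
                      pos = start(sites),
                      tags = unname(tags$siteTagCounts),
                      motifPlanted = mcols(sites)$site %in%
                        (if (length(planted)) mcols(planted)$site else
                         character(0)))
  truth <- cbind(truth, as.data.frame(siteMarks))
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(genome = genome, sites = sites, genes = ann$genes,
       tracks = ann$tracks, treatment = tags$treatment,
       control = tags$control, planted = planted, truth = truth,
       chromSizes = sizes, paths = paths)
}

#' Truth intervals for recall/precision against planted sites
#'
#' A called peak matches a planted site when it overlaps the site's
#' +/- `halfWidth` neighbourhood by at least one base.
#'
#' @param sites Site `GRanges` (or a truth data frame from
#'   [simulateDataset()]).
#' @param halfWidth Neighbourhood half-width in bases.
#' @return A `GRanges` of truth intervals.
#' @export
truthIntervals <- function(sites, halfWidth = 100) {
  if (is.data.frame(sites))
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  GRanges(seqnames(sites),
          IRanges(pmax(start(sites) - halfWidth, 1),
                  start(sites) + halfWidth))
}

#' Recall and precision of called peaks against planted sites
#' @param peaks Called peak `GRanges`.
#' @param truth Truth intervals from [truthIntervals()].
#' @return A list with `recall`, `precision`, `nPeaks`, `nSites`.
#' @export
peakRecovery <- function(peaks, truth) {
  rec <- if (length(truth))
    mean(countOverlaps(truth, peaks, ignore.strand = TRUE) > 0) else NaN
  pre <- if (length(peaks))
    mean(countOverlaps(peaks, truth, ignore.strand = TRUE) > 0) else NaN
  list(recall = rec, precision = pre, nPeaks = length(peaks),
       nSites = length(truth))
}
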