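#' Assemble a run configuration for one condition
#'
#' Collects the input paths and analysis parameters for a single-condition
#' run of the full pipeline. All referenced files must exist.
#'
#' @param treatment,control Tag BED6 paths.
#' @param chromSizes Chromosome sizes path.
#' @param genes Gene table path (see [readGeneTable()]).
#' @param tracks Named character vector of feature-track BED paths.
#' @param genome Optional FASTA path (needed for motif scanning).
#' @param motifs Optional MEME minimal motif file path.
#' @param annotationMap Optional two-column TSV (term, gene) for gene-set
#'   enrichment.
#' @param params A [CallerParams-class]; its `fragmentShift` is replaced
#'   by the cross-correlation estimate unless `estimateShift = FALSE`.
#' @param minSupport Consensus support threshold (default 2, the
#'   at-least-two-of-three tier).
#' @param geneAlpha,motifAlpha BH significance thresholds (defaults 0.01
#'   and 0.05).
#' @param estimateShift Estimate the fragment shift from the treatment
#'   tags (default TRUE).
#' @return A `runConfig` list, input to [runCondition()].
#' @export
runConfig <- function(treatment, control, chromSizes, genes,
                      tracks = character(0), genome = NULL, motifs = NULL,
                      annotationMap = NULL, params = callerParams(),
                      minSupport = 2L, geneAlpha = 0.01, motifAlpha = 0.05,
                      estimateShift = TRUE) {
  files <- c(treatment = treatment, control = control,
             chromSizes = chromSizes, genes = genes, tracks,
             genome = genome, motifs = motifs,
             annotationMap = annotationMap)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "))
  list(treatment = treatment, control = control, chromSizes = chromSizes,
       genes = genes, tracks = tracks, genome = genome, motifs = motifs,
       annotationMap = annotationMap, params = params,
       minSupport = minSupport, geneAlpha = geneAlpha,
       motifAlpha = motifAlpha, estimateShift = estimateShift)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis for one condition
#'
#' Executes, in order: fragment-shift estimation, the three peak callers,
#' consensus clustering and tier selection, gene categorisation,
#' TSS-distance profiling, chromosome density, per-track coincidence,
#' motif scanning and enrichment (when a genome and motifs are supplied),
#' and gene-set enrichment of peak-associated genes (when an annotation
#' map is supplied). Every table is written to `outdir` as TSV/BED along
#' with a manifest recording parameters and input checksums; re-running
#' with unchanged inputs reuses the cached results.
#'
#' @param config A list from [runConfig()].
#' @param condition Label for this condition (used in file names).
#' @param outdir Output directory.
#' @param force Recompute even when the manifest matches.
#' @return A report bundle: a list with the main result objects, the
#'   table paths and the manifest.
#' @export
runCondition <- function(config, condition, outdir, force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(config$treatment, config$control, config$chromSizes,
              config$genes, config$tracks, config$genome, config$motifs,
              config$annotationMap)
  checks <- tools::md5sum(inputs)
  p <- config$params
  manifest <- c(condition = condition,
                minSupport = config$minSupport,
                geneAlpha = config$geneAlpha, motifAlpha = config$motifAlpha,
                window = p@window, transitionWindow = p@transitionWindow,
                pvalueCutoff = p@pvalueCutoff, foldCutoff = p@foldCutoff,
                minTags = p@minTags, minRun = p@minRun,
                estimateShift = config$estimateShift,
                setNames(as.character(checks), basename(inputs)))
  manifestPath <- file.path(outdir, paste0(condition, "_manifest.tsv"))
  manifestDf <- data.frame(key = names(manifest),
                           value = unname(unlist(manifest)))
  if (!force && file.exists(manifestPath)) {
    old <- tryCatch(read.table(manifestPath, sep = "\t", header = TRUE,
                               colClasses = "character"),
                    error = function(e) NULL)
    if (!is.null(old) && identical(old$key, manifestDf$key) &&
        identical(old$value, as.character(manifestDf$value))) {
      cached <- loadBundle(outdir, condition)
      if (!is.null(cached)) return(cached)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  treatment <- stage("read_tags", readBed(config$treatment, "bed6"))
  control <- stage("read_tags", readBed(config$control, "bed6"))
  sizes <- stage("read_sizes", readChromSizes(config$chromSizes))
  genes <- stage("read_genes", readGeneTable(config$genes))
  if (config$estimateShift) {
    sh <- stage("fragment_shift",
                suppressWarnings(estimateFragmentShift(treatment, sizes)))
    p@fragmentShift <- max(sh$d, 1)
  }
  peaksets <- list(
    poisson = stage("poisson", callPeaksPoisson(treatment, control, sizes, p)),
    strand_transition = stage("strand_transition",
      callPeaksStrandTransition(treatment, control, sizes, p)),
    threshold = stage("threshold",
      callPeaksThreshold(treatment, control, sizes, p)))
  cs <- stage("consensus", clusterPeaks(peaksets))
  tier <- selectConsensus(cs, config$minSupport)
  peaks <- consensusPeaks(tier)
  pfx <- function(nm) file.path(outdir, paste0(condition, "_", nm))
  paths <- list(manifest = manifestPath)
  for (cl in names(peaksets)) {
    paths[[cl]] <- pfx(paste0("peaks_", cl, ".bed"))
    pk <- peaksets[[cl]]
    mcols(pk)$name <- rep(cl, length(pk))
    writeBed(pk[, c("name", "score")], paths[[cl]])
  }
  paths$consensus <- pfx("consensus.bed")
  paths$venn <- pfx("venn.tsv")
  writeConsensus(cs, pfx("clusters_all.bed"), paths$venn)
  writeConsensus(tier, paths$consensus)
  ann <- stage("annotation", categorizePeaks(peaks, genes))
  paths$annotation <- writeTsv(ann, pfx("annotation.tsv"))
  fr <- stage("fractions", categoryFractions(peaks, genes))
  paths$fractions <- writeTsv(
    data.frame(category = c(names(fr$fractions), "within_100kb_of_gene"),
               fraction = c(unname(fr$fractions), fr$within100kb)),
    pfx("category_fractions.tsv"))
  tp <- stage("tss_profile", tssProfile(peaks, genes))
  paths$tss <- writeTsv(tp$histogram, pfx("tss_profile.tsv"))
  cd <- stage("density", chromosomeDensity(peaks, sizes))
  paths$density <- writeTsv(cd$table, pfx("chromosome_density.tsv"))
  coinc <- NULL
  if (length(config$tracks)) {
    coinc <- do.call(rbind, lapply(names(config$tracks), function(tn)
      stage("coincidence",
            peakTrackCoincidence(peaks, readBed(config$tracks[[tn]]),
                                 sum(sizes), tn))))
    paths$coincidence <- writeTsv(coinc, pfx("coincidence.tsv"))
  }
  motifTab <- NULL
  motifHits <- list()
  if (!is.null(config$genome) && !is.null(config$motifs)) {
    genome <- stage("read_genome", readGenome(config$genome))
    motifs <- stage("read_motifs", readMeme(config$motifs))
    me <- stage("motif_enrichment",
                motifEnrichmentScan(motifs, genome, peaks,
                                    alpha = config$motifAlpha))
    motifTab <- me$table
    motifHits <- me$hits
    paths$motifEnrichment <- writeTsv(motifTab, pfx("motif_enrichment.tsv"))
    hitsDf <- do.call(rbind, lapply(me$hits, function(h)
      if (length(h)) data.frame(motif = mcols(h)$motif,
                                chrom = as.character(seqnames(h)),
                                start = start(h) - 1L, end = end(h),
                                strand = as.character(strand(h)),
                                score = mcols(h)$score,
                                pvalue = mcols(h)$pvalue) else NULL))
    if (is.null(hitsDf))
      hitsDf <- data.frame(motif = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), score = numeric(0),
                           pvalue = numeric(0))
    paths$motifHits <- writeTsv(hitsDf, pfx("motif_hits.tsv"))
  }
  geneTab <- NULL
  if (!is.null(config$annotationMap)) {
    amap <- read.table(config$annotationMap, sep = "\t", header = FALSE,
                       col.names = c("term", "gene"),
                       colClasses = "character")
    annotation <- split(amap$gene, amap$term)
    selectedGenes <- unique(stats::na.omit(ann$gene))
    universe <- unique(mcols(genes)$name)
    if (length(selectedGenes)) {
      geneTab <- stage("gene_enrichment",
                       geneSetEnrichment(selectedGenes, universe, annotation,
                                         alpha = config$geneAlpha))
      paths$geneEnrichment <- writeTsv(geneTab, pfx("gene_enrichment.tsv"))
    }
  }
  writeTsv(manifestDf, manifestPath)
  bundle <- list(condition = condition, params = p, peaksets = peaksets,
                 consensus = cs, tier = tier, peaks = peaks,
                 annotation = ann, fractions = fr, tssProfile = tp,
                 density = cd, coincidence = coinc, motifTable = motifTab,
                 motifHits = motifHits, geneEnrichment = geneTab,
                 genomeChecksum = unname(checks[match(config$chromSizes,
                                                      inputs)]),
                 paths = paths, manifest = manifestDf, outdir = outdir)
  saveBundle(bundle, outdir, condition)
  bundle
}

# run cache: the bundle is serialised next to the tables; a re-run with a
# matching manifest loads it instead of recomputing
saveBundle <- function(bundle, outdir, condition) {
  saveRDS(bundle, file.path(outdir, paste0(condition, "_bundle.rds")))
  invisible(NULL)
}

loadBundle <- function(outdir, condition) {
  f <- file.path(outdir, paste0(condition, "_bundle.rds"))
  if (!file.exists(f)) return(NULL)
  tryCatch(readRDS(f), error = function(e) NULL)
}

#' Compare the report bundles of two conditions
#'
#' Descriptive between-condition comparison (the analysis applies no
#' significance test across conditions): per-track coincidence fold
#' changes, category-fraction deltas, side-by-side TSS histograms, and
#' per-motif significance patterns (significant in A only, B only, both
#' or neither).
#'
#' @param bundleA,bundleB Bundles from [runCondition()] computed on the
#'   same reference inputs.
#' @return A list of comparison data frames: `coincidence`, `categories`,
#'   `tss`, `motifs`.
#' @export
compareConditions <- function(bundleA, bundleB) {
  if (!identical(bundleA$genomeChecksum, bundleB$genomeChecksum))
    stop("bundles were computed on different reference inputs")
  out <- list()
  if (!is.null(bundleA$coincidence) && !is.null(bundleB$coincidence)) {
    shared <- intersect(bundleA$coincidence$track, bundleB$coincidence$track)
    out$coincidence <- do.call(rbind, lapply(shared, function(tn)
      conditionCompare(
        bundleA$coincidence[bundleA$coincidence$track == tn, ],
        bundleB$coincidence[bundleB$coincidence$track == tn, ])))
  }
  fa <- bundleA$fractions$fractions
  fb <- bundleB$fractions$fractions
  out$categories <- data.frame(category = names(fa),
                               fractionA = unname(fa),
                               fractionB = unname(fb[names(fa)]),
                               delta = unname(fa - fb[names(fa)]))
  ha <- bundleA$tssProfile$histogram
  hb <- bundleB$tssProfile$histogram
  out$tss <- data.frame(lower = ha$lower, upper = ha$upper,
                        countA = ha$count, countB = hb$count)
  if (!is.null(bundleA$motifTable) && !is.null(bundleB$motifTable)) {
    ma <- bundleA$motifTable
    mb <- bundleB$motifTable
    shared <- intersect(ma$motif, mb$motif)
    sa <- ma$significant[match(shared, ma$motif)]
    sb <- mb$significant[match(shared, mb$motif)]
    out$motifs <- data.frame(motif = shared, significantA = sa,
                             significantB = sb,
                             pattern = ifelse(sa & sb, "both",
                                       ifelse(sa, "A_only",
                                       ifelse(sb, "B_only", "neither"))))
  }
  out
}
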