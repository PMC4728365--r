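suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# GRanges from BED-style 0-based half-open coordinates
bedGR <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start + 1L, end), strand = strand)
}

# tag GRanges from 5' positions (1-based)
makeTags <- function(chrom, p5, strand, readLength = 36L) {
  strand <- rep(strand, length.out = length(p5))
  plus <- strand == "+"
  GRanges(chrom,
          IRanges(ifelse(plus, p5, p5 - readLength + 1L),
                  ifelse(plus, p5 + readLength - 1L, p5)),
          strand = strand)
}

# random PWM with one dominant base per column
sharpPwm <- function(name, width, seed, dominant = 0.97) {
  set.seed(seed)
  m <- matrix((1 - dominant) / 3, width, 4)
  for (i in seq_len(width)) m[i, sample(4, 1)] <- dominant
  motifMatrix(name, m)
}

randomPwm <- function(name, width, seed) {
  set.seed(seed)
  m <- matrix(runif(width * 4), width, 4)
  motifMatrix(name, m / rowSums(m))
}

# per-base brute-force coverage over a small chromosome
baseCoverage <- function(gr, L) {
  cov <- logical(L)
  for (i in seq_along(gr)) cov[seq(start(gr)[i], min(end(gr)[i], L))] <- TRUE
  cov
}

# one shared "strong"-preset dataset with planted and decoy motifs, the
# three callers run on it, and the consensus set; computed once per run
.fixtures <- new.env(parent = emptyenv())

strongFixture <- function() {
  if (!is.null(.fixtures$strong)) return(.fixtures$strong)
  plantedPwm <- sharpPwm("PLANTED", 10, seed = 401)
  decoyPwm <- sharpPwm("DECOY", 10, seed = 402)
  cfg <- simPreset("strong", seed = 101, motifPlantFraction = 0.8)
  dir <- file.path(tempdir(), "triPeaks-strong-fixture")
  sim <- simulateDataset(cfg, dir, pwm = plantedPwm)
  sizes <- sim$chromSizes
  sh <- suppressWarnings(estimateFragmentShift(sim$treatment, sizes))
  params <- callerParams(fragmentShift = max(sh$d, 1))
  peaksets <- list(
    poisson = callPeaksPoisson(sim$treatment, sim$control, sizes, params),
    strand_transition = callPeaksStrandTransition(sim$treatment,
                                                  sim$control, sizes, params),
    threshold = callPeaksThreshold(sim$treatment, sim$control, sizes, params))
  consensus <- clusterPeaks(peaksets)
  .fixtures$strong <- list(cfg = cfg, sim = sim, shift = sh,
                           params = params, peaksets = peaksets,
                           consensus = consensus, dir = dir,
                           plantedPwm = plantedPwm, decoyPwm = decoyPwm)
  .fixtures$strong
}
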