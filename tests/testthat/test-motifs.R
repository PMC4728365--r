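test_that("log-odds scoring matches hand computation on one-hot matrices", {
  m <- matrix(rep(c(1, 0, 0, 0), 6), ncol = 4, byrow = TRUE)
  pwm <- motifMatrix("A6", m, pseudocount = 0)
  # uniform background: each matching column contributes log2(1/0.25)
  expect_equal(scoreWindow(pwm, "AAAAAA"), 12)
  # full mismatch with a tiny pseudocount: strongly negative
  pwm2 <- motifMatrix("A6", m, pseudocount = 1e-4)
  expect_lt(scoreWindow(pwm2, "CCCCCC"), -30)
  expect_error(scoreWindow(pwm, "AAA"), "width")
  expect_error(scoreWindow(pwm, "AANAAA"), "non-ACGT")
  expect_identical(scoreWindow(pwm, "AANAAA", nPolicy = "skip"), -Inf)
})

test_that("the consensus word maximises the score over all words", {
  pwm <- randomPwm("W6", 6, seed = 12)
  words <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                       stringsAsFactors = FALSE)
  scores <- apply(as.matrix(words), 1L, function(w)
    scoreWindow(pwm, paste(w, collapse = "")))
  expect_equal(paste(as.matrix(words)[which.max(scores), ], collapse = ""),
               motifConsensus(pwm))
})

test_that("score p-values hit their boundary conventions", {
  pwm <- randomPwm("W5", 5, seed = 13)
  expect_equal(scorePvalue(pwm, -1e6), 1)
  top <- scorePvalue(pwm, scoreWindow(pwm, motifConsensus(pwm)))
  beyond <- scorePvalue(pwm, 1e6)
  expect_lte(beyond, top)
  expect_gt(beyond, 0)
})

test_that("the p-value dynamic programme equals full enumeration", {
  for (seed in 1:4) {
    pwm <- randomPwm(paste0("W", seed), 5, seed = 100 + seed)
    Si <- triPeaks:::integerScoreMatrix(triPeaks:::logOddsMatrix(pwm))
    words <- as.matrix(expand.grid(rep(list(1:4), 5)))
    scores <- integer(nrow(words))
    for (i in 1:5) scores <- scores + Si[i, words[, i]]
    wt <- apply(words, 1L, function(w) prod(pwm@background[w]))
    set.seed(200 + seed)
    thresholds <- sample(sort(unique(scores)), 20)
    for (t in thresholds) {
      expect_equal(scorePvalue(pwm, t / 1000), sum(wt[scores >= t]),
                   tolerance = 1e-9)
    }
  }
})

test_that("scanning finds a planted consensus on the forward strand", {
  pwm <- sharpPwm("P8", 8, seed = 14)
  set.seed(15)
  g <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), 4000,
                                          TRUE), collapse = "")))
  subseq(g[[1]], 1500, 1507) <- DNAString(motifConsensus(pwm))
  h <- scanMotif(pwm, g)
  fwd <- h[as.character(strand(h)) == "+"]
  expect_true(any(start(fwd) == 1500))
  expect_true(all(width(h) == 8))
  expect_true(all(mcols(h)$pvalue < 1e-4))
})

test_that("palindromic instances are reported on both strands at one interval", {
  m <- matrix(0.001, 8, 4)
  for (i in seq_len(8)) m[i, c(2, 2, 1, 4, 1, 4, 3, 3)[i]] <- 0.997
  pwm <- motifMatrix("PAL", m) # consensus CCATATGG, its own reverse complement
  set.seed(16)
  g <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000,
                                          TRUE), collapse = "")))
  subseq(g[[1]], 900, 907) <- DNAString("CCATATGG")
  h <- scanMotif(pwm, g)
  at <- h[start(h) == 900]
  expect_setequal(as.character(strand(at)), c("+", "-"))
})

test_that("region-restricted scans equal filtered whole-genome scans", {
  pwm <- sharpPwm("P6", 6, seed = 17)
  set.seed(18)
  g <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), 6000,
                                          TRUE), collapse = "")))
  for (s in c(500, 2500, 4500))
    subseq(g[[1]], s, s + 5) <- DNAString(motifConsensus(pwm))
  regions <- GRanges("chr1", IRanges(c(301, 4301), c(1300, 5300)))
  inRegion <- scanMotif(pwm, g, regions = regions)
  whole <- scanMotif(pwm, g)
  filtered <- whole[countOverlaps(whole, regions, type = "within") > 0]
  expect_identical(as.data.frame(inRegion), as.data.frame(filtered))
  expect_error(scanMotif(pwm, g, regions = GRanges("chr1",
                                                   IRanges(5990, 6020))),
               "outside sequence")
})

test_that("hit counts survive genome reverse-complementation", {
  pwm <- sharpPwm("P7", 7, seed = 19)
  set.seed(20)
  g <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), 5000,
                                          TRUE), collapse = "")))
  subseq(g[[1]], 2000, 2006) <- DNAString(motifConsensus(pwm))
  rc <- DNAStringSet(c(chr1 = as.character(reverseComplement(g[[1]]))))
  h <- scanMotif(pwm, g)
  hrc <- scanMotif(pwm, rc)
  expect_equal(length(h), length(hrc))
  # intervals mirror: start' = L - end + 1, strands flip
  L <- 5000
  mirrored <- sort(GRanges("chr1", IRanges(L - end(h) + 1, L - start(h) + 1),
                           strand = chartr("+-", "-+",
                                           as.character(strand(h)))))
  got <- sort(granges(hrc))
  expect_equal(as.data.frame(mirrored), as.data.frame(got))
})

test_that("tightening the occurrence cutoff never adds hits", {
  pwm <- randomPwm("W8", 8, seed = 21)
  set.seed(22)
  g <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), 20000,
                                          TRUE), collapse = "")))
  loose <- scanMotif(pwm, g, pvalueCutoff = 1e-2)
  strict <- scanMotif(pwm, g, pvalueCutoff = 1e-3)
  expect_lte(length(strict), length(loose))
  key <- function(x) paste(start(x), strand(x))
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("motif enrichment counts feed the hypergeometric correctly", {
  expect_equal(motifEnrichment(0, 100, 50, 10000)$p, 1)
  expect_error(motifEnrichment(60, 100, 50, 10000), "invalid counts")
  # all genome hits inside small peaks: near-minimal p, vs direct summation
  N <- 5000; n <- 100; K <- 20; k <- 20
  direct <- sum(dhyper(k:min(K, n), K, N - K, n))
  got <- motifEnrichment(k, n, K, N)
  expect_equal(got$p, direct, tolerance = 1e-12)
  expect_lt(got$p, 1e-20)
  # k at expectation is unremarkable
  N <- 1000; n <- 100; K <- 50; k <- 5
  pExp <- motifEnrichment(k, n, K, N)$p
  expect_equal(pExp, sum(dhyper(5:50, 50, 950, 100)), tolerance = 1e-12)
  expect_gt(pExp, 0.3)
})

test_that("motif-bearing peak TSS distributions follow construction", {
  g <- bedGR("chr1", 50000, 60000, "+")
  mcols(g)$name <- "g1"
  # no peak contains a hit: empty histogram
  peaks <- bedGR("chr1", c(10000, 30000), c(10400, 30400))
  empty <- motifTssDistribution(peaks, GRanges(), g)
  expect_equal(sum(empty$histogram$count), 0)
  expect_equal(empty$nPeaksWithMotif, 0L)
  # all motif-bearing peaks centred at the TSS: single central bin
  atTss <- GRanges("chr1", IRanges(50001 - 200, 50001 + 200))
  hit <- GRanges("chr1", IRanges(50001, 50008))
  r <- motifTssDistribution(atTss, hit, g, window = 20000, bin = 500)
  expect_equal(r$nPeaksWithMotif, 1L)
  expect_equal(sum(r$histogram$count), 1)
  expect_equal(r$histogram$count[r$histogram$lower == 0], 1)
  # planted distances are recovered bin-exactly
  offs <- c(-4750, -250, 1250, 7250)
  pk <- GRanges("chr1", IRanges(50001 + offs - 100, 50001 + offs + 100))
  hits <- GRanges("chr1", IRanges(50001 + offs - 4, 50001 + offs + 3))
  r <- motifTssDistribution(pk, hits, g, window = 20000, bin = 500)
  expect_equal(sum(r$histogram$count), 4)
  for (o in offs)
    expect_equal(r$histogram$count[r$histogram$lower == 500 *
                                     floor(o / 500)], 1)
})
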