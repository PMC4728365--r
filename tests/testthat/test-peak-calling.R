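sizes1 <- c(chr1 = 1e5)

test_that("fragment shift is recovered from fixed-length fragments", {
  cfg <- simConfig(seed = 7, nChroms = 1, chromLength = 2e5, nSites = 30,
                   tagsPerSite = 40, backgroundRate = 0.2,
                   fragmentRange = c(150, 150), siteJitterSd = 50)
  sites <- generateSites(cfg)
  tags <- simulateTags(cfg, sites)
  sh <- estimateFragmentShift(tags$treatment, c(chr1 = 2e5))
  expect_gte(sh$d, 140)
  expect_lte(sh$d, 160)
  expect_false(sh$lowCorrelation)
})

test_that("coincident strand densities give zero shift", {
  set.seed(1)
  p5 <- sample(5e4, 600) + 100
  tags <- c(makeTags("chr1", p5, "+"), makeTags("chr1", p5, "-"))
  sh <- suppressWarnings(estimateFragmentShift(tags, sizes1))
  expect_equal(sh$d, 0)
})

test_that("uniform tags are flagged as having no strand structure", {
  set.seed(2)
  tags <- makeTags("chr1", sample(99000, 2000) + 50,
                   sample(c("+", "-"), 2000, replace = TRUE))
  expect_warning(sh <- estimateFragmentShift(tags, sizes1),
                 "cross-correlation below 0.1")
  expect_true(sh$lowCorrelation)
  expect_lt(sh$cor, 0.1)
})

test_that("single-strand input cannot drive the shift estimator", {
  tags <- makeTags("chr1", 1:2000 * 10, rep("+", 2000))
  expect_error(estimateFragmentShift(tags, sizes1), "both strands")
})

test_that("a stacked locus over uniform control yields one Poisson peak", {
  set.seed(3)
  center <- 50000
  fwd <- makeTags("chr1", center - 75 + round(rnorm(250, 0, 30)), "+")
  rvs <- makeTags("chr1", center + 75 + round(rnorm(250, 0, 30)), "-")
  ctrl <- makeTags("chr1", sample(99000, 400) + 50,
                   sample(c("+", "-"), 400, replace = TRUE))
  pk <- callPeaksPoisson(c(fwd, rvs), ctrl, sizes1,
                         callerParams(fragmentShift = 150))
  expect_length(pk, 1L)
  expect_true(start(pk) <= center && end(pk) >= center)
  expect_true(mcols(pk)$summit >= start(pk) && mcols(pk)$summit <= end(pk))
  expect_gt(mcols(pk)$score, 5)
})

test_that("identical treatment and control produce no Poisson peaks", {
  set.seed(4)
  tags <- makeTags("chr1", sample(99000, 1500) + 50,
                   sample(c("+", "-"), 1500, replace = TRUE))
  pk <- callPeaksPoisson(tags, tags, sizes1, callerParams())
  expect_length(pk, 0L)
})

test_that("copy-number gains present in both samples are not called", {
  # 5x density inside chr1:20k-30k in BOTH samples; the 5k/10k local
  # control rates absorb the shared gain
  set.seed(5)
  mk <- function() {
    base <- sample(99000, 300) + 50
    gain <- sample(10000, 150) + 20000
    makeTags("chr1", c(base, gain),
             sample(c("+", "-"), 450, replace = TRUE))
  }
  pk <- callPeaksPoisson(mk(), mk(), sizes1, callerParams())
  seg <- GRanges("chr1", IRanges(20001, 30000))
  expect_equal(sum(countOverlaps(pk, seg) > 0), 0L)
})

test_that("empty treatment gives an empty peak set", {
  ctrl <- makeTags("chr1", 1:100 * 900, rep("+", 100))
  expect_length(callPeaksPoisson(GRanges(), ctrl, sizes1, callerParams()), 0L)
  expect_length(callPeaksStrandTransition(GRanges(), ctrl, sizes1,
                                          callerParams()), 0L)
  expect_length(callPeaksThreshold(GRanges(), ctrl, sizes1,
                                   callerParams()), 0L)
})

test_that("a bidirectional pileup yields one strand-transition peak at the site", {
  set.seed(6)
  center <- 40000
  fwd <- makeTags("chr1", center - 75 + round(rnorm(60, 0, 20)), "+")
  rvs <- makeTags("chr1", center + 75 + round(rnorm(60, 0, 20)), "-")
  ctrl <- makeTags("chr1", sample(99000, 200) + 50,
                   sample(c("+", "-"), 200, replace = TRUE))
  pk <- callPeaksStrandTransition(c(fwd, rvs), ctrl, sizes1,
                                  callerParams(fragmentShift = 150))
  expect_length(pk, 1L)
  expect_lt(abs(mcols(pk)$summit - center), 150)
})

test_that("single-strand data produces no strand transitions", {
  tags <- makeTags("chr1", 30000 + round(rnorm(200, 0, 50)), rep("+", 200))
  ctrl <- makeTags("chr1", 1:100 * 900, rep("+", 100))
  pk <- callPeaksStrandTransition(tags, ctrl, sizes1, callerParams())
  expect_length(pk, 0L)
})

test_that("two distant sites give two strand-transition peaks in order", {
  set.seed(7)
  mkSite <- function(center) {
    c(makeTags("chr1", center - 75 + round(rnorm(50, 0, 20)), "+"),
      makeTags("chr1", center + 75 + round(rnorm(50, 0, 20)), "-"))
  }
  tags <- c(mkSite(30000), mkSite(40000))
  ctrl <- makeTags("chr1", sample(99000, 200) + 50,
                   sample(c("+", "-"), 200, replace = TRUE))
  pk <- callPeaksStrandTransition(tags, ctrl, sizes1,
                                  callerParams(fragmentShift = 150))
  expect_length(pk, 2L)
  expect_lt(abs(mcols(pk)$summit[1] - 30000), 150)
  expect_lt(abs(mcols(pk)$summit[2] - 40000), 150)
})

test_that("flat coverage yields no threshold peaks", {
  tags <- makeTags("chr1", seq(100, 99000, by = 100), "+")
  ctrl <- makeTags("chr1", seq(150, 99000, by = 500), "+")
  pk <- callPeaksThreshold(tags, ctrl, sizes1,
                           callerParams(fragmentShift = 100))
  expect_length(pk, 0L)
})

test_that("a high stack over even background becomes one threshold peak", {
  bg <- makeTags("chr1", seq(200, 99000, by = 200), "+")
  stack <- makeTags("chr1", rep(50000, 10), rep("+", 10))
  ctrl <- makeTags("chr1", seq(300, 99000, by = 900), "+")
  p <- callerParams(fragmentShift = 200)
  pk <- callPeaksThreshold(c(bg, stack), ctrl, sizes1, p)
  expect_length(pk, 1L)
  expect_gte(width(pk), p@minRun)
  expect_true(start(pk) >= 49900 && end(pk) <= 50300)
})

test_that("runs one base short of the minimum are rejected", {
  stack <- makeTags("chr1", rep(1000, 10), rep("+", 10))
  ctrl <- makeTags("chr1", rep(90000, 1), "+")
  # extension length = plateau width; 49 < minRun = 50 fails, 50 passes
  expect_length(callPeaksThreshold(stack, ctrl, sizes1,
                                   callerParams(fragmentShift = 49)), 0L)
  expect_length(callPeaksThreshold(stack, ctrl, sizes1,
                                   callerParams(fragmentShift = 50)), 1L)
})

test_that("all callers emit sorted, disjoint, in-bounds peaks", {
  fx <- strongFixture()
  sizes <- fx$sim$chromSizes
  for (pk in fx$peaksets) {
    expect_gt(length(pk), 0L)
    df <- as.data.frame(pk)
    o <- order(df$seqnames, df$start)
    expect_identical(o, seq_len(nrow(df)))
    for (ch in unique(df$seqnames)) {
      on <- df[df$seqnames == ch, ]
      if (nrow(on) > 1)
        expect_true(all(on$start[-1] > on$end[-nrow(on)]))
      expect_true(all(on$start >= 1 & on$end <= sizes[[as.character(ch)]]))
    }
    expect_true(all(df$summit >= df$start & df$summit <= df$end))
    expect_true(all(df$score >= 0))
  }
})

test_that("relaxing cutoffs never removes called coverage", {
  fx <- strongFixture()
  sizes <- fx$sim$chromSizes
  pStrict <- fx$params
  pLoose <- fx$params
  pLoose@pvalueCutoff <- 1e-3
  pkS <- callPeaksPoisson(fx$sim$treatment, fx$sim$control, sizes, pStrict)
  pkL <- callPeaksPoisson(fx$sim$treatment, fx$sim$control, sizes, pLoose)
  notCovered <- GenomicRanges::setdiff(reduce(pkS), reduce(pkL))
  expect_equal(sum(width(notCovered)), 0)
  pLoose <- fx$params
  pLoose@foldCutoff <- 1.5
  pkS <- callPeaksThreshold(fx$sim$treatment, fx$sim$control, sizes, pStrict)
  pkL <- callPeaksThreshold(fx$sim$treatment, fx$sim$control, sizes, pLoose)
  notCovered <- GenomicRanges::setdiff(reduce(pkS), reduce(pkL))
  expect_equal(sum(width(notCovered)), 0)
})
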