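plusGene <- function() {
  g <- bedGR("chr1", 10000, 20000, "+")
  mcols(g)$name <- "g1"
  g
}

test_that("location categories follow the documented precedence windows", {
  g <- plusGene()
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 12000, 12200),
                                            g)$category), "intragenic")
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 6000, 6200),
                                            g)$category), "promoter_5kb")
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 21000, 21200),
                                            g)$category), "downstream_5kb")
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 4000, 4200),
                                            g)$category),
               "within_100kb_upstream")
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 30000, 30200),
                                            g)$category),
               "within_100kb_downstream")
  # 121000 - 20000 > 100000: just beyond the downstream flank
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 121000, 121200),
                                            g)$category), "gene_desert")
})

test_that("minus-strand genes mirror the plus-strand category logic", {
  g <- bedGR("chr1", 10000, 20000, "-")
  mcols(g)$name <- "g1"
  # upstream of a minus-strand TSS (at base 20000) lies to the right
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 21000, 21200),
                                            g)$category), "promoter_5kb")
  expect_equal(as.character(categorizePeaks(bedGR("chr1", 6000, 6200),
                                            g)$category), "downstream_5kb")
})

test_that("category labels are invariant under coordinate reflection", {
  fx <- strongFixture()
  genes <- fx$sim$genes
  peaks <- consensusPeaks(selectConsensus(fx$consensus, 2))
  L <- fx$sim$chromSizes[1] + 1
  flip <- function(gr) {
    out <- GRanges(seqnames(gr), IRanges(L - end(gr), L - start(gr)),
                   strand = chartr("+-", "-+", as.character(strand(gr))))
    mcols(out) <- mcols(gr)
    out
  }
  a <- categorizePeaks(peaks, genes)
  b <- categorizePeaks(flip(peaks), flip(genes))
  expect_equal(as.character(a$category), as.character(b$category))
  expect_equal(a$gene, b$gene)
})

test_that("empty gene list puts everything in gene deserts with a warning", {
  expect_warning(ann <- categorizePeaks(bedGR("chr1", 100, 200), GRanges()),
                 "empty gene list")
  expect_equal(as.character(ann$category), "gene_desert")
  expect_true(is.na(ann$gene))
})

test_that("category fractions sum to one and match direct construction", {
  g <- plusGene()
  expect_error(categoryFractions(GRanges(), g), "empty peak")
  allIn <- bedGR("chr1", c(11000, 13000, 15000), c(11200, 13200, 15200))
  fr <- categoryFractions(allIn, g)
  expect_equal(unname(fr$fractions["intragenic"]), 1)
  # constructed fixture: 2 intragenic, 1 promoter, 1 downstream, 1 desert
  mixed <- bedGR("chr1", c(11000, 15000, 6000, 21000, 150000),
                 c(11200, 15200, 6200, 21200, 150200))
  fr <- categoryFractions(mixed, g)
  expect_equal(unname(fr$fractions[c("intragenic", "promoter_5kb",
                                     "downstream_5kb", "gene_desert")]),
               c(0.4, 0.2, 0.2, 0.2))
  expect_equal(sum(fr$fractions), 1)
  expect_equal(unname(fr$within100kb), 0.8)
  # conservation on arbitrary peaks
  fx <- strongFixture()
  set.seed(31)
  s <- sample(290000, 1000)
  rnd <- GRanges(sample(paste0("chr", 1:3), 1000, TRUE), IRanges(s, s + 400))
  fr <- categoryFractions(rnd, fx$sim$genes)
  expect_equal(sum(fr$fractions), 1)
})

test_that("TSS distances are signed, strand-aware, and cutoff counts correct", {
  g <- plusGene() # TSS at base 10001 (1-based)
  # midpoint exactly at the TSS
  atTss <- GRanges("chr1", IRanges(10001 - 50, 10001 + 50))
  tp <- tssProfile(atTss, g)
  expect_equal(tp$distances, 0)
  expect_equal(tp$nWithin1kb, 1L)
  expect_equal(tp$nWithin500, 1L)
  # 999 bases downstream: inside 1 kb, outside 500 b
  down <- GRanges("chr1", IRanges(11000 - 50, 11000 + 50))
  tp <- tssProfile(down, g)
  expect_equal(tp$distances, 999)
  expect_equal(tp$nWithin1kb, 1L)
  expect_equal(tp$nWithin500, 0L)
  # minus-strand gene: downstream in gene orientation is leftward
  gm <- bedGR("chr1", 10000, 20000, "-")
  mcols(gm)$name <- "gm"
  tp <- tssProfile(GRanges("chr1", IRanges(19000, 19100)), gm)
  expect_gt(tp$distances, 0) # midpoint left of TSS = downstream for minus
  expect_error(tssProfile(atTss, g, window = 1000, bin = 300),
               "multiple of bin")
})

test_that("cutoff counts equal a linear-scan recomputation on random peaks", {
  fx <- strongFixture()
  genes <- fx$sim$genes
  set.seed(17)
  s <- sample(295000, 2000, replace = TRUE)
  peaks <- GRanges(sample(paste0("chr", 1:3), 2000, TRUE), IRanges(s, s + 300))
  tp <- tssProfile(peaks, genes)
  mid <- floor((start(peaks) + end(peaks)) / 2)
  n1k <- 0L; n500 <- 0L
  for (i in seq_along(peaks)) {
    on <- as.character(seqnames(genes)) == as.character(seqnames(peaks))[i]
    d <- min(abs(mid[i] - mcols(genes)$tss[on]))
    if (d <= 1000) n1k <- n1k + 1L
    if (d <= 500) n500 <- n500 + 1L
  }
  expect_equal(tp$nWithin1kb, n1k)
  expect_equal(tp$nWithin500, n500)
  expect_lte(tp$nWithin500, tp$nWithin1kb)
  expect_equal(sum(tp$histogram$count), sum(abs(tp$distances) <= 10000))
  expect_equal(tp$nTotal, 2000L)
})

test_that("chromosome density reports counts and the length correlation", {
  sizes <- c(chr1 = 1e5, chr2 = 2e5, chr3 = 3e5)
  mkN <- function(n, ch, L) {
    s <- seq(1000, L - 1000, length.out = n)
    GRanges(factor(rep(ch, n), levels = paste0("chr", 1:3)),
            IRanges(round(s), round(s) + 10))
  }
  # counts exactly proportional to length
  pk <- c(mkN(10, "chr1", 1e5), mkN(20, "chr2", 2e5), mkN(30, "chr3", 3e5))
  cd <- chromosomeDensity(pk, sizes)
  expect_equal(cd$r, 1)
  expect_equal(cd$table$count, c(10L, 20L, 30L))
  # hand-computed textbook Pearson on a 3-point fixture
  pk2 <- c(mkN(2, "chr1", 1e5), mkN(1, "chr2", 2e5), mkN(3, "chr3", 3e5))
  cd2 <- chromosomeDensity(pk2, sizes)
  l <- c(1e5, 2e5, 3e5); n <- c(2, 1, 3)
  rHand <- sum((l - mean(l)) * (n - mean(n))) /
    sqrt(sum((l - mean(l))^2) * sum((n - mean(n))^2))
  expect_equal(cd2$r, rHand)
  # fewer than 3 chromosomes: counts only
  cd3 <- chromosomeDensity(mkN(5, "chr1", 1e5), c(chr1 = 1e5))
  expect_true(is.na(cd3$r))
  expect_equal(cd3$table$count, 5L)
})
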