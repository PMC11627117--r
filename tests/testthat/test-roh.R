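test_that("allele frequencies carry a single pseudocount each way", {
  x <- makeTable(matrix(1L, 1, 5))            # 5 samples, all het
  expect_equal(estimateAlleleFreqs(x), (5 + 1) / (10 + 2))
  x0 <- makeTable(matrix(0L, 1, 5))           # all hom-ref: 10 of 10 ref
  expect_equal(estimateAlleleFreqs(x0), 11 / 12)
  x2 <- makeTable(matrix(2L, 1, 5))
  expect_equal(estimateAlleleFreqs(x2), 1 / 12)
  expect_true(all(estimateAlleleFreqs(x0) > 0 & estimateAlleleFreqs(x0) < 1))
})

test_that("a site with no called genotypes is an error for frequencies", {
  x <- makeTable(matrix(NA_integer_, 1, 3))
  expect_error(estimateAlleleFreqs(x), "zero called")
})

test_that("heterozygote LOD is log10(eps) regardless of frequency", {
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(genotypeLod(1L, p, 0.1), -1)
})

test_that("hom-ref LOD matches hand arithmetic", {
  # p = 0.5, eps = 0.001: log10((0.999*0.5 + 0.001*0.25) / 0.25)
  expect_equal(genotypeLod(0L, 0.5, 0.001),
               log10((0.999 * 0.5 + 0.001 * 0.25) / 0.25),
               tolerance = 1e-12)
  expect_equal(round(genotypeLod(0L, 0.5, 0.001), 4), 0.3008)
})

test_that("hom-alt LOD grows as the alt allele gets rarer", {
  qs <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  scores <- genotypeLod(2L, 1 - qs, 0.01)
  expect_true(all(diff(scores) > 0))
  # brute-force evaluation of the declared emission model
  brute <- vapply(qs, function(q) {
    log10(((1 - 0.01) * q + 0.01 * q^2) / q^2)
  }, numeric(1))
  expect_equal(scores, brute, tolerance = 1e-12)
})

test_that("invalid model inputs are rejected", {
  expect_error(genotypeLod(0L, 1, 0.01), "strictly in")
  expect_error(genotypeLod(0L, 0.5, 0), "eps")
  expect_error(genotypeLod(0L, 0.5, 0.3), "eps")
})

test_that("window scores equal a brute-force per-SNP summation oracle", {
  set.seed(10)
  n <- 260
  d <- matrix(sample(c(0:2, NA), n * 2, TRUE, prob = c(.4, .25, .25, .1)),
              n, 2)
  d[rowSums(is.na(d)) == 2, 1] <- 1L  # keep >= 1 called genotype per site
  colnames(d) <- c("s01", "s02")
  GQ <- matrix(sample(10:99, n * 2, TRUE), n, 2)
  x <- makeTable(d, GQ = GQ,
                 chrom = rep(c("chr1", "chr2"), c(200, 60)),
                 pos = c(sort(sample.int(3e6, 200)),
                         sort(sample.int(1e6, 60))))
  p <- estimateAlleleFreqs(x)
  expect_warning(ws <- windowScores(x, p, winsize = 100L), "fewer than")
  # chr2 (60 SNPs) yields no windows; chr1 yields 101 per sample
  expect_equal(nrow(ws), 2 * 101)
  eps <- pmin(pmax(10^(-GQ / 10), 1e-6), 0.25)
  for (r in c(1, 57, 202)) {
    row <- ws[r, ]
    j <- match(row$sample, colnames(d))
    idx <- which(rep(c("chr1", "chr2"), c(200, 60)) == row$chrom)
    tot <- 0
    for (i in seq(row$first, row$last)) {
      ii <- idx[i]
      if (!is.na(d[ii, j]))
        tot <- tot + genotypeLod(d[ii, j], p[ii], eps[ii, j])
    }
    expect_equal(row$score, tot, tolerance = 1e-9)
  }
})

test_that("an all-missing window scores zero and 100 hets score -100", {
  d <- cbind(c(rep(NA_integer_, 100), rep(1L, 100)))
  GQ <- matrix(10L, 200, 1)  # eps = 0.1 -> het LOD -1
  x <- makeTable(d, GQ = GQ, pos = sort(sample.int(3e6, 200)))
  ws <- windowScores(x, p = rep(0.5, 200), winsize = 100L)
  expect_equal(ws$score[1], 0)
  expect_equal(ws$score[101], -100)
})

test_that("the KDE threshold lands in the valley of a bimodal mixture", {
  set.seed(2)
  scores <- c(rnorm(3000, -30, 5), rnorm(3000, 30, 5))
  thr <- selectThreshold(scores)
  expect_gt(thr, -10); expect_lt(thr, 10)
  # invariant to shuffling window order
  expect_equal(selectThreshold(sample(scores)), thr)
})

test_that("degenerate or scant score sets fall back to threshold zero", {
  expect_equal(selectThreshold(rep(3.7, 500)), 0)
  expect_warning(thr <- selectThreshold(rnorm(50)), "fewer than")
  expect_equal(thr, 0)
  set.seed(3)
  expect_equal(selectThreshold(rnorm(5000)), 0)  # unimodal
})

test_that("no passing window yields no segments", {
  seg <- assembleRohSegments(pos = seq(1e5, 1e7, 1e5), lod = rep(-1, 100),
                             winScore = rep(-50, 1), threshold = 0)
  expect_length(seg, 0L)
})

test_that("segment classification uses half-open bounds at exactly 1 Mb", {
  # construct 150 SNPs spanning exactly 1,000,000 bp, all strongly autozygous
  pos <- as.integer(seq(2000001, 3000000, length.out = 150))
  lod <- rep(0.5, 150)
  win <- rep(10, 51)
  seg <- assembleRohSegments(pos, lod, win, threshold = 0, winsize = 100L,
                             minLen = 5e5, sample = "s", chrom = "chr1")
  expect_length(seg, 1L)
  expect_equal(width(seg), 1000000L)
  expect_equal(S4Vectors::mcols(seg)$sizeClass, "[1,2)")
})

test_that("a planted 3 Mb tract is recovered with tight boundaries", {
  cfg <- simConfig(seed = 17,
                   species = list(list(label = "spA", n = 7L)),
                   chromMap = ChromosomeMap("chr1", 30e6),
                   snpDensity = 100)
  sim <- simulateCohort(cfg)
  # plant a fixed 3 Mb tract by hand for exact truth
  x <- sim$genotypes
  pos <- start(rowRanges(x))
  inT <- pos >= 1e7 & pos <= 1.3e7 - 1
  d <- dosages(x)
  set.seed(18)
  q <- 1 - estimateAlleleFreqs(subsetSpecies(x, "spA"))
  d[inT, 1] <- 2L * rbinom(sum(inT), 1, q[inT])
  SummarizedExperiment::assay(x, "dosage") <- d
  roh <- callRoh(x)
  seg <- as.data.frame(roh$segments)
  seg <- seg[seg$sample == sampleNames(x)[1], ]
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$sizeClass, "[3,4)")
  # boundaries within 100 SNPs (~1 Mb at this density) of truth
  expect_lt(abs(seg$start - 1e7), 1e6)
  expect_lt(abs(seg$end - (1.3e7 - 1)), 1e6)
  # and recovery is near-complete
  expect_gt(bpOverlap(seg$start, seg$end, 1e7, 1.3e7 - 1) / 3e6, 0.9)
})

test_that("detection is deterministic for fixed input", {
  cfg <- simConfig(seed = 23, species = list(list(label = "spA", n = 5L)),
                   chromMap = ChromosomeMap("chr1", 20e6),
                   snpDensity = 100,
                   tracts = data.frame(species = "spA", sampleIndex = 1L,
                                       chrom = "chr1", g = 8, count = 1L))
  sim <- simulateCohort(cfg)
  a <- callRoh(sim$genotypes)
  b <- callRoh(sim$genotypes)
  expect_identical(as.data.frame(a$segments), as.data.frame(b$segments))
  expect_identical(a$thresholds, b$thresholds)
})

test_that("rohSummary accounts per size class and computes F_ROH", {
  cm <- ChromosomeMap(c("chr1", "chr2"), c(6e7, 4e7))
  seg <- rohSegments(sample = c("s1", "s1", "s2"),
                     chrom = c("chr1", "chr2", "chr1"),
                     start = c(1L, 1L, 1L),
                     end = c(2e6, 6e5, 55e5))
  out <- rohSummary(seg, c("s1", "s2", "s3"), cm)
  expect_equal(out$NROH, c(2L, 1L, 0L))
  expect_equal(out$SROH, c(2e6 + 6e5, 55e5, 0))
  expect_equal(out$`NROH_[2,3)`, c(1L, 0L, 0L))
  expect_equal(out$`NROH_[5,Inf)`, c(0L, 1L, 0L))
  expect_equal(out$FROH, c(2.6e6, 5.5e6, 0) / 1e8)
  # per-class counts sum to the overall count
  classCols <- grep("^NROH_", names(out))
  expect_equal(unname(rowSums(out[, classCols])), as.numeric(out$NROH))
})
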