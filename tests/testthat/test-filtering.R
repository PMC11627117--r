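test_that("depth bounds use the nearest-rank percentile definition", {
  x <- makeTable(matrix(c(0L, 1L), 10, 2), siteDP = seq(10L, 100L, 10L))
  expect_equal(computeDepthBounds(x, 5, 95), c(10L, 100L))
  xc <- makeTable(matrix(1L, 4, 2), siteDP = rep(37L, 4))
  expect_equal(computeDepthBounds(xc, 5, 95), c(37L, 37L))
})

test_that("depth bounds equal an independent sort-and-index oracle", {
  set.seed(1)
  dp <- sample(100:600, 1000, replace = TRUE)
  x <- makeTable(matrix(1L, 1000, 2), siteDP = dp)
  got <- computeDepthBounds(x, 5, 95)
  s <- sort(dp)
  expect_equal(got, c(s[ceiling(0.05 * 1000)], s[ceiling(0.95 * 1000)]))
})

test_that("site filters apply the strict QUAL and biallelic-SNV rules", {
  x <- makeTable(matrix(c(0L, 1L), 5, 2),
                 qual = c(51, 50, 49, 300, 300),
                 alt = c("T", "T", "T", "T,C", "TA"),
                 siteDP = rep(300L, 5))
  res <- filterSites(x, filterParams(depthBounds = c(1, 1e9),
                                     dropNonAutosomes = FALSE))
  # kept: site 1 only (2 fails QUAL==50 strictly, 3 fails QUAL,
  # 4 is multi-allelic, 5 is an indel-like record)
  expect_equal(nrow(res$table), 1L)
  expect_equal(unname(siteQual(res$table)), 51)
  rep <- res$report
  expect_equal(rep$removed[rep$filter == "non_snv_or_multiallelic"], 2L)
  expect_equal(rep$removed[rep$filter == "site_qual"], 2L)
})

test_that("non-autosomes are removed first", {
  cm <- ChromosomeMap(c("chr1", "chrZ"), c(1e6, 1e6), c(TRUE, FALSE))
  x <- makeTable(matrix(c(0L, 1L), 4, 2),
                 chrom = c("chr1", "chr1", "chrZ", "chrZ"),
                 pos = c(100L, 200L, 100L, 200L))
  res <- filterSites(x, filterParams(depthBounds = c(1, 1e9)), cm)
  expect_equal(unique(as.character(seqnames(rowRanges(res$table)))), "chr1")
  expect_equal(res$report$removed[res$report$filter == "non_autosome"], 2L)
})

test_that("excess-het thresholds act per species at the documented counts", {
  # spA has 5 samples, spB has 7: thresholds 4 and 6
  nA <- 5; nB <- 7
  mk <- function(hetsA, hetsB) {
    row <- c(rep(1L, hetsA), rep(0L, nA - hetsA),
             rep(1L, hetsB), rep(0L, nB - hetsB))
    makeTable(matrix(row, 1, nA + nB),
              species = rep(c("spA", "spB"), c(nA, nB)))
  }
  keep <- function(x) nrow(filterExcessHet(x)$table)
  expect_equal(keep(mk(4, 0)), 0L)  # 4 hets at n=5: removed
  expect_equal(keep(mk(3, 5)), 1L)  # below both thresholds: kept
  expect_equal(keep(mk(0, 6)), 0L)  # 6 hets at n=7: removed
  expect_equal(keep(mk(0, 5)), 1L)
})

test_that("a species without a threshold is an error", {
  x <- makeTable(matrix(1L, 2, 3), species = c("spA", "spA", "spB"))
  expect_error(filterExcessHet(x, hetThresholds = c(spA = 4L)),
               "no excess-het threshold")
})

test_that("generic het threshold defaults follow the cohort size", {
  expect_equal(defaultHetThreshold(c(5L, 7L, 10L)), c(4L, 6L, 8L))
})

test_that("genotype DP/GQ masking precedes the missingness count", {
  d <- matrix(1L, 3, 4)
  DP <- matrix(20L, 3, 4)
  GQ <- matrix(40L, 3, 4)
  DP[1, 1:3] <- c(5L, 35L, 20L)   # two DP violations at site 1
  GQ[1, 3] <- 19L                 # plus one GQ violation -> 3 missing
  DP[2, 1] <- 6L; DP[2, 2] <- 34L # boundary values are kept
  x <- makeTable(d, DP = DP, GQ = GQ)
  res <- filterGenotypesAndMissingness(
    x, filterParams(dropMonomorphic = FALSE))
  expect_equal(nrow(res$table), 2L)  # site 1 hits >= 3 missing
  rep <- res$report
  expect_equal(rep$removed[rep$filter == "genotype_dp_gq"], 3L)
  expect_equal(rep$removed[rep$filter == "site_missingness"], 1L)
})

test_that("sites monomorphic after masking are removed", {
  # all called genotypes hom-ref once the single alt carrier is masked
  d <- matrix(c(1L, 0L, 0L, 0L), 1, 4)
  DP <- matrix(c(5L, 20L, 20L, 20L), 1, 4)
  x <- makeTable(d, DP = DP)
  res <- filterGenotypesAndMissingness(x, filterParams())
  expect_equal(nrow(res$table), 0L)
  expect_equal(res$report$removed[res$report$filter == "monomorphic"], 1L)
})

test_that("filter accounting reconstructs input minus output and is idempotent", {
  set.seed(7)
  cfg <- simConfig(seed = 7,
                   species = list(list(label = "spA", n = 5L),
                                  list(label = "spB", n = 7L)),
                   chromMap = ChromosomeMap("chr1", 10e6),
                   snpDensity = 80)
  sim <- simulateCohort(cfg)
  params <- filterParams(depthBounds = c(180, 300))
  res <- filterPipeline(sim$genotypes, params, cfg$chromMap)
  rep <- res$report
  siteRemovals <- sum(rep$removed[rep$unit == "site"])
  expect_equal(attr(rep, "inputSites") - siteRemovals,
               attr(rep, "outputSites"))
  expect_equal(nrow(res$table), attr(rep, "outputSites"))
  # a second pass with the same explicit parameters removes nothing
  res2 <- filterPipeline(res$table, params, cfg$chromMap)
  expect_equal(nrow(res2$table), nrow(res$table))
  expect_equal(sum(res2$report$removed), 0L)
})

test_that("survivors of a seeded-violation fixture match a brute-force oracle", {
  set.seed(123)
  nSites <- 200; nA <- 5; nB <- 7; n <- nA + nB
  species <- rep(c("spA", "spB"), c(nA, nB))
  chrom <- rep(c("chr1", "chrZ"), c(170, 30))
  pos <- c(sort(sample.int(9e6, 170)), sort(sample.int(9e6, 30)))
  qual <- sample(c(20, 50, 51, 400, 800), nSites, TRUE)
  alt <- sample(c("T", "T", "T", "T,C", "TAG"), nSites, TRUE)
  siteDP <- sample(150:450, nSites, TRUE)
  dosage <- matrix(sample(0:2, nSites * n, TRUE, prob = c(.45, .3, .25)),
                   nSites, n)
  DP <- matrix(sample(c(3:45), nSites * n, TRUE), nSites, n)
  GQ <- matrix(sample(5:99, nSites * n, TRUE), nSites, n)
  x <- makeTable(dosage, chrom = chrom, pos = pos, species = species,
                 qual = qual, siteDP = siteDP, DP = DP, GQ = GQ,
                 alt = alt)
  cm <- ChromosomeMap(c("chr1", "chrZ"), c(1e7, 1e7), c(TRUE, FALSE))
  bounds <- c(200, 400)
  res <- filterPipeline(x, filterParams(depthBounds = bounds), cm)

  # independent per-site rule evaluation, one site at a time
  surviving <- 0L
  for (i in seq_len(nSites)) {
    if (chrom[i] == "chrZ") next
    if (grepl(",", alt[i]) || nchar(alt[i]) > 1) next
    if (!(qual[i] > 50)) next
    if (siteDP[i] < bounds[1] || siteDP[i] > bounds[2]) next
    hetsA <- sum(dosage[i, species == "spA"] == 1)
    hetsB <- sum(dosage[i, species == "spB"] == 1)
    if (hetsA >= 4 || hetsB >= 6) next
    g <- dosage[i, ]
    g[DP[i, ] < 6 | DP[i, ] > 34 | GQ[i, ] < 20] <- NA
    if (sum(is.na(g)) >= 3) next
    called <- g[!is.na(g)]
    if (length(called) == 0 || sum(called) == 0 ||
        sum(called) == 2 * length(called)) next
    surviving <- surviving + 1L
  }
  expect_equal(nrow(res$table), surviving)
})
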