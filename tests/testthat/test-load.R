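test_that("annotation collapse follows the severity hierarchy and effect rules", {
  r <- collapseAnnotation(c("synonymous", "nonsynonymous"),
                          c("tolerated", "deleterious"))
  expect_equal(r$consequence, "nonsynonymous")
  expect_equal(r$effect, "deleterious")

  # LOF without a prediction + tolerated synonymous transcript:
  # consequence collapses to LOF, effect follows the predicted transcripts
  r <- collapseAnnotation(c("stop-gain", "synonymous"),
                          c("absent", "tolerated"))
  expect_equal(r$consequence, "LOF")
  expect_equal(r$effect, "tolerated")
  expect_true(r$conflict)

  r <- collapseAnnotation("synonymous", "tolerated")
  expect_equal(r$consequence, "synonymous")
  expect_equal(r$effect, "tolerated")
  expect_false(r$conflict)

  r <- collapseAnnotation(c("start-lost", "stop-loss"), c("absent", "absent"))
  expect_equal(r$consequence, "LOF")
  expect_equal(r$effect, "none")

  r <- collapseAnnotation("noncoding", "absent")
  expect_true(r$excluded)
})

test_that("collapse is idempotent and order-invariant", {
  set.seed(6)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    cons <- sample(c("synonymous", "nonsynonymous", "stop-gain",
                     "stop-loss", "start-lost"), k, TRUE)
    pred <- sample(c("deleterious", "tolerated", "absent"), k, TRUE)
    a <- collapseAnnotation(cons, pred)
    perm <- sample(k)
    b <- collapseAnnotation(cons[perm], pred[perm])
    expect_identical(a, b)
    # idempotence: collapsing the collapsed single pair changes nothing
    predSelf <- if (a$effect == "none") "absent" else a$effect
    consSelf <- if (a$consequence == "LOF") "stop-gain" else a$consequence
    c2 <- collapseAnnotation(consSelf, predSelf)
    expect_equal(c2$consequence, a$consequence)
    expect_equal(c2$effect, a$effect)
  }
})

test_that("load counts equal a per-cell hand tally on a 4-site fixture", {
  # sites:            s1        s2        s3        s4
  # consequence:      syn/del   nonsyn/tol LOF/del  syn/none
  # sampleA dosage:   1         2          0        2
  # sampleB dosage:   2         1          1        NA
  d <- matrix(c(1L, 2L,
                2L, 1L,
                0L, 1L,
                2L, NA), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("sampleA", "sampleB")))
  x <- makeTable(d, pos = c(100L, 200L, 300L, 400L),
                 alt = c("T", "T", "T", "T"))
  ann <- AnnotationTable(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L), alt = "T",
    transcript = "t1",
    consequence = c("synonymous", "nonsynonymous", "stop-gain",
                    "synonymous"),
    prediction = c("deleterious", "tolerated", "deleterious", "absent")))
  collapsed <- collapseAnnotations(ann)
  counts <- loadCounts(x, collapsed, scope = "all")
  pick <- function(s, ct, cl, col)
    counts[counts$sample == s & counts$classType == ct &
             counts$class == cl, col]
  expect_equal(pick("sampleA", "consequence", "synonymous", "nHet"), 1L)
  expect_equal(pick("sampleA", "consequence", "synonymous", "nHomAlt"), 1L)
  expect_equal(pick("sampleB", "consequence", "synonymous", "nHomAlt"), 1L)
  expect_equal(pick("sampleB", "consequence", "synonymous", "nCalled"), 1L)
  expect_equal(pick("sampleA", "consequence", "LOF", "nHet"), 0L)
  expect_equal(pick("sampleB", "consequence", "LOF", "nHet"), 1L)
  expect_equal(pick("sampleA", "effect", "deleterious", "nHet"), 1L)
  # sampleA's dosage-2 genotype sits at the effect-"none" site, so no
  # deleterious alt-homozygote is counted
  expect_equal(pick("sampleA", "effect", "deleterious", "nHomAlt"), 0L)
  expect_equal(pick("sampleB", "effect", "tolerated", "nHet"), 1L)
  # site 4 (effect none) contributes to no effect class
  expect_equal(sum(counts$nCalled[counts$classType == "effect" &
                                    counts$sample == "sampleA"]), 3L)
})

test_that("all-hom-ref genotypes give zero load counts", {
  d <- matrix(0L, 3, 2)
  x <- makeTable(d, pos = c(10L, 20L, 30L))
  ann <- AnnotationTable(data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L), alt = "T", transcript = "t1",
    consequence = "nonsynonymous", prediction = "deleterious"))
  counts <- loadCounts(x, collapseAnnotations(ann), scope = "all")
  expect_true(all(counts$nHet == 0L & counts$nHomAlt == 0L))
})

test_that("deleterious proportions are simple ratios of the counts", {
  counts <- data.frame(
    sample = "s1", species = "spA", classType = "effect",
    class = c("deleterious", "tolerated"),
    nHet = c(2L, 8L), nHomAlt = c(1L, 4L), nCalled = c(20L, 60L))
  pr <- loadProportions(counts)
  expect_equal(pr$propHetDel, 0.2)
  expect_equal(pr$propHomAltDel, 1 / 5)
  expect_equal(pr$propAltDel, (2 + 2) / (2 + 2 + 8 + 8))
})

test_that("exact Mann-Whitney matches the 20-assignment enumeration", {
  r <- mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
})

test_that("identical samples give p = 1", {
  r <- mannWhitneyExact(c(3, 1, 2), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_equal(mannWhitneyExact(rep(2, 4), rep(2, 3))$p, 1)
})

test_that("exact p-values match the independent enumeration oracle at 7v7", {
  set.seed(11)
  for (rep_i in 1:3) {
    x <- round(rnorm(7), 1)
    y <- round(rnorm(7, 0.5), 1)
    got <- mannWhitneyExact(x, y)
    want <- mwuOracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p)
  }
})

test_that("the exact branch agrees with wilcox.test when there are no ties", {
  set.seed(12)
  x <- rnorm(6); y <- rnorm(8)
  got <- mannWhitneyExact(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("private alternate alleles require observed absence elsewhere", {
  # 3 species; site rows explained inline
  d <- matrix(c(
    1L, 0L, 0L, 0L, 0L, 0L,   # alt only in spA: private to spA
    1L, 0L, 2L, 0L, 0L, 0L,   # alt in spA and spB: not private
    0L, 1L, NA, NA, 0L, 0L,   # spB all missing: excluded
    0L, 0L, 0L, 2L, 0L, 1L),  # alt in spB and spC: not private
    4, 6, byrow = TRUE,
    dimnames = list(NULL, paste0("s", 1:6)))
  x <- makeTable(d, pos = c(10L, 20L, 30L, 40L),
                 species = c("spA", "spA", "spB", "spB", "spC", "spC"))
  priv <- privateAltSites(x)
  expect_equal(nrow(priv), 1L)
  expect_equal(priv$species, "spA")
  expect_equal(priv$derivedCount, 1L)
  expect_equal(priv$calledHaploid, 4L)
})

test_that("SFS projection is the identity at M = N and conserves mass", {
  out <- projectSfs(3L, 14L, M = 14L)
  expect_equal(out$mass[out$j == 3], 1)
  expect_equal(sum(out$mass), 1)
  out2 <- projectSfs(1L, 4L, M = 2L)
  expect_equal(out2$mass, c(1 / 2, 1 / 2, 0))
  set.seed(14)
  i <- sample(0:10, 50, TRUE); N <- pmax(i, sample(8:12, 50, TRUE))
  out3 <- projectSfs(i, N, M = 6L)
  used <- attr(out3, "nSitesUsed")
  expect_lt(abs(sum(out3$mass) - used), 1e-12)
})

test_that("projection equals exhaustive subset enumeration for small N", {
  for (N in 4:8) {
    for (M in 2:4) {
      for (i in 0:N) {
        got <- projectSfs(i, N, M)$mass
        # oracle: enumerate all choose(N, M) haploid subsets directly
        subsets <- utils::combn(N, M)
        derived <- seq_len(N) <= i   # i derived haploids, N - i ancestral
        cnt <- apply(subsets, 2, function(s) sum(derived[s]))
        oracle <- vapply(0:M, function(j) mean(cnt == j), numeric(1))
        expect_equal(got, oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("sites below the projection size are dropped, empty set errors", {
  out <- projectSfs(c(1L, 2L), c(4L, 10L), M = 6L)
  expect_equal(attr(out, "nSitesDropped"), 1L)
  expect_error(projectSfs(1L, 4L, M = 6L), "haploid size")
})

test_that("a species with elevated deleterious homozygosity is flagged", {
  # power check at the configured cohort sizes: spB gets its deleterious
  # alternate alleles pushed toward fixation
  cfg <- simConfig(seed = 41,
                   species = list(list(label = "spA", n = 7L),
                                  list(label = "spB", n = 7L)),
                   chromMap = ChromosomeMap("chr1", 12e6),
                   snpDensity = 250,
                   delFreqShift = c(spA = 0, spB = 0.55))
  sim <- simulateCohort(cfg)
  collapsed <- collapseAnnotations(sim$annotations)
  counts <- loadCounts(sim$genotypes, collapsed, scope = "polymorphic")
  props <- loadProportions(counts)
  a <- props$propHomAltDel[props$species == "spA"]
  b <- props$propHomAltDel[props$species == "spB"]
  expect_gt(mean(b), mean(a))
  expect_lt(mannWhitneyExact(a, b)$p, 0.05)
})
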