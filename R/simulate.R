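#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate
#' the study design the package targets: three warbler-like cohorts of 7, 5
#' and 7 diploid individuals, ~100 SNPs/Mb, alternate-allele frequencies
#' from a truncated Beta(0.2, 0.2) (a neutral-ish SFS), per-genotype
#' depth/quality noise at ~20x coverage, and SIFT4G-style annotation classes
#' with roughly 16% of predicted coding sites deleterious.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param species List of per-cohort specs: `list(label, n)`.
#' @param chromMap A [ChromosomeMap-class]; defaults to three 30-Mb
#'   autosomes.
#' @param snpDensity Target SNP density per Mb.
#' @param freqShape Length-2 Beta parameters of the alternate-allele
#'   frequency law (truncated to (0, 1)).
#' @param privateFrac Named (by species label) fraction of sites whose
#'   alternate allele is private to that species.
#' @param tracts Planted autozygous tracts: a data frame with columns
#'   `species`, `sampleIndex`, `chrom`, `g` (generations to the tract's
#'   common ancestor) and `count`. Tract physical length is drawn as
#'   Exponential with mean `100/(2g)` cM, converted to bp at the
#'   chromosome's size-binned cM/Mb rate (see [rateForChromosome()]).
#' @param errorModel `list(meanDP, dpSize, gqShape, gqScale)`: genotype DP is
#'   negative binomial (`mu = meanDP`, `size = dpSize`); GQ is a discretised
#'   Gamma capped at 99.
#' @param annotationSpec Class fractions for the annotation table; see
#'   Details.
#' @param delFreqShift Named (by species) push of deleterious-site alternate
#'   frequencies toward fixation, `q' = q + shift * (1 - q)`; default 0.
#' @param minTractSnps Minimum number of SNPs a planted tract must span.
#'
#' @details `annotationSpec` fields: `fracAnnotated` (fraction of sites with
#' an annotation record), `fracSyn`/`fracNonsyn`/`fracLof` (consequence mix
#' among coding records, summing to 1), `fracNoncoding` (annotated rows that
#' are noncoding, flagged for exclusion downstream), `pDelSyn`/`pDelNonsyn`/
#' `pDelLof` (probability a predicted transcript is deleterious, by
#' consequence), `pAbsentCoding`/`pAbsentLof` (probability a transcript
#' carries no prediction).
#'
#' @return A list of class `"SimulationConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      species = list(list(label = "sp1", n = 7L),
                                     list(label = "sp2", n = 5L),
                                     list(label = "sp3", n = 7L)),
                      chromMap = ChromosomeMap(paste0("chr", 1:3),
                                               rep(30e6, 3)),
                      snpDensity = 100,
                      freqShape = c(0.2, 0.2),
                      privateFrac = NULL,
                      tracts = NULL,
                      errorModel = list(meanDP = 20, dpSize = 10,
                                        gqShape = 9, gqScale = 5),
                      annotationSpec = list(fracAnnotated = 0.3,
                                            fracSyn = 0.61, fracNonsyn = 0.38,
                                            fracLof = 0.01,
                                            fracNoncoding = 0.05,
                                            pDelSyn = 0.02, pDelNonsyn = 0.386,
                                            pDelLof = 1, pAbsentCoding = 0.03,
                                            pAbsentLof = 0.8),
                      delFreqShift = NULL,
                      minTractSnps = 10L) {
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("species labels must be unique")
  if (is.null(privateFrac))
    privateFrac <- stats::setNames(rep(0.15, length(labels)), labels)
  if (is.null(delFreqShift))
    delFreqShift <- stats::setNames(rep(0, length(labels)), labels)
  if (any(privateFrac < 0) || sum(privateFrac) > 1)
    stop("privateFrac entries must be >= 0 and sum to <= 1")
  a <- annotationSpec
  if (abs(a$fracSyn + a$fracNonsyn + a$fracLof - 1) > 1e-8)
    stop("fracSyn + fracNonsyn + fracLof must sum to 1")
  if (!is.null(tracts)) {
    tracts <- as.data.frame(tracts)
    lens <- chromLengths(chromMap)[tracts$chrom]
    if (anyNA(lens)) stop("tract chromosome not in chromosome map")
    meanBp <- 100 / (2 * tracts$g) /
      rateForChromosome(lens) * 1e6
    if (any(meanBp > lens))
      stop("mean tract length exceeds chromosome length (g too small?)")
  }
  structure(list(seed = as.integer(seed), species = species,
                 chromMap = chromMap, snpDensity = snpDensity,
                 freqShape = freqShape, privateFrac = privateFrac,
                 tracts = tracts, errorModel = errorModel,
                 annotationSpec = annotationSpec,
                 delFreqShift = delFreqShift,
                 minTractSnps = as.integer(minTractSnps)),
            class = "SimulationConfig")
}

.rbetaTrunc <- function(n, shape) {
  q <- stats::rbeta(n, shape[1], shape[2])
  pmin(pmax(q, 0.005), 0.995)
}

#' Plant one autozygous tract into a sample's genotype vector
#'
#' Draws a tract length from Exponential(mean = `100/(2g)` cM) converted to
#' bp at `rateCmMb`, places it uniformly on the chromosome (avoiding
#' `avoid` intervals), and sets every covered site homozygous by copying a
#' single haplotype drawn from the site's alternate-allele frequency.
#' Error injection happens later, from the simulated GQ, so the returned
#' interval is 100% homozygous as constructed.
#'
#' @param dosage Integer dosage vector for the sample on this chromosome.
#' @param pos Site positions (bp) parallel to `dosage`.
#' @param qAlt Alternate-allele frequencies parallel to `dosage`.
#' @param chromLength Chromosome length (bp).
#' @param g Generations to the most recent common ancestor of the two
#'   haplotypes.
#' @param rateCmMb Recombination rate in cM/Mb.
#' @param minSnps Minimum SNPs the tract must cover; the interval is
#'   extended if the drawn length covers fewer.
#' @param avoid Two-column matrix of (start, end) intervals to keep clear.
#' @return `list(dosage, start, end)` with the modified vector and the
#'   planted 1-based inclusive interval.
#' @export
plantRohTract <- function(dosage, pos, qAlt, chromLength, g, rateCmMb,
                          minSnps = 10L, avoid = NULL) {
  stopifnot(g > 0, rateCmMb > 0)
  meanBp <- 100 / (2 * g) / rateCmMb * 1e6
  if (meanBp > chromLength)
    stop("mean tract length exceeds chromosome length")
  for (try in 1:200) {
    len <- max(stats::rexp(1, rate = 1 / meanBp), 1)
    len <- min(len, chromLength - 1)
    start <- floor(stats::runif(1, 1, chromLength - len)) + 0
    end <- min(start + round(len) - 1, chromLength)
    idx <- which(pos >= start & pos <= end)
    if (length(idx) < minSnps) {
      # extend symmetrically in SNP space to reach the floor
      centre <- which.min(abs(pos - (start + end) / 2))
      lo <- max(1L, centre - ceiling(minSnps / 2))
      hi <- min(length(pos), lo + minSnps - 1L)
      lo <- max(1L, hi - minSnps + 1L)
      idx <- lo:hi
      start <- min(start, pos[lo]); end <- max(end, pos[hi])
    }
    overlaps <- !is.null(avoid) && nrow(avoid) > 0 &&
      any(start <= avoid[, 2] & end >= avoid[, 1])
    if (!overlaps) {
      hap <- stats::rbinom(length(idx), 1, qAlt[idx])
      dosage[idx] <- 2L * hap
      return(list(dosage = dosage, start = as.integer(start),
                  end = as.integer(end)))
    }
  }
  stop("could not place tract without overlap after 200 attempts")
}

#' Simulate a multi-species genotype cohort with planted ground truth
#'
#' Generates a [GenotypeTable-class], a matching annotation table and a
#' truth set. Outside planted tracts genotypes are Hardy-Weinberg draws from
#' per-species alternate-allele frequencies; inside a planted tract the two
#' haplotypes are copies of one draw (fully homozygous), later flipped to
#' heterozygous with probability `10^(-GQ/10)` from that genotype's
#' simulated GQ. A fraction of sites is private to each species (alternate
#' frequency zero elsewhere).
#'
#' @param config A [simConfig()] object.
#' @return `list(genotypes = GenotypeTable, annotations = AnnotationTable,
#'   truth = list(tracts = data.frame, kinshipPairs = data.frame))`.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  cm <- config$chromMap
  chroms <- chromNames(cm)
  lens <- chromLengths(cm)
  labels <- vapply(config$species, `[[`, character(1), "label")
  ns <- as.integer(vapply(config$species, function(s) as.numeric(s$n),
                          numeric(1)))
  samples <- unlist(lapply(seq_along(labels), function(i)
    sprintf("%s_%02d", labels[i], seq_len(ns[i]))))
  speciesOfSample <- rep(labels, ns)
  nSamp <- length(samples)

  # Candidate sites are oversampled, genotyped, and conditioned on being
  # segregating in the joint cohort: the configured density targets SNPs
  # (sites that are actually polymorphic), as in a variant-only VCF.
  targetL <- vapply(chroms, function(ch)
    max(as.integer(round(config$snpDensity * lens[ch] / 1e6)), 1L),
    integer(1))
  posL <- lapply(chroms, function(ch)
    sort(sample.int(lens[ch] - 1L,
                    min(3L * max(as.integer(round(config$snpDensity *
                                                    lens[ch] / 1e6)), 1L),
                        lens[ch] - 1L))))
  chromOf <- rep(chroms, lengths(posL))
  pos <- unlist(posL, use.names = FALSE)
  nCand <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nCand, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1)))

  # private-allele ownership, then per-species alternate frequencies
  owner <- sample(c(labels, NA), nCand, replace = TRUE,
                  prob = c(config$privateFrac, 1 - sum(config$privateFrac)))
  qMat <- matrix(0, nCand, length(labels), dimnames = list(NULL, labels))
  for (s in labels) {
    shared <- is.na(owner)
    qMat[shared, s] <- .rbetaTrunc(sum(shared), config$freqShape)
    mine <- !is.na(owner) & owner == s
    qMat[mine, s] <- .rbetaTrunc(sum(mine), config$freqShape)
  }

  # Hardy-Weinberg genotypes, then keep target counts of segregating sites
  dosage <- matrix(0L, nCand, nSamp, dimnames = list(NULL, samples))
  for (j in seq_len(nSamp))
    dosage[, j] <- stats::rbinom(nCand, 2L, qMat[, speciesOfSample[j]])
  altSum <- rowSums(dosage)
  poly <- altSum > 0L & altSum < 2L * nSamp
  keep <- logical(nCand)
  for (ci in seq_along(chroms)) {
    onChr <- which(chromOf == chroms[ci] & poly)
    if (length(onChr) > targetL[ci])
      onChr <- sort(sample(onChr, targetL[ci]))
    keep[onChr] <- TRUE
  }
  chromOf <- chromOf[keep]; pos <- pos[keep]; ref <- ref[keep]
  alt <- alt[keep]; owner <- owner[keep]
  qMat <- qMat[keep, , drop = FALSE]
  dosage <- dosage[keep, , drop = FALSE]
  nSites <- length(pos)

  # annotations on the retained sites
  ann <- .simulateAnnotations(chromOf, pos, alt, config$annotationSpec)
  isDel <- rep(FALSE, nSites)
  if (nrow(ann)) {
    delKeys <- unique(ann$key[ann$prediction == "deleterious"])
    isDel[paste(chromOf, pos, alt, sep = ":") %in% delKeys] <- TRUE
  }
  # optional per-species push of deleterious alternate alleles toward
  # fixation: shift the frequency and redraw those genotypes
  for (s in labels) {
    sh <- config$delFreqShift[[s]]
    if (!is.null(sh) && sh > 0) {
      shiftable <- which(isDel & qMat[, s] > 0)
      qMat[shiftable, s] <- qMat[shiftable, s] +
        sh * (1 - qMat[shiftable, s])
      for (j in which(speciesOfSample == s))
        dosage[shiftable, j] <- stats::rbinom(length(shiftable), 2L,
                                              qMat[shiftable, s])
    }
  }

  # plant tracts
  truthTracts <- data.frame(sample = character(), chrom = character(),
                            start = integer(), end = integer(),
                            g = numeric())
  if (!is.null(config$tracts)) {
    tr <- config$tracts
    for (k in seq_len(nrow(tr))) {
      lab <- tr$species[k]
      sampIdx <- which(speciesOfSample == lab)[tr$sampleIndex[k]]
      if (is.na(sampIdx)) stop("tract sampleIndex out of range for ", lab)
      ch <- tr$chrom[k]
      onChr <- which(chromOf == ch)
      rate <- rateForChromosome(lens[ch])
      for (rep_i in seq_len(tr$count[k])) {
        avoid <- as.matrix(truthTracts[truthTracts$sample == samples[sampIdx] &
                                         truthTracts$chrom == ch,
                                       c("start", "end")])
        res <- plantRohTract(dosage[onChr, sampIdx], pos[onChr],
                             qMat[onChr, lab], lens[ch], tr$g[k], rate,
                             minSnps = config$minTractSnps, avoid = avoid)
        dosage[onChr, sampIdx] <- res$dosage
        truthTracts <- rbind(truthTracts,
                             data.frame(sample = samples[sampIdx], chrom = ch,
                                        start = res$start, end = res$end,
                                        g = tr$g[k]))
      }
    }
  }

  # depth / quality noise, then GQ-driven heterozygote flips inside tracts
  em <- config$errorModel
  DP <- matrix(stats::rnbinom(nSites * nSamp, mu = em$meanDP,
                              size = em$dpSize),
               nSites, nSamp, dimnames = list(NULL, samples))
  GQ <- matrix(pmin(pmax(round(stats::rgamma(nSites * nSamp,
                                             shape = em$gqShape,
                                             scale = em$gqScale)), 1L), 99L),
               nSites, nSamp, dimnames = list(NULL, samples))
  if (nrow(truthTracts)) {
    eps <- pmin(10^(-GQ / 10), 0.25)
    for (k in seq_len(nrow(truthTracts))) {
      j <- match(truthTracts$sample[k], samples)
      idx <- which(chromOf == truthTracts$chrom[k] &
                     pos >= truthTracts$start[k] & pos <= truthTracts$end[k])
      flip <- stats::runif(length(idx)) < eps[idx, j]
      dosage[idx[flip], j] <- 1L
    }
  }

  qual <- round(stats::rgamma(nSites, shape = 2, scale = 300), 1)
  siteDP <- as.integer(rowSums(DP))

  gt <- GenotypeTable(chrom = chromOf, pos = pos, ref = ref, alt = alt,
                      qual = qual, siteDP = siteDP,
                      dosage = dosage, DP = DP, GQ = GQ,
                      samples = samples,
                      species = stats::setNames(speciesOfSample, samples))

  kin <- if (nSamp >= 2) {
    pairs <- utils::combn(samples, 2)
    data.frame(sampleA = pairs[1, ], sampleB = pairs[2, ],
               class = "unrelated", expectedKinship = 0)
  } else data.frame(sampleA = character(), sampleB = character(),
                    class = character(), expectedKinship = numeric())

  list(genotypes = gt, annotations = ann,
       truth = list(tracts = truthTracts, kinshipPairs = kin,
                    siteFreqs = qMat))
}

.simulateAnnotations <- function(chrom, pos, alt, spec) {
  nSites <- length(pos)
  annotated <- which(stats::runif(nSites) < spec$fracAnnotated)
  if (!length(annotated))
    return(AnnotationTable(data.frame(chrom = character(), pos = integer(),
                                      alt = character(),
                                      transcript = character(),
                                      consequence = character(),
                                      prediction = character())))
  nonc <- stats::runif(length(annotated)) < spec$fracNoncoding
  classes <- c("synonymous", "nonsynonymous", "LOF")
  classProb <- c(spec$fracSyn, spec$fracNonsyn, spec$fracLof)
  base <- sample(classes, length(annotated), replace = TRUE,
                 prob = classProb)
  nT <- ifelse(nonc, 1L,
               sample(1:3, length(annotated), replace = TRUE,
                      prob = c(0.7, 0.25, 0.05)))
  siteIdx <- rep(seq_along(annotated), nT)
  isFirst <- unlist(lapply(nT, function(k) c(TRUE, rep(FALSE, k - 1L))),
                    use.names = FALSE)
  nRows <- length(siteIdx)
  # extra transcripts re-draw their consequence with probability 0.3
  rowClass <- base[siteIdx]
  redraw <- !isFirst & stats::runif(nRows) < 0.3
  rowClass[redraw] <- sample(classes, sum(redraw), replace = TRUE,
                             prob = classProb)
  rowClass[nonc[siteIdx]] <- "noncoding"
  cons <- rowClass
  isLof <- rowClass == "LOF"
  cons[isLof] <- sample(c("stop-gain", "stop-loss", "start-lost"),
                        sum(isLof), replace = TRUE,
                        prob = c(0.78, 0.06, 0.16))
  pred <- rep("absent", nRows)
  u1 <- stats::runif(nRows); u2 <- stats::runif(nRows)
  codingRow <- rowClass %in% c("synonymous", "nonsynonymous")
  pDel <- ifelse(rowClass == "synonymous", spec$pDelSyn, spec$pDelNonsyn)
  pred[codingRow] <- ifelse(u1[codingRow] < spec$pAbsentCoding, "absent",
                            ifelse(u2[codingRow] < pDel[codingRow],
                                   "deleterious", "tolerated"))
  pred[isLof] <- ifelse(u1[isLof] < spec$pAbsentLof, "absent",
                        ifelse(u2[isLof] < spec$pDelLof,
                               "deleterious", "tolerated"))
  transcript <- unlist(lapply(nT, function(k) paste0("t", seq_len(k))),
                       use.names = FALSE)
  i <- annotated[siteIdx]
  AnnotationTable(data.frame(chrom = chrom[i], pos = pos[i], alt = alt[i],
                             transcript = transcript, consequence = cons,
                             prediction = pred))
}

#' Simulate a genotype pair of known relatedness
#'
#' Builds two diploid dosage vectors under an explicit identity-by-descent
#' model: `self` duplicates one Hardy-Weinberg draw (kinship 0.5),
#' `parent-offspring` shares exactly one allele IBD per site (0.25),
#' `full-sib` shares 0/1/2 alleles with probability 1/4, 1/2, 1/4 (0.25),
#' `unrelated` shares none (0).
#'
#' @param class One of `"self"`, `"parent-offspring"`, `"full-sib"`,
#'   `"unrelated"`.
#' @param nSites Number of sites.
#' @param freqShape Beta parameters of the allele-frequency law.
#' @param seed RNG seed.
#' @return `list(dosage1, dosage2, expectedKinship)`.
#' @export
simulatePairKinship <- function(class, nSites = 20000L,
                                freqShape = c(0.2, 0.2), seed = 1L) {
  set.seed(seed)
  q <- .rbetaTrunc(nSites, freqShape)
  draw <- function() stats::rbinom(nSites, 1L, q)
  switch(class,
    "self" = {
      g <- draw() + draw()
      list(dosage1 = g, dosage2 = g, expectedKinship = 0.5)
    },
    "parent-offspring" = {
      p1 <- draw(); p2 <- draw()
      pick <- stats::rbinom(nSites, 1L, 0.5)
      shared <- ifelse(pick == 1L, p1, p2)
      list(dosage1 = p1 + p2, dosage2 = shared + draw(),
           expectedKinship = 0.25)
    },
    "full-sib" = {
      f1 <- draw(); f2 <- draw(); m1 <- draw(); m2 <- draw()
      pickF <- function() ifelse(stats::rbinom(nSites, 1L, 0.5) == 1L, f1, f2)
      pickM <- function() ifelse(stats::rbinom(nSites, 1L, 0.5) == 1L, m1, m2)
      list(dosage1 = pickF() + pickM(), dosage2 = pickF() + pickM(),
           expectedKinship = 0.25)
    },
    "unrelated" = list(dosage1 = draw() + draw(), dosage2 = draw() + draw(),
                       expectedKinship = 0),
    stop("unknown relationship class: ", class))
}
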