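#' Per-site reference-allele frequencies with a pseudocount
#'
#' `p = (2 * n_homref + n_het + 1) / (2 * n_called + 2)` — one pseudocount
#' allele each way, so `0 < p < 1` even at sites fixed in the sample.
#'
#' @param x A [GenotypeTable-class], normally one species' polymorphic
#'   table (see [subsetSpecies()]).
#' @return Numeric vector of reference-allele frequencies, one per site.
#' @export
estimateAlleleFreqs <- function(x) {
  d <- dosages(x)
  nCalled <- rowSums(!is.na(d))
  if (any(nCalled == 0))
    stop("site(s) with zero called genotypes: ",
         paste(utils::head(which(nCalled == 0)), collapse = ", "))
  nHomRef <- rowSums(d == 0L, na.rm = TRUE)
  nHet <- rowSums(d == 1L, na.rm = TRUE)
  (2 * nHomRef + nHet + 1) / (2 * nCalled + 2)
}

#' Genotype autozygosity LOD score
#'
#' log10 likelihood ratio of a genotype under the autozygous model versus
#' Hardy-Weinberg. Under autozygosity the two haplotypes are identical by
#' descent, so a heterozygote can only arise through genotyping error
#' `eps`: `P(homref | auto) = (1 - eps) p + eps p^2`,
#' `P(het | auto) = eps 2pq`, `P(homalt | auto) = (1 - eps) q + eps q^2`;
#' under the non-autozygous model the HWE probabilities `p^2, 2pq, q^2`
#' apply.
#'
#' @param dosage Alternate-allele dosage (0, 1, 2); vectorised.
#' @param p Reference-allele frequency in (0, 1).
#' @param eps Genotype error probability in (0, 0.25].
#' @return Numeric LOD score(s); positive favours autozygosity.
#' @export
genotypeLod <- function(dosage, p, eps) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(eps <= 0 | eps > 0.25)) stop("eps must lie in (0, 0.25]")
  n <- max(length(dosage), length(p), length(eps))
  dosage <- rep_len(dosage, n)
  p <- rep_len(p, n)
  eps <- rep_len(eps, n)
  q <- 1 - p
  auto <- ifelse(dosage == 0L, (1 - eps) * p + eps * p^2,
          ifelse(dosage == 1L, eps * 2 * p * q,
                               (1 - eps) * q + eps * q^2))
  hwe <- ifelse(dosage == 0L, p^2,
         ifelse(dosage == 1L, 2 * p * q, q^2))
  log10(auto / hwe)
}

.epsFromGQ <- function(gq) {
  eps <- 10^(-gq / 10)
  eps[is.na(eps)] <- 0.25
  pmin(pmax(eps, 1e-6), 0.25)
}

# sites x samples LOD matrix; missing dosage contributes 0
.lodMatrix <- function(x, p) {
  d <- dosages(x)
  eps <- .epsFromGQ(genoQual(x))
  lod <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    called <- !is.na(d[, j])
    lod[called, j] <- genotypeLod(d[called, j], p[called], eps[called, j])
  }
  lod
}

.rollSum <- function(v, w) {
  cs <- cumsum(c(0, v))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Sliding-window autozygosity scores
#'
#' Sums per-genotype LOD scores over windows of `winsize` consecutive SNPs,
#' stepping one SNP at a time, separately per sample and chromosome.
#' Missing genotypes contribute 0. The per-genotype error is
#' `min(10^(-GQ/10), 0.25)` (floored at 1e-6).
#'
#' @param x A [GenotypeTable-class] (one species).
#' @param p Reference-allele frequencies from [estimateAlleleFreqs()].
#' @param winsize Window size in SNPs.
#' @return A `data.frame` with columns `sample`, `chrom`, `first`, `last`
#'   (SNP indices within the chromosome) and `score`. Chromosomes with
#'   fewer than `winsize` SNPs yield no windows (with a warning).
#' @export
windowScores <- function(x, p = estimateAlleleFreqs(x), winsize = 100L) {
  lod <- .lodMatrix(x, p)
  chrom <- as.character(seqnames(rowRanges(x)))
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < winsize) {
      warning("chromosome ", ch, " has fewer than ", winsize,
              " SNPs; no windows")
      next
    }
    nw <- length(idx) - winsize + 1L
    for (s in colnames(lod)) {
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = ch, first = seq_len(nw),
        last = seq_len(nw) + winsize - 1L,
        score = .rollSum(lod[idx, s], winsize))
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      first = integer(), last = integer(),
                      score = numeric()))
  do.call(rbind, out)
}

#' Kernel-density window-score threshold
#'
#' Fits a Gaussian kernel density (Silverman's rule bandwidth) to the
#' pooled window scores of a species on a 512-point grid. When the density
#' is multimodal, the threshold is the grid position of the minimum density
#' between the two highest-density modes — the valley separating the
#' non-autozygous bulk from autozygous windows. A unimodal density (no
#' autozygous mass to separate) falls back to 0.
#'
#' @param scores Numeric vector of pooled window scores.
#' @param minWindows Fewer scores than this triggers the 0 fallback with a
#'   warning.
#' @return Scalar threshold; windows scoring strictly above it are called
#'   autozygous.
#' @export
selectThreshold <- function(scores, minWindows = 100L) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < minWindows) {
    warning("fewer than ", minWindows, " windows; falling back to threshold 0")
    return(0)
  }
  if (stats::sd(scores) == 0) return(0)
  d <- stats::density(scores, n = 512)
  y <- d$y
  n <- length(y)
  isMax <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]
  modes <- which(isMax) + 1L
  if (length(modes) < 2) return(0)
  top2 <- modes[order(y[modes], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  d$x[valley]
}

.kadane <- function(v) {
  best <- -Inf; bestRange <- c(1L, 1L)
  cur <- 0; curStart <- 1L
  for (i in seq_along(v)) {
    if (cur <= 0) { cur <- v[i]; curStart <- i } else cur <- cur + v[i]
    if (cur > best) { best <- cur; bestRange <- c(curStart, i) }
  }
  list(sum = best, start = bestRange[1], end = bestRange[2])
}

#' Assemble and classify ROH segments for one sample and chromosome
#'
#' A SNP is provisionally autozygous when at least one window covering it
#' scores above the threshold. Maximal runs of autozygous SNPs become
#' candidate segments; each candidate is then trimmed to its
#' maximal-scoring contiguous subsegment of per-SNP LOD, which removes the
#' low-evidence overhang a passing window drags past a tract edge.
#' Segments shorter than `minLen` are discarded; survivors are labelled
#' with the fixed half-open size classes (see [rohSizeClass()]).
#'
#' @param pos SNP positions (bp) on the chromosome.
#' @param lod Per-SNP LOD scores (missing genotypes as 0).
#' @param winScore Window scores from [windowScores()] for this
#'   sample/chromosome.
#' @param threshold Score threshold from [selectThreshold()].
#' @param winsize Window size in SNPs.
#' @param minLen Minimum segment length in bp.
#' @param sample,chrom Labels for the output.
#' @param refine Trim candidates to their maximal-scoring subsegment.
#' @return A `GRanges` of ROH segments (possibly empty).
#' @export
assembleRohSegments <- function(pos, lod, winScore, threshold,
                                winsize = 100L, minLen = 5e5,
                                sample = "sample", chrom = "chrom",
                                refine = TRUE) {
  empty <- rohSegments(character(), character(), integer(), integer())
  nw <- length(winScore)
  if (nw < 1) return(empty)
  pass <- winScore > threshold
  if (!any(pass)) return(empty)
  cp <- cumsum(c(0, pass))
  n <- length(pos)
  i <- seq_len(n)
  j1 <- pmax(i - winsize + 1L, 1L)
  j2 <- pmin(i, nw)
  autoSnp <- j2 >= j1 & (cp[j2 + 1L] - cp[j1]) > 0
  r <- rle(autoSnp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (refine && e > s) {
      kd <- .kadane(lod[s:e])
      s2 <- s + kd$start - 1L; e2 <- s + kd$end - 1L
      s <- s2; e <- e2
    }
    lenBp <- pos[e] - pos[s] + 1L
    if (lenBp >= minLen)
      segs[[length(segs) + 1L]] <- data.frame(
        start = pos[s], end = pos[e], lod = sum(lod[s:e]))
  }
  if (!length(segs)) return(empty)
  segs <- do.call(rbind, segs)
  rohSegments(sample = rep(sample, nrow(segs)), chrom = rep(chrom, nrow(segs)),
              start = segs$start, end = segs$end, lod = segs$lod)
}

#' Call runs of homozygosity for a whole cohort
#'
#' Per species: subsets the table to that species' polymorphic sites,
#' estimates allele frequencies, scores 100-SNP sliding windows of
#' genotype LOD, selects a threshold from the pooled window-score density
#' (allele frequencies — hence scores — are species-specific), and
#' assembles size-classified segments per sample and chromosome.
#'
#' @param x A filtered [GenotypeTable-class] (all species).
#' @param winsize Window size in SNPs.
#' @param minLen Minimum ROH length in bp (0.5 Mb default).
#' @param threshold Optional fixed threshold (otherwise KDE-selected per
#'   species).
#' @param refine Trim candidate segments to their maximal-scoring
#'   subsegment.
#' @return `list(segments = GRanges, thresholds = named numeric)`.
#' @export
callRoh <- function(x, winsize = 100L, minLen = 5e5, threshold = NULL,
                    refine = TRUE) {
  sp <- speciesOf(x)
  allSegs <- list()
  thresholds <- numeric()
  for (s in unique(sp)) {
    xs <- subsetSpecies(x, s, polymorphicOnly = TRUE)
    if (nrow(xs) < winsize) {
      thresholds[s] <- NA_real_
      next
    }
    p <- estimateAlleleFreqs(xs)
    lod <- .lodMatrix(xs, p)
    ws <- suppressWarnings(windowScores(xs, p, winsize))
    thr <- if (is.null(threshold)) selectThreshold(ws$score) else threshold
    thresholds[s] <- thr
    chrom <- as.character(seqnames(rowRanges(xs)))
    for (samp in sampleNames(xs)) {
      for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        w <- ws[ws$sample == samp & ws$chrom == ch, "score"]
        if (!length(w)) next
        seg <- assembleRohSegments(
          pos = start(rowRanges(xs))[idx], lod = lod[idx, samp],
          winScore = w, threshold = thr, winsize = winsize,
          minLen = minLen, sample = samp, chrom = ch, refine = refine)
        if (length(seg)) allSegs[[length(allSegs) + 1L]] <- seg
      }
    }
  }
  segments <- if (length(allSegs)) {
    df <- do.call(rbind, lapply(allSegs, as.data.frame))
    rohSegments(df$sample, as.character(df$seqnames), df$start, df$end,
                df$lod)
  } else rohSegments(character(), character(), integer(), integer())
  list(segments = segments, thresholds = thresholds)
}

#' Per-sample ROH summary
#'
#' Counts and total lengths of ROH per sample, overall and per size class,
#' plus `F_ROH` when a chromosome map is supplied.
#'
#' @param segments ROH `GRanges` from [callRoh()].
#' @param samples All sample names (so ROH-free samples appear with zeros).
#' @param chromMap Optional [ChromosomeMap-class] for `F_ROH`.
#' @return A `data.frame` with one row per sample: `NROH`, `SROH` (bp),
#'   per-class `NROH_*` counts, and `FROH` when computable.
#' @export
rohSummary <- function(segments, samples, chromMap = NULL) {
  classes <- c("[0.5,1)", "[1,2)", "[2,3)", "[3,4)", "[4,5)", "[5,Inf)")
  out <- data.frame(sample = samples, NROH = 0L, SROH = 0)
  for (cl in classes) out[[paste0("NROH_", cl)]] <- 0L
  out$SROH_over5Mb <- 0
  if (length(segments)) {
    segSample <- mcols(segments)$sample
    for (i in seq_along(samples)) {
      mine <- segSample == samples[i]
      out$NROH[i] <- sum(mine)
      out$SROH[i] <- sum(width(segments)[mine])
      for (cl in classes)
        out[[paste0("NROH_", cl)]][i] <-
          sum(mine & mcols(segments)$sizeClass == cl)
      out$SROH_over5Mb[i] <-
        sum(width(segments)[mine & mcols(segments)$sizeClass == "[5,Inf)"])
    }
  }
  if (!is.null(chromMap))
    out$FROH <- out$SROH / autosomeLength(chromMap)
  out
}
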