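#' Allele-sharing distance matrix
#'
#' For every sample pair, over pairwise-complete sites, the shared-allele
#' count is `s = 2 - |d_i - d_j|` (both-heterozygous pairs share both
#' alleles, s = 2); the distance is `1 - mean(s) / 2`, in [0, 1].
#'
#' @param x A [GenotypeTable-class] with at least two samples.
#' @return `list(distance = matrix, nSites = matrix)` — the symmetric
#'   distance matrix (zero diagonal) and the per-pair count of
#'   pairwise-complete sites. Pairs with zero complete sites get `NA`
#'   (flagged with a warning).
#' @export
alleleSharingDistance <- function(x) {
  d <- dosages(x)
  n <- ncol(d)
  if (n < 2) stop("need at least two samples")
  samples <- colnames(d)
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  NS <- matrix(0L, n, n, dimnames = list(samples, samples))
  diag(NS) <- colSums(!is.na(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      NS[i, j] <- NS[j, i] <- sum(ok)
      if (!any(ok)) {
        warning("no pairwise-complete sites for ", samples[i], " / ",
                samples[j])
        D[i, j] <- D[j, i] <- NA_real_
        next
      }
      s <- 2 - abs(d[ok, i] - d[ok, j])
      D[i, j] <- D[j, i] <- 1 - mean(s) / 2
    }
  }
  list(distance = D, nSites = NS)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS via [stats::cmdscale()] (double-centred squared
#' distances, top-k positive eigenpairs scaled by the square root of
#' their eigenvalues). The sign of each axis is made reproducible by
#' forcing its largest-magnitude loading positive.
#'
#' @param D Symmetric distance matrix (e.g. from
#'   [alleleSharingDistance()]).
#' @param k Number of dimensions.
#' @return `list(points = matrix, eig = numeric)`.
#' @export
classicalMds <- function(D, k = 2L) {
  stopifnot(k >= 1)
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < 1 || all(fit$eig <= 1e-12))
    stop("no positive eigenvalues; distances carry no Euclidean structure")
  for (a in seq_len(ncol(pts))) {
    m <- which.max(abs(pts[, a]))
    if (pts[m, a] < 0) pts[, a] <- -pts[, a]
  }
  list(points = pts, eig = fit$eig)
}

.KING_CLASSES <- data.frame(
  class = c("duplicate/self", "first-degree", "second-degree", "unrelated"),
  lower = c(0.354, 0.177, 0.0884, -Inf))

#' KING-robust pairwise kinship
#'
#' `phi = (N_bothhet - 2 N_oppohom) / (N_het_i + N_het_j)` over
#' pairwise-complete sites — robust to population structure because it
#' conditions on the pair's own heterozygosity rather than population
#' allele frequencies. Degree classes use the standard powers-of-sqrt(2)
#' cutoffs (>= 0.354 duplicate/self, [0.177, 0.354) first-degree,
#' [0.0884, 0.177) second-degree, else unrelated); the label is reporting
#' only.
#'
#' @param di,dj Dosage vectors of the two samples.
#' @param minSites Minimum pairwise-complete sites.
#' @return `list(phi, class, nBothHet, nOppoHom, nHetI, nHetJ, nSites)`;
#'   `phi` is `NA` (flagged) when no heterozygotes exist in either sample.
#' @export
kingRobust <- function(di, dj, minSites = 100L) {
  ok <- !is.na(di) & !is.na(dj)
  if (sum(ok) < minSites)
    stop("fewer than ", minSites, " pairwise-complete sites")
  di <- di[ok]; dj <- dj[ok]
  nBothHet <- sum(di == 1L & dj == 1L)
  nOppoHom <- sum(abs(di - dj) == 2L)
  nHetI <- sum(di == 1L)
  nHetJ <- sum(dj == 1L)
  denom <- nHetI + nHetJ
  if (denom == 0) {
    warning("no heterozygous sites in either sample; kinship undefined")
    phi <- NA_real_
  } else phi <- (nBothHet - 2 * nOppoHom) / denom
  cls <- if (is.na(phi)) NA_character_ else
    .KING_CLASSES$class[which(phi >= .KING_CLASSES$lower)[1]]
  list(phi = phi, class = cls, nBothHet = nBothHet, nOppoHom = nOppoHom,
       nHetI = nHetI, nHetJ = nHetJ, nSites = sum(ok))
}

#' All-pairs KING-robust kinship for a cohort
#'
#' @param x A [GenotypeTable-class].
#' @param minSites Minimum pairwise-complete sites per pair.
#' @return A `data.frame` with one row per sample pair.
#' @export
kinshipMatrix <- function(x, minSites = 100L) {
  d <- dosages(x)
  samples <- colnames(d)
  pairs <- utils::combn(length(samples), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    r <- kingRobust(d[, i], d[, j], minSites)
    data.frame(sampleA = samples[i], sampleB = samples[j], phi = r$phi,
               class = r$class, nSites = r$nSites)
  })
  do.call(rbind, rows)
}

#' Weir-Cockerham Fst variance components
#'
#' Per-site variance components of the two-level 1984 estimator computed
#' from per-population sample sizes, alternate-allele frequencies and
#' observed heterozygosities: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals). The
#' genome-wide estimate is the weighted ratio `sum(a) / sum(a + b + c)`.
#' Sites where any population has no called genotype are skipped; sites
#' with `a + b + c = 0` are reported with `NA` per-site Fst and excluded
#' from the weighted sums.
#'
#' @param x A [GenotypeTable-class].
#' @param populations Named (by sample) population labels; defaults to the
#'   table's species assignment.
#' @return `list(weighted = scalar, perSite = data.frame(a, b, c, fst),
#'   nSitesUsed)`.
#' @export
weirCockerhamFst <- function(x, populations = speciesOf(x)) {
  d <- dosages(x)
  pops <- unique(unname(populations[colnames(d)]))
  r <- length(pops)
  if (r < 2) stop("need at least two populations")
  nMat <- sapply(pops, function(P)
    rowSums(!is.na(d[, populations[colnames(d)] == P, drop = FALSE])))
  pMat <- sapply(pops, function(P) {
    sub <- d[, populations[colnames(d)] == P, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  })
  hMat <- sapply(pops, function(P) {
    sub <- d[, populations[colnames(d)] == P, drop = FALSE]
    rowSums(sub == 1L, na.rm = TRUE) / rowSums(!is.na(sub))
  })
  usable <- rowSums(nMat == 0) == 0
  a <- b <- cc <- rep(NA_real_, nrow(d))
  for (s in which(usable)) {
    ni <- nMat[s, ]; pi <- pMat[s, ]; hi <- hMat[s, ]
    nbar <- mean(ni)
    if (nbar <= 1) { usable[s] <- FALSE; next }
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a[s] <- nbar / nc *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b[s] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[s] <- hbar / 2
  }
  tot <- a + b + cc
  fst <- ifelse(!is.na(tot) & abs(tot) > 1e-12, a / tot, NA_real_)
  use <- usable & !is.na(fst)
  weighted <- if (any(use)) sum(a[use]) / sum(tot[use]) else NA_real_
  list(weighted = weighted,
       perSite = data.frame(a = a, b = b, c = cc, fst = fst),
       nSitesUsed = sum(use))
}
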