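# Shared fixture builders and small independent oracles.

# Direct GenotypeTable constructor with sensible defaults for site metadata.
makeTable <- function(dosage, chrom = NULL, pos = NULL, species = NULL,
                      qual = NULL, siteDP = NULL, DP = NULL, GQ = NULL,
                      ref = NULL, alt = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- stats::ave(seq_len(n), chrom, FUN = seq_along) * 100L
  if (is.null(species)) species <- rep("spA", m)
  if (is.null(qual)) qual <- rep(100, n)
  if (is.null(siteDP)) siteDP <- rep(300L, n)
  if (is.null(DP)) DP <- matrix(20L, n, m)
  if (is.null(GQ)) GQ <- matrix(40L, n, m)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  GenotypeTable(chrom = chrom, pos = pos, ref = ref, alt = alt,
                qual = qual, siteDP = siteDP, dosage = dosage,
                DP = DP, GQ = GQ, samples = colnames(dosage),
                species = stats::setNames(species, colnames(dosage)))
}

# bp overlap of [s1,e1] and [s2,e2], 1-based inclusive
bpOverlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)

# Jaccard between one truth tract and all called segments of that
# sample/chromosome
tractJaccard <- function(tract, segDf) {
  s <- segDf[segDf$sample == tract$sample &
               as.character(segDf$seqnames) == tract$chrom, , drop = FALSE]
  len <- tract$end - tract$start + 1
  ov <- 0; un <- len
  for (i in seq_len(nrow(s))) {
    o <- bpOverlap(s$start[i], s$end[i], tract$start, tract$end)
    ov <- ov + o
    un <- un + s$width[i] - o
  }
  list(recovered = ov / len, jaccard = ov / un)
}

# Independent Mann-Whitney oracle: U by direct pair counting and the
# two-sided p by full enumeration of value reassignments.
mwuOracle <- function(x, y) {
  countU <- function(a, b) {
    u <- 0
    for (xi in a) for (yj in b)
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  U <- countU(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  sets <- utils::combn(length(pooled), n1)
  Uperm <- apply(sets, 2, function(idx)
    countU(pooled[idx], pooled[-idx]))
  tol <- 1e-9
  p <- min(1, 2 * min(mean(Uperm <= U + tol), mean(Uperm >= U - tol)))
  list(U = U, p = p)
}
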