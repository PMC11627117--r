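#' Filtering parameters
#'
#' Site- and genotype-level filter thresholds. Defaults follow the strict
#' small-cohort regime the package targets: site QUAL strictly greater than
#' 50; combined-depth keep-range from the 5th/95th nearest-rank percentiles
#' (or explicit bounds); per-species excess-heterozygosity thresholds of 4
#' at n = 5 and 6 at n = 7 (generic default `ceiling(0.8 * n)` otherwise);
#' genotype read-depth keep-range [6, 34]; genotype GQ >= 20; sites with 3
#' or more missing genotypes removed; non-autosomes and joint-monomorphic
#' sites dropped.
#'
#' @param qualMin Site QUAL must be strictly greater than this.
#' @param depthBounds `NULL` (derive from percentiles) or `c(low, high)`
#'   inclusive keep-range for combined site depth.
#' @param depthPercentiles Percentiles used when `depthBounds` is `NULL`.
#' @param hetThresholds Optional named (by species) integer vector: a site
#'   is removed when any species has at least this many heterozygotes.
#' @param gtDepthRange Inclusive keep-range for per-genotype DP.
#' @param gqMin Genotypes with GQ below this are set missing.
#' @param maxMissing Sites with at least this many missing genotypes are
#'   removed.
#' @param dropNonAutosomes Remove sites on non-autosomes.
#' @param dropMonomorphic Remove sites monomorphic across all called
#'   genotypes of the joint table.
#' @return A list of class `"FilterParams"`.
#' @export
filterParams <- function(qualMin = 50, depthBounds = NULL,
                         depthPercentiles = c(5, 95),
                         hetThresholds = NULL,
                         gtDepthRange = c(6L, 34L), gqMin = 20,
                         maxMissing = 3L, dropNonAutosomes = TRUE,
                         dropMonomorphic = TRUE) {
  stopifnot(qualMin >= 0, gqMin >= 0, maxMissing >= 1,
            length(gtDepthRange) == 2, gtDepthRange[1] <= gtDepthRange[2])
  if (!is.null(depthBounds))
    stopifnot(length(depthBounds) == 2, depthBounds[1] <= depthBounds[2])
  structure(list(qualMin = qualMin, depthBounds = depthBounds,
                 depthPercentiles = depthPercentiles,
                 hetThresholds = hetThresholds,
                 gtDepthRange = gtDepthRange, gqMin = gqMin,
                 maxMissing = as.integer(maxMissing),
                 dropNonAutosomes = dropNonAutosomes,
                 dropMonomorphic = dropMonomorphic),
            class = "FilterParams")
}

#' Default excess-heterozygosity threshold for a cohort size
#'
#' 4 at n = 5 and 6 at n = 7 (the two cohort sizes the regime was defined
#' for); `ceiling(0.8 * n)` otherwise.
#'
#' @param n Number of diploid samples in the species.
#' @return Integer threshold: a site with this many (or more) heterozygotes
#'   in the species is flagged.
#' @export
defaultHetThreshold <- function(n) {
  ifelse(n == 5L, 4L, ifelse(n == 7L, 6L, as.integer(ceiling(0.8 * n))))
}

.emptyReport <- function() {
  data.frame(filter = character(), unit = character(), removed = integer(),
             stringsAsFactors = FALSE)
}

.addReport <- function(report, filter, unit, removed) {
  rbind(report, data.frame(filter = filter, unit = unit,
                           removed = as.integer(removed)))
}

#' Nearest-rank percentile bounds of the combined site depth
#'
#' @param x A [GenotypeTable-class].
#' @param lower,upper Percentiles in (0, 100].
#' @return `c(low, high)` depth values at the nearest-rank percentiles.
#' @export
computeDepthBounds <- function(x, lower = 5, upper = 95) {
  stopifnot(nrow(x) > 0, lower >= 0, lower < upper, upper <= 100)
  d <- sort(siteDepth(x))
  rank <- function(p) max(1L, as.integer(ceiling(p / 100 * length(d))))
  c(d[rank(lower)], d[rank(upper)])
}

#' Site-level filters
#'
#' Removes, in order: sites on non-autosomes; records that are not
#' biallelic SNVs (multi-nucleotide, indel, complex or multi-allelic);
#' sites with QUAL not strictly above `qualMin`; sites whose combined depth
#' falls outside the keep-range (derived from nearest-rank percentiles when
#' not given explicitly).
#'
#' @param x A [GenotypeTable-class].
#' @param params A [filterParams()] object.
#' @param chromMap A [ChromosomeMap-class]; required when
#'   `dropNonAutosomes` is `TRUE`.
#' @return `list(table, report)`.
#' @export
filterSites <- function(x, params = filterParams(), chromMap = NULL) {
  report <- .emptyReport()
  if (params$dropNonAutosomes) {
    if (is.null(chromMap))
      stop("chromMap required to drop non-autosomes")
    auto <- names(which(isAutosome(chromMap)))
    keep <- as.character(seqnames(rowRanges(x))) %in% auto
    report <- .addReport(report, "non_autosome", "site", sum(!keep))
    x <- x[keep, ]
  }
  rr <- mcols(rowRanges(x))
  snv <- !rr$multiallelic &
    rr$REF %in% c("A", "C", "G", "T") & rr$ALT %in% c("A", "C", "G", "T")
  report <- .addReport(report, "non_snv_or_multiallelic", "site", sum(!snv))
  x <- x[snv, ]
  q <- siteQual(x)
  keep <- !is.na(q) & q > params$qualMin
  report <- .addReport(report, "site_qual", "site", sum(!keep))
  x <- x[keep, ]
  bounds <- params$depthBounds
  if (is.null(bounds) && nrow(x) > 0)
    bounds <- computeDepthBounds(x, params$depthPercentiles[1],
                                 params$depthPercentiles[2])
  if (!is.null(bounds)) {
    d <- siteDepth(x)
    keep <- !is.na(d) & d >= bounds[1] & d <= bounds[2]
    report <- .addReport(report, "combined_depth", "site", sum(!keep))
    x <- x[keep, ]
  } else {
    report <- .addReport(report, "combined_depth", "site", 0L)
  }
  list(table = x, report = report)
}

#' Excess-heterozygosity filter
#'
#' A site is removed when, in any species evaluated separately, its
#' heterozygote count reaches that species' threshold.
#'
#' @param x A [GenotypeTable-class].
#' @param hetThresholds Named (by species) integer thresholds; defaults via
#'   [defaultHetThreshold()] from each species' sample count.
#' @return `list(table, report)`.
#' @export
filterExcessHet <- function(x, hetThresholds = NULL) {
  sp <- speciesOf(x)
  labels <- unique(sp)
  if (is.null(hetThresholds)) {
    ns <- vapply(labels, function(s) sum(sp == s), integer(1))
    hetThresholds <- stats::setNames(defaultHetThreshold(ns), labels)
  }
  missing <- setdiff(labels, names(hetThresholds))
  if (length(missing))
    stop("no excess-het threshold for species: ",
         paste(missing, collapse = ", "))
  d <- dosages(x)
  flag <- rep(FALSE, nrow(x))
  for (s in labels) {
    hets <- rowSums(d[, sp == s, drop = FALSE] == 1L, na.rm = TRUE)
    flag <- flag | hets >= hetThresholds[[s]]
  }
  report <- .addReport(.emptyReport(), "excess_het", "site", sum(flag))
  list(table = x[!flag, ], report = report)
}

#' Genotype-level masking, missingness and monomorphic filters
#'
#' Genotypes with DP outside the keep-range or GQ below the minimum (or
#' with no DP/GQ value) are set missing; sites accumulating `maxMissing`
#' or more missing genotypes are then removed; finally sites monomorphic
#' across all remaining called genotypes are removed.
#'
#' @param x A [GenotypeTable-class].
#' @param params A [filterParams()] object.
#' @return `list(table, report)`.
#' @export
filterGenotypesAndMissingness <- function(x, params = filterParams()) {
  report <- .emptyReport()
  d <- dosages(x); dp <- genoDepth(x); gq <- genoQual(x)
  bad <- !is.na(d) & (is.na(dp) | dp < params$gtDepthRange[1] |
                        dp > params$gtDepthRange[2] |
                        is.na(gq) | gq < params$gqMin)
  report <- .addReport(report, "genotype_dp_gq", "genotype", sum(bad))
  d[bad] <- NA_integer_
  SummarizedExperiment::assay(x, "dosage") <- d
  nMissing <- rowSums(is.na(d))
  keep <- nMissing < params$maxMissing
  report <- .addReport(report, "site_missingness", "site", sum(!keep))
  x <- x[keep, ]
  if (params$dropMonomorphic) {
    d <- dosages(x)
    altSum <- rowSums(d, na.rm = TRUE)
    nCalled <- rowSums(!is.na(d))
    poly <- nCalled > 0 & altSum > 0 & altSum < 2 * nCalled
    report <- .addReport(report, "monomorphic", "site", sum(!poly))
    x <- x[poly, ]
  }
  list(table = x, report = report)
}

#' Full filter chain
#'
#' Runs [filterSites()], [filterExcessHet()] and
#' [filterGenotypesAndMissingness()] in order and concatenates their
#' reports. The report's site removals reconstruct input minus output
#' exactly.
#'
#' @inheritParams filterSites
#' @param hetThresholds Passed to [filterExcessHet()] (`NULL` = defaults
#'   from `params$hetThresholds` or cohort sizes).
#' @return `list(table, report)`; the report carries attributes
#'   `inputSites` and `outputSites`.
#' @export
filterPipeline <- function(x, params = filterParams(), chromMap = NULL,
                           hetThresholds = params$hetThresholds) {
  nIn <- nrow(x)
  s1 <- filterSites(x, params, chromMap)
  s2 <- filterExcessHet(s1$table, hetThresholds)
  s3 <- filterGenotypesAndMissingness(s2$table, params)
  report <- rbind(s1$report, s2$report, s3$report)
  attr(report, "inputSites") <- nIn
  attr(report, "outputSites") <- nrow(s3$table)
  list(table = s3$table, report = report)
}

#' Subset a table to one species
#'
#' @param x A [GenotypeTable-class].
#' @param species Species label.
#' @param polymorphicOnly Keep only sites polymorphic among the species'
#'   called genotypes.
#' @return A [GenotypeTable-class] with only that species' samples.
#' @export
subsetSpecies <- function(x, species, polymorphicOnly = TRUE) {
  keep <- speciesOf(x) == species
  if (!any(keep)) stop("no samples for species ", species)
  x <- x[, keep]
  if (polymorphicOnly) {
    d <- dosages(x)
    altSum <- rowSums(d, na.rm = TRUE)
    nCalled <- rowSums(!is.na(d))
    x <- x[nCalled > 0 & altSum > 0 & altSum < 2 * nCalled, ]
  }
  x
}
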