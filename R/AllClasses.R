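#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' Multi-sample genotype table
#'
#' `GenotypeTable` holds a sites-by-samples diploid genotype matrix together
#' with its per-genotype and per-site metadata. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with three integer
#' assays:
#'
#' * `dosage` — alternate-allele count per genotype (0, 1, 2 or `NA` for an
#'   uncalled genotype),
#' * `DP` — per-genotype read depth,
#' * `GQ` — per-genotype phred-scaled quality.
#'
#' Row ranges carry the site coordinates (1-based, width 1) plus `REF`,
#' `ALT` (comma-separated when multi-allelic), `QUAL`, the combined
#' across-sample depth `DP`, and a `multiallelic` flag. Column data carry the
#' `species` label of every sample.
#'
#' @section Invariants:
#' Positions are strictly increasing within a chromosome; every sample has a
#' non-missing species label; dosage is `NA` exactly where the genotype is
#' uncalled.
#'
#' @export
setClass("GenotypeTable", contains = "RangedSummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  msg <- character()
  need <- c("dosage", "DP", "GQ")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, sprintf("assays must include %s", paste(need, collapse = ", ")))
  rr <- rowRanges(object)
  needCols <- c("REF", "ALT", "QUAL", "DP", "multiallelic")
  if (!all(needCols %in% names(mcols(rr))))
    msg <- c(msg, sprintf("rowRanges mcols must include %s",
                          paste(needCols, collapse = ", ")))
  if (!"species" %in% names(colData(object)))
    msg <- c(msg, "colData must include a 'species' column")
  else if (anyNA(colData(object)$species))
    msg <- c(msg, "every sample needs a species label")
  if (length(rr) > 1L) {
    bad <- tapply(start(rr), as.character(seqnames(rr)),
                  function(p) any(diff(p) <= 0))
    if (any(unlist(bad)))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
  }
  if ("dosage" %in% names(assays(object))) {
    d <- assay(object, "dosage")
    if (any(!is.na(d) & !(d %in% 0:2)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param chrom,pos Character / integer vectors of site coordinates
#'   (1-based bp).
#' @param ref,alt Reference and alternate alleles; `alt` may contain
#'   comma-separated values for multi-allelic records.
#' @param qual Per-site QUAL scores.
#' @param siteDP Combined across-sample read depth per site.
#' @param dosage,DP,GQ Sites-by-samples matrices (see [GenotypeTable-class]).
#' @param samples Sample identifiers (column names).
#' @param species Named character vector or plain vector (recycled against
#'   `samples`) giving each sample's species label.
#' @return A [GenotypeTable-class] object.
#' @export
GenotypeTable <- function(chrom, pos, ref, alt, qual, siteDP,
                          dosage, DP, GQ, samples, species) {
  dosage <- as.matrix(dosage); DP <- as.matrix(DP); GQ <- as.matrix(GQ)
  if (is.null(names(species))) {
    species <- rep_len(species, length(samples))
    names(species) <- samples
  }
  if (!all(samples %in% names(species)))
    stop("species label missing for sample(s): ",
         paste(setdiff(samples, names(species)), collapse = ", "))
  rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  mcols(rr) <- DataFrame(
    REF = as.character(ref), ALT = as.character(alt),
    QUAL = as.numeric(qual), DP = as.integer(siteDP),
    multiallelic = grepl(",", alt, fixed = TRUE))
  dimnames(dosage) <- dimnames(DP) <- dimnames(GQ) <- list(NULL, samples)
  se <- SummarizedExperiment(
    assays = list(dosage = dosage, DP = DP, GQ = GQ),
    rowRanges = rr,
    colData = DataFrame(species = unname(species[samples]),
                        row.names = samples))
  new("GenotypeTable", se)
}

#' Chromosome map
#'
#' Names, lengths (bp) and autosome status of the chromosomes the genotype
#' data refer to. Non-autosomes (sex chromosomes, unmapped scaffolds) are
#' flagged so they can be dropped before analysis.
#'
#' @slot chrom Chromosome names (unique).
#' @slot length Chromosome lengths in bp (> 0).
#' @slot autosome Logical autosome flag.
#' @export
setClass("ChromosomeMap",
         representation(chrom = "character", length = "numeric",
                        autosome = "logical"))

setValidity("ChromosomeMap", function(object) {
  msg <- character()
  n <- length(object@chrom)
  if (length(object@length) != n || length(object@autosome) != n)
    msg <- c(msg, "chrom, length and autosome must have equal length")
  if (anyDuplicated(object@chrom))
    msg <- c(msg, "chromosome names must be unique")
  if (any(object@length <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ChromosomeMap-class
#' @param chrom,length,autosome See slots.
#' @export
ChromosomeMap <- function(chrom, length, autosome = rep(TRUE, base::length(chrom))) {
  new("ChromosomeMap", chrom = as.character(chrom),
      length = as.numeric(length), autosome = as.logical(autosome))
}
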