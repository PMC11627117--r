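#' Accessors for GenotypeTable and ChromosomeMap
#'
#' Small wrappers so downstream code never touches slots or assay names
#' directly.
#'
#' @param x A [GenotypeTable-class] or [ChromosomeMap-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeTable", function(x) assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("genoDepth", function(x) standardGeneric("genoDepth"))
#' @rdname accessors
#' @export
setMethod("genoDepth", "GenotypeTable", function(x) assay(x, "DP"))

#' @rdname accessors
#' @export
setGeneric("genoQual", function(x) standardGeneric("genoQual"))
#' @rdname accessors
#' @export
setMethod("genoQual", "GenotypeTable", function(x) assay(x, "GQ"))

#' @rdname accessors
#' @export
setGeneric("siteQual", function(x) standardGeneric("siteQual"))
#' @rdname accessors
#' @export
setMethod("siteQual", "GenotypeTable", function(x) mcols(rowRanges(x))$QUAL)

#' @rdname accessors
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))
#' @rdname accessors
#' @export
setMethod("siteDepth", "GenotypeTable", function(x) mcols(rowRanges(x))$DP)

#' @rdname accessors
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))
#' @rdname accessors
#' @export
setMethod("speciesOf", "GenotypeTable", function(x) {
  s <- colData(x)$species
  names(s) <- colnames(x)
  s
})

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname accessors
#' @export
setMethod("sampleNames", "GenotypeTable", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname accessors
#' @export
setMethod("chromNames", "ChromosomeMap", function(x) x@chrom)

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "ChromosomeMap", function(x) {
  stats::setNames(x@length, x@chrom)
})

#' @rdname accessors
#' @export
setGeneric("isAutosome", function(x) standardGeneric("isAutosome"))
#' @rdname accessors
#' @export
setMethod("isAutosome", "ChromosomeMap", function(x) {
  stats::setNames(x@autosome, x@chrom)
})

#' Total autosomal genome length
#'
#' @param x A [ChromosomeMap-class].
#' @return Summed length (bp) of the autosomes.
#' @export
setGeneric("autosomeLength", function(x) standardGeneric("autosomeLength"))
#' @rdname autosomeLength
#' @export
setMethod("autosomeLength", "ChromosomeMap", function(x) sum(x@length[x@autosome]))

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d sites x %d samples\n",
              nrow(object), ncol(object)))
  sp <- table(colData(object)$species)
  cat("  species:", paste(sprintf("%s (n=%d)", names(sp), sp), collapse = ", "),
      "\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(rowRanges(object)))), collapse = ", "),
      "\n")
  cat(sprintf("  missing genotypes: %.2f%%\n",
              100 * mean(is.na(assay(object, "dosage")))))
})

setMethod("show", "ChromosomeMap", function(object) {
  cat(sprintf("ChromosomeMap: %d chromosomes (%d autosomes), %.1f Mb autosomal\n",
              length(object@chrom), sum(object@autosome),
              autosomeLength(object) / 1e6))
})
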