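#' Chromosome-size-binned recombination rate
#'
#' Mean recombination rate assigned by the length of the chromosome
#' carrying a ROH (flycatcher chromosome-level means): >= 100 Mb ->
#' 1.6 cM/Mb, [50, 100) -> 2.0, [25, 50) -> 1.7, [10, 25) -> 1.5, and
#' < 10 Mb -> 1.5 (no rate reported for microchromosomes, so the smallest
#' bin's rate is reused). Bin edges are half-open `[low, high)`.
#'
#' @param lengthBp Chromosome length(s) in bp.
#' @return Rate(s) in cM/Mb.
#' @export
rateForChromosome <- function(lengthBp) {
  stopifnot(all(lengthBp > 0))
  mb <- lengthBp / 1e6
  ifelse(mb >= 100, 1.6,
  ifelse(mb >= 50, 2.0,
  ifelse(mb >= 25, 1.7, 1.5)))
}

#' Date the haplotypes underlying ROH segments
#'
#' Converts each segment's physical length to genetic length at its
#' chromosome's size-binned rate, `l = (length / 1e6) * rate` cM, then
#' inverts the expected IBD-segment length relationship `l = 100 / (2 g)`
#' to get generations to the most recent common ancestor, `g = 50 / l`.
#' Years before sampling are `g * generationTime`; the calendar year is the
#' sampling year minus the whole-year (floored) TMRCA, reproducing
#' conventional whole-year reporting (e.g. 66.67 years -> 66 years ->
#' sampling year minus 66).
#'
#' @param segments ROH `GRanges` (see [rohSegments()]).
#' @param chromMap A [ChromosomeMap-class] giving each chromosome's length
#'   (which selects the rate bin).
#' @param generationTime Generation time in years.
#' @param samplingYear Calendar year of sampling.
#' @return A `data.frame` with one row per segment: `sample`, `chrom`,
#'   `start`, `end`, `lengthBp`, `sizeClass`, `rateCmMb`, `lCm`,
#'   `generations`, `years`, `yearsWhole`, `calendarYear`.
#' @export
estimateTmrca <- function(segments, chromMap, generationTime = 2,
                          samplingYear = 2006) {
  if (!length(segments))
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      lengthBp = integer(), sizeClass = character(),
                      rateCmMb = numeric(), lCm = numeric(),
                      generations = numeric(), years = numeric(),
                      yearsWhole = integer(), calendarYear = integer()))
  chrom <- as.character(seqnames(segments))
  chromLen <- chromLengths(chromMap)[chrom]
  if (anyNA(chromLen))
    stop("segment chromosome(s) missing from chromosome map: ",
         paste(unique(chrom[is.na(chromLen)]), collapse = ", "))
  rate <- rateForChromosome(chromLen)
  lCm <- width(segments) / 1e6 * rate
  g <- 50 / lCm
  years <- g * generationTime
  data.frame(sample = mcols(segments)$sample, chrom = chrom,
             start = start(segments), end = end(segments),
             lengthBp = width(segments),
             sizeClass = mcols(segments)$sizeClass,
             rateCmMb = unname(rate), lCm = unname(lCm),
             generations = unname(g), years = unname(years),
             yearsWhole = as.integer(floor(years)),
             calendarYear = as.integer(samplingYear - floor(years)))
}

#' Expected ROH genetic length for a given age
#'
#' Inverse of the dating relationship: a common ancestor `g` generations
#' back leaves IBD segments of expected genetic length `100 / (2 g)` cM.
#'
#' @param g Generations to the most recent common ancestor.
#' @return Expected segment length in cM.
#' @export
expectedLengthCm <- function(g) {
  stopifnot(all(g > 0))
  100 / (2 * g)
}

#' Inbreeding coefficient F_ROH
#'
#' Fraction of the autosomal genome covered by a sample's ROH:
#' `sum(segment lengths) / sum(autosome lengths)`.
#'
#' @param segments ROH `GRanges` for one sample (an empty set gives 0).
#' @param chromMap A [ChromosomeMap-class]; the denominator is the summed
#'   autosome length, not the SNP-covered span.
#' @return Scalar in [0, 1].
#' @export
froh <- function(segments, chromMap) {
  if (!length(segments)) return(0)
  if (length(unique(mcols(segments)$sample)) > 1)
    stop("froh expects segments of a single sample; see rohSummary() for cohorts")
  red <- GenomicRanges::reduce(segments)
  if (length(red) < length(segments) || sum(width(red)) < sum(width(segments)))
    stop("overlapping ROH segments within one sample")
  sum(width(segments)) / autosomeLength(chromMap)
}
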