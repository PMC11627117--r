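#' @importFrom utils read.delim write.table
NULL

.CONSEQUENCES <- c("synonymous", "nonsynonymous", "stop-gain", "stop-loss",
                   "start-lost", "noncoding")
.PREDICTIONS <- c("deleterious", "tolerated", "absent")
.LOF <- c("stop-gain", "stop-loss", "start-lost")

#' Read a multi-sample VCF into a GenotypeTable
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) keeping the `GT`, `DP` and `GQ`
#' FORMAT fields. Genotypes are stored as alternate-allele dosages; `./.`
#' becomes `NA`. Phased separators are treated as unphased. Multi-allelic
#' records are retained and flagged for downstream filtering; their dosage
#' is the count of non-reference alleles.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param speciesMap Named character vector, sample name -> species label.
#'   Every sample in the file must be present.
#' @return A [GenotypeTable-class].
#' @export
readGenotypeVcf <- function(path, speciesMap) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(samples, names(speciesMap))
  if (length(missing))
    stop("sample(s) in VCF absent from species map: ",
         paste(missing, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dosage <- .gtToDosage(gt)
  info <- fix[, "INFO"]
  siteDP <- suppressWarnings(as.integer(sub("^.*?DP=([0-9]+).*$", "\\1",
                                            info, perl = TRUE)))
  siteDP[!grepl("DP=", info)] <- NA_integer_
  GenotypeTable(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    siteDP = siteDP,
    dosage = dosage,
    DP = matrix(as.integer(dp), nrow = nrow(dp), dimnames = dimnames(dp)),
    GQ = matrix(as.integer(gq), nrow = nrow(gq), dimnames = dimnames(gq)),
    samples = samples, species = speciesMap[samples])
}

.gtToDosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  called <- !is.na(norm) & !grepl("\\.", norm)
  alleles <- strsplit(norm[called], "/", fixed = TRUE)
  d[called] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
  d
}

#' Write a GenotypeTable as VCF v4.2
#'
#' Emits `GT:DP:GQ` genotypes (dosage 0/1/2 as `0/0`, `0/1`, `1/1`; `NA` as
#' `./.`) and the combined site depth in `INFO/DP`. Contig header lines are
#' written when a [ChromosomeMap-class] is supplied, making the output
#' self-describing for downstream tools.
#'
#' @param x A [GenotypeTable-class].
#' @param path Output path (plain text).
#' @param chromMap Optional [ChromosomeMap-class] for `##contig` lines.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(x, path, chromMap = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=inbredscope-%s",
                   as.character(utils::packageVersion("inbredscope"))))
  if (!is.null(chromMap))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chromNames(chromMap),
                          as.integer(chromLengths(chromMap))))
  hdr <- c(hdr,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth across samples\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames(x)), collapse = "\t"))
  rr <- rowRanges(x)
  gtCode <- c("0/0", "0/1", "1/1")
  d <- dosages(x); dp <- genoDepth(x); gq <- genoQual(x)
  cells <- matrix(sprintf("%s:%s:%s",
                          ifelse(is.na(d), "./.", gtCode[d + 1L]),
                          ifelse(is.na(dp), ".", dp),
                          ifelse(is.na(gq), ".", gq)),
                  nrow = nrow(d))
  qual <- mcols(rr)$QUAL
  body <- paste(as.character(seqnames(rr)), start(rr), ".",
                mcols(rr)$REF, mcols(rr)$ALT,
                ifelse(is.na(qual), ".", format(qual, trim = TRUE, digits = 10)),
                "PASS",
                ifelse(is.na(mcols(rr)$DP), ".",
                       sprintf("DP=%d", mcols(rr)$DP)),
                "GT:DP:GQ",
                apply(cells, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a chromosome map
#'
#' Tab-separated with columns `chrom`, `length`, `autosome` (TRUE/FALSE).
#'
#' @param path File path.
#' @return [readChromosomeMap()] a [ChromosomeMap-class];
#'   [writeChromosomeMap()] `path` invisibly.
#' @export
readChromosomeMap <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length", "autosome")
  if (!all(need %in% names(d)))
    stop("chromosome map needs columns: ", paste(need, collapse = ", "))
  ChromosomeMap(d$chrom, d$length, as.logical(d$autosome))
}

#' @rdname readChromosomeMap
#' @param x A [ChromosomeMap-class].
#' @export
writeChromosomeMap <- function(x, path) {
  write.table(data.frame(chrom = chromNames(x),
                         length = as.integer(chromLengths(x)),
                         autosome = unname(isAutosome(x))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site transcript annotation table
#'
#' Tab-separated normalisation of a SIFT4G-style annotator output: one row
#' per transcript annotation with columns `chrom`, `pos`, `alt`,
#' `transcript`, `consequence`, `prediction`. The consequence vocabulary is
#' closed (`synonymous`, `nonsynonymous`, `stop-gain`, `stop-loss`,
#' `start-lost`, `noncoding`); predictions are `deleterious`, `tolerated` or
#' `absent` (no prediction made). Multiple rows per (chrom, pos, alt) key
#' are transcript-level entries of a single site record.
#'
#' @param path File path.
#' @return A `data.frame` of class `"AnnotationTable"` with one row per
#'   transcript entry and a character `key` column `chrom:pos:alt`.
#' @export
readAnnotationTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = list(chrom = "character", alt = "character"))
  need <- c("chrom", "pos", "alt", "transcript", "consequence", "prediction")
  if (!all(need %in% names(d)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  AnnotationTable(d)
}

#' @rdname readAnnotationTable
#' @param d A data frame with the columns listed above (the `transcript`
#'   column is filled with `"t1"` when absent).
#' @export
AnnotationTable <- function(d) {
  if (!"transcript" %in% names(d)) d$transcript <- "t1"
  bad <- setdiff(unique(d$consequence), .CONSEQUENCES)
  if (length(bad))
    stop("unknown consequence token(s): ", paste(bad, collapse = ", "))
  d$prediction[is.na(d$prediction) | d$prediction == ""] <- "absent"
  badp <- setdiff(unique(d$prediction), .PREDICTIONS)
  if (length(badp))
    stop("unknown prediction token(s): ", paste(badp, collapse = ", "))
  d$key <- paste(d$chrom, d$pos, d$alt, sep = ":")
  class(d) <- c("AnnotationTable", "data.frame")
  d
}

#' @rdname readAnnotationTable
#' @param x An `AnnotationTable`.
#' @export
writeAnnotationTable <- function(x, path) {
  cols <- c("chrom", "pos", "alt", "transcript", "consequence", "prediction")
  write.table(as.data.frame(x)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct ROH segments
#'
#' ROH segments are kept as a [GenomicRanges::GRanges] (1-based inclusive)
#' with metadata columns `sample`, `lod` (summed window LOD) and
#' `sizeClass`. Size classes follow the fixed half-open Mb intervals
#' `[0.5,1) [1,2) [2,3) [3,4) [4,5) [5,Inf)`.
#'
#' @param sample,chrom,start,end,lod Parallel vectors describing segments.
#' @return A `GRanges` of segments.
#' @export
rohSegments <- function(sample, chrom, start, end, lod = NA_real_) {
  if (length(sample) == 0L) {
    g <- GRanges()
    mcols(g) <- DataFrame(sample = character(), lod = numeric(),
                          sizeClass = character())
    return(g)
  }
  stopifnot(all(end >= start))
  g <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  mcols(g) <- DataFrame(sample = as.character(sample),
                        lod = as.numeric(lod),
                        sizeClass = rohSizeClass(width(g)))
  g
}

#' Size-class label for a ROH length
#'
#' @param lengthBp Segment lengths in bp.
#' @return Character labels among `[0.5,1)`, `[1,2)`, ..., `[5,Inf)` Mb;
#'   `NA` below 0.5 Mb.
#' @export
rohSizeClass <- function(lengthBp) {
  breaks <- c(0.5e6, 1e6, 2e6, 3e6, 4e6, 5e6, Inf)
  labels <- c("[0.5,1)", "[1,2)", "[2,3)", "[3,4)", "[4,5)", "[5,Inf)")
  as.character(cut(lengthBp, breaks = breaks, labels = labels, right = FALSE))
}

#' Write / read ROH segments as BED6
#'
#' Internal 1-based inclusive coordinates are converted exactly to BED's
#' 0-based half-open convention (`start - 1`, `end`). Column 4 is the sample
#' name, column 5 the size class, column 6 `"."`.
#'
#' @param segments A `GRanges` from [rohSegments()].
#' @param path File path.
#' @return `path` invisibly; [readRohBed()] returns a `GRanges`.
#' @export
writeRohBed <- function(segments, path) {
  if (length(segments)) {
    key <- split(segments, mcols(segments)$sample)
    for (s in names(key)) {
      red <- GenomicRanges::reduce(key[[s]])
      if (length(red) < length(key[[s]]))
        stop("overlapping ROH segments for sample ", s)
    }
  }
  lines <- "#chrom\tstart\tend\tsample\tsize_class\tstrand"
  if (length(segments))
    lines <- c(lines, paste(as.character(seqnames(segments)),
                            start(segments) - 1L, end(segments),
                            mcols(segments)$sample,
                            mcols(segments)$sizeClass, ".", sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRohBed
#' @export
readRohBed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) return(rohSegments(character(), character(), integer(), integer()))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  rohSegments(sample = f[, 4], chrom = f[, 1],
              start = as.integer(f[, 2]) + 1L, end = as.integer(f[, 3]))
}

#' Read a species configuration
#'
#' Two-column TSV `sample`, `species` mapping every sample to its cohort.
#'
#' @param path File path.
#' @return Named character vector sample -> species.
#' @export
readSpeciesConfig <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "species") %in% names(d)))
    stop("species config needs columns sample, species")
  stats::setNames(d$species, d$sample)
}
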