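#' Pipeline configuration
#'
#' A single structured configuration drives the whole
#' simulate/filter/roh/date/load/relate pipeline. Either a simulation
#' config (synthetic cohort) or input paths (VCF + annotation TSV +
#' chromosome map + species config) supply the data.
#'
#' @param seed Integer seed recorded in every output header.
#' @param outDir Output directory.
#' @param simulate A [simConfig()] object, or `NULL` to read inputs from
#'   disk.
#' @param vcf,annotations,chromMap,speciesConfig Input paths (used when
#'   `simulate` is `NULL`); `chromMap` may also be a
#'   [ChromosomeMap-class].
#' @param filter A [filterParams()] object, or `NULL` to skip filtering.
#' @param winsize,minRohBp ROH caller settings.
#' @param generationTime,samplingYear Dating settings.
#' @param loadScope `"polymorphic"` or `"all"` for load counting.
#' @param projection Named (by species) haploid projection sizes for the
#'   private-allele SFS; `NULL` uses `2 * n - 4` per species.
#' @param relate Run the relatedness/structure checks.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, outDir = "inbredscope_out",
                           simulate = simConfig(seed = seed),
                           vcf = NULL, annotations = NULL, chromMap = NULL,
                           speciesConfig = NULL,
                           filter = filterParams(),
                           winsize = 100L, minRohBp = 5e5,
                           generationTime = 2, samplingYear = 2006,
                           loadScope = "polymorphic", projection = NULL,
                           relate = TRUE) {
  if (is.null(simulate) &&
      (is.null(vcf) || is.null(chromMap) || is.null(speciesConfig)))
    stop("without a simulation config, vcf, chromMap and speciesConfig paths are required")
  structure(list(seed = as.integer(seed), outDir = outDir,
                 simulate = simulate, vcf = vcf, annotations = annotations,
                 chromMap = chromMap, speciesConfig = speciesConfig,
                 filter = filter, winsize = as.integer(winsize),
                 minRohBp = minRohBp, generationTime = generationTime,
                 samplingYear = samplingYear, loadScope = loadScope,
                 projection = projection, relate = relate),
            class = "PipelineConfig")
}

# FNV-1a 32-bit checksum of the deparsed config, for output provenance
.configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    lb <- h %% 256                      # xor touches the low byte only
    h <- h - lb + bitwXor(as.integer(lb), as.integer(ch %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.writeTsv <- function(d, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# inbredscope seed=%d config=%s", seed, hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (or load inputs), filter, ROH
#' calling, TMRCA dating + F_ROH, genetic load + private-allele SFS, and
#' relatedness checks — writing per-stage TSV/BED outputs plus the summary
#' report tables of [makeReport()]. Outputs are deterministic under a
#' fixed config and seed; every file header carries the seed and a config
#' checksum.
#'
#' @param config A [pipelineConfig()] object.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the stage outputs and report tables.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- .configHash(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "input"
  out <- tryCatch({
    t0 <- Sys.time()
    if (!is.null(config$simulate)) {
      say("[simulate] generating synthetic cohort (seed %d)", config$seed)
      sim <- simulateCohort(config$simulate)
      gt <- sim$genotypes
      ann <- sim$annotations
      cm <- config$simulate$chromMap
      truth <- sim$truth
    } else {
      say("[input] reading %s", config$vcf)
      cm <- if (inherits(config$chromMap, "ChromosomeMap")) config$chromMap
        else readChromosomeMap(config$chromMap)
      spMap <- readSpeciesConfig(config$speciesConfig)
      gt <- readGenotypeVcf(config$vcf, spMap)
      ann <- if (!is.null(config$annotations))
        readAnnotationTable(config$annotations) else NULL
      truth <- NULL
    }
    nIn <- nrow(gt)

    stage <- "filter"
    if (!is.null(config$filter)) {
      f <- filterPipeline(gt, config$filter, chromMap = cm)
      gt <- f$table
      say("[filter] %d -> %d sites", nIn, nrow(gt))
      .writeTsv(f$report, file.path(config$outDir, "filter_report.tsv"),
                config$seed, hash)
      report <- f$report
    } else report <- NULL

    stage <- "roh"
    roh <- callRoh(gt, winsize = config$winsize, minLen = config$minRohBp)
    say("[roh] %d segments", length(roh$segments))
    writeRohBed(roh$segments, file.path(config$outDir, "roh_segments.bed"))
    rs <- rohSummary(roh$segments, sampleNames(gt), cm)
    .writeTsv(rs, file.path(config$outDir, "roh_summary.tsv"),
              config$seed, hash)

    stage <- "date"
    tmrca <- estimateTmrca(roh$segments, cm,
                           generationTime = config$generationTime,
                           samplingYear = config$samplingYear)
    .writeTsv(tmrca, file.path(config$outDir, "tmrca.tsv"),
              config$seed, hash)

    stage <- "load"
    loadOut <- NULL
    if (!is.null(ann) && nrow(ann)) {
      collapsed <- collapseAnnotations(ann)
      counts <- loadCounts(gt, collapsed, scope = config$loadScope)
      props <- loadProportions(counts)
      tests <- .pairwiseLoadTests(props)
      .writeTsv(counts, file.path(config$outDir, "load_counts.tsv"),
                config$seed, hash)
      .writeTsv(props, file.path(config$outDir, "load_proportions.tsv"),
                config$seed, hash)
      .writeTsv(tests, file.path(config$outDir, "load_tests.tsv"),
                config$seed, hash)
      sfs <- .sfsTables(gt, collapsed, config$projection)
      if (!is.null(sfs))
        .writeTsv(sfs, file.path(config$outDir, "sfs.tsv"),
                  config$seed, hash)
      loadOut <- list(collapsed = collapsed, counts = counts,
                      props = props, tests = tests, sfs = sfs)
      say("[load] %d collapsed sites", nrow(collapsed))
    }

    stage <- "relate"
    relOut <- NULL
    if (isTRUE(config$relate)) {
      asd <- alleleSharingDistance(gt)
      mds <- classicalMds(asd$distance, k = 2)
      kin <- kinshipMatrix(gt)
      fst <- weirCockerhamFst(gt)
      .writeTsv(as.data.frame(asd$distance),
                file.path(config$outDir, "asd.tsv"), config$seed, hash)
      .writeTsv(data.frame(sample = rownames(mds$points), mds$points),
                file.path(config$outDir, "mds.tsv"), config$seed, hash)
      .writeTsv(kin, file.path(config$outDir, "kinship.tsv"),
                config$seed, hash)
      .writeTsv(data.frame(weighted_fst = fst$weighted,
                           n_sites = fst$nSitesUsed),
                file.path(config$outDir, "fst.tsv"), config$seed, hash)
      relOut <- list(asd = asd, mds = mds, kinship = kin, fst = fst)
      say("[relate] weighted Fst %.4f", fst$weighted)
    }

    stage <- "report"
    rep <- makeReport(list(rohSummary = rs, tmrca = tmrca,
                           load = loadOut))
    for (nm in names(rep))
      .writeTsv(rep[[nm]],
                file.path(config$outDir, paste0("report_", nm, ".tsv")),
                config$seed, hash)
    meta <- list(seed = config$seed, config = hash,
                 package = as.character(utils::packageVersion("inbredscope")),
                 elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
    jsonlite::write_json(meta, file.path(config$outDir, "run_meta.json"),
                         auto_unbox = TRUE)
    list(genotypes = gt, chromMap = cm, truth = truth,
         filterReport = report, roh = roh, rohSummary = rs, tmrca = tmrca,
         load = loadOut, relate = relOut, report = rep)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(config$outDir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}

.pairwiseLoadTests <- function(props) {
  metrics <- c("propAltDel", "propHetDel", "propHomAltDel")
  species <- unique(props$species)
  if (length(species) < 2)
    return(data.frame(metric = character(), speciesA = character(),
                      speciesB = character(), U = numeric(),
                      p = numeric()))
  pairs <- utils::combn(species, 2)
  rows <- list()
  for (m in metrics) {
    for (k in seq_len(ncol(pairs))) {
      a <- props[props$species == pairs[1, k], m]
      b <- props[props$species == pairs[2, k], m]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (!length(a) || !length(b)) next
      t <- mannWhitneyExact(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, speciesA = pairs[1, k], speciesB = pairs[2, k],
        U = t$U, p = t$p)
    }
  }
  do.call(rbind, rows)
}

.sfsTables <- function(gt, collapsed, projection) {
  sp <- speciesOf(gt)
  species <- unique(unname(sp))
  if (is.null(projection)) {
    ns <- vapply(species, function(s) sum(sp == s), integer(1))
    projection <- stats::setNames(pmax(2L * ns - 4L, 2L), species)
  }
  rows <- list()
  for (s in species) {
    M <- projection[[s]]
    if (is.null(M)) next
    for (cl in c("synonymous", "nonsynonymous", "LOF", "deleterious",
                 "tolerated")) {
      sfs <- tryCatch(sfsForClass(gt, collapsed, s, cl, M),
                      error = function(e) NULL)
      if (is.null(sfs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, class = cl, M = M, j = sfs$j, mass = sfs$mass)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Assemble the summary report tables
#'
#' From saved stage outputs, builds the cohort-level summary surfaces:
#' NROH-vs-SROH per sample, per-class NROH, total ROH > 5 Mb per sample,
#' TMRCA by size class, genotype counts by consequence, and the
#' deleterious-load proportions with pairwise species tests.
#'
#' @param stages `list(rohSummary =, tmrca =, load = )` as produced by
#'   [runPipeline()].
#' @return Named list of `data.frame`s.
#' @export
makeReport <- function(stages) {
  if (is.null(stages$rohSummary)) stop("missing stage output: rohSummary")
  rs <- stages$rohSummary
  rep <- list()
  frohCol <- if ("FROH" %in% names(rs)) rs$FROH else NA_real_
  rep$nroh_sroh <- data.frame(sample = rs$sample, NROH = rs$NROH,
                              SROH = rs$SROH, FROH = frohCol)
  classCols <- grep("^NROH_", names(rs), value = TRUE)
  rep$nroh_by_class <- rs[, c("sample", classCols)]
  rep$sroh_over_5mb <- data.frame(sample = rs$sample,
                                  SROH_over5Mb = rs$SROH_over5Mb)
  if (!is.null(stages$tmrca) && nrow(stages$tmrca)) {
    tm <- stages$tmrca
    agg <- do.call(rbind, lapply(split(tm, tm$sizeClass), function(g)
      data.frame(sizeClass = g$sizeClass[1], n = nrow(g),
                 medianYears = stats::median(g$years),
                 minYears = min(g$years), maxYears = max(g$years),
                 earliestCalendar = min(g$calendarYear),
                 latestCalendar = max(g$calendarYear))))
    rep$tmrca_by_class <- agg[order(agg$sizeClass), , drop = FALSE]
  }
  if (!is.null(stages$load)) {
    cc <- stages$load$counts
    rep$genotype_counts_by_consequence <-
      cc[cc$classType == "consequence",
         c("sample", "species", "class", "nHet", "nHomAlt")]
    rep$load_proportions <- stages$load$props
    rep$load_tests <- stages$load$tests
  }
  rep
}
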