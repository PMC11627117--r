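#' Collapse transcript-level annotations for one site
#'
#' Multiple overlapping transcripts give a site several (consequence,
#' prediction) pairs; they collapse to a single pair by severity. The
#' consequence is the worst under `LOF > nonsynonymous > synonymous`
#' (stop-gain, stop-loss and start-lost all count as loss of function).
#' The effect is `deleterious` when any transcript is predicted
#' deleterious, `tolerated` only when every *predicted* transcript is
#' tolerated, and `none` when no transcript carries a prediction. Sites
#' whose entries are all noncoding carry no collapsed consequence and are
#' flagged `excluded`.
#'
#' @param consequence Character vector of transcript consequences.
#' @param prediction Character vector of transcript predictions
#'   (`deleterious`, `tolerated`, `absent`).
#' @return `list(consequence, effect, excluded, conflict)`; `conflict`
#'   marks sites whose collapsed consequence is LOF while the only
#'   predicted transcripts are tolerated.
#' @export
collapseAnnotation <- function(consequence, prediction) {
  stopifnot(length(consequence) == length(prediction),
            length(consequence) >= 1)
  bad <- setdiff(consequence, .CONSEQUENCES)
  if (length(bad)) stop("unknown consequence token(s): ",
                        paste(bad, collapse = ", "))
  coding <- consequence != "noncoding"
  if (!any(coding))
    return(list(consequence = NA_character_, effect = NA_character_,
                excluded = TRUE, conflict = FALSE))
  cons <- consequence[coding]
  collapsedCons <- if (any(cons %in% .LOF)) "LOF" else
    if (any(cons == "nonsynonymous")) "nonsynonymous" else "synonymous"
  pred <- prediction[coding]
  predicted <- pred[pred != "absent"]
  effect <- if (!length(predicted)) "none" else
    if (any(predicted == "deleterious")) "deleterious" else "tolerated"
  conflict <- collapsedCons == "LOF" && effect == "tolerated"
  list(consequence = collapsedCons, effect = effect,
       excluded = FALSE, conflict = conflict)
}

#' Collapse a whole annotation table
#'
#' Applies [collapseAnnotation()] to every (chrom, pos, alt) key.
#'
#' @param ann An `AnnotationTable` (see [readAnnotationTable()]).
#' @return A `data.frame` with one row per site key: `chrom`, `pos`,
#'   `alt`, `key`, `consequence` (`LOF`/`nonsynonymous`/`synonymous`),
#'   `effect` (`deleterious`/`tolerated`/`none`), `excluded`, `conflict`.
#' @export
collapseAnnotations <- function(ann) {
  if (!nrow(ann))
    return(data.frame(chrom = character(), pos = integer(),
                      alt = character(), key = character(),
                      consequence = character(), effect = character(),
                      excluded = logical(), conflict = logical()))
  sp <- split(seq_len(nrow(ann)), ann$key)
  rows <- lapply(names(sp), function(k) {
    i <- sp[[k]]
    cc <- collapseAnnotation(ann$consequence[i], ann$prediction[i])
    data.frame(chrom = ann$chrom[i[1]], pos = ann$pos[i[1]],
               alt = ann$alt[i[1]], key = k,
               consequence = cc$consequence, effect = cc$effect,
               excluded = cc$excluded, conflict = cc$conflict)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Masked and realized load counts per sample
#'
#' For every sample and annotation class, counts heterozygous (masked) and
#' alternate-homozygous (realized) genotypes among annotated, called
#' sites. Classes are the collapsed consequences (`synonymous`,
#' `nonsynonymous`, `LOF`) and the collapsed effects (`deleterious`,
#' `tolerated`); `effect = "none"` sites are excluded from effect classes
#' but still counted under their consequence.
#'
#' @param x A [GenotypeTable-class].
#' @param collapsed Output of [collapseAnnotations()].
#' @param scope `"all"` counts every annotated site; `"polymorphic"`
#'   restricts to sites polymorphic among called genotypes of the joint
#'   table.
#' @return A long `data.frame`: `sample`, `species`, `classType`
#'   (`consequence` or `effect`), `class`, `nHet`, `nHomAlt`, `nCalled`.
#' @export
loadCounts <- function(x, collapsed, scope = c("polymorphic", "all")) {
  scope <- match.arg(scope)
  collapsed <- collapsed[!collapsed$excluded, , drop = FALSE]
  rr <- rowRanges(x)
  key <- paste(as.character(seqnames(rr)), start(rr), mcols(rr)$ALT,
               sep = ":")
  idx <- match(collapsed$key, key)
  present <- !is.na(idx)
  collapsed <- collapsed[present, , drop = FALSE]
  idx <- idx[present]
  d <- dosages(x)[idx, , drop = FALSE]
  if (scope == "polymorphic") {
    altSum <- rowSums(d, na.rm = TRUE)
    nCalled <- rowSums(!is.na(d))
    poly <- nCalled > 0 & altSum > 0 & altSum < 2 * nCalled
    d <- d[poly, , drop = FALSE]
    collapsed <- collapsed[poly, , drop = FALSE]
  }
  sp <- speciesOf(x)
  tally <- function(rows, class, classType) {
    sub <- d[rows, , drop = FALSE]
    data.frame(sample = colnames(d), species = unname(sp[colnames(d)]),
               classType = classType, class = class,
               nHet = colSums(sub == 1L, na.rm = TRUE),
               nHomAlt = colSums(sub == 2L, na.rm = TRUE),
               nCalled = colSums(!is.na(sub)), row.names = NULL)
  }
  out <- list()
  for (cl in c("synonymous", "nonsynonymous", "LOF"))
    out[[length(out) + 1L]] <- tally(collapsed$consequence == cl, cl,
                                     "consequence")
  for (cl in c("deleterious", "tolerated"))
    out[[length(out) + 1L]] <- tally(collapsed$effect == cl, cl, "effect")
  do.call(rbind, out)
}

#' Per-sample deleterious-load proportions
#'
#' Among sites with a prediction (`deleterious` or `tolerated`), per
#' sample: the proportion of carried alternate alleles that are
#' deleterious (`propAltDel`), of heterozygous genotypes that are
#' deleterious (`propHetDel`), and of alternate homozygotes that are
#' deleterious (`propHomAltDel`).
#'
#' @param counts Output of [loadCounts()].
#' @return A `data.frame` with one row per sample.
#' @export
loadProportions <- function(counts) {
  eff <- counts[counts$classType == "effect", , drop = FALSE]
  samples <- unique(eff$sample)
  out <- lapply(samples, function(s) {
    del <- eff[eff$sample == s & eff$class == "deleterious", ]
    tol <- eff[eff$sample == s & eff$class == "tolerated", ]
    altDel <- del$nHet + 2 * del$nHomAlt
    altAll <- altDel + tol$nHet + 2 * tol$nHomAlt
    data.frame(sample = s, species = del$species[1],
               propAltDel = altDel / altAll,
               propHetDel = del$nHet / (del$nHet + tol$nHet),
               propHomAltDel = del$nHomAlt / (del$nHomAlt + tol$nHomAlt))
  })
  do.call(rbind, out)
}

#' Exact Mann-Whitney U test
#'
#' Mid-rank U statistic with an exact permutation p-value for small
#' samples: when `n1 + n2 <= maxExact` the two-sided p is computed over
#' all `choose(n1 + n2, n1)` reassignments of the observed values
#' (`2 * min(tail)`, capped at 1). Larger samples use the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @param maxExact Largest pooled size for full enumeration.
#' @return `list(U, p, method)` where `U` counts wins of `x` over `y`
#'   (ties as 1/2).
#' @export
mannWhitneyExact <- function(x, y, maxExact = 20L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))
  if (n <= maxExact) {
    sets <- utils::combn(n, n1)
    Uperm <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    pLow <- mean(Uperm <= U + tol)
    pHigh <- mean(Uperm >= U - tol)
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieCorr))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

#' Sites with a private alternate allele
#'
#' A site is private to species S when its alternate allele is carried by
#' at least one called genotype of S and by none of any other species.
#' Sites where some other species has no called genotype are excluded —
#' absence of the allele there cannot be established.
#'
#' @param x A joint [GenotypeTable-class] across all species.
#' @return A `data.frame` of private sites: `key`, `chrom`, `pos`, `alt`,
#'   `species` (owner), `derivedCount` (alternate alleles in the owner)
#'   and `calledHaploid` (2 x called genotypes in the owner). The private
#'   alternate allele is treated as the derived allele.
#' @export
privateAltSites <- function(x) {
  d <- dosages(x)
  sp <- speciesOf(x)
  labels <- unique(sp)
  altBySp <- sapply(labels, function(s)
    rowSums(d[, sp == s, drop = FALSE], na.rm = TRUE))
  calledBySp <- sapply(labels, function(s)
    rowSums(!is.na(d[, sp == s, drop = FALSE])))
  carriers <- altBySp > 0
  nCarrierSp <- rowSums(carriers)
  allObserved <- rowSums(calledBySp > 0) == length(labels)
  private <- nCarrierSp == 1 & allObserved
  if (!any(private))
    return(data.frame(key = character(), chrom = character(),
                      pos = integer(), alt = character(),
                      species = character(), derivedCount = integer(),
                      calledHaploid = integer()))
  owner <- labels[apply(carriers[private, , drop = FALSE], 1, which)]
  rr <- rowRanges(x)[private]
  i <- which(private)
  data.frame(
    key = paste(as.character(seqnames(rr)), start(rr), mcols(rr)$ALT,
                sep = ":"),
    chrom = as.character(seqnames(rr)), pos = start(rr),
    alt = mcols(rr)$ALT, species = owner,
    derivedCount = altBySp[cbind(i, match(owner, labels))],
    calledHaploid = 2L * calledBySp[cbind(i, match(owner, labels))])
}

#' Hypergeometric projection of an unfolded SFS
#'
#' Projects per-site derived-allele counts observed at varying called
#' haploid sizes down to a common size `M`. A site with derived count `i`
#' of `N` called haploids contributes mass
#' `choose(i, j) choose(N - i, M - j) / choose(N, M)` to bin `j`
#' (`j = 0..M`); sites with `N < M` are dropped. Bin `M` (fixed in the
#' projected sample) is retained.
#'
#' @param derivedCount Integer vector of per-site derived-allele counts.
#' @param calledHaploid Integer vector of per-site called haploid sizes.
#' @param M Projection size (haploid).
#' @param normalizeBy Optional divisor (e.g. the total number of private
#'   alternate sites of the mutation class); `NULL` leaves raw expected
#'   site counts.
#' @return A `data.frame` with columns `j` (0..M) and `mass`, plus
#'   attributes `nSitesUsed` and `nSitesDropped`.
#' @export
projectSfs <- function(derivedCount, calledHaploid, M,
                       normalizeBy = NULL) {
  stopifnot(length(derivedCount) == length(calledHaploid), M >= 1)
  keep <- calledHaploid >= M
  if (!any(keep))
    stop("no site has called haploid size >= projection M = ", M)
  i <- derivedCount[keep]; N <- calledHaploid[keep]
  mass <- vapply(0:M, function(j)
    sum(stats::dhyper(j, m = i, n = N - i, k = M)), numeric(1))
  if (!is.null(normalizeBy)) mass <- mass / normalizeBy
  out <- data.frame(j = 0:M, mass = mass)
  attr(out, "nSitesUsed") <- sum(keep)
  attr(out, "nSitesDropped") <- sum(!keep)
  out
}

#' Private-allele SFS by species and mutation class
#'
#' Combines [privateAltSites()], [collapseAnnotations()] and
#' [projectSfs()]: for one species, selects private sites of a collapsed
#' consequence or effect class and projects their derived counts to `M`
#' haploids, normalised by the species' total private-site count of that
#' class.
#'
#' @param x A joint [GenotypeTable-class].
#' @param collapsed Output of [collapseAnnotations()].
#' @param species Focal species label.
#' @param class Collapsed class: one of `synonymous`, `nonsynonymous`,
#'   `LOF`, `deleterious`, `tolerated`.
#' @param M Projection size.
#' @return As [projectSfs()], with bins `1..M` of primary interest.
#' @export
sfsForClass <- function(x, collapsed, species, class, M) {
  priv <- privateAltSites(x)
  priv <- priv[priv$species == species, , drop = FALSE]
  field <- if (class %in% c("deleterious", "tolerated", "none"))
    "effect" else "consequence"
  keys <- collapsed$key[!collapsed$excluded & collapsed[[field]] == class]
  sel <- priv[priv$key %in% keys, , drop = FALSE]
  if (!nrow(sel))
    stop("no private ", class, " sites for species ", species)
  projectSfs(sel$derivedCount, sel$calledHaploid, M,
             normalizeBy = nrow(sel))
}
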