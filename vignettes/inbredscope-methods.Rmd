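---
title: "Methods: ROH detection, haplotype dating and genetic load in inbredscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, haplotype dating and genetic load in inbredscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbredscope)
```

# Scope and scientific setting

`inbredscope` characterises recent inbreeding and deleterious variation in
small, multi-species genotype cohorts of the kind produced by conservation
genomics resequencing projects: a handful of diploid individuals per
species (typically 5–7), jointly genotyped against a common reference, with
one bottlenecked focal species compared against stable relatives. The
package covers the downstream analysis only — it consumes a multi-sample
VCF with `GT`/`DP`/`GQ` fields, a chromosome map, and a per-transcript
consequence/prediction annotation table; read alignment and variant
calling are out of scope.

The central quantities are:

* **Runs of homozygosity (ROH)** — contiguous autozygous tracts where both
  haplotypes descend from a recent common ancestor.
* **TMRCA of ROH haplotypes** — the age of that common ancestor, inverted
  from segment length.
* **F_ROH** — the fraction of the autosomal genome in ROH, an inbreeding
  coefficient.
* **Masked vs realized load** — deleterious variants carried heterozygous
  (shielded if recessive) versus homozygous (exposed).
* **Private-allele site frequency spectra** — the frequency distribution
  of variants unique to one species, projected to a common sample size.

# Genotype filtering

Filters run in a fixed order, and the `FilterReport` reconstructs
input − output exactly at every step:

1. non-autosomes (sex chromosomes, unmapped scaffolds) are dropped;
2. only biallelic single-nucleotide records are kept (multi-nucleotide,
   indel, complex and multi-allelic records fail);
3. site QUAL must be **strictly** greater than the threshold (default 50);
4. the combined across-sample depth must fall inside an inclusive
   keep-range — by default the 5th/95th **nearest-rank** percentiles of
   the data at hand (nearest-rank is reproducible across platforms and
   needs no interpolation convention);
5. a site fails if any species, evaluated separately, reaches its
   excess-heterozygosity threshold (4 at n = 5, 6 at n = 7, else
   `ceiling(0.8 n)`). Per-species evaluation keeps the rule calibrated to
   each cohort's size, because formal excess-het tests are underpowered at
   these sample counts. The n = 5 rule is implemented as ≥ 4 to parallel
   the unambiguous "six or more" convention at n = 7, and both are
   parameters;
6. genotypes with DP outside [6, 34] or GQ below 20 are set missing
   (masking **precedes** the missingness count, since masking creates the
   missingness that matters), then sites with ≥ 3 missing genotypes fail;
7. sites monomorphic across all remaining called genotypes are dropped.

With explicit depth bounds the chain is idempotent: a second pass removes
nothing. With percentile-derived bounds idempotence cannot hold in
general — the percentiles of the surviving depths are interior to the
previous keep-range — so bounds derivation is treated as parameter
estimation, done once, rather than as part of the repeatable chain.

# ROH detection

## Genotype LOD model

For each genotype at a site with reference-allele frequency $p$
(alternate $q = 1 - p$) and genotype error $\varepsilon$, the autozygosity
evidence is the log-likelihood ratio

$$\mathrm{LOD} = \log_{10}
  \frac{P(g \mid \text{autozygous})}{P(g \mid \text{non-autozygous})},$$

with emission probabilities

| genotype | autozygous | non-autozygous (HWE) |
|---|---|---|
| hom-ref | $(1-\varepsilon)p + \varepsilon p^2$ | $p^2$ |
| het | $\varepsilon \cdot 2pq$ | $2pq$ |
| hom-alt | $(1-\varepsilon)q + \varepsilon q^2$ | $q^2$ |

Under autozygosity the two haplotypes are identical by descent, so a
heterozygote can only be a genotyping error: its LOD is
$\log_{10}\varepsilon$ exactly, independent of frequency. The error is
taken from the genotype's own quality, $\varepsilon = 10^{-GQ/10}$,
floored at $10^{-6}$ and capped at 0.25 to keep the likelihoods proper
(an error probability above 1/4 would make the "error" model more likely
than random assortment). Allele frequencies are estimated per species
with a single pseudocount allele each way,
$p = (2 n_\text{homref} + n_\text{het} + 1) / (2 n_\text{called} + 2)$,
which keeps $0 < p < 1$ even at sites fixed within the sample. Missing
genotypes contribute LOD 0.

## Windows, threshold, assembly

LOD scores are summed over sliding windows of 100 consecutive SNPs
(step 1 SNP), separately per sample and chromosome; chromosomes with
fewer SNPs than one window yield none. Thresholding is per species, with
window scores pooled across that species' samples, because the
frequencies — and therefore the score scale — are species-specific: a
Gaussian kernel density (Silverman's rule bandwidth, 512-point grid) is
fitted to the pooled scores, and the threshold is the grid position of
the minimum density between the two highest-density modes. The lower mode
collects ordinary heterozygous-rich windows, the upper mode autozygous
windows; the valley separates them without any tuned constant. A unimodal
density (no autozygous mass) falls back to threshold 0, which in practice
passes nothing, since a window must be essentially heterozygote-free to
score positive.

A SNP is provisionally autozygous when **any** window covering it passes.
This union rule is the standard window-caller convention, but on its own
it drags segment ends up to `winsize − 1` SNPs past a tract edge (a window
with 90 autozygous SNPs still passes and stamps its 10 outside SNPs).
Each candidate run is therefore trimmed to its **maximal-scoring
contiguous subsegment** of per-SNP LOD (Kadane's algorithm): inside a true
tract the running sum grows, outside it falls, so the maximising
subsegment ends close to the true boundary. On simulated tracts this
keeps boundary error to a few SNPs where the raw union rule leaves
hundreds of kb of overhang.

Trimmed segments shorter than 0.5 Mb are discarded as likely false calls;
survivors get the fixed half-open size classes
$[0.5,1), [1,2), [2,3), [3,4), [4,5), [5,\infty)$ Mb. Detection is fully
deterministic given its input.

# Dating and F_ROH

An IBD segment whose common ancestor lived $g$ generations ago has
expected genetic length $l = 100/(2g)$ cM. Physical lengths are converted
at chromosome-level mean recombination rates binned by the **chromosome's**
(not the segment's) size — macrochromosomes recombine less per Mb:
≥ 100 Mb → 1.6 cM/Mb, [50, 100) → 2.0, [25, 50) → 1.7, [10, 25) → 1.5,
and < 10 Mb → 1.5 (no separate microchromosome estimate exists, so the
smallest reported bin's rate is reused). Bin edges are half-open
$[low, high)$; the source prose ("50–100 Mb") does not resolve the edges,
so one convention is fixed and documented. Then $g = 50/l$, years before
sampling $= g \times$ generation time (2 years for a small passerine),
and the calendar year subtracts the **floored** whole-year value from the
sampling year (2006): a 1 Mb segment on a microchromosome gives
$l = 1.5$ cM, $g = 33.3$, 66.67 years → reported as 66 whole years and
calendar year 1940; a 2 Mb segment in the 2.0 cM/Mb class gives 25 years
and 1981. Truncation (rather than rounding) is what makes the printed
pair (66, 1940) self-consistent, and it is configurable.

Because segment lengths are exponentially distributed around their
expectation, the per-segment age estimate $\hat g = 50/l$ is strongly
skewed: its **median** is $g/\ln 2 \approx 1.44\,g$, not $g$. The
property suite asserts this analytically correct behaviour; users should
read per-segment ages as order-of-magnitude statements and class-level
summaries as the robust quantity.

`F_ROH` divides a sample's summed segment lengths by the chromosome map's
total **autosomal** length — not by the SNP-covered span — so sparse
chromosome ends do not inflate the coefficient. Overlapping segments for
one sample are a validation error.

# Genetic load

Transcript-level annotations collapse to one (consequence, effect) pair
per site: the worst consequence under
LOF > nonsynonymous > synonymous (stop-gain, stop-loss and start-lost all
count as LOF); the effect is deleterious if **any** transcript is
predicted deleterious, tolerated only if **all predicted** transcripts are
tolerated, and none if no transcript carries a prediction. Sites whose
collapsed consequence is LOF while their only predicted transcripts are
tolerated satisfy both letter-rules simultaneously; they are kept but
flagged (`conflict`), since the two rules pull in different directions
there. All-noncoding sites are excluded, with a flag rather than silent
dropping.

Load counts tally, per sample and class, heterozygous (masked) and
alternate-homozygous (realized) genotypes among annotated called sites,
either over all sites or restricted to sites polymorphic in the joint
table. Effect-"none" sites are excluded from effect-based proportions but
still counted under their consequence — the effect table is genuinely
smaller than the consequence table because LOF predictions are often
unavailable. The three reported proportions per sample are: deleterious
share of carried alternate alleles, of heterozygous genotypes, and of
alternate homozygotes, each over predicted sites only; these denominators
are declared rather than inherited from any external convention, and are
configurable.

Species comparisons use a Mann–Whitney U test with mid-ranks. At these
cohort sizes asymptotics are unreliable, so for pooled $n \le 20$ the
two-sided p-value is exact: all $\binom{n}{n_1}$ reassignments of the
observed values are enumerated and $p = \min(1, 2\min(\text{tails}))$.
Larger samples fall back to the normal approximation with tie and
continuity corrections. No multiple-testing correction is applied; raw
p-values are reported.

A site is **private** to a species when at least one of its called
genotypes carries the alternate allele and no called genotype of any
other species does; sites where some other species is entirely missing
are excluded, because absence cannot be established there. The private
alternate allele is treated as derived (all species are mapped to an
outgroup reference). Per class, derived counts at varying called sample
sizes are projected to a common haploid size $M$ by the hypergeometric
expectation — a site with $i$ derived of $N$ called haploids contributes
$\binom{i}{j}\binom{N-i}{M-j}/\binom{N}{M}$ to bin $j$ — dropping sites
with $N < M$. The fixed bin $j = M$ is retained (fixed derived mutations
are a finding, not an artefact), and spectra can be normalised by the
class's total private-site count.

# Relatedness and structure checks

These guard the ROH analysis: close relatives or admixed cohorts bias
autozygosity inference.

* **Allele-sharing distance**: per pair over pairwise-complete sites,
  shared alleles $s = 2 - |d_i - d_j|$ (both-het pairs share 2), distance
  $1 - \bar s/2$. Classical (Torgerson) MDS via `cmdscale` embeds the
  matrix; axis signs are fixed by forcing the largest-magnitude loading
  positive so plots are reproducible.
* **KING-robust kinship**:
  $\varphi = (N_\text{both-het} - 2N_\text{opposite-hom}) /
  (N_\text{het},_i + N_\text{het},_j)$, robust to structure because it
  never uses population frequencies. Degree labels use the standard
  powers-of-$\sqrt2$ cutoffs and are reporting only.
* **Weir–Cockerham Fst** (1984 two-level estimator): per-site variance
  components $a$ (among populations), $b$ (among individuals within) and
  $c$ (within individuals) from sample sizes, allele frequencies and
  observed heterozygosities; the genome-wide estimate is
  $\sum a / \sum (a+b+c)$. Sites with an all-missing population are
  skipped; $(a+b+c) = 0$ sites are excluded from the weighted sums.

# The synthetic cohort generator

Every stage is validated against planted ground truth, so the generator
is first-class code. It emulates:

* 2–3 species cohorts of 5–7 diploid samples (defaults 7/5/7);
* alternate-allele frequencies from a truncated Beta(0.2, 0.2) — a
  U-shaped, neutral-ish SFS — drawn independently per species for shared
  sites, with a configurable fraction of sites private to each species;
* `snpDensity` **segregating** sites per Mb (default 100): candidate
  sites are oversampled, genotyped, and conditioned on joint polymorphism
  before trimming to the target count — a variant-only VCF contains
  polymorphic sites, and an unconditioned U-shaped law would silently
  halve the density every downstream stage sees;
* planted autozygous tracts: physical length drawn
  Exponential(mean $100/(2g)$ cM) at the chromosome's size-binned rate,
  placed uniformly without overlap, all covered sites set homozygous by
  copying one haplotype draw, floored at 10 SNPs so the caller has
  signal (the floor is a parameter; length-law tests disable it);
* genotype noise: DP negative-binomial (mean 20, size 10 — ~20×
  coverage with realistic overdispersion), GQ a discretised Gamma
  (shape 9, scale 5; mean 45) capped at 99; inside tracts genotypes flip
  to heterozygous with probability $10^{-GQ/10}$, so error rates and
  reported qualities are mutually consistent;
* SIFT-style annotations: ~30% of sites annotated; consequence mix 61%
  synonymous / 38% nonsynonymous / 1% LOF with stop-gain dominating LOF;
  predictions mostly absent for LOF; deleterious probabilities set so
  roughly 16% of predicted sites are deleterious — proportions typical of
  passerine coding annotation;
* an optional per-species push of deleterious alternate frequencies
  toward fixation (`delFreqShift`) for power checks of the load
  comparison.

The truth set records every planted tract with its true $g$, the pairwise
kinship classes, and the realized per-species frequency draws (so tests
can use closed-form oracles conditional on the realized law). A fixed
seed yields byte-identical VCF output.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium outside planted
tracts (sites are independent), recombination within tracts, shared
pedigree among cohort samples (kinship pairs are generated separately
from an explicit IBD model), reference bias, variable per-site mutation
rates, and genotype-calling artefacts beyond symmetric DP/GQ noise.

# Numerical choices and degenerate inputs

* $\varepsilon \in [10^{-6}, 0.25]$; allele-frequency pseudocount 1 each
  way; KDE on 512 grid points with `nrd0` bandwidth.
* Fewer than 100 pooled windows, or a constant score set, falls back to
  threshold 0 with a warning; a chromosome with fewer SNPs than one
  window yields no windows (warning, not error).
* Kadane trimming of an all-negative candidate keeps its single best SNP;
  such fragments are then removed by the 0.5 Mb floor.
* Exact Mann–Whitney ties use mid-ranks with a $10^{-9}$ comparison
  tolerance in the tail counts; identical multisets return $p = 1$.
* Pairs with zero complete sites (distance), zero heterozygotes (KING) or
  an all-missing population (Fst) are flagged/skipped, never silently
  imputed.
* BED output converts the internal 1-based inclusive coordinates exactly
  (`start − 1`, `end`); phased genotype separators are read as unphased.

# Problem sizes used by the test suite

The suite exercises the caller on 7 samples across three 30 Mb
chromosomes at 100 SNPs/Mb with tracts planted at $g \in \{5, 15, 40\}$ —
large enough that every size class from ~0.7 Mb to ~20 Mb occurs, small
enough to run in seconds. Length-law and dating properties use 400–1000
planted tracts; kinship checks use 50 replicate pairs of 20,000 sites per
class; the exact Mann–Whitney implementation is checked against full
enumeration for every partition of pooled size ≤ 14; SFS projection is
checked against exhaustive subset enumeration for $N \le 8$, $M \le 4$.

# Known limitations

* The ROH emission model is declared here, not claimed identical to any
  external caller; exact numerical replication of other tools' output is
  a non-goal.
* Chromosome-level mean recombination rates ignore local rate variation;
  segment ages in low-recombination regions are overestimated and vice
  versa.
* Private-allele polarisation assumes the reference is a true outgroup at
  private sites.
* The package treats samples as unrelated and unadmixed; the relatedness
  module checks, but does not correct for, violations.
* Uncertainty intervals on per-segment $g$ are not produced; the
  exponential length distribution makes single-segment ages noisy by
  nature.
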