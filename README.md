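# inbredscope

Runs of homozygosity, haplotype dating and genetic load for small
multi-species genotype cohorts.

## What it is for

Severely bottlenecked populations — the situation of many
conservation-listed birds and mammals — accumulate long runs of
homozygosity (ROH): contiguous tracts where both haplotypes descend from
a recent common ancestor. The lengths of those tracts date the
inbreeding, and the genotypes inside them expose recessive deleterious
variation ("realized load") that larger populations keep masked in
heterozygotes. `inbredscope` implements the full desk analysis for
whole-genome genotype data from a few individuals per species:

* strict site- and genotype-level VCF filtering with an exact removal
  report;
* a model-based ROH caller: per-genotype autozygosity LOD scores
  (log10 of `P(g | autozygous) / P(g | Hardy–Weinberg)`, with the
  heterozygote-under-autozygosity probability `ε·2pq` taken from each
  genotype's GQ), summed over 100-SNP sliding windows, thresholded at the
  valley of the pooled window-score kernel density, assembled into
  segments with fixed half-open size classes `[0.5,1) … [5,∞)` Mb;
* TMRCA dating by inverting the expected IBD length relationship
  `l = 100/(2g)` cM, with chromosome-size-binned recombination rates
  (1.6 / 2.0 / 1.7 / 1.5 cM/Mb) and calendar back-projection from the
  sampling year;
* the inbreeding coefficient `F_ROH` against the autosomal genome length;
* masked vs realized deleterious-load accounting from SIFT-style
  transcript annotations (worst-consequence collapse, any-deleterious
  effect rule), with exact small-sample Mann–Whitney U comparisons;
* private-allele unfolded site frequency spectra by hypergeometric
  projection;
* relatedness and structure checks: allele-sharing distance + classical
  MDS, KING-robust kinship, Weir–Cockerham Fst;
* a synthetic cohort generator that plants autozygous tracts of known
  age, so every stage is testable against ground truth without external
  data.

## Worked example

Simulate a 7-sample cohort on three 30 Mb chromosomes (100 SNPs/Mb) with
autozygous tracts planted in samples 1–4 at ages of 5, 15 and 40
generations, then call and date ROH:

```r
library(inbredscope)

cfg <- simConfig(seed = 11,
  species = list(list(label = "kw", n = 7)),
  chromMap = ChromosomeMap(paste0("chr", 1:3), rep(30e6, 3)),
  snpDensity = 100,
  tracts = data.frame(species = "kw", sampleIndex = rep(1:4, each = 3),
                      chrom = rep(paste0("chr", 1:3), 4),
                      g = rep(c(5, 15, 40), 4), count = 1))
sim <- simulateCohort(cfg)
sim$genotypes
#> GenotypeTable: 9000 sites x 7 samples
#>   species: kw (n=7)
#>   chromosomes: chr1, chr2, chr3
#>   missing genotypes: 0.00%

roh <- callRoh(sim$genotypes)
head(as.data.frame(roh$segments), 4)
#>   seqnames    start      end   width strand sample      lod sizeClass
#> 1     chr1 17309943 22570621 5260679      *  kw_01 92.70112   [5,Inf)
#> 2     chr2 19802073 21952230 2150158      *  kw_01 38.27649     [2,3)
#> 3     chr1  6272425 11612672 5340248      *  kw_02 86.49169   [5,Inf)
#> 4     chr2  4861135  8864480 4003346      *  kw_02 71.54043     [4,5)

rohSummary(roh$segments, sampleNames(sim$genotypes), cfg$chromMap)[,
  c("sample", "NROH", "SROH", "FROH")]
#>   sample NROH     SROH       FROH
#> 1  kw_01    2  7410837 0.08234263
#> 2  kw_02    3 10462514 0.11625016
#> 3  kw_03    2  3304115 0.03671239
#> 4  kw_04    2  6405931 0.07117701
#> 5  kw_05    0        0 0.00000000
#> 6  kw_06    0        0 0.00000000
#> 7  kw_07    0        0 0.00000000

tm <- estimateTmrca(roh$segments, cfg$chromMap)
head(tm[, c("sample", "chrom", "lengthBp", "sizeClass", "lCm",
            "generations", "years", "calendarYear")], 4)
#>   sample chrom lengthBp sizeClass      lCm generations    years calendarYear
#> 1  kw_01  chr1  5260679   [5,Inf) 8.943154    5.590869 11.18174         1995
#> 2  kw_01  chr2  2150158     [2,3) 3.655269   13.678885 27.35777         1979
#> 3  kw_02  chr1  5340248   [5,Inf) 9.078422    5.507565 11.01513         1995
#> 4  kw_02  chr2  4003346     [4,5) 6.805688    7.346796 14.69359         1992
```

Reading the output: tract-free samples `kw_05`–`kw_07` come back with
`NROH = 0` and `F_ROH = 0`; the planted samples carry 3.3–10.5 Mb of ROH
(`F_ROH` 0.037–0.116). A 5.26 Mb segment on a 30 Mb chromosome
(1.7 cM/Mb bin) has genetic length 8.9 cM, so its haplotypes coalesce
`g = 50/8.9 ≈ 5.6` generations ≈ 11 years before the 2006 sampling date —
calendar year 1995 — while the 2.15 Mb segment dates ~27 years back
(1979). Longer ROH mean more recent inbreeding.

The same analysis runs end-to-end on files via
`runPipeline(pipelineConfig(...))`, which writes per-stage TSV/BED
outputs plus summary report tables (per-sample NROH/SROH/F_ROH, per-class
counts, TMRCA by class, load proportions with pairwise species tests,
SFS tables), each stamped with the seed and a config checksum. A thin
command-line wrapper is included at `inst/scripts/inbredscope`.

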