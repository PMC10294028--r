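---
title: "Detecting selective sweeps with windowed Hp and Fst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with windowed Hp and Fst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Domestication and breed formation leave footprints in the genome: around a
beneficial allele driven toward fixation, genetic diversity collapses in the
selected population and allele frequencies diverge sharply from related wild
populations. `sweepscan` implements the classic two-population genome scan
for such footprints, contrasting a wild and a domestic population (the
motivating design is 12 wild against 59 domestic diploid sheep genomes): it
slides windows along the genome, computes diversity and differentiation
statistics per window, and calls the extreme tails of their genome-wide
distributions as candidate sweep regions.

## The statistics

**Pooled heterozygosity (Hp).** For every SNP in a window, the within-
population major and minor allele *counts* $n_{Maj}, n_{Min}$ are summed
over sites, and

$$H_p = \frac{2\,\Sigma n_{Maj}\,\Sigma n_{Min}}
             {(\Sigma n_{Maj} + \Sigma n_{Min})^2}.$$

$H_p \in [0, 0.5]$, with 0.5 when pooled major and minor counts balance and
0 when every site is fixed; a sweep in the focal population drags window Hp
toward 0. Some descriptions of this statistic speak of summed allele
*frequencies*; we sum integer allele counts, which is the dimensional
structure of the formula above. The two readings coincide whenever every
site in a window has the same number of called chromosomes and diverge only
under missingness, where counts weight each site by its call rate.

**Fixation index (Fst).** Per site,

$$F_{ST} = \frac{H_T - H_S}{H_T},$$

with $H_S$ the average within-population expected heterozygosity
$2p(1-p)$ and $H_T$ the expected heterozygosity at the pooled frequency.
The estimator needs two choices the formula leaves open, both exposed as
switches with these defaults:

* the two populations enter $H_S$ and the pooled frequency **unweighted**
  (`fst_weighting = "weighted"` switches to weighting by called chromosome
  counts, which matters with 12 vs 59 samples);
* the window summary is the **mean of per-site ratios**
  (`fst_method = "ratio_of_averages"` instead forms one ratio from
  window-averaged $H_T$ and $H_S$).

Sites monomorphic in the pool ($H_T = 0$) are undefined ($0/0$) and are
excluded from window averages rather than scored 0; sites uncallable in
either population are likewise skipped.

**Nucleotide diversity.** Per window,
$\pi = \frac{1}{L}\sum_s 2 n_{Maj} n_{Min} / (n_c (n_c - 1))$ with $n_c$
the called chromosomes at site $s$ and $L$ the window span — the unbiased
per-site heterozygosity summed over SNPs. Invariant sites contribute
nothing, so $\pi$ is computable from a SNP-only table; its absolute scale
therefore tracks the SNP density of the input.

**LD r².** Unphased linkage disequilibrium is the squared Pearson
correlation of ALT-dosage vectors (Rogers–Huff style), since only
genotypes, not phased haplotypes, are assumed available.

## The scan

Windows are 150 kb sliding by 50 kb by default. Windows start at 1,
1 + step, …, and a partial trailing window is dropped rather than clipped,
keeping the per-window SNP-count distribution homogeneous for the
standardisation that follows. Windows with fewer than
`min_snps_per_window = 10` SNPs are excluded before standardisation:
sparse windows have high-variance Hp and Fst and would otherwise dominate
the tails artifactually.

Retained windows are Z-transformed — $(x - \bar x)/s$ with the sample
standard deviation — jointly across all scanned contigs, since the tail
cutoff is meant to act on one genome-wide distribution. Outliers are
called with strict inequalities at `z_cutoff = 2.326` (the upper 1%
normal quantile): windows with $Z(H_p) < -2.326$ form the low-diversity
tail and windows with $Z(F_{ST}) > +2.326$ the high-differentiation tail.
By default Hp is tested in the *domestic* population only (the second
population label in map order, configurable via `hp_population`), which is
the population expected to carry the sweeps.

Selected windows that overlap or abut are merged into maximal regions, and
the final candidate sweep regions are the genomic intersection of the Hp
and Fst evidence tracks — a region must show both reduced domestic
diversity and elevated differentiation. Intersection can split intervals,
so region *counts* need not be ordered across tracks, but intersected
base pairs never exceed either parent track's.

All internal coordinates are 1-based inclusive (the VCF/GFF3 convention);
BED input and output are converted at the file boundary. Sex chromosomes
are excluded by default (`exclude_contigs = c("chrX", "X")`) because the
scan targets autosomal directional selection.

## The simulator

`simulate_dataset()` emulates the statistical structure of a
wild-vs-domestic resequencing panel without modelling its history:

* Each SNP gets an ancestral frequency $p \sim U(0.05, 0.95)$, then
  per-population frequencies from the Balding–Nichols Beta
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, the simplest generator with a
  tunable differentiation expectation ($E[F_{ST}] \approx F$).
* The default drift coefficients are $F = 0.05$ (wild) and $F = 0.15$
  (domestic), so that expected domestic diversity is lower by the factor
  $(1-F_d)/(1-F_w) \approx 0.89$ — the direction of the wild/domestic
  contrast the scan is designed around. Analyses of neutral calibration
  and parameter recovery use a symmetric $F = 0.05$.
* Sweeps are injected at the *frequency* level: inside each planted
  region the domestic ALT frequency is redrawn from a Beta tightly
  concentrated (concentration 400) at `sweep_domestic_freq = 0.99`. The
  scan consumes site frequencies only, so frequency-level injection
  suffices and keeps the simulator dependency-free; no coalescent
  haplotype structure is simulated.
* Genotypes are Binomial(2, $p$) per diploid (Hardy–Weinberg within
  populations), masked missing independently at `missing_rate = 0.02`.
  Sample sizes default to the unequal 12 wild / 59 domestic design.
* Sites are independent by default (no LD). An optional founder-haplotype
  mosaic mode (`ld_mode = "block"`) makes each haploid genome copy one of
  `n_founders` founder haplotypes, switching founders at exponentially
  distributed distances (`block_length_bp`), which yields r² decaying
  with distance and is used only to exercise the LD-curve code.

What passing tests on this simulator do **not** show: robustness to real
LD structure, demography, depth-dependent genotyping error, reference
bias, or variant-calling artefacts. The simulator plants no depth
structure and applies no site filters; on real data any MAF/missingness
filtering is the caller's explicit choice before the scan.

`simulate_annotations()` tiles non-overlapping fixed-length genes along
the genome (one gene per `gene_spacing_bp`) and assigns genes to terms
independently with probability `term_prob`, giving a fully known gene
universe for the enrichment stage.

## Annotation and enrichment

Genes overlapping any candidate region by ≥ 1 bp are selected (no minimum
overlap fraction) and deduplicated. An optional consequence table (e.g. a
variant-effect-predictor export) restricts candidates to genes with a
missense variant located *inside* a candidate region. Over-representation
per term is the upper-tail hypergeometric probability of drawing at least
the observed number of in-term study genes from the background (default
background: all annotated genes); terms without study genes are reported
with $p = 1$. P-values get Benjamini–Hochberg adjustment and a
`significant` flag at FDR < 0.05; the full table is always returned,
never pre-filtered.

## Numerical and design choices

* Major/minor alleles are classified per population per site; exact ties
  call REF major (Hp is invariant to the tie-break).
* A constant statistic vector has no tails, so `z_transform()` refuses
  zero-spread input rather than returning zeros.
* Boundary windows with Z exactly at the cutoff are *not* selected
  (strict inequalities).
* Merging treats abutting intervals (gap 0 bp) as one region; a 1 bp gap
  separates regions.
* `evaluate_detection()` scores recall as the fraction of truth regions
  hit by ≥ 1 bp and precision as the fraction of detected regions hitting
  truth; an empty truth set is an error (recall would be 0/0), and an
  empty detection reports recall 0 with precision NA.
* Half-calls and non-diploid genotypes are read as missing: the allele-
  count statistics need complete two-allele calls.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while leaving the statistics in their asymptotic regime: oracle
equivalence on ≤ 20-site/≤ 25-gene instances (1e-12 agreement against
naive reimplementations); tail calibration on a neutral 502 Mb, 10-contig
genome at 1 SNP/kb, giving ~10,000 retained windows of ~150 SNPs each
(each 1% tail must capture 0.5–1.5% of windows); parameter recovery on
the default 30 Mb genome with ten 300 kb sweeps over 10 seeds (median
recall ≥ 0.8, precision ≥ 0.5); and the diversity ordering over 20
seeded 6 Mb replicates (domestic π < wild π in ≥ 95%).

## Worked example

```{r example}
cfg <- sim_config(
  genome_length_bp = 5e6, seed = 7,
  sweep_regions = data.frame(contig = "chr1",
                             start = c(1e6, 3.5e6), end = c(1.3e6, 3.8e6)))
sim <- simulate_dataset(cfg)
res <- sweep_scan(sim$sites, sim$popmap)
res
res$regions
evaluate_detection(res$regions, sim$truth)
```

## Known limitations

The scan is frequency-based only: haplotype statistics (iHS, XP-EHH) and
the Weir–Cockerham variance-component Fst estimator are out of scope, as
are permutation/simulation-based significance, GO-DAG-aware enrichment
and ortholog mapping. Region counts from real studies depend on the real
panels behind them; this package mirrors the logic, and its simulator
recovers *planted* sweeps, which bounds but does not guarantee behaviour
on real data.
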