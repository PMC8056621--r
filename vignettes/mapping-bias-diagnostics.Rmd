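---
title: "Detecting reference mapping bias in RNA-seq eQTL studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reference mapping bias in RNA-seq eQTL studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlbias)
```

## The problem

When RNA-seq reads from genetically distinct individuals are quantified
against a single reference genome, reads carrying alleles that diverge
from the reference may fail to map or map elsewhere. Transcript
abundances of non-reference alleles are then systematically
underestimated. In a biparental recombinant inbred line (RIL) panel this
artifact has a clean genetic signature: at a cis-eQTL, lines carrying
the reference (template) parent's allele appear to express more, so the
template parent accumulates an implausible excess of "positively
acting" regulatory alleles. In an unbiased experiment the two parents
should contribute positive alleles in roughly equal numbers.

`eqtlbias` implements the full diagnostic battery around that idea —
dual-template eQTL mapping, direction-asymmetry and discordance
statistics, divergence-scaled bias profiles, haplotype-consistency
coexpression analysis, and UTR/splice-junction read-ratio tests —
together with a synthetic-data generator that reproduces the data
structure of a maize-like RIL expression study so that every stage can
be exercised against known ground truth without any download.

## The synthetic study design

`sim_config()` describes a two-parent cross: ten chromosomes of 200 Mb,
97 RILs (a 105-line population minus excluded heterozygous lines), and
~300 genotyped markers. Each RIL chromosome is a Markov mosaic of the
two parental haplotypes; the switch probability between adjacent loci at
map distance $d$ cM is the selfed-RIL expansion of the Haldane map
function,

$$R(d) = \frac{2r}{1+2r},\qquad r = \tfrac12\left(1-e^{-2d/100}\right),$$

with no interference. Residual heterozygous calls (1%) and missing
calls (2%) are injected into the observed genotype matrix; the clean
parental origins are kept as ground truth.

Genes receive exonic SNP counts $s_g \sim \mathrm{Poisson}(\lambda)$
with $\lambda$ rising linearly from `lambda0` = 1 at the centromere to
`lambda0 + lambda1` = 1.5 at the telomere, reproducing the
centromere-to-telomere divergence gradient of the B73/Mo17 contrast.
A mean-one multiplier couples each gene's SNP rate to its geometry: UTR
length fraction increases divergence (weight 1) and junction-read
fraction decreases it (weight 3). The weights were fixed once by a
design experiment balancing two constraints that pull in opposite
directions — coupling variance dilutes the positional gradient, while
the junction-conservation signal must be strong enough to dominate the
mechanical inflation of pooled junction ratios in biased genes (see
"Feature ratios" below).

Expression is generated as
$T_{gi} = \max(0,\ \mu_g + a_g z_{ig})\,e^{\varepsilon_{gi}}$ with
baseline $\mu_g$ log-normal (meanlog 2, sdlog 1, FPKM scale),
multiplicative noise $\varepsilon \sim N(0, 0.3^2)$, and allele coding
$z = \pm 1$ at the gene's nearest marker. A fraction `cis_fraction`
(default 0.2) of genes carries a true additive effect $a_g$ with signs
balanced exactly 50:50 and magnitude sd `cis_effect_sd` = 0.75. That
default places detected genuine effects on the same magnitude scale as
bias effects, matching the regime in which most template-positive
cis-eQTL are artifacts; with much stronger true effects the
direction asymmetry would be diluted beyond anything observed in real
maize data.

Mapping bias is injected as a multiplicative retention on lines
carrying the non-template allele. Reads are treated as a mixture of
three categories with their own per-SNP dropout rates — UTR reads at
$2\delta$, junction-spanning reads at $\delta/2$, other exonic reads at
$\delta$ (defaults $\delta = 0.05$) — giving

$$\rho_g = u_g(1-2\delta)^{s_g} + j_g(1-\tfrac{\delta}{2})^{s_g} +
(1-u_g-j_g)(1-\delta)^{s_g},$$

where $u_g$ and $j_g$ are the UTR and junction read fractions. With
both category multipliers at 1 this collapses to the pure per-SNP law
$(1-\delta)^{s_g}$. Using one mechanism for both the expression-level
bias and the feature-count thinning means the eQTL diagnostics and the
UTR/junction ratio tests probe the same injected physics. The
`vs_parent2` matrix applies the same retention to template-1-allele
lines, so swapping templates reverses the asymmetry exactly.

What the generator does *not* emulate: read-level artifacts (no FASTQ),
indels and structural variants (the dominant cause of residual bias in
real maize data — the SNP-count dropout deliberately conflates SNP and
SV effects), library-size variation, trans-regulation (off by default),
and correlated expression noise between neighbouring genes. Passing
tests therefore demonstrate that the statistics detect the modelled
dropout mechanism at realistic scale, not that they capture every
artifact of a real aligner.

## The eQTL scan

Phenotypes are filtered as in a standard RIL expression study: expressed
above 1 (FPKM scale) in at least 42 lines, then the 75% most variable by
variance of $\log_2(x+1)$. Genotype probabilities on a 1-cM grid come
from a two-state forward–backward HMM with genotyping error
$\varepsilon = 0.001$; heterozygous and missing calls are
uninformative.

The scan statistic is rank-based interval mapping. With mid-rank scores
$u_i = \mathrm{rank}_i - (n+1)/2$ and weights
$w_i = P_i(\text{parent-1})$,

$$H = \frac{\left(\sum_i w_i u_i\right)^2 (n-1)}
{\sum_i (w_i-\bar w)^2 \cdot \sum_i u_i^2},
\qquad \mathrm{LOD} = \frac{H}{2\ln 10}.$$

The denominator is the exact permutation variance of the linear rank
statistic, so at a fully informative marker $H$ equals the two-sample
Kruskal–Wallis statistic (including its tie correction) — the package
asserts this equality against `kruskal.test()` on hundreds of random
instances. Because $H$ depends on the phenotype only through its ranks,
one permutation null (genome-wide maxima of 200–1000 shuffles of the
scores $1..n$) serves every tie-free phenotype on the same genotype
grid; a per-gene mode recomputes the null from a tied phenotype's own
scores. Thresholds are the type-7 empirical $1-\alpha$ quantile at
$\alpha = 0.05$.

One peak per chromosome is retained where the LOD maximum exceeds the
threshold. A peak is cis when it sits on the gene's chromosome and the
gene's interpolated position falls inside the 1.5-LOD support interval
or within 10 cM of the peak (the window is configurable; published
definitions delegate to external conventions without printing a
number). Genes with exactly one significant peak, that peak cis, form
the "cis-only" set used by all direction diagnostics — matching the
published tables, which exclude genes with both cis and trans eQTL.
Effects are estimated on the original scale: lines assigned by posterior
probability > 0.5, magnitude = half the group-mean difference, direction
= the parent with the larger mean.

## Bias diagnostics

* `bias_proportion()` — counts of parent-1- vs parent-2-positive
  cis-only genes with an exact two-sided binomial test against 0.5.
* `compare_references()` — per direction class, the fraction of genes
  absent from the other template's cis-only set, plus the overall
  single-template fraction.
* `window_bias_profile()` — 2-Mb windows anchored at coordinate 0,
  genes assigned by start position; per-window mean SNP count and
  parent-1-positive proportion with lowess smooths (span 2/3, 3
  robustness iterations).
* `divergence_effect_regression()` — genes binned by the integer floor
  of SNPs per kb exon (open-ended top bin, bins under 10 genes
  dropped); per-bin median of the allelic difference $2a$; unweighted
  OLS of medians on bin mean density.
* `compare_criteria()` — across two quantification settings, the
  fraction of shared template-positive genes with larger magnitude
  under the first (ties counted separately, excluded from the
  numerator; denominator = all shared genes), with an exact binomial
  test on non-tied pairs and a 2×2 chi-square (no continuity
  correction) on the direction proportions.

The divergence–magnitude experiment deserves a note on scale. At the
window-profile divergence (~1–1.5 SNPs per gene) every *detectable* bias
effect sits at the detection floor imposed by winner's curse
(an apparent shift of roughly $0.23\mu$ at 97 lines and noise 0.3), so
bin medians are flat regardless of mechanism. The packaged experiment
therefore uses species-scale divergence (`lambda0 = 2`, `lambda1 = 4`,
tightened exon lengths so SNP density tracks SNP count) — several SNPs
per kb, as in the maize B73/Mo17 contrast — where bias shifts span the
floor. There the template-positive class shows a clearly positive
slope of median allelic difference on SNP density while the opposite
class stays near zero, the published Fig-3-style asymmetry.

## Coexpression and haplotype consistency

Linked genes inside a biased chromosomal block are all up-regulated by
the template haplotype, so they form a single coexpressed group with one
consistent direction; a block whose genes are genuinely regulated with
mixed signs still co-varies through the shared haplotype but with
opposite directions. `adjacency_tom()` builds the unsigned
$|r|^\beta$ adjacency ($\beta = 5$) and its topological overlap;
`detect_modules()` clusters $1-\mathrm{TOM}$ by average linkage with a
static cut at 0.97, then iteratively absorbs modules smaller than 60
genes or with mean inter-module TOM similarity above 0.8 into their
closest neighbour. A static cut replaces a dynamic tree cut: it is
fully specified and testable, and suffices for planted-structure
recovery; the cut height is configurable. Small modules whose
closest-neighbour similarity falls below 0.05 are left unassigned (the
grey-module analogue) — without that floor, unrelated noise genes would
be absorbed into real modules and dilute their consistency.
`haplotype_direction()` scores each gene by the sign of the
point-biserial correlation between expression and its nearest marker's
parental coding; a module is bias-suspect when at least 90% of scored
members share one sign and at least half its members lie within a
contiguous 150-Mb span on one chromosome (the scale of the largest
single-direction region reported in maize).

Because the adjacency is unsigned, the two scenarios are separated by
*consistency*, not module count: the biased block yields one module with
consistency ≈ 1, while the mixed block yields one module (anticorrelated
genes are still strongly adjacent) with consistency ≈ 0.5.

## Feature ratios

`compute_ratios()` forms, per gene and parental read origin, the UTR
ratio (UTR reads / all exon reads) and the junction ratio
(junction-spanning reads / all exon reads), excluding genes lacking
reads in the focal category or its complement in both origins, or with
zero totals. `ratio_tests()` runs the four comparisons per ratio type:
paired Wilcoxon signed-rank tests of origin-1 vs origin-2 ratios within
each direction class, and a Wilcoxon rank-sum test of the pooled
(all-reads) ratios between classes. Tests are two-sided, exact below 50
genes and normal-approximated with continuity correction above; medians
are reported as percentages. Two effects emerge from the injected
mechanism: within genes, template-origin reads retain relatively more
UTR signal and fewer junction reads survive thinning in the
non-template origin with rate $\delta/2$ (so the non-template origin's
*ratio* of junction reads is higher); between classes, template-positive
genes are UTR-rich and junction-poor because geometry modulates both
their SNP rate and their effective retention.

## Numerical choices and degenerate inputs

Rank ties use mid-ranks; the scan returns LOD 0 for constant phenotypes
and at grid positions with no genotype information. Recombination
fractions are capped at 0.49 before Haldane inversion, with a warning
when the observed recombinant fraction reaches 0.5. Gene positions are
linearly interpolated in cM and clamped at terminal markers. The
divergence regression refuses fits with fewer than three populated
bins; effect estimation flags genes whose peak assigns every line to one
genotype. TSV output formats doubles with 17 significant digits so
write→read round trips are bit-identical; coordinates are 0-based
half-open internally, converted from 1-based closed GFF3 on read. All
stochastic stages derive from a single recorded seed, and
`run_pipeline()` re-seeds before analysis so simulate-then-analyse and
analyse-from-files produce identical results.

## Problem sizes used in the packaged experiments

The test-suite and acceptance-script experiments run at a deliberate
desk scale: 97 lines, 300 markers, 200 shared permutations, 500–1500
filtered genes per scan, 5–10 seeds where replication is pooled. The
null calibration experiment that checks direction balance gives every
gene a strong cis effect (`cis_fraction = 1`, `cis_effect_sd = 3`):
measuring a proportion within ±0.05 requires several hundred detected
cis-eQTL per seed, which the default effect mix cannot supply at this
gene count; the design choice affects only that calibration, not the
pipeline defaults.

## Known limitations

The dropout model is SNP-count-driven and cannot separate SNP from
structural-variant effects; real residual bias after relaxed alignment
is largely structural. The simulator draws genes independently, so
coexpression structure beyond haplotype sharing is absent. De novo
marker ordering, multiple-QTL models, covariates, eigengene networks
and dynamic tree cutting are out of scope. The published real-data
magnitudes (absolute eQTL counts, the 0.05 FPKM-per-SNP slope, map
length) require the original sequencing data and genomes and are not
reproduced here; the package reproduces their printed-count arithmetic
and the qualitative mechanics at simulation scale.
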