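# eqtlbias

Diagnostics for RNA-seq read **mapping bias** in biparental recombinant
inbred line (RIL) expression studies, for quantitative geneticists and
transcriptomics analysts who map eQTL against a single reference
genome.

When reads from two genetically distinct parents are quantified against
one parent's genome, reads carrying divergent alleles fail to map and
the non-reference allele's expression is underestimated. In a RIL
panel this artifact masquerades as biology: cis-eQTL whose
"positively acting" allele is, far too often, the reference parent's.
`eqtlbias` quantifies that signature end-to-end:

* **Rank-based interval mapping.** Expression phenotypes are converted
  to mid-ranks and scanned on a cM grid of HMM genotype probabilities.
  With scores `u_i = rank_i − (n+1)/2` and weights
  `w_i = P_i(parent 1)`, the statistic

  `H = (Σ w_i u_i)² (n−1) / (Σ (w_i − w̄)² · Σ u_i²)`,  `LOD = H / (2 ln 10)`,

  reduces exactly to the two-sample Kruskal–Wallis statistic at
  informative markers. Genome-wide thresholds come from a shared
  permutation null at α = 0.05; cis/trans calls use 1.5-LOD support
  intervals; effects are half the allele-group mean difference.
* **Bias statistics.** Direction asymmetry among cis-only genes (exact
  binomial vs 0.5), discordance between reference templates, 2-Mb
  window profiles of SNP density and direction proportion with lowess
  smooths, and regressions of median allelic difference on SNP-per-kb
  bins.
* **Coexpression signature.** Unsigned `|r|^β` (β = 5) topological
  overlap, average-linkage modules with 60-gene/0.8-similarity merge
  rules, and per-module haplotype-direction consistency — one
  high-consistency module marks a biased region; mixed directions mark
  genuine regulation.
* **Feature ratios.** Per-gene UTR and splice-junction read ratios by
  parental read origin, with the four Wilcoxon signed-rank/rank-sum
  comparisons across eQTL direction classes.
* **Synthetic study generator.** A maize-like two-parent design (10
  chromosomes, 97 RILs, Haldane/selfed-RIL recombination, a
  centromere-to-telomere SNP gradient from 1 to 1.5 SNPs per gene, and
  per-SNP allele-specific read dropout with UTR/junction-specific
  rates) so every stage runs against known ground truth.

## Worked example

Simulate a 2000-gene study with dropout `delta = 0.05`, map eQTL
against both parental templates, and compare:

```r
library(eqtlbias)

cfg  <- sim_config(n_genes = 2000, n_markers = 300, seed = 11)
sim  <- simulate_dataset(cfg)

gt    <- filter_markers(sim$genotypes)          # MAF > 30%, missing < 5%
map   <- estimate_map(gt)
probs <- genotype_probabilities(gt, map)
thr   <- permutation_threshold(probs, 200, 0.05)

g1   <- filter_genes(sim$expression$vs_parent1) # > 1 FPKM in ≥ 42 lines,
g2   <- filter_genes(sim$expression$vs_parent2) # top 75% by variability
rec1 <- map_eqtl(g1, gt, map, sim$panel, probs = probs, threshold = thr)
rec2 <- map_eqtl(g2, gt, map, sim$panel, probs = probs, threshold = thr)

bias_proportion(rec1)
bias_proportion(rec2)
compare_references(rec1, rec2)
```

```
cis-eQTL direction summary: 186 genes, 138 (74.2%) parent-1 positive,
  48 (25.8%) parent-2 positive; exact binomial p = 2.76e-11
cis-eQTL direction summary: 213 genes, 38 (17.8%) parent-1 positive,
  175 (82.2%) parent-2 positive; exact binomial p = 3.31e-22
Reference-template discordance (fraction absent from the other template's cis-only set):
  ref1_parent1     138 genes,    88 absent (63.8%)
  ref1_parent2      48 genes,     1 absent (2.1%)
  ref2_parent1      38 genes,     0 absent (0.0%)
  ref2_parent2     175 genes,   116 absent (66.3%)
  union 302 genes; 67.9% detected under one template only
```

Although true cis effects were injected with exactly balanced signs,
74% of cis-eQTL appear parent-1-positive when quantified against the
parent-1 template — and the asymmetry reverses (82% parent-2-positive)
when the same expression is quantified against the other parent. Most
template-positive calls vanish under the opposite template: the
hallmark of mapping bias rather than regulation. With `delta = 0` both
summaries sit at 50% and the discordance shrinks to threshold noise.

`run_pipeline(run_config(...))` wires these stages (plus the window
profile, divergence regressions, optional coexpression report and
ratio tests) into one reproducible run that writes TSV/JSON/BED
artifacts and a provenance log; `inst/scripts/eqtlbias.R` exposes it as
a small command-line tool with `simulate`, `analyze` and `all`
subcommands.

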