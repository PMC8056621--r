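Package: eqtlbias
Title: Reference Mapping Bias Diagnostics for RNA-Seq eQTL Studies in
    Biparental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies RNA-seq read mapping bias in biparental
    recombinant inbred line (RIL) populations. Expression matrices quantified
    against each of two parental reference templates are mapped to the genome
    by rank-based (Kruskal-Wallis) interval mapping with permutation-derived
    genome-wide LOD thresholds; cis-eQTL allele directions are compared
    between templates to measure reference-allele preference, bias is
    profiled along chromosomes in 2-Mb windows against sequence divergence,
    eQTL magnitudes are regressed on exonic SNP density, coexpressed linked
    gene groups are scored for haplotype-direction consistency, and UTR and
    splice-junction read ratios are tested by parental read origin. A
    synthetic-data generator emulates the study design (97 RILs, ten
    chromosomes, centromere-to-telomere divergence gradient, per-SNP
    allele-specific read dropout) so every stage runs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
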