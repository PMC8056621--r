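#' Simulation configuration
#'
#' Bundles every tunable of the synthetic biparental RIL study. Defaults
#' emulate a maize-like design: ten chromosomes, 97 recombinant inbred
#' lines, an exonic SNP rate rising from about 1 SNP per gene near the
#' centromere to about 1.5 at the telomeres, and a per-SNP probability
#' `delta` that a read from the non-template allele is lost during
#' alignment. UTR-derived reads are lost more often
#' (`delta * delta_utr_mult`) and splice-junction reads less often
#' (`delta * delta_sj_mult`), reflecting the higher divergence of UTRs and
#' the conservation of splice sites.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Physical length of each chromosome in bp.
#' @param centromere_frac Fractional position of the centromere along each
#'   chromosome, in (0, 1).
#' @param n_genes Number of genes to simulate.
#' @param n_markers Total number of genotyped markers (spread evenly across
#'   chromosomes).
#' @param n_lines Number of recombinant inbred lines (>= 2).
#' @param lambda0 Mean exonic SNPs per gene at the centromere.
#' @param lambda1 Added mean SNPs at the telomere (linear gradient along the
#'   chromosome arm).
#' @param delta Per-SNP dropout probability for reads from the
#'   non-template allele, in \[0, 1\].
#' @param delta_utr_mult Multiplier on `delta` for UTR-region reads
#'   (default 2: UTRs diverge more).
#' @param delta_sj_mult Multiplier on `delta` for splice-junction reads
#'   (default 0.5: junctions are conserved).
#' @param cis_fraction Fraction of genes given a true cis-acting effect.
#' @param cis_effect_sd Standard deviation of true additive effects, in
#'   expression (FPKM-scale) units.
#' @param noise_sigma Scale of the multiplicative log-normal expression
#'   noise (sd of the log).
#' @param residual_het Probability that an observed genotype call is
#'   heterozygous (`H`).
#' @param missing_rate Probability that an observed genotype call is
#'   missing (`N`).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of the baseline
#'   expression level `mu_g` (FPKM scale).
#' @param cm_per_mb Genetic map expansion, cM per Mb, used to place the
#'   true marker map.
#' @param exon_meanlog,exon_sdlog Log-normal parameters of total exon
#'   length per gene (bp).
#' @param utr_beta Two shape parameters of the Beta distribution of the
#'   per-gene UTR fraction of exon length.
#' @param sj_beta Two shape parameters of the Beta distribution of the
#'   per-gene fraction of reads that span splice junctions.
#' @param div_utr_coupling,div_sj_coupling Strength of the mean-one
#'   coupling between a gene's SNP rate and its UTR fraction (positive)
#'   and junction-read fraction (negative). Zero decouples geometry from
#'   divergence.
#' @param mean_reads Mean exon-mapped read count per gene and parental
#'   origin in [simulate_feature_counts()].
#' @param seed Optional RNG seed recorded in the configuration; applied by
#'   [simulate_dataset()] and [run_pipeline()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 100, n_markers = 40, seed = 1)
#' cfg$n_lines
#' @export
sim_config <- function(n_chromosomes = 10,
                       chrom_length_bp = 2e8,
                       centromere_frac = 0.45,
                       n_genes = 2000,
                       n_markers = 300,
                       n_lines = 97,
                       lambda0 = 1.0,
                       lambda1 = 0.5,
                       delta = 0.05,
                       delta_utr_mult = 2,
                       delta_sj_mult = 0.5,
                       cis_fraction = 0.2,
                       cis_effect_sd = 0.75,
                       noise_sigma = 0.3,
                       residual_het = 0.01,
                       missing_rate = 0.02,
                       mu_meanlog = 2,
                       mu_sdlog = 1,
                       cm_per_mb = 1,
                       exon_meanlog = log(2000),
                       exon_sdlog = 0.5,
                       utr_beta = c(2, 8),
                       sj_beta = c(3, 17),
                       div_utr_coupling = 1,
                       div_sj_coupling = 3,
                       mean_reads = 200,
                       seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min)
      stop(sprintf("'%s' must be a single number >= %s", nm, min),
           call. = FALSE)
  }
  chk_prob <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm),
           call. = FALSE)
  }
  chk_count(cfg$n_chromosomes, "n_chromosomes")
  chk_count(cfg$chrom_length_bp, "chrom_length_bp")
  chk_count(cfg$n_genes, "n_genes")
  chk_count(cfg$n_markers, "n_markers", min = 2)
  chk_count(cfg$n_lines, "n_lines", min = 2)
  if (cfg$centromere_frac <= 0 || cfg$centromere_frac >= 1)
    stop("'centromere_frac' must lie strictly inside (0, 1)", call. = FALSE)
  if (cfg$lambda0 < 0 || cfg$lambda1 < 0)
    stop("'lambda0' and 'lambda1' must be >= 0", call. = FALSE)
  for (nm in c("delta", "cis_fraction", "residual_het", "missing_rate"))
    chk_prob(cfg[[nm]], nm)
  if (cfg$delta_sj_mult <= 0)
    stop("'delta_sj_mult' must be > 0", call. = FALSE)
  if (cfg$noise_sigma < 0 || cfg$cis_effect_sd < 0)
    stop("'noise_sigma' and 'cis_effect_sd' must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  cat(sprintf("  %d chromosomes x %.0f Mb, %d genes, %d markers, %d lines\n",
              x$n_chromosomes, x$chrom_length_bp / 1e6, x$n_genes,
              x$n_markers, x$n_lines))
  cat(sprintf("  SNP gradient lambda0=%.2f lambda1=%.2f; dropout delta=%.3f",
              x$lambda0, x$lambda1, x$delta))
  cat(sprintf(" (UTR x%.1f, SJ x%.1f)\n", x$delta_utr_mult, x$delta_sj_mult))
  cat(sprintf("  cis fraction %.2f (sd %.2f), noise sigma %.2f, seed %s\n",
              x$cis_fraction, x$cis_effect_sd, x$noise_sigma,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
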