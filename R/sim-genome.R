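#' Simulate a two-parent gene panel with a divergence gradient
#'
#' Places genes uniformly on the configured chromosomes, draws exon/UTR
#' geometry, and assigns each gene an exonic SNP count
#' `s_g ~ Poisson(lambda(pos) * m_g)` where
#' `lambda(pos) = lambda0 + lambda1 * (distance from centromere / arm
#' length)` reproduces the centromere-to-telomere divergence gradient and
#' `m_g` is a mean-one multiplier coupling divergence to gene geometry
#' (UTR-rich genes more divergent, junction-rich genes less; see
#' [sim_config()]).
#'
#' @param config A [sim_config()].
#' @return A `gene_panel` data.frame with one row per gene: `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open gene span), `exon_bp`,
#'   `utr_bp`, `n_junctions`, `sj_frac` (expected junction-read fraction),
#'   `snp_count` and `snps_per_kb_exon = 1000 * snp_count / exon_bp`.
#' @examples
#' set.seed(1)
#' panel <- simulate_genome_pair(sim_config(n_genes = 50))
#' head(panel)
#' @export
simulate_genome_pair <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  L <- config$chrom_length_bp

  chrom <- sample.int(config$n_chromosomes, n, replace = TRUE)
  exon_bp <- pmin(pmax(round(stats::rlnorm(n, config$exon_meanlog,
                                           config$exon_sdlog)), 200L), 20000L)
  utr_frac <- stats::rbeta(n, config$utr_beta[1], config$utr_beta[2])
  utr_bp <- round(utr_frac * exon_bp)
  n_junctions <- stats::rpois(n, 7) + 1L
  sj_frac <- stats::rbeta(n, config$sj_beta[1], config$sj_beta[2])

  span <- pmin(round(exon_bp * stats::runif(n, 1.5, 3)), L)
  start <- floor(stats::runif(n, 0, L - span))
  end <- start + span

  cen <- config$centromere_frac * L
  arm <- ifelse(start < cen, cen, L - cen)
  rel <- pmin(abs(start - cen) / arm, 1)

  utr_mean <- config$utr_beta[1] / sum(config$utr_beta)
  sj_mean <- config$sj_beta[1] / sum(config$sj_beta)
  mult <- pmax(0, 1 + config$div_utr_coupling * (utr_frac - utr_mean) -
                 config$div_sj_coupling * (sj_frac - sj_mean))
  lambda <- (config$lambda0 + config$lambda1 * rel) * mult
  snp_count <- stats::rpois(n, lambda)

  panel <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    chrom = chrom,
    start = start,
    end = end,
    exon_bp = as.integer(exon_bp),
    utr_bp = as.integer(utr_bp),
    n_junctions = as.integer(n_junctions),
    sj_frac = sj_frac,
    snp_count = as.integer(snp_count),
    snps_per_kb_exon = 1000 * snp_count / exon_bp,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Simulate the true marker map
#'
#' Distributes markers evenly along each chromosome and assigns genetic
#' positions at a constant `cm_per_mb` expansion, yielding a monotone map
#' with known truth for recovery experiments.
#'
#' @param config A [sim_config()].
#' @return A `genetic_map` data.frame: `marker_id`, `chrom`, `bp`, `cm`.
#' @export
simulate_marker_map <- function(config) {
  validate_sim_config(config)
  per <- rep(config$n_markers %/% config$n_chromosomes, config$n_chromosomes)
  extra <- config$n_markers %% config$n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  if (any(per < 2))
    stop("need at least 2 markers per chromosome; increase n_markers",
         call. = FALSE)
  L <- config$chrom_length_bp
  maps <- lapply(seq_len(config$n_chromosomes), function(k) {
    m <- per[k]
    bp <- round(seq(L / (m + 1), L * m / (m + 1), length.out = m))
    data.frame(marker_id = sprintf("c%02d_m%03d", k, seq_len(m)),
               chrom = k, bp = bp, cm = bp / 1e6 * config$cm_per_mb,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}
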