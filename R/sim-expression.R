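# Read-category mixture retention for the non-template allele: UTR,
# junction and other exonic reads drop at their own per-SNP rates.
retention_mixture <- function(panel, config) {
  u <- panel$utr_bp / panel$exon_bp
  j <- panel$sj_frac
  oth <- pmax(0, 1 - u - j)
  tot <- u + j + oth
  s <- panel$snp_count
  keep <- function(mult) (1 - pmin(1, config$delta * mult))^s
  (u * keep(config$delta_utr_mult) + j * keep(config$delta_sj_mult) +
      oth * keep(1)) / tot
}

# Nearest genotyped marker for each gene (same chromosome, closest bp).
# Errors when a gene sits on a chromosome with no markers.
nearest_marker <- function(panel, markers) {
  idx <- integer(nrow(panel))
  for (k in unique(panel$chrom)) {
    gi <- which(panel$chrom == k)
    mi <- which(markers$chrom == k)
    if (length(mi) == 0)
      stop(sprintf("gene(s) on chromosome %s but no marker there", k),
           call. = FALSE)
    mbp <- markers$bp[mi]
    for (g in gi) idx[g] <- mi[which.min(abs(mbp - panel$start[g]))]
  }
  idx
}

#' Simulate expression against two parental reference templates
#'
#' Generates the bias-free truth `T_gi = max(0, mu_g + a_g z_ig) *
#' exp(N(0, noise_sigma^2))`, where `z_ig` is +1/-1 for the parent-1 /
#' parent-2 allele at the gene's nearest marker and `a_g` is the true
#' additive cis effect (zero for non-cis genes, signs balanced 50:50 among
#' cis genes). Mapping bias is injected as a multiplicative retention
#' `rho_g` applied to the lines carrying the non-template allele:
#' quantified against parent 1, lines with the parent-2 allele keep only
#' `rho_g` of their true signal, and vice versa for the parent-2
#' template. The retention is the read-category mixture
#' `rho_g = u (1 - delta_u)^s + j (1 - delta_j)^s +
#' (1 - u - j) (1 - delta)^s`, where `u` and `j` are the gene's UTR and
#' junction-read fractions and `delta_u = delta * delta_utr_mult`,
#' `delta_j = delta * delta_sj_mult` are the category dropout rates —
#' the same per-category mechanism as [simulate_feature_counts()], so
#' UTR-rich genes suffer more expression bias and junction-rich genes
#' less. With both multipliers at 1 this reduces to the pure per-SNP law
#' `(1 - delta)^s`.
#'
#' @param panel A `gene_panel` from [simulate_genome_pair()].
#' @param genotypes A `ril_genotypes` from [simulate_ril_population()]
#'   (its `truth` attribute supplies the parental origins).
#' @param config A [sim_config()].
#' @return A list with elements `truth`, `vs_parent1`, `vs_parent2`
#'   (genes x lines matrices, `attr(, "reference")` set) and
#'   `truth_table` (data.frame: `gene_id`, `mu`, `a_true`, `rho`,
#'   `cis_true`, `bias_affected`).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_genes = 20, n_markers = 20, n_lines = 30)
#' map <- simulate_marker_map(cfg)
#' rils <- simulate_ril_population(map, cfg)
#' ex <- simulate_expression(simulate_genome_pair(cfg), rils, cfg)
#' str(ex$truth_table)
#' @export
simulate_expression <- function(panel, genotypes, config) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "gene_panel"), inherits(genotypes,
                                                   "ril_genotypes"))
  truth_geno <- attr(genotypes, "truth")
  if (is.null(truth_geno))
    stop("genotypes carry no 'truth' attribute; simulate them with ",
         "simulate_ril_population()", call. = FALSE)

  n_genes <- nrow(panel)
  n_lines <- nrow(truth_geno)
  mk <- nearest_marker(panel, genotypes$markers)
  # z: genes x lines, +1 parent-1 allele, -1 parent-2 allele
  z <- t(ifelse(truth_geno[, mk, drop = FALSE] == "A", 1, -1))

  a_true <- numeric(n_genes)
  n_cis <- round(config$cis_fraction * n_genes)
  if (n_cis > 0) {
    cis_idx <- sample.int(n_genes, n_cis)
    signs <- sample(rep(c(1, -1), length.out = n_cis))
    a_true[cis_idx] <- signs * abs(stats::rnorm(n_cis, 0,
                                                config$cis_effect_sd))
  }
  mu <- stats::rlnorm(n_genes, config$mu_meanlog, config$mu_sdlog)
  noise <- matrix(exp(stats::rnorm(n_genes * n_lines, 0,
                                   config$noise_sigma)), n_genes)
  truth <- pmax(0, mu + a_true * z) * noise
  dimnames(truth) <- list(panel$gene_id, rownames(truth_geno))

  rho <- retention_mixture(panel, config)
  vs1 <- truth * ifelse(z < 0, rho, 1)
  vs2 <- truth * ifelse(z > 0, rho, 1)
  attr(truth, "reference") <- "truth"
  attr(vs1, "reference") <- "parent1"
  attr(vs2, "reference") <- "parent2"

  tt <- data.frame(gene_id = panel$gene_id, mu = mu, a_true = a_true,
                   rho = rho, cis_true = a_true != 0,
                   bias_affected = panel$snp_count > 0 & config$delta > 0,
                   stringsAsFactors = FALSE)
  list(truth = truth, vs_parent1 = vs1, vs_parent2 = vs2, truth_table = tt)
}

#' Apparent cis direction implied by the truth table
#'
#' For each gene the apparent log expression shift between genotype groups
#' under the parent-1 template is `log((mu + a) / ((mu - a) * rho))`:
#' true effect plus mapping-bias retention. Genes whose absolute shift
#' exceeds `min_log_shift` (roughly the 50% detection power point at the
#' default population size and noise) are classified as apparent
#' parent-1- or parent-2-positive cis-eQTL; the rest are unclassified.
#' This emulates conditioning on significant cis-eQTL without a genome
#' scan and is used to build direction sets for the feature-ratio study.
#'
#' @param truth_table The `truth_table` from [simulate_expression()].
#' @param min_log_shift Minimum absolute log shift to classify a gene.
#' @return data.frame `gene_id`, `log_shift`, `direction`
#'   (`"parent1"`/`"parent2"`/`NA`).
#' @export
truth_cis_directions <- function(truth_table, min_log_shift = 0.23) {
  up <- pmax(truth_table$mu + truth_table$a_true, 1e-9)
  dn <- pmax(truth_table$mu - truth_table$a_true, 1e-9) * truth_table$rho
  shift <- log(up / dn)
  dir <- ifelse(shift > min_log_shift, "parent1",
                ifelse(shift < -min_log_shift, "parent2", NA_character_))
  data.frame(gene_id = truth_table$gene_id, log_shift = shift,
             direction = dir, stringsAsFactors = FALSE)
}

#' Simulate feature-level read counts by parental origin
#'
#' For each gene, draws total exon-mapped reads and the UTR-mapped and
#' junction-spanning subsets for the template (parent-1) origin, then
#' thins the non-template (parent-2) origin binomially with per-SNP
#' retention `(1 - delta * mult)^{s_g}` per category: `delta *
#' delta_utr_mult` for UTR reads, `delta * delta_sj_mult` for
#' junction-spanning reads, and `delta` for other exonic reads.
#'
#' @param panel A `gene_panel`.
#' @param config A [sim_config()].
#' @return A `feature_counts` data.frame: `gene_id`, `origin`
#'   (`"parent1"`/`"parent2"`), `utr_reads`, `sj_reads`, `total_reads`.
#' @export
simulate_feature_counts <- function(panel, config) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "gene_panel"))
  n <- nrow(panel)
  total1 <- stats::rpois(n, config$mean_reads)
  p_utr <- panel$utr_bp / panel$exon_bp
  utr1 <- stats::rbinom(n, total1, p_utr)
  sj1 <- stats::rbinom(n, total1, panel$sj_frac)

  ret <- function(mult) (1 - pmin(1, config$delta * mult))^panel$snp_count
  utr2 <- stats::rbinom(n, utr1, ret(config$delta_utr_mult))
  oth2 <- stats::rbinom(n, total1 - utr1, ret(1))
  total2 <- utr2 + oth2
  sj2 <- pmin(stats::rbinom(n, sj1, ret(config$delta_sj_mult)), total2)

  out <- data.frame(
    gene_id = rep(panel$gene_id, 2),
    origin = rep(c("parent1", "parent2"), each = n),
    utr_reads = c(utr1, utr2),
    sj_reads = c(sj1, sj2),
    total_reads = c(total1, total2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_counts", "data.frame")
  out
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from `config$seed` (when set) and runs the full
#' generator: gene panel, marker map, RIL population, expression against
#' both templates, and feature read counts. Rerunning with the same
#' configuration reproduces every output bit-identically.
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `panel`, `map`, `genotypes`, `expression`
#'   (list from [simulate_expression()]), `feature_counts`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 30, n_markers = 20,
#'                                    n_lines = 25, seed = 7))
#' names(sim)
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- simulate_genome_pair(config)
  map <- simulate_marker_map(config)
  genotypes <- simulate_ril_population(map, config)
  expression <- simulate_expression(panel, genotypes, config)
  feature_counts <- simulate_feature_counts(panel, config)
  list(config = config, panel = panel, map = map, genotypes = genotypes,
       expression = expression, feature_counts = feature_counts)
}
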