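#' Simulate a linked chromosomal region for the haplotype-consistency test
#'
#' Builds the two archetypal patterns that discriminate mapping bias from
#' ordinary regulatory variation in a block of physically linked genes:
#'
#' * `"biased"` — every gene in the region is expression-neutral but its
#'   reads from the non-template haplotype are lost at retention `rho`, so
#'   all region genes rise with the template (parent-1) haplotype and form
#'   a single coexpressed group with one consistent direction.
#' * `"unbiased"` — genes carry genuine cis effects of alternating sign
#'   and no dropout, so the region still yields correlated transcripts
#'   (through the shared haplotype) but with mixed directions.
#'
#' The region spans most of chromosome 1 and is in complete linkage
#' (a single haplotype per line); background genes on chromosome 2 are
#' independent noise.
#'
#' @param scenario `"biased"` or `"unbiased"`.
#' @param n_region,n_background Gene counts in the linked region and the
#'   unlinked background.
#' @param n_lines Number of RILs.
#' @param rho Retention applied to non-template-haplotype lines in the
#'   biased scenario (strongly diverged region).
#' @param effect Absolute true additive effect in the unbiased scenario.
#' @param noise_sigma Log-normal noise scale.
#' @param mu_meanlog,mu_sdlog Baseline expression log-normal parameters.
#' @return A list: `expr` (genes x lines), `genotypes` (`ril_genotypes`),
#'   `panel` (`gene_panel`), `region_genes` (ids), `truth_direction`
#'   (+1/-1 per region gene).
#' @examples
#' set.seed(1)
#' sc <- simulate_region_scenario("biased", n_region = 40,
#'                                n_background = 40, n_lines = 40)
#' dim(sc$expr)
#' @export
simulate_region_scenario <- function(scenario = c("biased", "unbiased"),
                                     n_region = 120, n_background = 120,
                                     n_lines = 97, rho = 0.4, effect = 3,
                                     noise_sigma = 0.3, mu_meanlog = 2,
                                     mu_sdlog = 0.5) {
  scenario <- match.arg(scenario)
  n <- n_region + n_background
  line_ids <- sprintf("RIL%03d", seq_len(n_lines))

  # one haplotype per chromosome and line; region in complete linkage
  h1 <- stats::runif(n_lines) < 0.5   # chromosome 1 (region)
  h2 <- stats::runif(n_lines) < 0.5   # chromosome 2 (background)
  markers <- data.frame(
    marker_id = c("c01_m001", "c01_m002", "c01_m003",
                  "c02_m001", "c02_m002"),
    chrom = c(1L, 1L, 1L, 2L, 2L),
    bp = c(10e6, 75e6, 140e6, 50e6, 150e6))
  calls <- cbind(matrix(ifelse(h1, "A", "B"), n_lines, 3),
                 matrix(ifelse(h2, "A", "B"), n_lines, 2))
  rownames(calls) <- line_ids
  genotypes <- ril_genotypes(calls, markers)
  attr(genotypes, "truth") <- calls

  panel <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    chrom = rep(c(1L, 2L), c(n_region, n_background)),
    start = c(round(seq(10e6, 142e6, length.out = n_region)),
              round(seq(5e6, 195e6, length.out = n_background))),
    stringsAsFactors = FALSE)
  panel$end <- panel$start + 5000L
  panel$exon_bp <- 2000L
  panel$utr_bp <- 400L
  panel$n_junctions <- 5L
  panel$sj_frac <- 0.15
  panel$snp_count <- rep(c(5L, 0L), c(n_region, n_background))
  panel$snps_per_kb_exon <- 1000 * panel$snp_count / panel$exon_bp
  class(panel) <- c("gene_panel", "data.frame")

  mu <- stats::rlnorm(n, mu_meanlog, mu_sdlog)
  z1 <- ifelse(h1, 1, -1)
  noise <- matrix(exp(stats::rnorm(n * n_lines, 0, noise_sigma)), n)
  base <- matrix(mu, n, n_lines) * noise
  expr <- base
  reg <- seq_len(n_region)
  truth_direction <- rep(1L, n_region)
  if (scenario == "biased") {
    # non-template-haplotype lines retain only rho of the signal
    expr[reg, !h1] <- expr[reg, !h1] * rho
  } else {
    truth_direction <- rep(c(1L, -1L), length.out = n_region)
    a <- effect * truth_direction
    expr[reg, ] <- pmax(0, mu[reg] + a %o% z1) * noise[reg, , drop = FALSE]
  }
  dimnames(expr) <- list(panel$gene_id, line_ids)

  list(expr = expr, genotypes = genotypes, panel = panel,
       region_genes = panel$gene_id[reg],
       truth_direction = truth_direction)
}
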