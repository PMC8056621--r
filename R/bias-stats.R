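#' Build minimal direction records from counts
#'
#' Convenience constructor for count-level arithmetic with the bias
#' diagnostics: produces a cis-only `eqtl_records` table with the given
#' numbers of parent-1-positive and parent-2-positive genes.
#'
#' @param n_parent1,n_parent2 Gene counts by allele direction.
#' @param prefix Gene-id prefix.
#' @return An `eqtl_records` data.frame with `gene_id`, `direction`,
#'   `cis`, `cis_only`, `magnitude` columns.
#' @examples
#' bias_proportion(direction_records(6341, 2965))
#' @export
direction_records <- function(n_parent1, n_parent2, prefix = "g") {
  n <- n_parent1 + n_parent2
  if (n == 0) {
    out <- data.frame(gene_id = character(0), direction = character(0),
                      cis = logical(0), cis_only = logical(0),
                      magnitude = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("eqtl_records", "data.frame")
    return(out)
  }
  out <- data.frame(
    gene_id = sprintf("%s%06d", prefix, seq_len(n)),
    direction = rep(c("parent1", "parent2"), c(n_parent1, n_parent2)),
    cis = TRUE, cis_only = TRUE, magnitude = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("eqtl_records", "data.frame")
  out
}

#' Allele-direction asymmetry among cis-eQTL
#'
#' Counts cis-only genes by the parental direction of their allele effect
#' and tests the parent-1-positive proportion against the unbiased
#' expectation of 0.5 with an exact two-sided binomial test. In the
#' absence of mapping bias the two parents contribute positively acting
#' alleles in roughly equal numbers; an excess of template-positive
#' directions is the primary bias signature.
#'
#' @param records An `eqtl_records` table; rows with `cis_only == TRUE`
#'   and a defined direction are used.
#' @return A `bias_summary` list: `n_total`, `n_parent1_positive`,
#'   `n_parent2_positive`, `proportion_parent1`, `p_value`.
#' @examples
#' bias_proportion(direction_records(6341, 2965))  # 68.1%
#' @export
bias_proportion <- function(records) {
  rec <- records[records$cis_only %in% TRUE &
                   records$direction %in% c("parent1", "parent2"), ,
                 drop = FALSE]
  if (nrow(rec) == 0)
    stop("no cis-only records with a defined direction", call. = FALSE)
  n1 <- sum(rec$direction == "parent1")
  n2 <- sum(rec$direction == "parent2")
  out <- list(n_total = n1 + n2, n_parent1_positive = n1,
              n_parent2_positive = n2,
              proportion_parent1 = n1 / (n1 + n2),
              p_value = stats::binom.test(n1, n1 + n2, 0.5)$p.value)
  class(out) <- "bias_summary"
  out
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(
    "cis-eQTL direction summary: %d genes, %d (%.1f%%) parent-1 positive,\n",
    x$n_total, x$n_parent1_positive, 100 * x$proportion_parent1))
  cat(sprintf("  %d (%.1f%%) parent-2 positive; exact binomial p = %.3g\n",
              x$n_parent2_positive, 100 * (1 - x$proportion_parent1),
              x$p_value))
  invisible(x)
}

#' Reference-template discordance of cis-eQTL sets
#'
#' For each direction class under each reference template, the fraction
#' of genes absent from the other template's cis-only set, plus the
#' overall fraction of the union detected under only one template. Under
#' mapping bias, most template-positive cis-eQTL vanish when reads are
#' re-quantified against the other parent's genome.
#'
#' @param recs_ref1,recs_ref2 `eqtl_records` tables from the two
#'   templates (cis-only rows are used, keyed by `gene_id`).
#' @return A `reference_discordance` list of fractions and counts.
#' @export
compare_references <- function(recs_ref1, recs_ref2) {
  c1 <- cis_only_records(recs_ref1)
  c2 <- cis_only_records(recs_ref2)
  if (nrow(c1) == 0 || nrow(c2) == 0)
    stop("both record sets must contain cis-only genes", call. = FALSE)
  frac_absent <- function(from, dir, other_ids) {
    ids <- from$gene_id[from$direction == dir]
    if (length(ids) == 0) return(list(frac = NA_real_, n = 0L, absent = 0L))
    ab <- sum(!ids %in% other_ids)
    list(frac = ab / length(ids), n = length(ids), absent = ab)
  }
  d <- list(
    ref1_parent1 = frac_absent(c1, "parent1", c2$gene_id),
    ref1_parent2 = frac_absent(c1, "parent2", c2$gene_id),
    ref2_parent1 = frac_absent(c2, "parent1", c1$gene_id),
    ref2_parent2 = frac_absent(c2, "parent2", c1$gene_id))
  un <- union(c1$gene_id, c2$gene_id)
  only_one <- sum(!un %in% c1$gene_id) + sum(!un %in% c2$gene_id)
  out <- list(discordance = d, n_union = length(un),
              frac_single_reference = only_one / length(un))
  class(out) <- "reference_discordance"
  out
}

#' @export
print.reference_discordance <- function(x, ...) {
  cat("Reference-template discordance (fraction absent from the other",
      "template's cis-only set):\n")
  for (nm in names(x$discordance)) {
    d <- x$discordance[[nm]]
    cat(sprintf("  %-14s %5d genes, %5d absent (%.1f%%)\n", nm, d$n,
                d$absent, 100 * d$frac))
  }
  cat(sprintf("  union %d genes; %.1f%% detected under one template only\n",
              x$n_union, 100 * x$frac_single_reference))
  invisible(x)
}

#' Windowed bias profile along chromosomes
#'
#' Assigns cis-only eQTL genes to consecutive, non-overlapping windows of
#' `window_bp` (anchored at coordinate 0, gene-to-window by start
#' position) and reports, per window, the mean exonic SNP count and the
#' parent-1-positive proportion, together with lowess smooths (span 2/3,
#' 3 robustness iterations) of both series against the window midpoint
#' for each chromosome.
#'
#' @param records An `eqtl_records` table (cis-only rows used).
#' @param panel A `gene_panel` with `gene_id`, `chrom`, `start`,
#'   `snp_count`.
#' @param window_bp Window width in bp (default 2 Mb).
#' @return A `window_profile` list: `windows` (data.frame `chrom`,
#'   `start`, `end`, `mid`, `n_genes`, `mean_snps`, `prop_parent1`) and
#'   `smooth` (per-chromosome list of lowess curves).
#' @export
window_bias_profile <- function(records, panel, window_bp = 2e6) {
  if (window_bp <= 0) stop("'window_bp' must be > 0", call. = FALSE)
  rec <- cis_only_records(records)
  rec <- rec[rec$direction %in% c("parent1", "parent2"), , drop = FALSE]
  m <- merge(rec[, c("gene_id", "direction")],
             panel[, c("gene_id", "chrom", "start", "snp_count")],
             by = "gene_id")
  if (nrow(m) == 0) {
    warning("no cis-only eQTL overlap the panel; empty profile")
    return(structure(list(windows = data.frame(), smooth = list()),
                     class = "window_profile"))
  }
  m$win <- floor(m$start / window_bp)
  rows <- list(); smooth <- list()
  for (k in sort(unique(m$chrom))) {
    mk <- m[m$chrom == k, , drop = FALSE]
    wins <- seq(0, max(mk$win))
    df <- data.frame(chrom = k, start = wins * window_bp,
                     end = (wins + 1) * window_bp,
                     mid = (wins + 0.5) * window_bp)
    df$n_genes <- vapply(wins, function(w) sum(mk$win == w), integer(1))
    df$mean_snps <- vapply(wins, function(w) {
      if (df$n_genes[w + 1] == 0) NA_real_ else
        mean(mk$snp_count[mk$win == w])
    }, numeric(1))
    df$prop_parent1 <- vapply(wins, function(w) {
      if (df$n_genes[w + 1] == 0) NA_real_ else
        mean(mk$direction[mk$win == w] == "parent1")
    }, numeric(1))
    rows[[as.character(k)]] <- df
    occ <- df[df$n_genes > 0, , drop = FALSE]
    smooth[[as.character(k)]] <- if (nrow(occ) >= 3) {
      list(snps = stats::lowess(occ$mid, occ$mean_snps, f = 2/3, iter = 3),
           prop = stats::lowess(occ$mid, occ$prop_parent1, f = 2/3,
                                iter = 3))
    } else NULL
  }
  windows <- do.call(rbind, rows)
  rownames(windows) <- NULL
  structure(list(windows = windows, smooth = smooth),
            class = "window_profile")
}

#' Regression of median allelic difference on SNP-density bins
#'
#' Bins cis-eQTL genes by the integer floor of their exonic SNPs per kb
#' (`snps_per_kb_exon`), with an open-ended top bin aggregated until it
#' holds at least `min_bin_count` genes; interior bins below
#' `min_bin_count` are dropped. The allelic expression difference is
#' twice the eQTL magnitude; per-bin medians are fit by unweighted OLS
#' against the bin's mean SNP density.
#'
#' @param records An `eqtl_records` table, typically restricted to one
#'   direction class; cis-only rows with defined magnitudes are used.
#' @param panel A `gene_panel` with `snps_per_kb_exon`.
#' @param min_bin_count Minimum genes per bin (default 10).
#' @return A `divergence_fit` list: `bins` (data.frame `bin`, `x`, `n`,
#'   `median_diff`), `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
divergence_effect_regression <- function(records, panel,
                                         min_bin_count = 10) {
  rec <- cis_only_records(records)
  rec <- rec[is.finite(rec$magnitude), , drop = FALSE]
  m <- merge(rec[, c("gene_id", "magnitude")],
             panel[, c("gene_id", "snps_per_kb_exon")], by = "gene_id")
  if (nrow(m) == 0) stop("no usable records", call. = FALSE)
  m$diff2a <- 2 * m$magnitude
  m$bin <- floor(m$snps_per_kb_exon)

  counts <- table(m$bin)
  vals <- sort(as.numeric(names(counts)))
  top <- vals[length(vals)]
  while (top > vals[1] &&
         sum(counts[as.character(vals[vals >= top])]) < min_bin_count) {
    top <- max(vals[vals < top])
  }
  m$bin[m$bin >= top] <- top
  keep <- names(which(table(m$bin) >= min_bin_count))
  m <- m[m$bin %in% as.numeric(keep), , drop = FALSE]
  bins <- sort(unique(m$bin))
  if (length(bins) < 3)
    stop("fit refused: fewer than 3 populated SNP bins", call. = FALSE)
  df <- data.frame(
    bin = bins,
    x = vapply(bins, function(b) mean(m$snps_per_kb_exon[m$bin == b]),
               numeric(1)),
    n = vapply(bins, function(b) sum(m$bin == b), integer(1)),
    median_diff = vapply(bins, function(b)
      stats::median(m$diff2a[m$bin == b]), numeric(1)))
  fit <- stats::lm(median_diff ~ x, data = df)
  sm <- summary(fit)
  structure(list(bins = df,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4]),
            class = "divergence_fit")
}

#' Compare eQTL effects between two quantification settings
#'
#' Over the parent-1-positive cis-only genes shared by both settings,
#' reports the fraction whose magnitude is larger under setting `a`
#' (ties excluded from the numerator and counted separately), an exact
#' binomial test of that fraction against 0.5 on the non-tied pairs, and
#' a 2x2 chi-square test (no continuity correction) comparing the
#' direction proportions of the two settings' cis-only sets.
#'
#' @param recs_a,recs_b `eqtl_records` tables from the two settings.
#' @return A `criteria_comparison` list: `n_shared`, `n_a_greater`,
#'   `n_ties`, `frac_a_greater`, `binom_p`, `chisq_stat`, `chisq_p`.
#' @export
compare_criteria <- function(recs_a, recs_b) {
  ca <- cis_only_records(recs_a)
  cb <- cis_only_records(recs_b)
  a1 <- ca[ca$direction %in% "parent1", c("gene_id", "magnitude")]
  b1 <- cb[cb$direction %in% "parent1", c("gene_id", "magnitude")]
  sh <- merge(a1, b1, by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(sh) == 0) stop("no shared parent-1-positive cis-eQTL",
                          call. = FALSE)
  has_mag <- is.finite(sh$magnitude_a) & is.finite(sh$magnitude_b)
  n_greater <- sum(sh$magnitude_a[has_mag] > sh$magnitude_b[has_mag])
  n_less <- sum(sh$magnitude_a[has_mag] < sh$magnitude_b[has_mag])
  n_ties <- sum(has_mag) - n_greater - n_less
  frac <- n_greater / nrow(sh)
  binom_p <- if (n_greater + n_less > 0)
    stats::binom.test(n_greater, n_greater + n_less, 0.5)$p.value else 1
  tab <- rbind(a = c(sum(ca$direction %in% "parent1"),
                     sum(ca$direction %in% "parent2")),
               b = c(sum(cb$direction %in% "parent1"),
                     sum(cb$direction %in% "parent2")))
  chi <- if (all(colSums(tab) > 0))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)) else
      list(statistic = NA_real_, p.value = NA_real_)
  structure(list(n_shared = nrow(sh), n_a_greater = n_greater,
                 n_ties = n_ties, frac_a_greater = frac,
                 binom_p = binom_p,
                 chisq_stat = unname(chi$statistic),
                 chisq_p = chi$p.value),
            class = "criteria_comparison")
}
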