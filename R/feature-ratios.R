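#' Per-gene UTR and splice-junction read ratios by parental origin
#'
#' For each gene and parental read origin, the UTR ratio is the number of
#' UTR-mapped reads divided by all exon-mapped reads, and the
#' splice-junction (SJ) ratio is the number of junction-spanning reads
#' divided by all exon-mapped reads. Genes are excluded from the UTR
#' analysis when they have no UTR reads in either origin or no
#' non-UTR (CDS) reads in either origin, and from the SJ analysis when
#' they have no junction-spanning reads in either origin or no
#' non-junction reads; genes with zero total reads in either origin are
#' excluded throughout. Exclusions are reported.
#'
#' @param counts A `feature_counts` data.frame (`gene_id`, `origin`,
#'   `utr_reads`, `sj_reads`, `total_reads`).
#' @return A `ratio_table` data.frame, one row per gene: ratios per
#'   origin and pooled (`_all`), plus logical `utr_ok`, `sj_ok`.
#' @examples
#' cnt <- data.frame(gene_id = rep("g1", 2),
#'                   origin = c("parent1", "parent2"),
#'                   utr_reads = c(20L, 15L), sj_reads = c(30L, 28L),
#'                   total_reads = c(100L, 90L))
#' compute_ratios(cnt)
#' @export
compute_ratios <- function(counts) {
  need <- c("gene_id", "origin", "utr_reads", "sj_reads", "total_reads")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$utr_reads > counts$total_reads) ||
      any(counts$sj_reads > counts$total_reads) ||
      any(counts[, c("utr_reads", "sj_reads", "total_reads")] < 0))
    stop("invalid counts: need 0 <= UTR, SJ <= total", call. = FALSE)
  c1 <- counts[counts$origin == "parent1", , drop = FALSE]
  c2 <- counts[counts$origin == "parent2", , drop = FALSE]
  m <- merge(c1, c2, by = "gene_id", suffixes = c("_1", "_2"))

  pos_total <- m$total_reads_1 > 0 & m$total_reads_2 > 0
  utr_sum <- m$utr_reads_1 + m$utr_reads_2
  cds_sum <- (m$total_reads_1 - m$utr_reads_1) +
    (m$total_reads_2 - m$utr_reads_2)
  sj_sum <- m$sj_reads_1 + m$sj_reads_2
  nonsj_sum <- (m$total_reads_1 - m$sj_reads_1) +
    (m$total_reads_2 - m$sj_reads_2)
  utr_ok <- pos_total & utr_sum > 0 & cds_sum > 0
  sj_ok <- pos_total & sj_sum > 0 & nonsj_sum > 0

  out <- data.frame(
    gene_id = m$gene_id,
    utr_ratio_parent1 = ifelse(m$total_reads_1 > 0,
                               m$utr_reads_1 / m$total_reads_1, NA),
    utr_ratio_parent2 = ifelse(m$total_reads_2 > 0,
                               m$utr_reads_2 / m$total_reads_2, NA),
    sj_ratio_parent1 = ifelse(m$total_reads_1 > 0,
                              m$sj_reads_1 / m$total_reads_1, NA),
    sj_ratio_parent2 = ifelse(m$total_reads_2 > 0,
                              m$sj_reads_2 / m$total_reads_2, NA),
    utr_ratio_all = ifelse(m$total_reads_1 + m$total_reads_2 > 0,
                           utr_sum / (m$total_reads_1 + m$total_reads_2),
                           NA),
    sj_ratio_all = ifelse(m$total_reads_1 + m$total_reads_2 > 0,
                          sj_sum / (m$total_reads_1 + m$total_reads_2),
                          NA),
    utr_ok = utr_ok, sj_ok = sj_ok,
    stringsAsFactors = FALSE)
  message(sprintf(
    "compute_ratios: %d genes; %d excluded from UTR, %d from SJ analysis",
    nrow(out), sum(!utr_ok), sum(!sj_ok)))
  class(out) <- c("ratio_table", "data.frame")
  out
}

wilcox_paired <- function(x, y, exact_below = 50) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) {
    warning("fewer than 10 genes in a direction set; exact test forced")
    exact <- TRUE
  } else exact <- n < exact_below
  if (all(x == y))               # no non-zero differences: no evidence
    return(list(n = n, statistic = 0, p = 1, median_diff = 0))
  t <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                           exact = exact, correct = TRUE))
  list(n = n, statistic = unname(t$statistic), p = t$p.value,
       median_diff = stats::median(x - y))
}

wilcox_ranksum <- function(x, y, exact_below = 50) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  exact <- min(length(x), length(y)) < exact_below
  if (min(length(x), length(y)) < 10)
    warning("fewer than 10 genes in a direction set; exact test forced")
  t <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                           correct = TRUE))
  list(n_x = length(x), n_y = length(y),
       statistic = unname(t$statistic), p = t$p.value)
}

#' Wilcoxon tests of UTR and splice-junction usage by eQTL direction
#'
#' Runs the four comparisons of the UTR/SJ bias analysis for each ratio
#' type: within each cis-eQTL direction set, a paired Wilcoxon
#' signed-rank test of the parent-1-origin versus parent-2-origin ratios
#' across genes; and between the two direction sets, a Wilcoxon rank-sum
#' test of the pooled (all-reads) ratios. Both tests are two-sided, with
#' the normal approximation (continuity-corrected) above 50 genes and
#' exact below. Medians are reported as percentages.
#'
#' @param ratios A `ratio_table` from [compute_ratios()].
#' @param directions data.frame `gene_id`, `direction`
#'   (`"parent1"`/`"parent2"`), e.g. from cis-only eQTL records or
#'   [truth_cis_directions()].
#' @return A `ratio_tests` list with components `utr` and `sj`, each
#'   holding `medians` (percent, by direction set and origin),
#'   `signed_rank` (per-set paired tests) and `rank_sum` (between-set
#'   test).
#' @export
ratio_tests <- function(ratios, directions) {
  stopifnot(all(c("gene_id", "direction") %in% names(directions)))
  dd <- directions[directions$direction %in% c("parent1", "parent2"), ,
                   drop = FALSE]
  m <- merge(ratios, dd, by = "gene_id")
  if (nrow(m) == 0) stop("no genes shared between ratios and directions",
                         call. = FALSE)
  one_type <- function(type) {
    ok <- m[[paste0(type, "_ok")]]
    d <- m[ok, , drop = FALSE]
    s1 <- d$direction == "parent1"
    med <- function(x) 100 * stats::median(x, na.rm = TRUE)
    sets <- list(parent1_positive = d[s1, , drop = FALSE],
                 parent2_positive = d[!s1, , drop = FALSE])
    medians <- do.call(rbind, lapply(sets, function(s) data.frame(
      n = nrow(s),
      parent1_reads = med(s[[paste0(type, "_ratio_parent1")]]),
      parent2_reads = med(s[[paste0(type, "_ratio_parent2")]]),
      all_reads = med(s[[paste0(type, "_ratio_all")]]))))
    signed <- lapply(sets, function(s)
      wilcox_paired(s[[paste0(type, "_ratio_parent1")]],
                    s[[paste0(type, "_ratio_parent2")]]))
    ranksum <- wilcox_ranksum(
      sets$parent1_positive[[paste0(type, "_ratio_all")]],
      sets$parent2_positive[[paste0(type, "_ratio_all")]])
    list(medians = medians, signed_rank = signed, rank_sum = ranksum)
  }
  structure(list(utr = one_type("utr"), sj = one_type("sj")),
            class = "ratio_tests")
}

#' @export
print.ratio_tests <- function(x, ...) {
  for (type in c("utr", "sj")) {
    cat(sprintf("%s read ratios (median %%):\n", toupper(type)))
    print(round(x[[type]]$medians, 2))
    for (nm in names(x[[type]]$signed_rank)) {
      s <- x[[type]]$signed_rank[[nm]]
      cat(sprintf("  signed-rank %s: V = %.0f, p = %.3g (n = %d)\n",
                  nm, s$statistic, s$p, s$n))
    }
    r <- x[[type]]$rank_sum
    cat(sprintf("  rank-sum between sets: W = %.0f, p = %.3g\n",
                r$statistic, r$p))
  }
  invisible(x)
}
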