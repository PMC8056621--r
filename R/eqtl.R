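#' Gene expression filter configuration
#'
#' Mirrors the standard two-stage filter for RIL expression panels: keep
#' genes expressed above `expr_min` in at least `min_lines` lines, then
#' the `variability_keep` fraction with the highest variance of
#' `log2(x + 1)`.
#'
#' @param expr_min Abundance threshold (default 1, FPKM scale).
#' @param min_lines Minimum number of lines above threshold (default 42).
#' @param variability_keep Fraction of stage-1 genes retained by
#'   variability, in (0, 1] (default 0.75).
#' @return A `gene_filter_config` list.
#' @export
gene_filter_config <- function(expr_min = 1, min_lines = 42,
                               variability_keep = 0.75) {
  if (variability_keep <= 0 || variability_keep > 1)
    stop("'variability_keep' must be in (0, 1]", call. = FALSE)
  structure(list(expr_min = expr_min, min_lines = min_lines,
                 variability_keep = variability_keep),
            class = "gene_filter_config")
}

#' Filter genes on expression level and variability
#'
#' @param expr Genes x lines numeric matrix (non-negative abundances).
#' @param cfg A [gene_filter_config()].
#' @return The filtered matrix (row order preserved, `reference`
#'   attribute carried over).
#' @examples
#' m <- rbind(a = rep(0, 50), b = rexp(50) + 2, c = rep(3, 50))
#' filter_genes(m, gene_filter_config(min_lines = 10,
#'                                    variability_keep = 0.5))
#' @export
filter_genes <- function(expr, cfg = gene_filter_config()) {
  stopifnot(is.matrix(expr))
  if (any(expr < 0)) stop("abundances must be >= 0", call. = FALSE)
  stage1 <- rowSums(expr > cfg$expr_min) >= cfg$min_lines
  if (!any(stage1))
    stop("no genes pass the expression-level filter", call. = FALSE)
  m1 <- expr[stage1, , drop = FALSE]
  lg <- log2(m1 + 1)
  v <- rowSums((lg - rowMeans(lg))^2) / (ncol(lg) - 1)
  keep_n <- max(1L, floor(nrow(m1) * cfg$variability_keep))
  keep <- sort(order(v, decreasing = TRUE)[seq_len(keep_n)])
  message(sprintf(
    "filter_genes: %d/%d genes pass expression filter; %d kept by variability",
    nrow(m1), nrow(expr), keep_n))
  out <- m1[keep, , drop = FALSE]
  attr(out, "reference") <- attr(expr, "reference")
  out
}

#' Genotype probabilities on a cM grid
#'
#' Runs a two-state (parent-1 / parent-2) hidden Markov model along each
#' chromosome for every line. Transitions between grid positions at map
#' distance `d` use the selfed-RIL expansion `R(d) = 2r/(1+2r)` of the
#' Haldane recombination fraction; observed marker calls are emitted with
#' genotyping error `error_prob`, and `H`/`N` calls are uninformative.
#' The grid consists of the markers plus pseudomarkers every `step_cm`.
#'
#' @param genotypes A `ril_genotypes`.
#' @param map A `genetic_map` covering the genotyped markers.
#' @param step_cm Pseudomarker spacing in cM (default 1).
#' @param error_prob Genotyping error probability (default 0.001).
#' @return An object of class `geno_prob`: list with `grid` (data.frame
#'   `chrom`, `cm`, `is_marker`) and `prob` (lines x grid matrix of
#'   posterior P(parent-1 allele)).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_genes = 5, n_markers = 20, n_lines = 20)
#' map <- simulate_marker_map(cfg)
#' rils <- simulate_ril_population(map, cfg)
#' pr <- genotype_probabilities(rils, map, step_cm = 5)
#' range(pr$prob)
#' @export
genotype_probabilities <- function(genotypes, map, step_cm = 1,
                                   error_prob = 1e-3) {
  stopifnot(inherits(genotypes, "ril_genotypes"))
  map <- validate_genetic_map(map)
  if (step_cm <= 0) stop("'step_cm' must be > 0", call. = FALSE)
  calls <- genotypes$calls
  if (!all(map$marker_id %in% colnames(calls)))
    stop("map contains markers absent from the genotype matrix",
         call. = FALSE)
  n <- nrow(calls)
  eps <- error_prob

  grids <- list(); probs <- list()
  for (k in unique(map$chrom)) {
    mk <- map[map$chrom == k, , drop = FALSE]
    mk <- mk[order(mk$cm), , drop = FALSE]
    gcm <- sort(unique(round(c(mk$cm, seq(min(mk$cm), max(mk$cm),
                                          by = step_cm)), 6)))
    K <- length(gcm)
    # marker -> grid index (several markers may share a grid point)
    midx <- match(round(mk$cm, 6), gcm)

    # emission likelihoods, lines x grid x 2 states, start uniform
    e1 <- matrix(1, n, K); e2 <- matrix(1, n, K)
    for (j in seq_len(nrow(mk))) {
      cc <- calls[, mk$marker_id[j]]
      g <- midx[j]
      e1[, g] <- e1[, g] * ifelse(cc == "A", 1 - eps,
                                  ifelse(cc == "B", eps, 1))
      e2[, g] <- e2[, g] * ifelse(cc == "B", 1 - eps,
                                  ifelse(cc == "A", eps, 1))
    }
    R <- ril_R(haldane_r(diff(gcm)))

    f1 <- matrix(0, n, K); f2 <- matrix(0, n, K)
    f1[, 1] <- 0.5 * e1[, 1]; f2[, 1] <- 0.5 * e2[, 1]
    sc <- f1[, 1] + f2[, 1]
    f1[, 1] <- f1[, 1] / sc; f2[, 1] <- f2[, 1] / sc
    if (K > 1) for (t in 2:K) {
      p1 <- f1[, t - 1] * (1 - R[t - 1]) + f2[, t - 1] * R[t - 1]
      p2 <- f1[, t - 1] * R[t - 1] + f2[, t - 1] * (1 - R[t - 1])
      f1[, t] <- p1 * e1[, t]; f2[, t] <- p2 * e2[, t]
      sc <- f1[, t] + f2[, t]
      f1[, t] <- f1[, t] / sc; f2[, t] <- f2[, t] / sc
    }
    b1 <- matrix(1, n, K); b2 <- matrix(1, n, K)
    if (K > 1) for (t in (K - 1):1) {
      x1 <- b1[, t + 1] * e1[, t + 1]; x2 <- b2[, t + 1] * e2[, t + 1]
      b1[, t] <- x1 * (1 - R[t]) + x2 * R[t]
      b2[, t] <- x1 * R[t] + x2 * (1 - R[t])
      sc <- b1[, t] + b2[, t]
      b1[, t] <- b1[, t] / sc; b2[, t] <- b2[, t] / sc
    }
    num1 <- f1 * b1; num2 <- f2 * b2
    probs[[as.character(k)]] <- num1 / (num1 + num2)
    grids[[as.character(k)]] <- data.frame(
      chrom = k, cm = gcm,
      is_marker = seq_len(K) %in% midx)
  }
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  prob <- do.call(cbind, probs)
  dimnames(prob) <- list(rownames(calls), NULL)
  structure(list(grid = grid, prob = prob), class = "geno_prob")
}

# Rank scores centred at zero; mid-ranks for ties.
rank_scores <- function(x) {
  n <- length(x)
  rank(x, ties.method = "average") - (n + 1) / 2
}

# Core of the rank-based scan. U: lines x phenotypes matrix of centred
# rank scores; returns a grid x phenotypes LOD matrix. The statistic is
# the squared linear rank statistic standardised by its exact permutation
# variance, H = (sum w_i u_i)^2 (n-1) / (sum (w_i - wbar)^2 * sum u_i^2),
# which reduces to the two-sample Kruskal-Wallis statistic (with tie
# correction) at fully informative positions. LOD = H / (2 ln 10).
scan_core <- function(U, probs) {
  W <- probs$prob
  n <- nrow(W)
  stopifnot(nrow(U) == n)
  Wc <- sweep(W, 2, colMeans(W))
  Sw <- colSums(Wc^2)
  su2 <- colSums(U^2)
  num <- crossprod(Wc, U)               # grid x phenotypes
  denom <- outer(Sw, su2)
  H <- (num * num) * (n - 1) / denom
  H[Sw < 1e-12, ] <- 0
  H[, su2 < 1e-12] <- 0
  H / (2 * log(10))
}

#' Nonparametric single-phenotype genome scan
#'
#' Rank-based (extended Kruskal-Wallis) interval mapping: the phenotype is
#' converted to mid-ranks and, at each grid position, the expected
#' parent-1 membership probabilities act as group weights. At a fully
#' informative position the statistic is exactly the two-sample
#' Kruskal-Wallis H; `LOD = H / (2 ln 10)`. A constant phenotype yields a
#' LOD curve identically zero.
#'
#' @param pheno Numeric phenotype vector, one value per line (order
#'   matching the rows of `probs$prob`).
#' @param probs A `geno_prob` from [genotype_probabilities()].
#' @return data.frame `chrom`, `cm`, `lod`.
#' @export
scan_np <- function(pheno, probs) {
  stopifnot(inherits(probs, "geno_prob"))
  if (length(pheno) != nrow(probs$prob))
    stop("phenotype length must equal the number of lines", call. = FALSE)
  u <- rank_scores(pheno)
  lod <- scan_core(matrix(u, ncol = 1), probs)[, 1]
  data.frame(chrom = probs$grid$chrom, cm = probs$grid$cm, lod = lod)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the rank-score vector across lines, records the genome-wide
#' maximum LOD of each permutation, and returns the empirical `1 - alpha`
#' quantile (type-7 interpolation). Because the scan statistic depends on
#' the phenotype only through its ranks, a single null built from the
#' tie-free scores `1..n` serves every tie-free phenotype on the same
#' genotype grid; pass `scores` to obtain a per-phenotype null for tied
#' phenotypes.
#'
#' @param probs A `geno_prob`.
#' @param n_perm Number of permutations (>= 20).
#' @param alpha Genome-wide significance level, in (0, 1].
#' @param scores Optional rank-score vector to permute (defaults to the
#'   tie-free scores).
#' @return Scalar LOD threshold, with attribute `max_lods` (the permuted
#'   maxima).
#' @export
permutation_threshold <- function(probs, n_perm = 1000, alpha = 0.05,
                                  scores = NULL) {
  stopifnot(inherits(probs, "geno_prob"))
  if (n_perm < 20) stop("'n_perm' must be >= 20", call. = FALSE)
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  if (alpha == 1)
    warning("alpha = 1 is degenerate; returning the minimum permuted maximum")
  n <- nrow(probs$prob)
  u0 <- if (is.null(scores)) seq_len(n) - (n + 1) / 2 else scores
  U <- vapply(seq_len(n_perm), function(i) sample(u0), numeric(n))
  lod <- scan_core(U, probs)
  max_lods <- apply(lod, 2, max)
  thr <- stats::quantile(max_lods, 1 - alpha, type = 7, names = FALSE)
  attr(thr, "max_lods") <- max_lods
  thr
}

# 1.5-LOD support interval around the peak (contiguous region on the
# peak's chromosome where lod >= peak - drop).
support_interval <- function(cm, lod, peak_idx, drop = 1.5) {
  thr <- lod[peak_idx] - drop
  lo <- peak_idx
  while (lo > 1 && lod[lo - 1] >= thr) lo <- lo - 1
  hi <- peak_idx
  while (hi < length(lod) && lod[hi + 1] >= thr) hi <- hi + 1
  c(cm[lo], cm[hi])
}

#' Call eQTL peaks from a LOD curve
#'
#' Retains at most one peak per chromosome (the curve maximum) where the
#' maximum LOD exceeds `threshold`. A peak is cis when it lies on the
#' gene's chromosome and the gene's genetic position falls inside the
#' peak's 1.5-LOD support interval or within `cis_window_cm` of the peak;
#' every other significant peak is trans. The gene is `cis_only` when it
#' has exactly one significant peak and that peak is cis.
#'
#' @param scan data.frame `chrom`, `cm`, `lod` from [scan_np()].
#' @param gene_pos list or vector with the gene's `chrom` and `cm`.
#' @param threshold Genome-wide LOD threshold.
#' @param cis_window_cm Cis window half-width in cM (default 10).
#' @return data.frame with one row per significant peak: `chrom`,
#'   `peak_cm`, `lod`, `ci_lo`, `ci_hi`, `cis`, `cis_only`. Zero rows when
#'   nothing is significant.
#' @export
call_eqtl <- function(scan, gene_pos, threshold, cis_window_cm = 10) {
  if (is.null(gene_pos$chrom) || is.null(gene_pos$cm) ||
      is.na(gene_pos$cm)) {
    warning("gene position missing; record skipped")
    return(NULL)
  }
  peaks <- lapply(unique(scan$chrom), function(k) {
    idx <- which(scan$chrom == k)
    pk <- idx[which.max(scan$lod[idx])]
    if (scan$lod[pk] <= threshold) return(NULL)
    ci <- support_interval(scan$cm[idx], scan$lod[idx],
                           which.max(scan$lod[idx]))
    cis <- k == gene_pos$chrom &&
      ((gene_pos$cm >= ci[1] && gene_pos$cm <= ci[2]) ||
         abs(scan$cm[pk] - gene_pos$cm) <= cis_window_cm)
    data.frame(chrom = k, peak_cm = scan$cm[pk], lod = scan$lod[pk],
               ci_lo = ci[1], ci_hi = ci[2], cis = cis)
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks))
    return(data.frame(chrom = numeric(0), peak_cm = numeric(0),
                      lod = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), cis = logical(0),
                      cis_only = logical(0)))
  peaks$cis_only <- nrow(peaks) == 1 & peaks$cis
  peaks
}

#' Allele effect at an eQTL peak
#'
#' Lines are assigned to the genotype with posterior probability above
#' 0.5; group means are computed on the original (unranked) expression
#' scale; the magnitude is half the absolute difference of the two
#' genotype-group means and the direction is the parent with the larger
#' mean.
#'
#' @param pheno Expression vector (original scale).
#' @param peak_probs P(parent-1 allele) for each line at the peak.
#' @return list `direction` (`"parent1"`, `"parent2"` or `NA` on a tie),
#'   `magnitude`, `mean_parent1`, `mean_parent2`, `degenerate` (TRUE when
#'   a genotype group is empty; magnitude is then NA).
#' @export
estimate_effect <- function(pheno, peak_probs) {
  g1 <- peak_probs > 0.5
  g2 <- peak_probs < 0.5
  if (!any(g1) || !any(g2))
    return(list(direction = NA_character_, magnitude = NA_real_,
                mean_parent1 = if (any(g1)) mean(pheno[g1]) else NA_real_,
                mean_parent2 = if (any(g2)) mean(pheno[g2]) else NA_real_,
                degenerate = TRUE))
  m1 <- mean(pheno[g1]); m2 <- mean(pheno[g2])
  list(direction = if (m1 > m2) "parent1" else if (m2 > m1) "parent2"
       else NA_character_,
       magnitude = abs(m1 - m2) / 2,
       mean_parent1 = m1, mean_parent2 = m2,
       degenerate = FALSE)
}

#' Map eQTL for an expression matrix
#'
#' End-to-end scan: genotype probabilities (unless supplied), a shared
#' permutation threshold from the tie-free null (with per-gene
#' permutation nulls for tied phenotypes when `tie_mode = "per-gene"`),
#' the rank-based scan of every gene, peak calling and allele-effect
#' estimation.
#'
#' @param expr Genes x lines matrix (already filtered; see
#'   [filter_genes()]). Column order must match the genotype lines.
#' @param genotypes A `ril_genotypes`.
#' @param map A `genetic_map`.
#' @param panel A `gene_panel` giving gene positions (`gene_id`, `chrom`,
#'   `start`); genes absent from the panel are skipped with a warning.
#' @param n_perm Permutations for the genome-wide threshold.
#' @param alpha Genome-wide significance level.
#' @param step_cm,error_prob Passed to [genotype_probabilities()].
#' @param cis_window_cm Passed to [call_eqtl()].
#' @param probs Optional precomputed `geno_prob`.
#' @param threshold Optional precomputed LOD threshold (skips the
#'   permutations).
#' @param tie_mode `"shared"` applies the shared threshold to all genes;
#'   `"per-gene"` recomputes the null from each tied phenotype's own rank
#'   scores.
#' @return An `eqtl_records` data.frame with one row per significant peak:
#'   `gene_id`, `gene_chrom`, `gene_cm`, `chrom`, `peak_cm`, `lod`,
#'   `threshold`, `cis`, `cis_only`, `direction`, `magnitude`,
#'   `mean_parent1`, `mean_parent2`, `n_peaks`. Attributes: `threshold`,
#'   `n_genes_scanned`.
#' @examples
#' set.seed(2)
#' cfg <- sim_config(n_genes = 40, n_markers = 40, n_lines = 40,
#'                   delta = 0, cis_fraction = 0.5, cis_effect_sd = 4)
#' sim <- simulate_dataset(cfg)
#' rec <- map_eqtl(sim$expression$vs_parent1, sim$genotypes, sim$map,
#'                 sim$panel, n_perm = 50)
#' head(rec)
#' @export
map_eqtl <- function(expr, genotypes, map, panel, n_perm = 1000,
                     alpha = 0.05, step_cm = 1, error_prob = 1e-3,
                     cis_window_cm = 10, probs = NULL, threshold = NULL,
                     tie_mode = c("shared", "per-gene")) {
  tie_mode <- match.arg(tie_mode)
  stopifnot(is.matrix(expr))
  if (ncol(expr) != nrow(genotypes$calls))
    stop("expression columns and genotype lines differ in number",
         call. = FALSE)
  if (is.null(probs))
    probs <- genotype_probabilities(genotypes, map, step_cm, error_prob)
  if (is.null(threshold))
    threshold <- permutation_threshold(probs, n_perm, alpha)

  gene_cm <- gene_cm_positions(panel, map)
  names(gene_cm) <- panel$gene_id
  gene_chrom <- panel$chrom
  names(gene_chrom) <- panel$gene_id

  U <- apply(expr, 1, rank_scores)       # lines x genes
  lod <- scan_core(U, probs)             # grid x genes
  grid <- probs$grid

  recs <- vector("list", nrow(expr))
  for (g in seq_len(nrow(expr))) {
    gid <- rownames(expr)[g]
    if (!gid %in% panel$gene_id) {
      warning(sprintf("gene %s absent from panel; skipped", gid))
      next
    }
    thr_g <- threshold
    if (tie_mode == "per-gene" && anyDuplicated(expr[g, ])) {
      thr_g <- permutation_threshold(probs, max(n_perm, 20), alpha,
                                     scores = U[, g])
    }
    sc <- data.frame(chrom = grid$chrom, cm = grid$cm, lod = lod[, g])
    pk <- call_eqtl(sc, list(chrom = gene_chrom[[gid]],
                             cm = gene_cm[[gid]]), thr_g, cis_window_cm)
    if (is.null(pk) || nrow(pk) == 0) next
    eff <- lapply(seq_len(nrow(pk)), function(i) {
      gi <- which(grid$chrom == pk$chrom[i] &
                    abs(grid$cm - pk$peak_cm[i]) < 1e-8)[1]
      estimate_effect(expr[g, ], probs$prob[, gi])
    })
    pk$gene_id <- gid
    pk$gene_chrom <- gene_chrom[[gid]]
    pk$gene_cm <- gene_cm[[gid]]
    pk$threshold <- as.numeric(thr_g)
    pk$direction <- vapply(eff, function(e) e$direction, character(1))
    pk$magnitude <- vapply(eff, function(e) e$magnitude, numeric(1))
    pk$mean_parent1 <- vapply(eff, function(e) e$mean_parent1, numeric(1))
    pk$mean_parent2 <- vapply(eff, function(e) e$mean_parent2, numeric(1))
    pk$n_peaks <- nrow(pk)
    recs[[g]] <- pk
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), gene_chrom = numeric(0),
                      gene_cm = numeric(0), chrom = numeric(0),
                      peak_cm = numeric(0), lod = numeric(0),
                      threshold = numeric(0), cis = logical(0),
                      cis_only = logical(0), direction = character(0),
                      magnitude = numeric(0), mean_parent1 = numeric(0),
                      mean_parent2 = numeric(0), n_peaks = integer(0))
  ord <- c("gene_id", "gene_chrom", "gene_cm", "chrom", "peak_cm", "lod",
           "threshold", "cis", "cis_only", "direction", "magnitude",
           "mean_parent1", "mean_parent2", "n_peaks")
  extra <- setdiff(names(out), ord)
  out <- out[, c(ord, extra)]
  rownames(out) <- NULL
  class(out) <- c("eqtl_records", "data.frame")
  attr(out, "threshold") <- as.numeric(threshold)
  attr(out, "n_genes_scanned") <- nrow(expr)
  attr(out, "reference") <- attr(expr, "reference")
  out
}

#' Cis-only records (one row per gene)
#'
#' Restricts an `eqtl_records` table to genes with exactly one significant
#' peak, that peak being cis — the set on which the direction-asymmetry
#' diagnostics operate.
#'
#' @param records An `eqtl_records` data.frame.
#' @return The cis-only subset (class preserved).
#' @export
cis_only_records <- function(records) {
  out <- records[records$cis_only %in% TRUE, , drop = FALSE]
  class(out) <- c("eqtl_records", "data.frame")
  attr(out, "reference") <- attr(records, "reference")
  out
}
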