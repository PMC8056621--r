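#' Coexpression configuration
#'
#' @param beta Soft-threshold power for the unsigned adjacency (default
#'   5).
#' @param min_module_size Modules smaller than this are merged into their
#'   closest neighbour (default 60).
#' @param merge_to_similarity Modules whose mean inter-module topological
#'   overlap with their closest neighbour exceeds this are merged
#'   (default 0.8).
#' @param cut_height Static dendrogram cut height on the 1 - TOM
#'   dissimilarity (default 0.97).
#' @param merge_floor Small modules whose closest-neighbour similarity is
#'   below this are left unassigned instead of being absorbed (default
#'   0.05) — the analogue of WGCNA's grey module.
#' @return A `coexpression_config` list.
#' @export
coexpression_config <- function(beta = 5, min_module_size = 60,
                                merge_to_similarity = 0.8,
                                cut_height = 0.97, merge_floor = 0.05) {
  if (beta < 1) stop("'beta' must be >= 1", call. = FALSE)
  if (min_module_size < 2) stop("'min_module_size' must be >= 2",
                                call. = FALSE)
  if (merge_to_similarity <= 0 || merge_to_similarity >= 1)
    stop("'merge_to_similarity' must be in (0, 1)", call. = FALSE)
  structure(list(beta = beta, min_module_size = min_module_size,
                 merge_to_similarity = merge_to_similarity,
                 cut_height = cut_height, merge_floor = merge_floor),
            class = "coexpression_config")
}

#' Unsigned adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^beta` (diagonal set to 0), from
#' which the unsigned topological overlap
#' `t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_u a_iu`; `t` is symmetric with unit diagonal
#' and values in \[0, 1\].
#'
#' @param expr Genes x lines matrix (>= 3 lines); constant genes are
#'   rejected by name.
#' @param beta Soft-threshold power.
#' @return The TOM matrix (genes x genes).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(5 * 30), 5, dimnames = list(paste0("g", 1:5), NULL))
#' range(adjacency_tom(x, beta = 5))
#' @export
adjacency_tom <- function(expr, beta = 5) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3) stop("need at least 3 lines", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant gene(s): %s",
                 paste(utils::head(rownames(expr)[sds == 0], 5),
                       collapse = ", ")), call. = FALSE)
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

# Mean inter-module TOM between two gene index sets.
module_similarity <- function(tom, i, j) mean(tom[i, j, drop = FALSE])

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, a static cut at `cut_height`, then iterative merging:
#' while any module is smaller than `min_module_size` or has mean
#' inter-module TOM similarity above `merge_to_similarity` to its
#' closest neighbour (the module with maximal mean inter-module TOM),
#' the smallest offending module is absorbed into that neighbour. Small
#' modules whose closest-neighbour similarity falls below `merge_floor`
#' are left unassigned (label 0) rather than absorbed. Each merge
#' strictly decreases the module count, so the procedure terminates.
#'
#' @param tom Symmetric TOM matrix in \[0, 1\].
#' @param cfg A [coexpression_config()].
#' @return Integer module labels (named by gene when `tom` has
#'   dimnames); 0 marks unassigned genes, positive labels are ordered by
#'   decreasing module size.
#' @export
detect_modules <- function(tom, cfg = coexpression_config()) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  if (max(abs(tom - t(tom))) > 1e-8 || min(tom) < -1e-8 ||
      max(tom) > 1 + 1e-8)
    stop("'tom' must be symmetric with values in [0, 1]", call. = FALSE)
  n <- nrow(tom)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels <- stats::cutree(hc, h = cfg$cut_height)

  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(m) sum(labels == m), integer(1))
    S <- matrix(NA_real_, length(ids), length(ids))
    for (i in seq_along(ids)) for (j in seq_along(ids)) if (i != j)
      S[i, j] <- module_similarity(tom, which(labels == ids[i]),
                                   which(labels == ids[j]))
    nb <- apply(S, 1, which.max)
    nb_sim <- S[cbind(seq_along(ids), nb)]
    offending <- sizes < cfg$min_module_size |
      nb_sim > cfg$merge_to_similarity
    if (!any(offending)) break
    cand <- which(offending)
    m <- cand[order(sizes[cand], ids[cand])][1]
    if (sizes[m] < cfg$min_module_size && nb_sim[m] < cfg$merge_floor) {
      labels[labels == ids[m]] <- 0L
    } else {
      labels[labels == ids[m]] <- ids[nb[m]]
    }
  }
  # renumber by decreasing size, stable
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 0) {
    sizes <- vapply(ids, function(m) sum(labels == m), integer(1))
    new <- integer(max(ids))
    new[ids[order(-sizes, ids)]] <- seq_along(ids)
    labels[labels > 0] <- new[labels[labels > 0]]
  }
  out <- as.integer(labels)
  names(out) <- rownames(tom)
  out
}

#' Haplotype-direction consistency of coexpression modules
#'
#' For every gene, the haplotype direction is the sign of the
#' point-biserial correlation between its expression and the
#' parent-1 = 1 / parent-2 = 0 coding of its nearest genotyped marker
#' (`H`/`N` calls excluded). A module's consistency is the fraction of
#' its direction-scored members sharing the majority sign. A module is
#' flagged bias-suspect when consistency is at least `consistency_min`
#' and at least `span_frac` of its members lie on one chromosome within a
#' contiguous span of `span_bp` — a single haplotype block driving one
#' direction is the mapping-bias signature, whereas genuine regulatory
#' variation in a linked block splits into opposite-direction gene sets.
#'
#' @param modules Integer module labels from [detect_modules()] (named by
#'   gene id, 0 = unassigned).
#' @param expr Genes x lines expression matrix.
#' @param genotypes A `ril_genotypes`.
#' @param panel A `gene_panel` with gene positions.
#' @param records Optional `eqtl_records`; when given, each module also
#'   reports how many members have cis-eQTL and their direction
#'   agreement with the module majority.
#' @param consistency_min Consistency flag threshold (default 0.9).
#' @param span_bp Maximum physical extent of the dominant span (default
#'   150 Mb).
#' @param span_frac Minimum fraction of members inside the span (default
#'   0.5).
#' @return A `module_report` list: `genes` (per-gene data.frame) and
#'   `modules` (per-module data.frame with `consistency`, `direction`,
#'   `span_fraction`, `bias_suspect`, ...).
#' @export
haplotype_direction <- function(modules, expr, genotypes, panel,
                                records = NULL, consistency_min = 0.9,
                                span_bp = 150e6, span_frac = 0.5) {
  stopifnot(inherits(genotypes, "ril_genotypes"))
  gene_ids <- names(modules)
  if (is.null(gene_ids)) gene_ids <- rownames(expr)
  pan <- panel[match(gene_ids, panel$gene_id), , drop = FALSE]
  mk <- nearest_marker(pan, genotypes$markers)
  dir_sign <- integer(length(gene_ids))
  for (g in seq_along(gene_ids)) {
    cc <- genotypes$calls[, mk[g]]
    x <- ifelse(cc == "A", 1, ifelse(cc == "B", 0, NA))
    ok <- !is.na(x)
    r <- if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 &&
             stats::sd(expr[g, ok]) > 0)
      stats::cor(expr[g, ok], x[ok]) else NA_real_
    dir_sign[g] <- if (is.na(r) || r == 0) NA_integer_ else sign(r)
  }
  genes <- data.frame(gene_id = gene_ids, module = as.integer(modules),
                      chrom = pan$chrom, bp = pan$start,
                      direction = ifelse(is.na(dir_sign), NA_character_,
                                         ifelse(dir_sign > 0, "parent1",
                                                "parent2")),
                      stringsAsFactors = FALSE)

  cis_dir <- NULL
  if (!is.null(records)) {
    co <- cis_only_records(records)
    cis_dir <- stats::setNames(co$direction, co$gene_id)
  }
  mods <- sort(unique(modules[modules > 0]))
  rows <- lapply(mods, function(m) {
    gi <- which(modules == m)
    s <- dir_sign[gi]
    s <- s[!is.na(s)]
    if (length(s) == 0)
      return(data.frame(module = m, n_genes = length(gi),
                        n_scored = 0L, consistency = NA_real_,
                        direction = NA_character_,
                        span_fraction = NA_real_, bias_suspect = NA,
                        n_cis_eqtl = NA_integer_,
                        cis_agreement = NA_real_))
    n_pos <- sum(s > 0); n_neg <- sum(s < 0)
    consistency <- max(n_pos, n_neg) / (n_pos + n_neg)
    direction <- if (n_pos >= n_neg) "parent1" else "parent2"
    # dominant contiguous span: best window of span_bp on the modal chrom
    tabk <- table(genes$chrom[gi])
    kmod <- as.numeric(names(tabk)[which.max(tabk)])
    bp <- sort(genes$bp[gi][genes$chrom[gi] == kmod])
    best <- 0L
    for (i in seq_along(bp))
      best <- max(best, sum(bp >= bp[i] & bp <= bp[i] + span_bp))
    sf <- best / length(gi)
    n_cis <- NA_integer_; agree <- NA_real_
    if (!is.null(cis_dir)) {
      memb <- genes$gene_id[gi]
      hit <- memb[memb %in% names(cis_dir)]
      n_cis <- length(hit)
      agree <- if (n_cis > 0) mean(cis_dir[hit] == direction) else NA_real_
    }
    data.frame(module = m, n_genes = length(gi), n_scored = length(s),
               consistency = consistency, direction = direction,
               span_fraction = sf,
               bias_suspect = consistency >= consistency_min &
                 sf >= span_frac,
               n_cis_eqtl = n_cis, cis_agreement = agree)
  })
  modules_df <- do.call(rbind, rows)
  structure(list(genes = genes, modules = modules_df),
            class = "module_report")
}
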