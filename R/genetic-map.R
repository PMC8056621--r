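validate_genetic_map <- function(map) {
  need <- c("marker_id", "chrom", "bp", "cm")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("a genetic map needs columns marker_id, chrom, bp, cm",
         call. = FALSE)
  for (k in unique(map$chrom)) {
    cm <- map$cm[map$chrom == k]
    bp <- map$bp[map$chrom == k]
    if (is.unsorted(bp) || is.unsorted(cm))
      stop(sprintf("map positions on chromosome %s are not monotone", k),
           call. = FALSE)
  }
  if (!inherits(map, "genetic_map"))
    class(map) <- c("genetic_map", class(map))
  map
}

#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers whose minor allele frequency (computed over the
#' homozygous `A`/`B` calls only) is strictly greater than `maf_min` and
#' whose missing-call (`N`) rate is strictly below `missing_max`. Marker
#' order is preserved and the counts removed at each stage are reported.
#' The defaults follow the standard map-construction filters for a
#' biparental RIL panel: MAF > 30%, missing rate < 5%.
#'
#' @param genotypes A `ril_genotypes`.
#' @param maf_min Minimum (exclusive) minor allele frequency.
#' @param missing_max Maximum (exclusive) missing-data rate.
#' @return A filtered `ril_genotypes` (the `truth` attribute, when
#'   present, is subset alongside).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_genes = 10, n_markers = 30, n_lines = 40)
#' rils <- simulate_ril_population(simulate_marker_map(cfg), cfg)
#' filter_markers(rils)
#' @export
filter_markers <- function(genotypes, maf_min = 0.30, missing_max = 0.05) {
  stopifnot(inherits(genotypes, "ril_genotypes"))
  calls <- genotypes$calls
  n_lines <- nrow(calls)
  nA <- colSums(calls == "A")
  nB <- colSums(calls == "B")
  nN <- colSums(calls == "N")
  maf <- pmin(nA, nB) / (nA + nB)
  miss <- nN / n_lines
  keep_maf <- is.finite(maf) & maf > maf_min
  keep_miss <- miss < missing_max
  keep <- keep_maf & keep_miss
  if (!any(keep))
    stop(sprintf(paste0("no markers survive filtering (MAF > %.2f, ",
                        "missing < %.2f)"), maf_min, missing_max),
         call. = FALSE)
  message(sprintf(
    "filter_markers: dropped %d/%d markers (%d on MAF, %d on missingness)",
    sum(!keep), length(keep), sum(!keep_maf), sum(!keep_miss)))
  out <- ril_genotypes(calls[, keep, drop = FALSE],
                       genotypes$markers[keep, , drop = FALSE])
  truth <- attr(genotypes, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth[, keep, drop = FALSE]
  out
}

#' Estimate a genetic map from RIL genotypes
#'
#' Marker order is taken from the physical positions. For each adjacent
#' marker pair the RIL recombinant fraction `Rhat` is the proportion of
#' recombinant lines among informative lines (homozygous `A`/`B` calls at
#' both markers; `H` and `N` are uninformative). `Rhat` is de-expanded to
#' a single-meiosis fraction Rhat / (2 - 2 Rhat) (capped at 0.49)
#' and converted to a Haldane map distance -50 log(1 - 2r) cM;
#' cumulative positions start at 0 on each chromosome.
#'
#' @param genotypes A `ril_genotypes` with at least two markers per
#'   chromosome.
#' @return A `genetic_map` data.frame: `marker_id`, `chrom`, `bp`, `cm`.
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_genes = 10, n_markers = 40, n_lines = 97)
#' rils <- simulate_ril_population(simulate_marker_map(cfg), cfg)
#' est <- estimate_map(rils)
#' tapply(est$cm, est$chrom, max)
#' @export
estimate_map <- function(genotypes) {
  stopifnot(inherits(genotypes, "ril_genotypes"))
  mk <- genotypes$markers
  calls <- genotypes$calls
  out <- lapply(unique(mk$chrom), function(k) {
    idx <- which(mk$chrom == k)
    idx <- idx[order(mk$bp[idx])]
    if (length(idx) < 2)
      stop(sprintf("chromosome %s has fewer than 2 markers", k),
           call. = FALSE)
    m <- length(idx)
    d <- numeric(m - 1)
    for (j in seq_len(m - 1)) {
      a <- calls[, idx[j]]
      b <- calls[, idx[j + 1]]
      inf <- a %in% c("A", "B") & b %in% c("A", "B")
      n_inf <- sum(inf)
      if (n_inf == 0) {
        warning(sprintf("no informative lines between %s and %s; 0 cM used",
                        mk$marker_id[idx[j]], mk$marker_id[idx[j + 1]]))
        next
      }
      Rhat <- sum(a[inf] != b[inf]) / n_inf
      if (Rhat >= 0.5) {
        warning(sprintf("Rhat >= 0.5 between %s and %s; spacing capped",
                        mk$marker_id[idx[j]], mk$marker_id[idx[j + 1]]))
        r <- 0.49
      } else {
        r <- min(ril_R_inv(Rhat), 0.49)
      }
      d[j] <- haldane_d(r)
    }
    data.frame(marker_id = mk$marker_id[idx], chrom = k, bp = mk$bp[idx],
               cm = cumsum(c(0, d)), stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Interpolate gene genetic positions from a map
#'
#' Linear interpolation of cM against bp between flanking markers on the
#' gene's chromosome, clamped to the terminal markers.
#'
#' @param panel A `gene_panel` (uses `chrom` and `start`).
#' @param map A `genetic_map`.
#' @return Numeric vector of cM positions (NA for genes on chromosomes
#'   absent from the map, with a warning).
#' @export
gene_cm_positions <- function(panel, map) {
  map <- validate_genetic_map(map)
  cm <- rep(NA_real_, nrow(panel))
  for (k in unique(panel$chrom)) {
    gi <- which(panel$chrom == k)
    mk <- map[map$chrom == k, , drop = FALSE]
    if (nrow(mk) == 0) {
      warning(sprintf("no markers on chromosome %s; gene positions NA", k))
      next
    }
    if (nrow(mk) == 1) {
      cm[gi] <- mk$cm
    } else {
      cm[gi] <- stats::approx(mk$bp, mk$cm, xout = panel$start[gi],
                              rule = 2, ties = "ordered")$y
    }
  }
  cm
}
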