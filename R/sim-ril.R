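#' Recombination helpers (Haldane map function, selfed-RIL expansion)
#'
#' `haldane_r()` converts a map distance in cM to a single-meiosis
#' recombination fraction, 0.5 * (1 - exp(-2 d / 100)) (no
#' interference). In a population of recombinant inbred lines produced by
#' repeated selfing, the observed proportion of recombinant lines between
#' two loci expands to R = 2r / (1 + 2r); `ril_R()` applies that
#' expansion and `ril_R_inv()` inverts it.
#'
#' @param d Map distance in cM.
#' @param r Single-meiosis recombination fraction.
#' @param R Observed RIL recombinant fraction.
#' @return A numeric vector.
#' @name map-functions
NULL

#' @rdname map-functions
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d / 100))

#' @rdname map-functions
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * r)

#' @rdname map-functions
#' @export
ril_R <- function(r) 2 * r / (1 + 2 * r)

#' @rdname map-functions
#' @export
ril_R_inv <- function(R) R / (2 - 2 * R)

#' Construct a RIL genotype object
#'
#' @param calls Character matrix of genotype calls, lines x markers, with
#'   codes `A` (parent 1), `B` (parent 2), `H` (heterozygous), `N`
#'   (missing). Row names are line ids, column names marker ids.
#' @param markers data.frame with columns `marker_id`, `chrom`, `bp`
#'   matching the columns of `calls`.
#' @return An object of class `ril_genotypes`.
#' @export
ril_genotypes <- function(calls, markers) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix (lines x markers)",
         call. = FALSE)
  bad <- !(calls %in% c("A", "B", "H", "N"))
  if (any(bad))
    stop(sprintf("invalid genotype code(s): %s",
                 paste(unique(calls[bad]), collapse = ", ")), call. = FALSE)
  need <- c("marker_id", "chrom", "bp")
  if (!all(need %in% names(markers)))
    stop("'markers' must have columns marker_id, chrom, bp", call. = FALSE)
  if (nrow(markers) != ncol(calls))
    stop("markers table and call matrix disagree on marker count",
         call. = FALSE)
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker ids", call. = FALSE)
  colnames(calls) <- markers$marker_id
  obj <- list(calls = calls, markers = as.data.frame(markers),
              line_ids = rownames(calls))
  class(obj) <- "ril_genotypes"
  obj
}

#' @export
print.ril_genotypes <- function(x, ...) {
  cat(sprintf("RIL genotypes: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$markers$chrom))))
  tab <- table(factor(x$calls, levels = c("A", "B", "H", "N")))
  cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Simulate a recombinant inbred line population
#'
#' Each line's genome is a mosaic of the two parental haplotypes: along
#' each chromosome the parental origin follows a two-state Markov chain
#' whose switch probability between adjacent markers is the selfed-RIL
#' expansion `R = 2r/(1+2r)` of the Haldane recombination fraction for the
#' map distance. The first marker of each chromosome is parent 1 with
#' probability 0.5. Residual heterozygous (`H`) and missing (`N`) calls
#' are injected at the configured rates; the uncorrupted parental-origin
#' matrix is kept in `attr(, "truth")`.
#'
#' @param map A `genetic_map` (marker_id, chrom, bp, cm) with monotone cM
#'   positions within each chromosome.
#' @param config A [sim_config()].
#' @return A `ril_genotypes` object with attribute `truth` (character
#'   matrix of `A`/`B`).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_genes = 10, n_markers = 20, n_lines = 30)
#' rils <- simulate_ril_population(simulate_marker_map(cfg), cfg)
#' rils
#' @export
simulate_ril_population <- function(map, config) {
  validate_sim_config(config)
  map <- validate_genetic_map(map)
  n <- config$n_lines
  line_ids <- sprintf("RIL%03d", seq_len(n))

  chroms <- unique(map$chrom)
  blocks <- lapply(chroms, function(k) {
    mk <- map[map$chrom == k, , drop = FALSE]
    m <- nrow(mk)
    state <- matrix(FALSE, n, m)  # TRUE = parent 1 allele
    state[, 1] <- stats::runif(n) < 0.5
    if (m > 1) {
      R <- ril_R(haldane_r(diff(mk$cm)))
      for (j in 2:m) {
        switch <- stats::runif(n) < R[j - 1]
        state[, j] <- xor(state[, j - 1], switch)
      }
    }
    state
  })
  truth_state <- do.call(cbind, blocks)
  truth <- ifelse(truth_state, "A", "B")
  dimnames(truth) <- list(line_ids, map$marker_id)

  calls <- truth
  het <- matrix(stats::runif(length(calls)) < config$residual_het,
                nrow(calls))
  calls[het] <- "H"
  mis <- matrix(stats::runif(length(calls)) < config$missing_rate,
                nrow(calls))
  calls[mis] <- "N"

  geno <- ril_genotypes(calls, map[, c("marker_id", "chrom", "bp")])
  attr(geno, "truth") <- truth
  geno
}
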