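# Small shared fixtures, built in code.

small_config <- function(...) {
  sim_config(n_genes = 30, n_markers = 20, n_lines = 30, seed = 99, ...)
}

# A fully informative single-position genotype probability object.
informative_probs <- function(group) {
  structure(list(grid = data.frame(chrom = 1, cm = 0, is_marker = TRUE),
                 prob = matrix(as.numeric(group == 1), ncol = 1)),
            class = "geno_prob")
}

# Run the default eQTL pipeline on a simulated dataset; returns records.
run_scan <- function(sim, expr = sim$expression$vs_parent1, n_perm = 200,
                     alpha = 0.05) {
  gt <- suppressMessages(filter_markers(sim$genotypes))
  map <- estimate_map(gt)
  probs <- genotype_probabilities(gt, map)
  thr <- permutation_threshold(probs, n_perm, alpha)
  gf <- suppressMessages(filter_genes(expr))
  map_eqtl(gf, gt, map, sim$panel, probs = probs, threshold = thr)
}

# Brute-force enumeration of P(parent-1) at the midpoint of a two-marker
# chain: sum over the two hidden states at the query point.
enumerate_two_marker <- function(call1, call2, d1, d2, eps = 0) {
  emis <- function(cc, state) {
    if (cc == "A") return(if (state == 1) 1 - eps else eps)
    if (cc == "B") return(if (state == 1) eps else 1 - eps)
    1
  }
  Rt <- function(d) ril_R(haldane_r(d))
  R1 <- Rt(d1); R2 <- Rt(d2)
  joint <- 0; total <- 0
  for (s1 in 1:2) for (sq in 1:2) for (s2 in 1:2) {
    p <- 0.5 * emis(call1, s1) *
      (if (s1 == sq) 1 - R1 else R1) *
      (if (sq == s2) 1 - R2 else R2) * emis(call2, s2)
    total <- total + p
    if (sq == 1) joint <- joint + p
  }
  joint / total
}

# Triple-loop TOM oracle.
tom_oracle <- function(expr, beta) {
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  n <- nrow(a)
  t <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { t[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    t[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t
}
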