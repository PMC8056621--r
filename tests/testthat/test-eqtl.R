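test_that("gene filtering applies both stages in order", {
  set.seed(1)
  n <- 50
  m <- matrix(rexp(100 * n) + 2, 100,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  m[1, ] <- 0                                   # never expressed
  m[2, ] <- 3                                   # constant: ranked last
  cfg <- gene_filter_config(min_lines = 10, variability_keep = 0.75)
  f <- suppressMessages(filter_genes(m, cfg))
  expect_false("g001" %in% rownames(f))
  expect_false("g002" %in% rownames(f))
  # 99 genes pass stage 1; floor(99 * 0.75) = 74 kept
  expect_equal(nrow(f), 74)
  expect_error(suppressMessages(
    filter_genes(matrix(0, 2, 50), cfg)), "no genes pass")
})

test_that("genotype probabilities honour observed and missing calls", {
  cfg <- sim_config(n_genes = 5, n_markers = 10, n_lines = 12,
                    n_chromosomes = 2, residual_het = 0,
                    missing_rate = 0, seed = 5)
  map <- simulate_marker_map(cfg)
  set.seed(5)
  g <- simulate_ril_population(map, cfg)
  pr <- genotype_probabilities(g, map, step_cm = 2, error_prob = 0)
  # at an observed marker with zero error the posterior is degenerate
  mk_idx <- which(pr$grid$is_marker)
  for (j in seq_len(ncol(g$calls))) {
    gi <- mk_idx[which(abs(pr$grid$cm[mk_idx] -
                             map$cm[map$marker_id ==
                                      colnames(g$calls)[j]]) < 1e-6 &
                         pr$grid$chrom[mk_idx] == g$markers$chrom[j])][1]
    obs <- g$calls[, j]
    expect_true(all(abs(pr$prob[obs == "A", gi] - 1) < 1e-9))
    expect_true(all(abs(pr$prob[obs == "B", gi]) < 1e-9))
  }
  # a line with all calls missing is uniform everywhere
  calls <- g$calls
  calls[3, ] <- "N"
  g2 <- ril_genotypes(calls, g$markers)
  pr2 <- genotype_probabilities(g2, map, step_cm = 2)
  expect_true(all(abs(pr2$prob[3, ] - 0.5) < 1e-9))
})

test_that("interval probabilities match brute-force enumeration", {
  # A and B calls flanking a d = 20 cM interval, query at the midpoint
  for (combo in list(c("A", "B"), c("A", "A"), c("B", "A"),
                     c("A", "N"))) {
    map <- data.frame(marker_id = c("m1", "m2"), chrom = 1,
                      bp = c(0, 20e6), cm = c(0, 20))
    class(map) <- c("genetic_map", "data.frame")
    calls <- matrix(combo, 1, dimnames = list("L1", c("m1", "m2")))
    g <- ril_genotypes(calls, map[, 1:3])
    pr <- genotype_probabilities(g, map, step_cm = 10, error_prob = 0)
    mid <- which(abs(pr$grid$cm - 10) < 1e-9)
    expect_equal(unname(pr$prob[1, mid]),
                 enumerate_two_marker(combo[1], combo[2], 10, 10),
                 tolerance = 1e-12,
                 label = paste(combo, collapse = "/"))
  }
})

test_that("the rank scan reduces exactly to Kruskal-Wallis", {
  # worked example: n = 20, groups 10/10, perfectly separated ranks
  pr <- informative_probs(rep(c(1, 2), each = 10))
  sc <- scan_np(c(11:20, 1:10), pr)
  H <- sc$lod * 2 * log(10)
  expect_equal(H, 14.2857, tolerance = 1e-4)
  expect_equal(sc$lod, 3.102, tolerance = 1e-3)

  # constant phenotype: zero LOD
  expect_true(all(scan_np(rep(1, 20), pr)$lod == 0))

  # joint relabelling invariance
  set.seed(8)
  cfg <- sim_config(n_genes = 5, n_markers = 12, n_lines = 20,
                    n_chromosomes = 2, seed = 8)
  map <- simulate_marker_map(cfg)
  g <- simulate_ril_population(map, cfg)
  pr2 <- genotype_probabilities(g, map, step_cm = 5)
  ph <- rnorm(20)
  perm <- sample(20)
  pr2p <- pr2
  pr2p$prob <- pr2$prob[perm, , drop = FALSE]
  expect_equal(scan_np(ph, pr2)$lod, scan_np(ph[perm], pr2p)$lod,
               tolerance = 1e-12)
})

test_that("scan equals two-sample Kruskal-Wallis on 200 random instances",
{
  set.seed(9)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    n1 <- sample(3:(n - 3), 1)
    grp <- sample(rep(c(1, 2), c(n1, n - n1)))
    ph <- if (i %% 3 == 0) sample(round(rnorm(n), 1)) else rnorm(n)
    ours <- scan_np(ph, informative_probs(grp))$lod * 2 * log(10)
    kw <- suppressWarnings(kruskal.test(ph, grp)$statistic)
    expect_equal(ours, unname(kw), tolerance = 1e-10)
  }
})

test_that("permutation thresholds are calibrated and stable", {
  cfg <- sim_config(n_genes = 5, n_markers = 60, n_lines = 50, seed = 12)
  map <- simulate_marker_map(cfg)
  set.seed(12)
  g <- simulate_ril_population(map, cfg)
  pr <- genotype_probabilities(g, map, step_cm = 2)
  expect_error(permutation_threshold(pr, 100, alpha = 0), "alpha")
  expect_error(permutation_threshold(pr, 100, alpha = 1.2), "alpha")
  expect_error(permutation_threshold(pr, 10), "n_perm")
  expect_warning(t1 <- permutation_threshold(pr, 50, alpha = 1),
                 "degenerate")
  expect_equal(as.numeric(t1), min(attr(t1, "max_lods")))

  # null calibration: fraction of null phenotypes over the threshold
  set.seed(13)
  thr <- permutation_threshold(pr, 200, 0.05)
  U <- vapply(1:500, function(i) rank(rnorm(50)) - 25.5, numeric(50))
  maxlod <- apply(eqtlbias:::scan_core(U, pr), 2, max)
  expect_lt(abs(mean(maxlod > thr) - 0.05), 0.02)

  # Monte-Carlo stability of the threshold across seeds
  set.seed(14); ta <- permutation_threshold(pr, 1000, 0.05)
  set.seed(15); tb <- permutation_threshold(pr, 1000, 0.05)
  expect_lt(abs(ta - tb), 0.15)
})

test_that("peak calling classifies cis and trans correctly", {
  grid <- data.frame(chrom = rep(1:2, each = 51),
                     cm = rep(seq(0, 100, by = 2), 2))
  lod <- rep(0.2, 102)
  # nothing significant: empty record list
  sc <- data.frame(chrom = grid$chrom, cm = grid$cm, lod = lod)
  expect_equal(nrow(call_eqtl(sc, list(chrom = 1, cm = 50), 3)), 0)

  # single peak 2 cM from the gene with a 10 cM window: one cis record
  lod1 <- lod; lod1[grid$chrom == 1] <-
    5 * exp(-0.005 * (grid$cm[grid$chrom == 1] - 48)^2)
  sc1 <- data.frame(chrom = grid$chrom, cm = grid$cm, lod = lod1)
  pk <- call_eqtl(sc1, list(chrom = 1, cm = 50), 3, cis_window_cm = 10)
  expect_equal(nrow(pk), 1)
  expect_true(pk$cis && pk$cis_only)
  expect_equal(pk$peak_cm, 48)

  # same peak but the gene on the other chromosome: trans
  pk2 <- call_eqtl(sc1, list(chrom = 2, cm = 50), 3)
  expect_false(pk2$cis)
  expect_false(pk2$cis_only)

  # missing gene position: skipped with a warning
  expect_warning(out <- call_eqtl(sc1, list(chrom = 1, cm = NA), 3),
                 "skipped")
  expect_null(out)
})

test_that("allele effects report direction, magnitude and group means", {
  ph <- c(rep(10, 5), rep(6, 5))
  pp <- c(rep(1, 5), rep(0, 5))
  e <- estimate_effect(ph, pp)
  expect_equal(e$magnitude, 2)
  expect_equal(e$direction, "parent1")
  expect_equal(e$mean_parent1, 10)
  # tie: direction undefined
  et <- estimate_effect(rep(5, 10), pp)
  expect_true(is.na(et$direction))
  expect_equal(et$magnitude, 0)
  # empty group: degenerate flag
  ed <- estimate_effect(ph, rep(1, 10))
  expect_true(ed$degenerate)
  expect_true(is.na(ed$magnitude))
})

test_that("cis-only calls and effect sizes recover the simulated truth", {
  cfg <- sim_config(n_genes = 300, n_markers = 200, n_lines = 97,
                    delta = 0, cis_fraction = 0.2, cis_effect_sd = 3,
                    seed = 17)
  sim <- simulate_dataset(cfg)
  rec <- run_scan(sim)
  co <- cis_only_records(rec)
  tt <- sim$expression$truth_table
  m <- merge(co, tt, by = "gene_id")
  expect_gt(nrow(m), 20)
  # >= 90% of recovered cis-only genes are true cis genes
  expect_gte(mean(m$cis_true), 0.9)
  # magnitudes track |a_true| with small average relative bias
  strong <- m$cis_true & abs(m$a_true) > 1.5
  expect_gt(sum(strong), 5)
  rel_bias <- mean(m$magnitude[strong] / abs(m$a_true[strong])) - 1
  expect_lt(abs(rel_bias), 0.10)
  # direction sign equals the sign of the group-mean difference
  expect_true(all((m$direction == "parent1") ==
                    (m$mean_parent1 > m$mean_parent2)))
})

test_that("mapping bias shifts detected directions toward the template", {
  p1 <- sapply(c(31, 32, 33), function(s) {
    sim0 <- simulate_dataset(sim_config(n_genes = 400, n_markers = 150,
                                        delta = 0, seed = s))
    simb <- simulate_dataset(sim_config(n_genes = 400, n_markers = 150,
                                        delta = 0.05, seed = s))
    c(bias_proportion(run_scan(sim0))$proportion_parent1,
      bias_proportion(run_scan(simb))$proportion_parent1)
  })
  expect_gt(mean(p1[2, ] - p1[1, ]), 0)
  expect_true(all(p1[2, ] > 0.5))
})
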