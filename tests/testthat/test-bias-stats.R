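test_that("direction counts reproduce the published proportions", {
  # 6341 / 2965 template-positive split: 68.1% (printed precision)
  b <- bias_proportion(direction_records(6341, 2965))
  expect_equal(b$n_total, 9306)
  expect_equal(round(100 * b$proportion_parent1, 1), 68.1)
  expect_lt(b$p_value, 1e-10)

  # symmetric counts: 50%, p = 1
  b2 <- bias_proportion(direction_records(7, 7))
  expect_equal(b2$proportion_parent1, 0.5)
  expect_equal(b2$p_value, 1)

  # (0, 10): exact binomial 2 * 0.5^10
  b3 <- bias_proportion(direction_records(0, 10))
  expect_equal(b3$proportion_parent1, 0)
  expect_equal(b3$p_value, 2 * 0.5^10)

  expect_error(bias_proportion(direction_records(0, 0)), "no cis-only")
})

test_that("label swap maps the proportion to its complement", {
  set.seed(2)
  for (i in 1:20) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    a <- bias_proportion(direction_records(n1, n2))
    b <- bias_proportion(direction_records(n2, n1))
    expect_equal(a$proportion_parent1, 1 - b$proportion_parent1)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("reference discordance reproduces the published fractions", {
  # 3525 of 6341 template-positive genes absent under the other
  # template; 2204 of 5169 reciprocally
  r1 <- direction_records(6341, 2965, prefix = "b")
  r1$gene_id[r1$direction == "parent2"] <-
    sprintf("m%06d", seq_len(2965))
  r2 <- rbind(
    direction_records(2816, 0, prefix = "b"),   # shared subset
    {
      x <- direction_records(0, 2965 + 2204, prefix = "m")
      x$gene_id <- c(sprintf("m%06d", seq_len(2965)),
                     sprintf("n%06d", seq_len(2204)))
      x
    })
  class(r2) <- c("eqtl_records", "data.frame")
  d <- compare_references(r1, r2)
  expect_equal(d$discordance$ref1_parent1$absent, 3525)
  expect_equal(round(100 * d$discordance$ref1_parent1$frac), 56)
  expect_equal(d$discordance$ref2_parent2$n, 5169)
  expect_equal(d$discordance$ref2_parent2$absent, 2204)
  expect_equal(round(100 * d$discordance$ref2_parent2$frac), 43)

  # identical lists: zero discordance; disjoint lists: full discordance
  same <- compare_references(r1, r1)
  expect_equal(same$discordance$ref1_parent1$frac, 0)
  expect_equal(same$frac_single_reference, 0)
  dis <- compare_references(direction_records(5, 5, "x"),
                            direction_records(5, 5, "y"))
  expect_equal(dis$discordance$ref1_parent1$frac, 1)
  expect_equal(dis$frac_single_reference, 1)
  expect_error(compare_references(r1, r1[0, ]), "cis-only")
})

test_that("window profiles aggregate exactly to the global proportion", {
  set.seed(3)
  panel <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      chrom = sample(1:2, 200, TRUE),
                      start = sample(0:19999999, 200),
                      snp_count = rpois(200, 2))
  rec <- data.frame(gene_id = panel$gene_id,
                    direction = sample(c("parent1", "parent2"), 200, TRUE,
                                       prob = c(0.7, 0.3)),
                    cis = TRUE, cis_only = TRUE)
  class(rec) <- c("eqtl_records", "data.frame")
  wp <- window_bias_profile(rec, panel, window_bp = 2e6)
  w <- wp$windows[wp$windows$n_genes > 0, ]
  agg <- sum(w$prop_parent1 * w$n_genes) / sum(w$n_genes)
  expect_equal(agg, mean(rec$direction == "parent1"), tolerance = 1e-12)
  # 4:1 window proportion arithmetic
  expect_equal(4 / (4 + 1), 0.8)
  # empty-window flagging and validation
  expect_true(any(wp$windows$n_genes == 0) ||
                all(is.finite(wp$windows$prop_parent1)))
  expect_true(all(is.na(wp$windows$prop_parent1[wp$windows$n_genes == 0])))
  expect_error(window_bias_profile(rec, panel, window_bp = 0), "window_bp")
  expect_warning(window_bias_profile(rec[0, ], panel), "empty profile")
})

test_that("divergence regression recovers an exact linear relation", {
  # medians on a perfect slope-0.05 line: recovered exactly, R^2 = 1
  set.seed(4)
  panel <- data.frame(gene_id = sprintf("g%03d", 1:150),
                      snps_per_kb_exon = rep(0:4, each = 30))
  rec <- data.frame(gene_id = panel$gene_id,
                    magnitude = rep(0.5 * (1 + 0.05 * (0:4)), each = 30),
                    cis = TRUE, cis_only = TRUE, direction = "parent1")
  class(rec) <- c("eqtl_records", "data.frame")
  f <- suppressWarnings(divergence_effect_regression(rec, panel))
  expect_equal(f$slope, 0.05, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(nrow(f$bins), 5)

  # all genes in one bin: fit refused
  panel1 <- panel; panel1$snps_per_kb_exon <- 1.2
  expect_error(divergence_effect_regression(rec, panel1), "refused")
})

test_that("criteria comparison reproduces the published yes-fraction", {
  # 4801 of 5951 shared template-positive eQTL larger under default
  mk <- function(mags) {
    r <- direction_records(5951, 0)
    r$magnitude <- mags
    r
  }
  set.seed(5)
  base <- runif(5951, 1, 5)
  shift <- c(rep(0.5, 4801), rep(-0.5, 1150))
  cc <- compare_criteria(mk(base + shift), mk(base))
  expect_equal(cc$n_shared, 5951)
  expect_equal(cc$n_a_greater, 4801)
  expect_equal(round(100 * cc$frac_a_greater, 1), 80.7)
  expect_lt(cc$binom_p, 1e-15)

  # identical magnitudes: fraction 0, ties reported
  ct <- compare_criteria(mk(base), mk(base))
  expect_equal(ct$frac_a_greater, 0)
  expect_equal(ct$n_ties, 5951)

  # exact 50:50: binomial p = 1
  half <- c(rep(0.5, 2975), rep(-0.5, 2976))
  ch <- compare_criteria(mk(base + half), mk(base))
  expect_gt(ch$binom_p, 0.95)
  expect_error(compare_criteria(mk(base),
                                direction_records(5, 5, "zz")), "shared")
})
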