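test_that("TOM formula matches limits and the brute-force oracle", {
  # two perfectly correlated genes alone: a = 1, t = 1
  x <- rbind(g1 = 1:10, g2 = (1:10) * 2 + 3)
  tom <- adjacency_tom(x + 0, beta = 5)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)

  # triple-loop oracle on 20-gene instances, exact
  set.seed(6)
  for (i in 1:3) {
    m <- matrix(rnorm(20 * 30), 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
    m[1:5, ] <- m[1:5, ] + rep(rnorm(30, sd = 2), each = 5)
    tom <- adjacency_tom(m, beta = 5)
    expect_lt(max(abs(tom - tom_oracle(m, 5))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }

  # independent noise at 97 lines: mean off-diagonal adjacency < 0.01
  set.seed(7)
  nz <- matrix(rnorm(50 * 97), 50,
               dimnames = list(sprintf("n%02d", 1:50), NULL))
  a <- abs(cor(t(nz)))^5; diag(a) <- 0
  expect_lt(mean(a), 0.01)

  # constant genes rejected by id
  bad <- rbind(gA = rnorm(10), gB = rep(1, 10))
  expect_error(adjacency_tom(bad, 5), "gB")
})

planted_blocks <- function(n_per = 80, n_lines = 97, r = 0.9) {
  drv <- rbind(rnorm(n_lines), rnorm(n_lines))
  expr <- rbind(
    t(sapply(seq_len(n_per), function(i)
      sqrt(r) * drv[1, ] + sqrt(1 - r) * rnorm(n_lines))),
    t(sapply(seq_len(n_per), function(i)
      sqrt(r) * drv[2, ] + sqrt(1 - r) * rnorm(n_lines))))
  rownames(expr) <- sprintf("g%03d", seq_len(2 * n_per))
  expr
}

rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2)); tot <- choose(n, 2)
  (tot + 2 * sij - si - sj) / tot
}

test_that("module detection recovers planted blocks", {
  set.seed(8)
  expr <- planted_blocks()
  tom <- adjacency_tom(expr, 5)
  mods <- detect_modules(tom, coexpression_config())
  truth <- rep(1:2, each = 80)
  expect_equal(length(unique(mods[mods > 0])), 2)
  expect_gt(rand_index(mods, truth), 0.95)

  # a 30-gene block (below min size) is absorbed or unassigned
  set.seed(9)
  small <- planted_blocks(n_per = 30)[1:30, ]
  big <- planted_blocks(n_per = 80)[1:80, ]
  rownames(small) <- sprintf("s%02d", 1:30)
  expr2 <- rbind(big, small)
  mods2 <- detect_modules(adjacency_tom(expr2, 5), coexpression_config())
  expect_lte(length(unique(mods2[mods2 > 0])), 2)
  expect_true(all(table(mods2[mods2 > 0]) >= 60) ||
                length(unique(mods2[mods2 > 0])) == 1)

  # merging is order-independent for the planted case
  set.seed(10)
  expr3 <- planted_blocks()
  perm <- sample(nrow(expr3))
  m_a <- detect_modules(adjacency_tom(expr3, 5), coexpression_config())
  m_b <- detect_modules(adjacency_tom(expr3[perm, ], 5),
                        coexpression_config())
  expect_gt(rand_index(m_a[perm], m_b), 0.999)
})

test_that("module labels are invariant to uniform expression scaling", {
  set.seed(11)
  expr <- planted_blocks(n_per = 70)
  m1 <- detect_modules(adjacency_tom(expr, 5), coexpression_config())
  m2 <- detect_modules(adjacency_tom(expr * 1000, 5),
                       coexpression_config())
  expect_identical(m1, m2)
})

test_that("haplotype consistency separates biased from unbiased regions", {
  set.seed(12)
  ok <- c(biased = 0, unbiased = 0)
  for (rep in 1:3) for (sc in c("biased", "unbiased")) {
    d <- simulate_region_scenario(sc, n_region = 80, n_background = 80)
    tom <- adjacency_tom(d$expr, 5)
    mods <- detect_modules(tom, coexpression_config())
    rep_out <- haplotype_direction(mods, d$expr, d$genotypes, d$panel)
    m <- rep_out$modules
    hit <- FALSE
    for (i in seq_len(nrow(m))) {
      memb <- rep_out$genes$gene_id[rep_out$genes$module == m$module[i]]
      capture <- mean(d$region_genes %in% memb)
      if (!is.na(m$consistency[i]) && m$consistency[i] >= 0.9 &&
          capture >= 0.9) hit <- TRUE
    }
    ok[sc] <- ok[sc] + (if (sc == "biased") hit else !hit)
  }
  expect_equal(unname(ok["biased"]), 3)
  expect_equal(unname(ok["unbiased"]), 3)
})

test_that("a uniformly positive module scores consistency 1", {
  set.seed(13)
  d <- simulate_region_scenario("biased", n_region = 40,
                                n_background = 0, rho = 0.3)
  mods <- stats::setNames(rep(1L, 40), rownames(d$expr))
  rep_out <- haplotype_direction(mods, d$expr, d$genotypes, d$panel)
  expect_equal(rep_out$modules$consistency, 1)
  expect_equal(rep_out$modules$direction, "parent1")
  expect_true(rep_out$modules$bias_suspect)
})
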