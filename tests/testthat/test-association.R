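test_that("module-trait correlation: exact cases and the r=0.91/n=8 anchor", {
  set.seed(1)
  tr <- cbind(a = c(1, 1, 0, 0, 0, 0, 0, 0))
  E <- cbind(m1 = scale(tr[, "a"])[, 1],             # equals the indicator
             m2 = c(1, -1, 1, -1, 1, -1, 1, -1) * sqrt(1 / 8))
  rownames(E) <- rownames(tr) <- paste0("s", 1:8)
  got <- module_trait_correlation(E, tr)
  expect_equal(got$r[got$module == "m1"], 1)
  expect_equal(got$p[got$module == "m1"], 0)
  expect_equal(got$r[got$module == "m2"], 0, tolerance = 1e-12)
  expect_equal(got$p[got$module == "m2"], 1, tolerance = 1e-12)

  # t transform at the printed operating point: r = 0.91, n = 8 -> p < 0.002
  p91 <- correlation_p_value(0.91, 8)
  expect_equal(p91, 2 * pt(0.91 * sqrt(6 / (1 - 0.91^2)), df = 6,
                           lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p91, 0.0017017, tolerance = 1e-4)
  expect_lte(p91, 0.002)

  # constant trait skipped with warning
  trc <- cbind(tr, const = rep(1, 8))
  expect_warning(got2 <- module_trait_correlation(E, trc), "constant")
  expect_false("const" %in% got2$trait)
})

test_that("correlation p-values agree with cor.test and a permutation null", {
  set.seed(2)
  x <- rnorm(10); y <- 0.7 * x + rnorm(10)
  r <- cor(x, y)
  expect_equal(correlation_p_value(r, 10), cor.test(x, y)$p.value,
               tolerance = 1e-12)
  # permutation oracle
  perm <- replicate(10000, abs(cor(x, sample(y))))
  p_perm <- (sum(perm >= abs(r)) + 1) / 10001
  expect_lt(abs(p_perm - correlation_p_value(r, 10)),
            3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
})

test_that("module membership ranks hubs first and flags degenerate genes", {
  sim <- small_sim(seed = 31, sizes = c(50, 50),
                   planted_hub_tf = list(module = 1, r = 0.998),
                   trait_links = list())
  E <- compute_eigengenes(sim$expr, sim$truth$module_labels)
  mm <- module_membership(sim$expr, E, sim$truth$module_labels)
  expect_true(all(tapply(mm$rank, mm$module, function(r) all(sort(r) == seq_along(r)))))
  hub_row <- mm[mm$gene == sim$truth$hub_gene, ]
  expect_equal(hub_row$rank, 1L)

  # gene identical to its eigengene scores MM = 1, rank 1
  expr2 <- rbind(sim$expr[1:10, ], star = E[, "1"])
  part2 <- setNames(rep(1L, 11), rownames(expr2))
  E2 <- compute_eigengenes(expr2, part2)
  mm2 <- module_membership(expr2, E2, part2)
  expect_gte(mm2$mm[mm2$gene == "star"], max(mm2$mm[mm2$gene != "star"]))

  # uncorrelated noise lands in the bottom half of a strong module
  set.seed(4)
  expr3 <- rbind(sim$expr[sim$truth$module_labels == 1, ],
                 noise = rnorm(ncol(sim$expr)))
  part3 <- setNames(rep(1L, nrow(expr3)), rownames(expr3))
  mm3 <- module_membership(expr3, compute_eigengenes(expr3, part3), part3)
  expect_gt(mm3$rank[mm3$gene == "noise"], nrow(expr3) / 2)
})

test_that("rank_top_tf finds the best TF and flags TF-free modules", {
  mm <- data.frame(gene = paste0("g", 1:6),
                   module = rep(1:2, each = 3),
                   mm = c(0.9, 0.8, 0.7, 0.9, 0.8, 0.7),
                   rank = rep(1:3, 2))
  top <- rank_top_tf(mm, tf_genes = c("g2", "g3"))
  expect_equal(top$r_obs[top$module == 1], 2L)
  expect_equal(top$tf_gene[top$module == 1], "g2")
  expect_equal(top$m[top$module == 1], 2L)
  expect_true(is.na(top$r_obs[top$module == 2]))
  expect_equal(top$m[top$module == 2], 0L)
})

test_that("TF rank test: closed forms, Monte-Carlo agreement, saturation", {
  # n = 100, m = 10, r = 1: analytic p = 0.1 exactly
  expect_equal(tf_rank_analytic_p(100, 10, 1), 0.1, tolerance = 1e-12)
  # n = 10, m = 1: best rank uniform; P(R* <= 3) = 0.3
  expect_equal(tf_rank_analytic_p(10, 1, 3), 0.3, tolerance = 1e-12)

  res <- tf_rank_permutation_test(100, 10, 1, n_perm = 20000, seed = 5)
  expect_lt(abs(res$p_mc - 0.1), 3 * sqrt(0.1 * 0.9 / 20000) + 1 / 20000)

  # saturation: every entity a TF means best rank is always 1
  res_sat <- tf_rank_permutation_test(5, 5, 1, n_perm = 100, seed = 1)
  expect_equal(res_sat$p_analytic, 1)
  expect_true(all(res_sat$null_ranks == 1))
  expect_error(tf_rank_permutation_test(10, 0, 1), "m = 0")

  # MC vs analytic across a grid, within 3 binomial SE
  set.seed(6)
  grid <- expand.grid(n = c(20, 60), m = c(2, 6), r = c(1, 3, 8))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tf_rank_permutation_test(g$n, g$m, g$r, n_perm = 5000,
                                    seed = 100 + i)
    pa <- res$p_analytic
    expect_lt(abs(res$p_mc - pa),
              3 * sqrt(pa * (1 - pa) / 5000) + 1 / 5000 + 1e-12)
  }
})

test_that("uniform-null TF placement rejects at the nominal rate", {
  # place TFs uniformly, take the observed best rank, test it; p <= 0.05
  # should occur for about 5% of modules
  # m = 1, n = 100 keeps the null exactly calibrated at 0.05 (p = r/100)
  set.seed(7)
  n <- 100; m <- 1
  n_mod <- 1000
  p <- vapply(seq_len(n_mod), function(i)
    tf_rank_analytic_p(n, m, min(sample.int(n, m))), numeric(1))
  expect_lt(abs(mean(p <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_mod))
})
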