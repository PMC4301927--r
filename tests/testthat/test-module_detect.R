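test_that("hierarchical clustering matches hand traces and a naive oracle", {
  d0 <- matrix(c(0, 0, 0, 0), 2)
  dend <- hierarchical_cluster(d0)
  expect_equal(dend$height, 0)                       # identical leaves merge at 0

  d <- block_dissim(c(3, 3), within = 0.1, between = 0.9)
  dend2 <- hierarchical_cluster(d)
  expect_equal(max(dend2$height), 0.9)               # last merge joins blocks
  expect_true(all(sort(dend2$height)[1:4] == 0.1))

  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(runif(36), 6); m <- (m + t(m)) / 2; diag(m) <- 0
    got <- sort(hierarchical_cluster(m)$height)
    expect_equal(got, complete_linkage_heights_oracle(m), tolerance = 1e-12)
  }
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dynamic tree cut recovers planted blocks and obeys the size rule", {
  d <- block_dissim(c(50, 50, 50), within = 0.1, between = 0.9)
  part <- dynamic_tree_cut(hierarchical_cluster(d), min_size = 30)
  truth <- rep(1:3, each = 50)
  expect_equal(adjusted_rand_index(part, truth), 1)
  expect_equal(sort(unique(part)), 1:3)

  # all-identical genes: one module covering everything
  dz <- matrix(0, 40, 40)
  expect_true(all(dynamic_tree_cut(hierarchical_cluster(dz), min_size = 30) == 1))

  # fewer genes than min_size: everything unassigned, with a warning
  d20 <- block_dissim(c(10, 10))
  expect_warning(p20 <- dynamic_tree_cut(hierarchical_cluster(d20), min_size = 30),
                 "min_size")
  expect_true(all(p20 == 0))

  # undersized side branches stay unassigned without a global failure
  d_mix <- block_dissim(c(40, 5), within = 0.1, between = 0.9)
  p_mix <- dynamic_tree_cut(hierarchical_cluster(d_mix), min_size = 30)
  expect_equal(unname(p_mix[1:40]), rep(1L, 40))
})

test_that("stability check is invariant for a deterministic cut", {
  d <- block_dissim(c(40, 40), within = 0.1, between = 0.9)
  rep <- stability_check(d, n_repeats = 5, seed = 1, min_size = 30)
  expect_equal(nrow(rep$ari), 10)                    # choose(5, 2)
  expect_true(all(rep$ari$ari == 1))
})

test_that("module detection recovers planted partitions under permutation", {
  sim <- small_sim(seed = 21)
  adj <- compute_adjacency(sim$expr, beta = 4)
  d <- tom_dissimilarity(compute_tom(adj))
  rep <- stability_check(d, n_repeats = 3, seed = 2, min_size = 30)
  for (lab in rep$labels)
    expect_gte(adjusted_rand_index(lab, sim$truth$module_labels), 0.9)
})

test_that("eigengenes: rank-1 exactness, sign convention, recovery", {
  # identical standardized profiles: eigengene proportional, var explained 1
  prof <- c(1, 3, 2, 5, 4, 6, 8, 7)
  expr <- matrix(rep(prof, each = 5), 5, byrow = FALSE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  expr <- expr * (1:5)                               # different scales, same shape
  part <- setNames(rep(1L, 5), rownames(expr))
  E <- compute_eigengenes(expr, part)
  expect_equal(abs(cor(E[, "1"], prof)), 1, tolerance = 1e-12)
  expect_equal(unname(attr(E, "var_explained")["1"]), 1, tolerance = 1e-12)
  expect_equal(sum(E[, "1"]^2), 1, tolerance = 1e-12)
  expect_gte(mean(cor(t(expr), E[, "1"])), 0)

  # noiseless planted module: eigengene recovers the latent signal
  sim0 <- small_sim(seed = 8, sizes = 30, background = 0, noise_sd = 0,
                    trait_links = list())
  E0 <- compute_eigengenes(sim0$expr, sim0$truth$module_labels)
  expect_gte(abs(cor(E0[, "1"], sim0$truth$signals[, 1])), 0.999)

  # sign convention on random instances
  set.seed(9)
  for (rep in 1:5) {
    x <- matrix(rnorm(6 * 10), 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    p <- setNames(rep(1L, 6), rownames(x))
    e <- compute_eigengenes(x, p)
    expect_gte(mean(cor(t(x), e[, "1"])), 0)
  }

  # single-gene module: the gene's own standardized profile
  p1 <- setNames(c(1L, 2L, 2L, 2L, 2L), rownames(expr))
  E1 <- compute_eigengenes(expr, p1)
  expect_equal(abs(cor(E1[, "1"], expr["g1", ])), 1, tolerance = 1e-12)
})

test_that("merging joins same-signal modules, leaves distinct ones, never grows", {
  sim <- small_sim(seed = 13, sizes = c(40, 40), trait_links = list())
  labs <- sim$truth$module_labels
  # artificially split module 1 into two halves: same latent signal
  split_part <- labs
  split_part[names(labs)[labs == 1][1:20]] <- 3L
  merged <- merge_modules(sim$expr, split_part, threshold = 0.65)
  expect_equal(ncol(merged$eigengenes), 2)
  expect_equal(adjusted_rand_index(merged$partition, labs), 1)
  expect_true(merged$converged)

  # independent-signal modules stay apart (eigengene cor well below 0.65)
  E <- compute_eigengenes(sim$expr, labs)
  stopifnot(abs(cor(E)[1, 2]) < 0.65)
  merged2 <- merge_modules(sim$expr, labs, threshold = 0.65)
  expect_equal(ncol(merged2$eigengenes), 2)
  expect_equal(adjusted_rand_index(merged2$partition, labs), 1)
})
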