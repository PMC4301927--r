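# Independent brute-force oracles kept deliberately naive: they check the
# vectorized implementations, never share code with them.

# O(G^3) topological overlap, straight from the definition
tom_oracle <- function(adj) {
  n <- nrow(adj)
  k <- sapply(seq_len(n), function(i) sum(adj[i, -i]))
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  out
}

# naive O(n^3) agglomerative clustering with complete linkage on a
# precomputed distance matrix; returns the sorted merge heights
complete_linkage_heights_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < best_h) { best_h <- h; best <- c(a, b) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# block-structured dissimilarity: low within, high between
block_dissim <- function(sizes, within = 0.1, between = 0.9) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  d <- matrix(between, n, n)
  for (b in seq_along(sizes)) d[lab == b, lab == b] <- within
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  d
}

# hypergeometric enrichment upper tail by explicit summation
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# small planted simulation used across module/association tests
small_sim <- function(seed = 1, sizes = c(50, 50, 50), background = 0,
                      trait_links = list("1" = list(trait = "reduced.leaf",
                                                    r = 0.9)),
                      replicates = 1, ...) {
  spec <- synthetic_spec(
    module_sizes = sizes, n_background_genes = background,
    sample_design = default_sample_design(replicates = replicates),
    trait_links = trait_links, seed = seed, ...)
  generate_expression(spec)
}

# full detection chain: adjacency -> TOM -> complete linkage -> cut -> merge
detect_modules <- function(expr, beta = 4, min_size = 30, threshold = 0.65) {
  adj <- compute_adjacency(expr, beta = beta)
  dend <- hierarchical_cluster(tom_dissimilarity(compute_tom(adj)))
  part <- dynamic_tree_cut(dend, min_size = min_size)
  if (!any(part > 0)) return(list(partition = part, eigengenes = NULL))
  merge_modules(expr, part, threshold = threshold)
}
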