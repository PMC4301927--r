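#' Hierarchical clustering of a dissimilarity matrix
#'
#' Complete-linkage agglomerative clustering (default) of genes. By default
#' the supplied matrix is treated as precomputed distances (the 1 - TOM
#' dissimilarity); `input = "euclidean"` instead computes Euclidean
#' distances between the matrix rows first, preserving the alternative
#' reading of "Euclidean distance on the TOM dissimilarity".
#'
#' @param dissim square symmetric matrix with zero diagonal.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param input `"precomputed"` (default) or `"euclidean"`.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(dissim, linkage = "complete",
                                 input = c("precomputed", "euclidean")) {
  input <- match.arg(input)
  .check_square_symmetric(dissim, "dissimilarity")
  if (any(diag(dissim) != 0)) stop("dissimilarity diagonal must be zero")
  d <- if (input == "precomputed") stats::as.dist(dissim) else stats::dist(dissim)
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into modules (tree-style dynamic cut)
#'
#' A static cut at `cut_height` (default 99% of the tallest merge) defines
#' the major branches; within a branch, a child subtree is detached when it
#' hangs below its parent merge by more than `gap_fraction` of the branch's
#' height range and holds at least `min_size` leaves, and the procedure
#' recurses into the parts. Leaf sets smaller than `min_size` are left
#' unassigned (label 0). Final labels are numbered 1..K by decreasing module
#' size (ties by smallest leaf index), which makes the cut deterministic.
#'
#' @param dend an [stats::hclust] tree.
#' @param min_size minimum module size (default 30, the conventional value
#'   for co-expression modules).
#' @param cut_height static cut height; default `0.99 * max(dend$height)`.
#' @param gap_fraction fraction of the branch height range a child must hang
#'   below its parent merge to be split off (default 0.25).
#' @return Named integer vector of module labels (0 = unassigned), ordered
#'   as the tree's leaves/labels.
#' @export
dynamic_tree_cut <- function(dend, min_size = 30, cut_height = NULL,
                             gap_fraction = 0.25) {
  if (!inherits(dend, "hclust")) stop("dend must be an hclust tree")
  n <- length(dend$order)
  labels <- if (is.null(dend$labels)) as.character(seq_len(n)) else dend$labels
  out <- integer(n)
  names(out) <- labels
  if (min_size > n) {
    warning("min_size exceeds the number of leaves; all genes unassigned")
    return(out)
  }
  if (n == 1) {
    out[] <- if (min_size <= 1) 1L else 0L
    return(out)
  }
  m <- dend$merge
  h <- dend$height
  if (is.null(cut_height)) cut_height <- 0.99 * max(h)

  # bottom-up tables: leaf set, subtree minimum merge height
  leafsets <- vector("list", nrow(m))
  minh <- numeric(nrow(m))
  node_set <- function(x) if (x < 0) -x else leafsets[[x]]
  node_h <- function(x) if (x < 0) 0 else h[x]
  node_minh <- function(x) if (x < 0) Inf else minh[x]
  for (i in seq_len(nrow(m))) {
    leafsets[[i]] <- c(node_set(m[i, 1]), node_set(m[i, 2]))
    minh[i] <- min(h[i], node_minh(m[i, 1]), node_minh(m[i, 2]))
  }

  kept <- list()
  stack <- list(nrow(m))          # root node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v < 0) {                  # singleton branch: below min_size unless 1
      if (min_size <= 1) kept[[length(kept) + 1]] <- -v
      next
    }
    ch <- m[v, ]
    split_here <- if (h[v] > cut_height) {
      TRUE                        # static cut: branches above it are separate
    } else {
      thr <- gap_fraction * (h[v] - minh[v])
      any(vapply(ch, function(c) {
        length(node_set(c)) >= min_size && (h[v] - node_h(c)) > thr
      }, logical(1)))
    }
    if (split_here) {
      stack[[length(stack) + 1]] <- ch[1]
      stack[[length(stack) + 1]] <- ch[2]
    } else {
      s <- leafsets[[v]]
      if (length(s) >= min_size) kept[[length(kept) + 1]] <- s
    }
  }
  for (i in seq_along(kept)) out[kept[[i]]] <- i
  .relabel_by_size(out)
}

#' Stability of module detection under gene-order permutation
#'
#' Reruns clustering + cutting `n_repeats` times with the gene order
#' randomly permuted (one derived seed per repeat), maps labels back to the
#' original order, and reports all pairwise adjusted Rand indices. The
#' pipeline is deterministic given gene order, so values below 1 expose
#' order sensitivity of the cut.
#'
#' @param dissim dissimilarity matrix with gene dimnames.
#' @param n_repeats number of permuted reruns (default 5).
#' @param seed master seed for the permutations.
#' @param linkage,min_size,cut_height,gap_fraction passed through to
#'   [hierarchical_cluster()] and [dynamic_tree_cut()].
#' @return `list(ari = <data.frame of pairwise ARIs>, labels = <list>)`.
#' @export
stability_check <- function(dissim, n_repeats = 5, seed = 1,
                            linkage = "complete", min_size = 30,
                            cut_height = NULL, gap_fraction = 0.25) {
  .check_square_symmetric(dissim, "dissimilarity")
  n <- nrow(dissim)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  labs <- vector("list", n_repeats)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(perm_seeds[r])
    perm <- sample.int(n)
    d <- dissim[perm, perm, drop = FALSE]
    dimnames(d) <- list(ids[perm], ids[perm])
    lab <- dynamic_tree_cut(hierarchical_cluster(d, linkage = linkage),
                            min_size = min_size, cut_height = cut_height,
                            gap_fraction = gap_fraction)
    labs[[r]] <- lab[ids]
  }
  pairs <- utils::combn(n_repeats, 2)
  ari <- data.frame(
    repeat_a = pairs[1, ], repeat_b = pairs[2, ],
    ari = apply(pairs, 2, function(p)
      adjusted_rand_index(labs[[p[1]]], labs[[p[2]]]))
  )
  list(ari = ari, labels = labs)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member genes' standardized profiles: the single per-sample profile that
#' explains the most variance in the module. Expression is standardized per
#' gene (zero mean, unit variance) before the decomposition so bright genes
#' do not dominate. Each eigengene is scaled to unit norm and its sign is
#' fixed so the mean correlation with member genes is non-negative.
#'
#' @param expr genes x samples matrix.
#' @param partition named integer module labels over the genes (0 ignored).
#' @return samples x modules matrix (columns named by module label) with
#'   attribute `var_explained`, the per-module fraction of variance carried
#'   by the eigengene.
#' @export
compute_eigengenes <- function(expr, partition) {
  .check_matrix(expr, "expression matrix")
  if (is.null(names(partition))) stop("partition must be named by gene id")
  if (!all(names(partition) %in% rownames(expr)))
    stop("partition names must match expression rownames")
  mods <- sort(setdiff(unique(partition), 0L))
  if (length(mods) == 0) stop("no modules in partition")
  n_samp <- ncol(expr)
  E <- matrix(NA_real_, n_samp, length(mods),
              dimnames = list(colnames(expr), as.character(mods)))
  ve <- numeric(length(mods))
  for (j in seq_along(mods)) {
    genes <- names(partition)[partition == mods[j]]
    x <- expr[genes, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) stop("zero-variance gene in module ", mods[j])
    xs <- (x - rowMeans(x)) / sds
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(t(x), e)) < 0) e <- -e
    E[, j] <- e / sqrt(sum(e^2))
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  names(ve) <- as.character(mods)
  attr(E, "var_explained") <- ve
  E
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters the eigengenes with average linkage on
#' `1 - cor(E)`, cuts at `1 - threshold`, merges modules that land in the
#' same group, recomputes eigengenes, and repeats until no eigengene pair
#' exceeds the similarity threshold (or `max_iter` passes). The module count
#' never increases; merged labels are renumbered by decreasing size.
#'
#' @param expr genes x samples matrix.
#' @param partition named integer module labels (0 = background).
#' @param threshold eigengene correlation above which modules merge
#'   (default 0.65).
#' @param max_iter safety bound on merge passes (default 10).
#' @return `list(partition, eigengenes, history, converged)`; `history`
#'   records the module count after each pass.
#' @export
merge_modules <- function(expr, partition, threshold = 0.65, max_iter = 10) {
  if (length(setdiff(unique(partition), 0L)) == 0) stop("no modules to merge")
  part <- partition
  history <- integer(0)
  converged <- FALSE
  E <- compute_eigengenes(expr, part)
  for (iter in seq_len(max_iter)) {
    if (ncol(E) == 1) { converged <- TRUE; break }
    C <- stats::cor(E)
    if (max(C[upper.tri(C)]) <= threshold) { converged <- TRUE; break }
    tree <- stats::hclust(stats::as.dist(1 - C), method = "average")
    grp <- stats::cutree(tree, h = 1 - threshold)
    map <- stats::setNames(as.integer(grp), colnames(E))
    new_part <- part
    assigned <- part != 0
    new_part[assigned] <- map[as.character(part[assigned])]
    part <- .relabel_by_size(new_part)
    E <- compute_eigengenes(expr, part)
    history <- c(history, ncol(E))
  }
  if (!converged)
    warning("module merging did not converge in ", max_iter, " passes")
  list(partition = part, eigengenes = E, history = history,
       converged = converged)
}
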