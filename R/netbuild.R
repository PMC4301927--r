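#' Soft-thresholded co-expression adjacency
#'
#' Computes `a_ij = |cor(x_i, x_j)|^beta` (unsigned, the default) or the
#' signed-magnitude variant `((1 + cor) / 2)^beta`. Raising the absolute
#' Pearson correlation to a power `beta` emphasizes strong co-expression and
#' pushes the connectivity distribution toward scale-free. The diagonal is
#' fixed at 1. Zero-variance genes cannot be correlated and are dropped with
#' a warning.
#'
#' @param expr genes x samples matrix; at least 3 samples.
#' @param beta positive soft-thresholding power.
#' @param mode `"unsigned"` (default) or `"signed"` (signed-magnitude).
#' @return Symmetric adjacency matrix in `[0, 1]` with attributes `beta` and
#'   `mode`.
#' @export
compute_adjacency <- function(expr, beta = 4, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  .check_matrix(expr, "expression matrix")
  if (ncol(expr) < 3) stop("need at least 3 samples to correlate")
  if (beta <= 0) stop("beta must be positive")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(rownames(expr)[v == 0], collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("fewer than 2 genes with variance")
  cc <- stats::cor(t(expr))
  adj <- if (mode == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(adj) <- 1
  adj <- pmin(pmax(adj, 0), 1)
  attr(adj, "beta") <- beta
  attr(adj, "mode") <- mode
  adj
}

#' Network connectivity
#'
#' `k_i = sum_{u != i} a_iu`: each gene's summed adjacency to all other
#' genes, excluding the unit diagonal.
#'
#' @param adj adjacency matrix.
#' @return Numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  .check_square_symmetric(adj, "adjacency")
  rowSums(adj) - diag(adj)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-width bins and regresses
#' `log10(frequency)` on `log10(mean k)` over non-empty bins. A scale-free
#' degree distribution is linear on this log-log plot with negative slope,
#' so the returned fit index is `R^2 * sign(-slope)`: positive-slope fits
#' come back negative and never look scale-free.
#'
#' @param k connectivity vector.
#' @param n_bins number of equal-width bins (default 10).
#' @return `list(r_squared, slope, fit_table)`; `r_squared` is `NA` (with
#'   a warning) when the connectivities are all equal.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 2) {
    warning("connectivity is constant; scale-free fit undefined")
    return(list(r_squared = NA_real_, slope = NA_real_, fit_table = NULL))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  x <- log10(mean_k[keep])
  y <- log10(freq[keep] / length(k))
  if (length(x) < 3 || length(unique(x)) < 2) {
    warning("too few occupied bins for a scale-free fit")
    return(list(r_squared = NA_real_, slope = NA_real_, fit_table = NULL))
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = r2 * sign(-slope), slope = slope,
       fit_table = data.frame(log10_k = unname(x), log10_freq = unname(y)))
}

#' Scan candidate soft-thresholding powers
#'
#' For each candidate power computes the adjacency, the connectivity summary
#' and the signed scale-free fit index. The absolute correlation matrix is
#' computed once and re-powered per candidate.
#'
#' @param expr genes x samples matrix.
#' @param powers candidate powers (default integers 1..20).
#' @param n_bins bins for [scale_free_fit()].
#' @param mode adjacency mode as in [compute_adjacency()].
#' @return data.frame with one row per power: `power`, `r_squared`, `slope`,
#'   `mean_k`, `median_k`, `max_k`.
#' @export
soft_threshold_scan <- function(expr, powers = 1:20, n_bins = 10,
                                mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  .check_matrix(expr, "expression matrix")
  v <- apply(expr, 1, stats::var)
  expr <- expr[v > 0, , drop = FALSE]
  cc <- stats::cor(t(expr))
  sim <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(sim) <- 0
  rows <- lapply(powers, function(p) {
    a <- sim^p
    k <- rowSums(a)
    sf <- suppressWarnings(scale_free_fit(k, n_bins = n_bins))
    data.frame(power = p, r_squared = sf$r_squared, slope = sf$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  do.call(rbind, rows)
}

#' Select the soft threshold from a power scan
#'
#' Applies the "last power before the fit curve reaches the target" rule:
#' with `beta_c` the smallest candidate whose signed `R^2` reaches `target`,
#' the selected power is the candidate immediately preceding `beta_c`
#' (keeping mean connectivity high); if `beta_c` is the first candidate it
#' is returned itself. If no candidate reaches the target, the argmax of
#' `R^2` is returned with a warning.
#'
#' @param scan data.frame from [soft_threshold_scan()] (ascending powers).
#' @param target signed R-squared target (default 0.90).
#' @return The selected power (single number).
#' @export
select_soft_threshold <- function(scan, target = 0.90) {
  if (is.null(scan) || nrow(scan) == 0) stop("empty soft-threshold scan")
  if (is.unsorted(scan$power)) stop("scan powers must be ascending")
  r2 <- scan$r_squared
  hit <- which(!is.na(r2) & r2 >= target)
  if (length(hit) == 0) {
    warning("no candidate power reaches R^2 = ", target,
            "; returning argmax R^2")
    return(scan$power[which.max(r2)])
  }
  i <- hit[1]
  scan$power[max(i - 1, 1)]
}

#' Topological overlap matrix
#'
#' `omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' with `l_ij = sum_{u != i,j} a_iu a_uj` the shared-neighbor term and
#' `k_i` the connectivity; `omega_ii = 1`. Two genes overlap strongly when
#' they are adjacent and share the same neighbors relative to the less
#' connected of the two. Vectorized via one matrix product.
#'
#' @param adj adjacency matrix in `[0, 1]` with unit diagonal.
#' @return Symmetric TOM with values in `[0, 1]` and unit diagonal.
#' @export
compute_tom <- function(adj) {
  .check_square_symmetric(adj, "adjacency")
  if (any(adj < 0) || any(adj > 1)) stop("adjacency values must lie in [0, 1]")
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  l <- a %*% a                      # l_ij = sum_{u != i,j} a_iu a_uj off-diagonal
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  if (any(denom <= 0)) stop("non-positive TOM denominator")
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(adj)
  tom
}

#' TOM dissimilarity
#'
#' `d_ij = 1 - omega_ij`, zero diagonal; the distance actually clustered.
#'
#' @param tom matrix from [compute_tom()].
#' @return Dissimilarity matrix.
#' @export
tom_dissimilarity <- function(tom) {
  .check_square_symmetric(tom, "TOM")
  d <- 1 - tom
  diag(d) <- 0
  d
}
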