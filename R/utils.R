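#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Label values are arbitrary (including 0 for background); only the induced
#' partitions matter. Returns 1 for identical partitions and has expectation
#' 0 under random labeling.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return A single number in \eqn{[-1, 1]}.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_comb <- function(x) sum(choose(x, 2))
  sum_ij <- sum_comb(tab)
  sum_a <- sum_comb(rowSums(tab))
  sum_b <- sum_comb(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# shared validation helpers (internal)

.check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

.check_square_symmetric <- function(x, what = "matrix", tol = 1e-10) {
  .check_matrix(x, what)
  if (nrow(x) != ncol(x)) stop(what, " must be square")
  if (max(abs(x - t(x))) > tol) stop(what, " must be symmetric")
  invisible(x)
}

# relabel modules 1..K by decreasing size, ties by smallest member position;
# label 0 (background) is preserved
.relabel_by_size <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0) return(labels)
  size <- vapply(ids, function(l) sum(labels == l), integer(1))
  first <- vapply(ids, function(l) which(labels == l)[1], integer(1))
  ord <- ids[order(-size, first)]
  out <- labels
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}
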