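#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: sort the p-values, multiply `p_(i)` by `m / i`,
#' enforce monotonicity from the largest p downward, cap at 1, and return in
#' the input order. `q >= p` elementwise and the result is invariant to the
#' input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Read a flat gene-term annotation table
#'
#' A two-column TSV (gene, term), optionally accompanied by a term table
#' (term, name, ontology with categories F/P/C). No DAG propagation is
#' performed: annotations are used exactly as given.
#'
#' @param path annotation TSV path (header row: gene, term).
#' @param term_path optional term table TSV (header: term, name, ontology).
#' @return `list(annotation = <data.frame>, terms = <data.frame or NULL>)`.
#' @export
read_annotation <- function(path, term_path = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(ann) < 2) stop("annotation table needs gene and term columns")
  names(ann)[1:2] <- c("gene", "term")
  terms <- NULL
  if (!is.null(term_path)) {
    terms <- utils::read.delim(term_path, stringsAsFactors = FALSE)
    missing_terms <- setdiff(ann$term, terms$term)
    if (length(missing_terms))
      stop("terms referenced but absent from the term table: ",
           paste(utils::head(missing_terms, 5), collapse = ", "))
  }
  list(annotation = ann[, c("gene", "term")], terms = terms)
}

#' Term enrichment of a gene list (singular enrichment analysis)
#'
#' One-sided hypergeometric (Fisher) enrichment of each annotation term in a
#' module gene list against a background universe, with Benjamini-Hochberg
#' FDR control across the tested terms. With `k` module genes annotated to a
#' term, `K` universe genes annotated, module size `n` (within the universe)
#' and universe size `N`, the p-value is the upper hypergeometric tail
#' `P(X >= k)`. By default the universe is every gene carrying at least one
#' annotation — the background choice materially changes p-values, so it is
#' explicit and overridable.
#'
#' @param module_genes character vector of gene ids.
#' @param annotation data.frame with columns `gene`, `term` (flat, no DAG).
#' @param universe background gene ids; default: all annotated genes.
#' @param terms optional term table (`term`, `name`, `ontology`) to join.
#' @param min_count only terms with at least this many module genes are
#'   tested (default 1).
#' @param alpha significance level on the q-value (default 0.05).
#' @return data.frame per term: `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `significant` (plus `name`/`ontology` when a term table is given),
#'   sorted by p.
#' @export
fisher_enrichment <- function(module_genes, annotation, universe = NULL,
                              terms = NULL, min_count = 1, alpha = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  module_genes <- unique(module_genes)
  if (length(module_genes) == 0) stop("empty module gene list")
  if (!all(module_genes %in% universe))
    stop("module genes outside the universe: ",
         paste(utils::head(setdiff(module_genes, universe), 5), collapse = ", "))
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  N <- length(universe)
  n <- length(module_genes)
  K_tab <- table(ann$term)
  in_mod <- ann[ann$gene %in% module_genes, , drop = FALSE]
  k_tab <- table(in_mod$term)
  tested <- names(k_tab)[k_tab >= min_count]
  if (length(tested) == 0)
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  k <- as.integer(k_tab[tested])
  K <- as.integer(K_tab[tested])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = tested, k = k, n = n, K = K, N = N, p = p,
                    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q <= alpha
  if (!is.null(terms)) out <- merge(out, terms, by = "term", all.x = TRUE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Enrichment for every module of a partition
#'
#' Runs [fisher_enrichment()] per module, FDR-controlled within each module.
#'
#' @param partition named integer module labels (0 skipped).
#' @param annotation,universe,terms,min_count,alpha as in
#'   [fisher_enrichment()].
#' @return data.frame with a leading `module` column. Modules with no
#'   annotated gene in the universe are skipped.
#' @export
enrich_modules <- function(partition, annotation, universe = NULL,
                           terms = NULL, min_count = 1, alpha = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  universe <- intersect(universe, names(partition))
  mods <- sort(setdiff(unique(partition), 0L))
  rows <- lapply(mods, function(q) {
    genes <- intersect(names(partition)[partition == q], universe)
    if (length(genes) == 0) return(NULL)
    res <- fisher_enrichment(genes, annotation, universe = universe,
                             terms = terms, min_count = min_count,
                             alpha = alpha)
    if (nrow(res) == 0) return(NULL)
    cbind(module = q, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
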