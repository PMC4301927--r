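#' Impute missing metabolite values with the per-compound minimum
#'
#' Each missing cell is replaced by its compound's observed minimum across
#' all samples — the standard treatment for left-censored (detection-limit)
#' missingness in metabolomics. Imputation happens on the original scale,
#' before any log transform. Compounds with no observed value at all are
#' dropped with a warning.
#'
#' @param mat compounds x samples matrix, `NA` for missing.
#' @return The imputed matrix (possibly with fewer rows).
#' @export
impute_minimum <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  all_missing <- apply(mat, 1, function(x) all(is.na(x)))
  if (any(all_missing)) {
    warning("dropping compound(s) with no observed values: ",
            paste(rownames(mat)[all_missing], collapse = ", "))
    mat <- mat[!all_missing, , drop = FALSE]
  }
  for (i in seq_len(nrow(mat))) {
    miss <- is.na(mat[i, ])
    if (any(miss)) mat[i, miss] <- min(mat[i, ], na.rm = TRUE)
  }
  mat
}

#' Welch two-sample tests for one group contrast
#'
#' For each compound, Welch's unequal-variance t-test of group A against
#' group B on natural-log-transformed abundances (the transform stabilizes
#' the variance growth with signal level), plus the A/B ratio of arithmetic
#' group means on the original scale — the fold change as printed in
#' comparison tables. Orientation: positive t and ratio > 1 both mean
#' higher in group A.
#'
#' @param mat compounds x samples matrix (imputed; strictly positive).
#' @param groups factor of group membership over the columns.
#' @param contrast length-2 character vector `c(A, B)`.
#' @param log_transform apply the natural log before testing (default TRUE;
#'   disable only for checking the Welch formula on raw toy vectors).
#' @return data.frame per compound: `compound`, `ratio`, `t`, `df`, `p`.
#' @export
welch_contrast <- function(mat, groups, contrast, log_transform = TRUE) {
  if (length(contrast) != 2) stop("contrast must name exactly two groups")
  if (!all(contrast %in% levels(factor(groups))))
    stop("contrast groups absent from `groups`")
  ia <- which(groups == contrast[1])
  ib <- which(groups == contrast[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("both contrast groups need >= 2 samples")
  if (anyNA(mat[, c(ia, ib)]))
    stop("missing values present; run impute_minimum() first")
  if (log_transform && any(mat[, c(ia, ib)] <= 0))
    stop("non-positive abundances cannot be log-transformed")
  out <- data.frame(compound = rownames(mat),
                    ratio = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    a <- mat[i, ia]
    b <- mat[i, ib]
    out$ratio[i] <- mean(a) / mean(b)
    xa <- if (log_transform) log(a) else a
    xb <- if (log_transform) log(b) else b
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      out$t[i] <- 0
      out$df[i] <- length(xa) + length(xb) - 2
      out$p[i] <- 1
      next
    }
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    out$t[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p[i] <- tt$p.value
  }
  rownames(out) <- NULL
  out
}

#' Standard nitrogen-study contrasts
#'
#' The three comparisons behind the response-pattern logic, with the ratio
#' orientation used in printed tables: adaptation `HN/LN`, induction
#' `(LN->HN)/LN`, reduction `(HN->LN)/HN`. Group names must be `LN`, `HN`,
#' `induced` (LN-to-HN shift) and `reduced` (HN-to-LN shift).
#'
#' @return Named list of length-2 contrast vectors.
#' @export
nitrogen_contrasts <- function() {
  list(adaptation = c("HN", "LN"),
       induction = c("induced", "LN"),
       reduction = c("reduced", "HN"))
}

#' Per-compound comparison table across contrasts
#'
#' Runs [welch_contrast()] for each contrast, computes Benjamini-Hochberg
#' q-values per contrast, and flags significance by the dual cut-off
#' p <= alpha and q <= q_cut.
#'
#' @param mat compounds x samples matrix (missing values allowed; minimum
#'   imputation is applied first).
#' @param groups factor over columns.
#' @param contrasts named list of length-2 contrast vectors (default
#'   [nitrogen_contrasts()]).
#' @param alpha p-value cut-off (default 0.05).
#' @param q_cut q-value cut-off (default 0.10).
#' @return data.frame: `compound`, `contrast`, `ratio`, `t`, `df`, `p`,
#'   `q`, `significant`.
#' @export
metabolite_comparisons <- function(mat, groups,
                                   contrasts = nitrogen_contrasts(),
                                   alpha = 0.05, q_cut = 0.10) {
  mat <- impute_minimum(mat)
  rows <- lapply(names(contrasts), function(nm) {
    r <- welch_contrast(mat, groups, contrasts[[nm]])
    r$contrast <- nm
    r$q <- bh_fdr(r$p)
    r$significant <- r$p <= alpha & r$q <= q_cut
    r
  })
  out <- do.call(rbind, rows)
  out[, c("compound", "contrast", "ratio", "t", "df", "p", "q", "significant")]
}

#' Classify metabolite response patterns
#'
#' Assigns each compound exactly one pattern from its adaptation (`HN/LN`)
#' and reduction (`(HN->LN)/HN`) calls:
#' \describe{
#'   \item{proportional-HN}{higher under sufficient N (HN/LN significantly
#'     > 1) and not additionally elevated by the reduction shift — the
#'     compound tracks the nitrate level.}
#'   \item{LN-accumulating}{HN/LN significantly < 1: accumulates under
#'     adapted low N.}
#'   \item{non-proportional-reduction}{not higher under adapted HN
#'     (ratio >= 1 but non-significant, or no call) yet significantly
#'     elevated after the sufficient-to-limiting shift — the signature of
#'     rapid N remobilization (e.g. allantoin, asparagine).}
#'   \item{unchanged}{no significant call in any contrast.}
#'   \item{other}{any remaining combination.}
#' }
#'
#' @param cmp data.frame from [metabolite_comparisons()] containing the
#'   `adaptation` and `reduction` contrasts (the `induction` contrast, when
#'   present, only distinguishes `unchanged` from `other`).
#' @return data.frame: `compound`, `pattern`.
#' @export
classify_response <- function(cmp) {
  need <- c("adaptation", "reduction")
  if (!all(need %in% cmp$contrast))
    stop("comparison table must contain contrasts: ",
         paste(setdiff(need, cmp$contrast), collapse = ", "))
  compounds <- unique(cmp$compound)
  pattern <- vapply(compounds, function(cp) {
    sub <- cmp[cmp$compound == cp, , drop = FALSE]
    get <- function(ct) sub[sub$contrast == ct, , drop = FALSE][1, ]
    ad <- get("adaptation")
    re <- get("reduction")
    if (is.na(ad$ratio) || is.na(re$ratio)) stop("missing contrast for ", cp)
    ad_up <- isTRUE(ad$significant) && ad$ratio > 1
    ad_down <- isTRUE(ad$significant) && ad$ratio < 1
    re_up <- isTRUE(re$significant) && re$ratio > 1
    any_sig <- any(sub$significant, na.rm = TRUE)
    if (ad_up && !re_up) return("proportional-HN")
    if (ad_down) return("LN-accumulating")
    if (re_up && (ad$ratio >= 1 || !isTRUE(ad$significant)))
      return("non-proportional-reduction")
    if (!any_sig) return("unchanged")
    "other"
  }, character(1))
  data.frame(compound = compounds, pattern = unname(pattern),
             stringsAsFactors = FALSE)
}

#' Classify response patterns from printed ratios and significance stars
#'
#' Entry point for published-table rows where only the fold-change ratios
#' and their significance flags are available (no raw data): builds a
#' minimal comparison table and applies [classify_response()].
#'
#' @param adaptation,reduction `c(ratio, significant)` pairs — ratio as
#'   printed, significance as 0/1.
#' @param induction optional `c(ratio, significant)` pair.
#' @return The pattern label (character).
#' @export
classify_from_ratios <- function(adaptation, reduction, induction = NULL) {
  mk <- function(nm, x) data.frame(compound = "x", contrast = nm,
                                   ratio = x[1], t = NA, df = NA, p = NA,
                                   q = NA, significant = as.logical(x[2]))
  cmp <- rbind(mk("adaptation", adaptation), mk("reduction", reduction),
               if (!is.null(induction)) mk("induction", induction))
  classify_response(cmp)$pattern
}
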