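#' Read an expression matrix and its sample design
#'
#' The expression file is tab-delimited with a header row; the first column
#' holds feature ids, the remaining columns one sample each. The design file
#' is a TSV with columns `sample`, `tissue`, `condition`, `replicate`.
#' Values are assumed already normalized and on a log scale (post-RMA); no
#' re-normalization is applied.
#'
#' @param path expression TSV path.
#' @param design_path design TSV path.
#' @return `list(expr = <matrix>, design = <data.frame>)`.
#' @export
read_expression <- function(path, design_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  expr <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- ids
  .check_matrix(expr, "expression matrix")
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  missing_in_design <- setdiff(colnames(expr), design$sample)
  missing_in_expr <- setdiff(design$sample, colnames(expr))
  if (length(missing_in_design) || length(missing_in_expr))
    stop("sample mismatch between expression and design; ",
         "not in design: [", paste(missing_in_design, collapse = ", "),
         "]; not in expression: [", paste(missing_in_expr, collapse = ", "), "]")
  design <- design[match(colnames(expr), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  list(expr = expr, design = design)
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(feature = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter features by exclusion list and optional detection floor
#'
#' Removes features named in `exclude_ids` (e.g. probe sets mapping to
#' multiple loci) and, if `detection_floor` is given, features that never
#' reach the floor in any sample of any replicate group — i.e. features with
#' no detectable signal in at least one experiment. The floor is off by
#' default because estimating it properly needs control probes.
#'
#' @param expr genes x samples matrix.
#' @param exclude_ids character vector of feature ids to drop (may be empty).
#' @param detection_floor optional numeric threshold.
#' @return `list(expr = <filtered matrix>, report = <data.frame>)` where the
#'   report has columns `feature` and `reason`.
#' @export
filter_features <- function(expr, exclude_ids = character(),
                            detection_floor = NULL) {
  .check_matrix(expr, "expression matrix")
  reasons <- character(0)
  feats <- character(0)
  excluded <- intersect(rownames(expr), exclude_ids)
  if (length(excluded)) {
    feats <- c(feats, excluded)
    reasons <- c(reasons, rep("excluded id", length(excluded)))
  }
  keep <- setdiff(rownames(expr), excluded)
  if (!is.null(detection_floor)) {
    mx <- apply(expr[keep, , drop = FALSE], 1, max)
    below <- keep[mx < detection_floor]
    if (length(below)) {
      feats <- c(feats, below)
      reasons <- c(reasons, rep("below detection floor in all samples",
                                length(below)))
      keep <- setdiff(keep, below)
    }
  }
  if (length(keep) == 0) stop("all features removed by filtering")
  list(expr = expr[keep, , drop = FALSE],
       report = data.frame(feature = feats, reason = reasons,
                           stringsAsFactors = FALSE))
}

#' Collapse replicates to per-group medians
#'
#' One column per (condition, tissue) combination; each cell is the median of
#' that combination's replicates. The default triplicate study design (2
#' tissues x 4 conditions x 3 replicates) collapses 24 columns to 8.
#' Single-replicate groups pass through unchanged, so the operation is
#' idempotent.
#'
#' @param expr genes x samples matrix.
#' @param design sample design data.frame covering `colnames(expr)`.
#' @return `list(expr = <collapsed matrix>, design = <collapsed design>)`;
#'   collapsed samples are named `<condition>.<tissue>`.
#' @export
collapse_replicates_median <- function(expr, design) {
  if (!all(colnames(expr) %in% design$sample))
    stop("design does not cover all expression samples")
  design <- design[match(colnames(expr), design$sample), , drop = FALSE]
  combo <- paste(design$condition, design$tissue, sep = ".")
  combos <- unique(combo)
  out <- matrix(NA_real_, nrow(expr), length(combos),
                dimnames = list(rownames(expr), combos))
  for (j in seq_along(combos)) {
    cols <- which(combo == combos[j])
    out[, j] <- apply(expr[, cols, drop = FALSE], 1, stats::median)
  }
  first <- match(combos, combo)
  cdesign <- data.frame(sample = combos,
                        tissue = design$tissue[first],
                        condition = design$condition[first],
                        replicate = 1L,
                        stringsAsFactors = FALSE)
  list(expr = out, design = cdesign)
}

#' Build binary trait indicators from a (collapsed) design
#'
#' One indicator per observed (condition, tissue) combination (a one-hot
#' encoding: each sample carries exactly one 1 across combination columns)
#' plus one per condition pooled over tissues, so both "LN in leaves"-style
#' and whole-plant "in LN"-style traits can be correlated against eigengenes.
#' Constant columns (all 0 or all 1) are unusable for correlation and are
#' flagged in the `"usable"` attribute.
#'
#' @param design sample design data.frame.
#' @return samples x traits 0/1 matrix; combination columns are named
#'   `<condition>.<tissue>`, pooled columns `<condition>`. Attribute
#'   `usable` marks non-constant columns.
#' @export
build_trait_indicators <- function(design) {
  combo <- paste(design$condition, design$tissue, sep = ".")
  combo_names <- unique(combo)
  cond_names <- unique(design$condition)
  cols <- c(combo_names, setdiff(cond_names, combo_names))
  m <- matrix(0, nrow(design), length(cols),
              dimnames = list(design$sample, cols))
  for (cn in combo_names) m[combo == cn, cn] <- 1
  for (cn in setdiff(cond_names, combo_names))
    m[design$condition == cn, cn] <- 1
  usable <- apply(m, 2, function(x) length(unique(x)) > 1)
  if (any(!usable))
    warning("constant trait indicator(s) unusable for correlation: ",
            paste(colnames(m)[!usable], collapse = ", "))
  attr(m, "usable") <- usable
  m
}
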