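#' Default nitrogen-study sample design
#'
#' Two tissues (leaf, root) x four nitrogen conditions (LN, HN, induced,
#' reduced) x three biological replicates: 24 samples. LN is severe-limiting
#' nitrate (0.3 mM), HN sufficient (3 mM); "induced" is an LN-to-HN shift and
#' "reduced" an HN-to-LN shift.
#'
#' @param tissues,conditions,replicates character/integer vectors defining the
#'   full factorial design.
#' @return A data.frame with columns `sample`, `tissue`, `condition`,
#'   `replicate`.
#' @export
default_sample_design <- function(tissues = c("leaf", "root"),
                                  conditions = c("LN", "HN", "induced", "reduced"),
                                  replicates = 1:3) {
  d <- expand.grid(replicate = replicates, condition = conditions,
                   tissue = tissues, stringsAsFactors = FALSE)
  d <- d[, c("tissue", "condition", "replicate")]
  d$sample <- paste(d$tissue, d$condition, d$replicate, sep = "_")
  d[, c("sample", "tissue", "condition", "replicate")]
}

#' Specify a synthetic co-expression dataset
#'
#' Describes planted module structure for [generate_expression()]: block sizes,
#' the sample design, trait-linked latent signals, the target gene-signal
#' correlation within modules, and an optional planted hub transcription
#' factor.
#'
#' @param module_sizes integer vector of planted module sizes.
#' @param n_background_genes number of unstructured (pure noise) genes.
#' @param sample_design data.frame as from [default_sample_design()].
#' @param trait_links named list; names are module indices (as character),
#'   values are `list(trait = <name>, r = <target correlation>)`. A trait name
#'   is either a condition (e.g. `"LN"`) or `"<condition>.<tissue>"` (e.g.
#'   `"reduced.leaf"`), and must be realizable from `sample_design`.
#' @param within_module_cor target gene-latent-signal correlation in (0, 1].
#' @param noise_sd scale of the per-gene noise relative to the
#'   `sqrt(1 - r^2)` loading; at the default 1 the expected gene-signal
#'   correlation equals `within_module_cor` exactly, at 0 modules are
#'   noiseless rank-1 blocks.
#' @param tf_fraction fraction of genes labeled as transcription factors.
#' @param planted_hub_tf `NULL` or `list(module = <index>, r = <loading>)`:
#'   one TF in that module gets gene-signal correlation `r` (near 1) so it
#'   ranks at the top of module membership.
#' @param seed integer seed; equal spec + seed gives bit-identical output.
#' @return A validated object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(module_sizes,
                           n_background_genes = 0,
                           sample_design = default_sample_design(),
                           trait_links = list(),
                           within_module_cor = 0.9,
                           noise_sd = 1,
                           tf_fraction = 0.05,
                           planted_hub_tf = NULL,
                           seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) < 1 || any(module_sizes < 1))
    stop("module_sizes must be positive integers")
  if (n_background_genes < 0) stop("n_background_genes must be >= 0")
  if (!(within_module_cor > 0 && within_module_cor <= 1))
    stop("within_module_cor must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tf_fraction < 0 || tf_fraction > 1) stop("tf_fraction must be in [0, 1]")
  req <- c("sample", "tissue", "condition", "replicate")
  if (!all(req %in% names(sample_design)))
    stop("sample_design needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(sample_design$sample)) stop("duplicate sample ids in design")
  if (length(trait_links)) {
    idx <- suppressWarnings(as.integer(names(trait_links)))
    if (anyNA(idx) || any(idx < 1) || any(idx > length(module_sizes)))
      stop("trait_links names must be module indices")
    avail <- c(unique(sample_design$condition),
               paste(sample_design$condition, sample_design$tissue, sep = "."))
    for (tl in trait_links) {
      if (!is.list(tl) || is.null(tl$trait) || is.null(tl$r))
        stop("each trait link must be list(trait=, r=)")
      if (!(tl$trait %in% avail))
        stop("trait '", tl$trait, "' not realizable from sample_design")
      if (tl$r < 0 || tl$r > 1) stop("trait link r must be in [0, 1]")
    }
  }
  if (!is.null(planted_hub_tf)) {
    if (is.null(planted_hub_tf$module) || is.null(planted_hub_tf$r))
      stop("planted_hub_tf must be list(module=, r=)")
    if (planted_hub_tf$module < 1 || planted_hub_tf$module > length(module_sizes))
      stop("planted_hub_tf module index out of range")
  }
  structure(list(
    module_sizes = module_sizes,
    n_background_genes = as.integer(n_background_genes),
    n_genes = sum(module_sizes) + as.integer(n_background_genes),
    sample_design = sample_design,
    trait_links = trait_links,
    within_module_cor = within_module_cor,
    noise_sd = noise_sd,
    tf_fraction = tf_fraction,
    planted_hub_tf = planted_hub_tf,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# unit-variance standardization (internal)
.standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# binary indicator for a trait name over a design; "cond" or "cond.tissue"
.trait_indicator <- function(trait, design) {
  parts <- strsplit(trait, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    as.numeric(design$condition == parts[1])
  } else {
    as.numeric(design$condition == parts[1] & design$tissue == parts[2])
  }
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Each planted module is driven by a latent per-sample signal (standardized
#' to unit variance). A trait-linked signal is built as
#' `r * z(indicator) + sqrt(1 - r^2) * z(noise orthogonal to indicator)`, so
#' its correlation with the binary trait is `r` exactly. Member genes are
#' `w * signal + sqrt(1 - w^2) * noise_sd * N(0,1)` with
#' `w = within_module_cor`; background genes are independent `N(0,1)` noise.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `"nitronet_sim"` with elements `expr` (genes x
#'   samples matrix), `design` (the sample design), and `truth`: planted
#'   module labels (0 = background), the latent signals (samples x modules),
#'   the TF gene ids and the hub gene id.
#' @examples
#' sim <- generate_expression(synthetic_spec(c(30, 30), 20, seed = 7))
#' dim(sim$expr)
#' table(sim$truth$module_labels)
#' @export
generate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  set.seed(spec$seed)
  design <- spec$sample_design
  n_samp <- nrow(design)
  if (n_samp < 3) stop("need at least 3 samples")
  n_mod <- length(spec$module_sizes)
  w <- spec$within_module_cor

  # latent signals live at the (condition, tissue) level and are shared by
  # replicates: expression is condition-driven, so median-collapsing the
  # replicates preserves the planted structure exactly
  combo <- factor(paste(design$condition, design$tissue, sep = "."))
  combo_idx <- as.integer(combo)
  n_combo <- nlevels(combo)
  if (n_combo < 3) stop("need at least 3 condition/tissue combinations")
  signals <- matrix(NA_real_, n_samp, n_mod,
                    dimnames = list(design$sample, paste0("signal", seq_len(n_mod))))
  for (q in seq_len(n_mod)) {
    link <- spec$trait_links[[as.character(q)]]
    if (is.null(link)) {
      signals[, q] <- .standardize(stats::rnorm(n_combo)[combo_idx])
    } else {
      ind <- .trait_indicator(link$trait, design)
      if (length(unique(ind)) < 2)
        stop("trait '", link$trait, "' is constant over the design")
      z_ind <- .standardize(ind)
      e <- stats::rnorm(n_combo)[combo_idx]
      e_orth <- .standardize(stats::residuals(stats::lm(e ~ z_ind)))
      signals[, q] <- link$r * z_ind + sqrt(1 - link$r^2) * e_orth
    }
  }

  gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))
  labels <- c(rep(seq_len(n_mod), spec$module_sizes),
              rep(0L, spec$n_background_genes))
  names(labels) <- gene_ids

  expr <- matrix(NA_real_, spec$n_genes, n_samp,
                 dimnames = list(gene_ids, design$sample))
  hub_gene <- NULL
  for (i in seq_len(spec$n_genes)) {
    q <- labels[i]
    if (q == 0) {
      expr[i, ] <- stats::rnorm(n_samp)
      next
    }
    loading <- w
    if (!is.null(spec$planted_hub_tf) && q == spec$planted_hub_tf$module &&
        i == which(labels == q)[1]) {
      loading <- spec$planted_hub_tf$r
      hub_gene <- gene_ids[i]
    }
    expr[i, ] <- loading * signals[, q] +
      sqrt(1 - loading^2) * spec$noise_sd * stats::rnorm(n_samp)
  }

  n_tf <- round(spec$tf_fraction * spec$n_genes)
  tf_genes <- sort(sample(gene_ids, n_tf))
  if (!is.null(hub_gene)) tf_genes <- sort(union(tf_genes, hub_gene))

  structure(list(
    expr = expr,
    design = design,
    truth = list(module_labels = labels, signals = signals,
                 tf_genes = tf_genes, hub_gene = hub_gene,
                 trait_links = spec$trait_links)
  ), class = "nitronet_sim")
}

#' Generate synthetic metabolite abundances with planted group ratios
#'
#' Abundances are log-normal: per compound a baseline log-mean is drawn, each
#' group's log-mean is offset by `log(ratio)`, and `sdlog` is set from the
#' coefficient of variation so the expected ratio of arithmetic group means
#' equals the planted ratio exactly. Missingness is left-censored: per
#' compound a Binomial(n, missing_rate) number of the lowest values is
#' removed, emulating detection-limit dropouts and matching downstream
#' minimum imputation.
#'
#' @param n_compounds number of compounds.
#' @param group_sizes named integer vector of samples per group; the first
#'   group is the ratio reference. All sizes must be >= 2.
#' @param planted_ratios `NULL` (all ratios 1), a named vector over groups
#'   applied to every compound, or a compounds x groups matrix.
#' @param cv within-group coefficient of variation on the original scale.
#' @param missing_rate fraction of cells removed per compound (must be < 1).
#' @param seed integer seed.
#' @return A list of class `"nitronet_metab_sim"`: `values` (compounds x
#'   samples, `NA` for missing), `groups` (factor over samples), and `truth`
#'   (the planted ratio matrix and missing counts).
#' @export
generate_metabolites <- function(n_compounds,
                                 group_sizes,
                                 planted_ratios = NULL,
                                 cv = 0.2,
                                 missing_rate = 0,
                                 seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop("group_sizes must be a named vector")
  if (any(group_sizes < 2)) stop("every group needs >= 2 samples")
  if (missing_rate >= 1 || missing_rate < 0) stop("missing_rate must be in [0, 1)")
  if (cv <= 0) stop("cv must be > 0")
  groups <- names(group_sizes)
  ratios <- matrix(1, n_compounds, length(groups),
                   dimnames = list(NULL, groups))
  if (!is.null(planted_ratios)) {
    if (is.matrix(planted_ratios)) {
      if (nrow(planted_ratios) != n_compounds ||
          !all(groups %in% colnames(planted_ratios)))
        stop("planted_ratios matrix must be n_compounds x groups")
      ratios <- planted_ratios[, groups, drop = FALSE]
    } else {
      if (!all(names(planted_ratios) %in% groups))
        stop("planted_ratios names must be group names")
      ratios[, names(planted_ratios)] <- rep(planted_ratios,
                                             each = n_compounds)
    }
  }
  if (any(ratios <= 0)) stop("planted ratios must be positive")

  set.seed(seed)
  n_samp <- sum(group_sizes)
  grp <- factor(rep(groups, group_sizes), levels = groups)
  samp_ids <- paste(grp, stats::ave(seq_len(n_samp), grp, FUN = seq_along),
                    sep = "_")
  comp_ids <- sprintf("cmpd%04d", seq_len(n_compounds))
  rownames(ratios) <- comp_ids
  sdlog <- sqrt(log(1 + cv^2))

  vals <- matrix(NA_real_, n_compounds, n_samp,
                 dimnames = list(comp_ids, samp_ids))
  for (i in seq_len(n_compounds)) {
    base <- stats::runif(1, log(1e3), log(1e5))
    meanlog <- base + log(ratios[i, as.integer(grp)]) - sdlog^2 / 2
    vals[i, ] <- stats::rlnorm(n_samp, meanlog = meanlog, sdlog = sdlog)
  }

  n_missing <- integer(n_compounds)
  if (missing_rate > 0) {
    for (i in seq_len(n_compounds)) {
      k <- min(stats::rbinom(1, n_samp, missing_rate), n_samp - 1L)
      if (k > 0) vals[i, order(vals[i, ])[seq_len(k)]] <- NA_real_
      n_missing[i] <- k
    }
  }

  structure(list(
    values = vals,
    groups = grp,
    truth = list(planted_ratios = ratios, n_missing = n_missing, cv = cv)
  ), class = "nitronet_metab_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Expression and design go to TSV (first column = feature/sample id), truth
#' to JSON, TF list to a plain text file.
#'
#' @param sim result of [generate_expression()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "nitronet_sim")) stop("sim must come from generate_expression")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  p_design <- file.path(dir, "design.tsv")
  p_tf <- file.path(dir, "tf_genes.txt")
  p_truth <- file.path(dir, "truth.json")
  write_expression(sim$expr, p_expr)
  utils::write.table(sim$design, p_design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$truth$tf_genes, p_tf)
  jsonlite::write_json(list(
    module_labels = as.list(sim$truth$module_labels),
    tf_genes = sim$truth$tf_genes,
    hub_gene = sim$truth$hub_gene
  ), p_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(p_expr, p_design, p_tf, p_truth))
}
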