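#' Assemble a pipeline configuration
#'
#' Paths may be `NULL` to skip optional stages (TF rank test, enrichment,
#' metabolites). Defaults follow the study settings: scale-free fit target
#' R^2 = 0.90 with automatic power selection, minimum module size 30,
#' eigengene merge threshold 0.65, 100000 permutations, alpha = 0.05,
#' metabolite q cut-off 0.10.
#'
#' @param expression,design paths to the expression and design TSVs.
#' @param out_dir output directory for artifacts and the run report.
#' @param exclusions optional path to a plain-text list of feature ids to
#'   drop (one per line).
#' @param tf_list optional path to a plain-text TF gene list.
#' @param annotation optional path to a gene-term TSV.
#' @param metabolites,metabolite_groups optional paths to a compounds x
#'   samples TSV and a (sample, group) TSV.
#' @param beta soft threshold: `"auto"` (select from a power scan) or a
#'   fixed number.
#' @param r2_target scale-free fit target for automatic selection.
#' @param min_module_size,merge_threshold,n_perm,alpha,q_cut,seed tuning
#'   parameters; see the stage functions.
#' @return A list of class `"nitronet_config"`.
#' @export
pipeline_config <- function(expression, design, out_dir,
                            exclusions = NULL, tf_list = NULL,
                            annotation = NULL, metabolites = NULL,
                            metabolite_groups = NULL,
                            beta = "auto", r2_target = 0.90,
                            min_module_size = 30, merge_threshold = 0.65,
                            n_perm = 100000, alpha = 0.05, q_cut = 0.10,
                            seed = 1L) {
  stopifnot(r2_target > 0, r2_target <= 1, min_module_size >= 1,
            merge_threshold > 0, merge_threshold < 1,
            alpha > 0, alpha < 1, q_cut > 0, q_cut <= 1, n_perm >= 1)
  structure(list(expression = expression, design = design, out_dir = out_dir,
                 exclusions = exclusions, tf_list = tf_list,
                 annotation = annotation, metabolites = metabolites,
                 metabolite_groups = metabolite_groups, beta = beta,
                 r2_target = r2_target, min_module_size = min_module_size,
                 merge_threshold = merge_threshold, n_perm = n_perm,
                 alpha = alpha, q_cut = q_cut, seed = as.integer(seed)),
            class = "nitronet_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields match [pipeline_config()] arguments.
#' @return A `"nitronet_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' prep (filter, median-collapse, trait indicators) -> network (power scan,
#' adjacency, TOM) -> modules (complete-linkage cut, eigengenes, merge) ->
#' association (module-trait correlations, module membership, TF rank test)
#' -> enrichment -> metabolites. Every stage writes its artifact under
#' `out_dir` and contributes counts to the run report; the report (minus
#' timestamps) is deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()] or a path to its JSON form.
#' @return The run report, invisibly also written to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "nitronet_config")) stop("not a pipeline config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config[setdiff(names(config),
                                             c("out_dir"))],
                 started = format(Sys.time(), tz = "UTC"))
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- prep ---
  prep <- stage("prep", function() {
    inp <- read_expression(config$expression, config$design)
    excl <- if (!is.null(config$exclusions)) readLines(config$exclusions)
            else character()
    filt <- filter_features(inp$expr, exclude_ids = excl)
    .write_tsv(filt$report, file.path(config$out_dir, "removed_features.tsv"))
    coll <- collapse_replicates_median(filt$expr, inp$design)
    write_expression(coll$expr, file.path(config$out_dir, "expression_collapsed.tsv"))
    traits <- build_trait_indicators(coll$design)
    list(expr = coll$expr, design = coll$design, traits = traits,
         n_in = nrow(inp$expr), n_removed = nrow(filt$report))
  })
  report$prep <- list(features_in = prep$n_in,
                      features_removed = prep$n_removed,
                      features_out = nrow(prep$expr),
                      samples_collapsed = ncol(prep$expr))

  # --- network ---
  net <- stage("network", function() {
    scan <- soft_threshold_scan(prep$expr)
    .write_tsv(scan, file.path(config$out_dir, "soft_threshold_scan.tsv"))
    beta <- if (identical(config$beta, "auto"))
      select_soft_threshold(scan, target = config$r2_target)
    else as.numeric(config$beta)
    adj <- compute_adjacency(prep$expr, beta = beta)
    tom <- compute_tom(adj)
    list(beta = beta, dissim = tom_dissimilarity(tom))
  })
  report$network <- list(beta = net$beta)

  # --- modules ---
  mods <- stage("modules", function() {
    dend <- hierarchical_cluster(net$dissim)
    part <- dynamic_tree_cut(dend, min_size = config$min_module_size)
    if (!any(part > 0)) stop("no modules found at min_size ",
                             config$min_module_size)
    merged <- merge_modules(prep$expr, part,
                            threshold = config$merge_threshold)
    .write_tsv(data.frame(gene = names(part), premerge = unname(part),
                          merged = unname(merged$partition[names(part)])),
               file.path(config$out_dir, "module_partition.tsv"))
    E <- merged$eigengenes
    .write_tsv(data.frame(sample = rownames(E), E, check.names = FALSE),
               file.path(config$out_dir, "eigengenes.tsv"))
    list(premerge = part, partition = merged$partition, eigengenes = E)
  })
  report$modules <- list(
    premerge = length(setdiff(unique(mods$premerge), 0L)),
    merged = ncol(mods$eigengenes),
    unassigned = sum(mods$partition == 0))

  # --- association ---
  assoc <- stage("association", function() {
    mt <- module_trait_correlation(mods$eigengenes, prep$traits)
    .write_tsv(mt, file.path(config$out_dir, "module_trait.tsv"))
    mm <- module_membership(prep$expr, mods$eigengenes, mods$partition)
    .write_tsv(mm, file.path(config$out_dir, "module_membership.tsv"))
    tf <- NULL
    if (!is.null(config$tf_list)) {
      tf_genes <- readLines(config$tf_list)
      tf <- tf_rank_test_modules(mm, tf_genes, n_perm = config$n_perm,
                                 seed = config$seed)
      jsonlite::write_json(tf, file.path(config$out_dir, "tf_rank_test.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(mt = mt, mm = mm, tf = tf)
  })
  report$association <- list(
    significant_module_trait = sum(assoc$mt$p < 0.05),
    tf_test = if (is.null(assoc$tf)) "skipped (no TF list)"
              else sum(!is.na(assoc$tf$p_mc)))

  # --- enrichment ---
  if (!is.null(config$annotation)) {
    enr <- stage("enrichment", function() {
      ann <- read_annotation(config$annotation)
      res <- enrich_modules(mods$partition, ann$annotation,
                            terms = ann$terms, alpha = config$alpha)
      if (!is.null(res))
        .write_tsv(res, file.path(config$out_dir, "enrichment.tsv"))
      res
    })
    report$enrichment <- if (is.null(enr)) list(enriched_terms = 0) else
      list(enriched_terms = sum(enr$significant),
           modules_tested = length(unique(enr$module)))
  } else report$enrichment <- "skipped (no annotation)"

  # --- metabolites ---
  if (!is.null(config$metabolites)) {
    met <- stage("metabolites", function() {
      raw <- utils::read.delim(config$metabolites, check.names = FALSE,
                               stringsAsFactors = FALSE)
      mat <- as.matrix(raw[, -1, drop = FALSE])
      storage.mode(mat) <- "double"
      rownames(mat) <- raw[[1]]
      grp_tab <- utils::read.delim(config$metabolite_groups,
                                   stringsAsFactors = FALSE)
      groups <- factor(grp_tab$group[match(colnames(mat), grp_tab$sample)])
      cmp <- metabolite_comparisons(mat, groups, alpha = config$alpha,
                                    q_cut = config$q_cut)
      .write_tsv(cmp, file.path(config$out_dir, "metabolite_comparisons.tsv"))
      pat <- classify_response(cmp)
      .write_tsv(pat, file.path(config$out_dir, "metabolite_patterns.tsv"))
      list(cmp = cmp, pat = pat)
    })
    report$metabolites <- list(
      significant_per_contrast = as.list(tapply(
        met$cmp$significant, met$cmp$contrast, sum)),
      patterns = as.list(table(met$pat$pattern)))
  } else report$metabolites <- "skipped (no metabolite table)"

  report$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
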