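make_tsv <- function(df, dir, name) {
  p <- file.path(dir, name)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("read_expression parses, cross-checks the design, rejects duplicates", {
  dir <- withr::local_tempdir()
  expr_df <- data.frame(feature = c("a", "b", "c"), s1 = 1:3, s2 = 4:6)
  des_df <- data.frame(sample = c("s1", "s2"), tissue = "leaf",
                       condition = c("LN", "HN"), replicate = 1L)
  p1 <- make_tsv(expr_df, dir, "e.tsv")
  p2 <- make_tsv(des_df, dir, "d.tsv")
  got <- read_expression(p1, p2)
  expect_equal(dim(got$expr), c(3L, 2L))
  expect_equal(got$expr["b", "s2"], 5)

  expr_dup <- expr_df; expr_dup$feature[2] <- "a"
  p3 <- make_tsv(expr_dup, dir, "dup.tsv")
  expect_error(read_expression(p3, p2), "duplicate feature id.*a")

  des_bad <- des_df; des_bad$sample[2] <- "s9"
  p4 <- make_tsv(des_bad, dir, "bad.tsv")
  expect_error(read_expression(p1, p4), "s2.*|s9.*")
})

test_that("write then read preserves values to 12 decimals", {
  dir <- withr::local_tempdir()
  set.seed(1)
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  des <- data.frame(sample = colnames(m), tissue = "leaf",
                    condition = c("LN", "HN", "reduced"), replicate = 1L)
  write_expression(m, file.path(dir, "m.tsv"))
  make_tsv(des, dir, "d.tsv")
  back <- read_expression(file.path(dir, "m.tsv"), file.path(dir, "d.tsv"))
  expect_equal(back$expr, m, tolerance = 1e-12)
})

test_that("filter_features removes exclusions and floor failures with a report", {
  m <- matrix(1:10 + 0, 5, 2,
              dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  got <- filter_features(m, exclude_ids = c("g1", "g3"))
  expect_setequal(rownames(got$expr), c("g2", "g4", "g5"))
  expect_setequal(got$report$feature, c("g1", "g3"))

  expect_identical(filter_features(m)$expr, m)      # identity case

  m2 <- m; m2["g2", ] <- c(0.1, 0.2)                 # below floor everywhere
  got2 <- filter_features(m2, detection_floor = 0.5)
  expect_false("g2" %in% rownames(got2$expr))
  expect_equal(got2$report$reason[got2$report$feature == "g2"],
               "below detection floor in all samples")
  expect_error(filter_features(m, exclude_ids = rownames(m)), "all features")
})

test_that("median collapse: odd/even medians, 24 -> 8 columns, idempotence", {
  des <- default_sample_design()                     # 24 samples
  m <- matrix(rnorm(24 * 3), 3, 24,
              dimnames = list(paste0("g", 1:3), des$sample))
  m["g1", des$condition == "LN" & des$tissue == "leaf"] <- c(1, 2, 9)
  m["g2", des$condition == "HN" & des$tissue == "root"][1:2] <- c(1, 3)
  coll <- collapse_replicates_median(m, des)
  expect_equal(ncol(coll$expr), 8)
  expect_setequal(coll$design$sample,
                  as.vector(outer(c("LN", "HN", "induced", "reduced"),
                                  c("leaf", "root"), paste, sep = ".")))
  expect_equal(coll$expr["g1", "LN.leaf"], 2)        # odd-count median

  two <- m[, 1:2]
  des2 <- des[1:2, ]
  two["g2", ] <- c(1, 3)
  expect_equal(collapse_replicates_median(two, des2)$expr["g2", "LN.leaf"], 2)

  again <- collapse_replicates_median(coll$expr, coll$design)
  expect_equal(again$expr, coll$expr)                # idempotent
})

test_that("filtering commutes with collapsing", {
  des <- default_sample_design()
  set.seed(7)
  m <- matrix(rnorm(24 * 6), 6, 24,
              dimnames = list(paste0("g", 1:6), des$sample))
  a <- collapse_replicates_median(
    filter_features(m, exclude_ids = c("g2", "g5"))$expr, des)$expr
  b0 <- collapse_replicates_median(m, des)$expr
  b <- filter_features(b0, exclude_ids = c("g2", "g5"))$expr
  expect_equal(a, b)
})

test_that("trait indicators: one-hot combos plus pooled conditions", {
  des <- collapse_replicates_median(
    matrix(rnorm(24), 1, 24,
           dimnames = list("g1", default_sample_design()$sample)),
    default_sample_design())$design
  tr <- build_trait_indicators(des)
  combo_cols <- grep("\\.", colnames(tr), value = TRUE)
  cond_cols <- setdiff(colnames(tr), combo_cols)
  expect_length(combo_cols, 8)
  expect_length(cond_cols, 4)
  expect_true(all(rowSums(tr[, combo_cols]) == 1))   # partition
  expect_true(all(colSums(tr[, cond_cols]) == 2))    # two tissues each
  expect_true(all(attr(tr, "usable")))

  # single-tissue design: pooled and combo indicators carry the same values
  des1 <- des[des$tissue == "leaf", ]
  tr1 <- build_trait_indicators(des1)
  for (cond in unique(des1$condition))
    expect_equal(unname(tr1[, cond]), unname(tr1[, paste0(cond, ".leaf")]))

  # constant indicator flagged unusable
  desc <- des1[des1$condition == "LN", , drop = FALSE]
  expect_warning(trc <- build_trait_indicators(desc), "constant")
  expect_false(any(attr(trc, "usable")))
})
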