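test_that("PCA embedding captures degenerate one-axis variance", {
  x <- matrix(0, 5, 8, dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  x[1, ] <- seq(0, 7)                      # all variance on one gene-axis
  x <- x + matrix(rnorm(40, 0, 1e-3), 5, 8)
  sce <- SingleCellExperiment(assays = list(
    counts = matrix(0L, 5, 8, dimnames = dimnames(x)),
    tpm = 2^x - 1, logtpm = x))
  emb <- embed_cells(sce, paste0("g", 1:5))
  v <- apply(emb$coords, 2, var)
  expect_gt(v[1] / sum(v), 0.99)
})

test_that("tsne embedding is deterministic in its seed", {
  sim <- tiny_sim()
  norm <- tpm_normalize(sim)
  genes <- expressed_gene_set(norm)
  e1 <- embed_cells(norm, genes, method = "tsne", seed = 3, perplexity = 5)
  e2 <- embed_cells(norm, genes, method = "tsne", seed = 3, perplexity = 5)
  expect_identical(e1$coords, e2$coords)
})

test_that("developmental axis recovers an exact stage axis", {
  coords <- cbind(dim1 = rep(c(2, 4, 8), each = 4),
                  dim2 = rep(0, 12), dim3 = rep(0, 12))
  rownames(coords) <- paste0("c", 1:12)
  emb <- structure(list(coords = coords, cells = rownames(coords),
                        method = "pca", seed = 0L), class = "embedding")
  stages <- rep(c(2, 4, 8), each = 4)
  axis <- fit_developmental_axis(emb, stages)
  expect_equal(unname(abs(axis$direction)), c(1, 0, 0))
  expect_true(all(diff(axis$centroids) > 0))
  ## stage assignment with non-monotone group means: surfaced as an error
  emb2 <- emb
  emb2$coords[, 1] <- 1:12
  expect_error(fit_developmental_axis(emb2, rep(c(2, 8, 4), 4)),
               "not strictly increasing")
})

test_that("axis orders the default simulation by true stage", {
  sim <- wtko_sim()
  norm <- wtko_norm()
  emb <- embed_cells(norm, expressed_gene_set(norm))
  axis <- fit_developmental_axis(
    emb, stats::setNames(norm$stage, colnames(norm)))
  rho <- cor(axis$score[colnames(norm)], norm$stage, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("consensus rule assigns the three labels as specified", {
  cells <- paste0("c", 1:12)
  meta <- data.frame(condition = "WT", stage = rep(c(2L, 4L), each = 6),
                     row.names = cells)
  ## 2-cell: tight low cluster c1-c3; high-mean cluster c4-c6 with c4
  ## below the stage centroid (cluster/position mismatch)
  ## 4-cell: tight cluster c7-c10 near centroid; clear advanced pair
  score <- c(0, 0.05, -0.05, 0.1, 2.0, 2.2,
             4.9, 5.0, 5.1, 5.0, 9.0, 9.2)
  names(score) <- cells
  axis <- structure(list(direction = c(1, 0, 0), score = score,
                         centroids = c(`2` = 0.5, `4` = 5.15, `8` = 10)),
                    class = "dev_axis")
  map_sub <- c(c1 = 1, c2 = 1, c3 = 1, c4 = 2, c5 = 2, c6 = 2,
               c7 = 3, c8 = 3, c9 = 3, c10 = 3, c11 = 4, c12 = 4)
  ## alpha relaxed here: the block tests the rule mechanics on 6-cell
  ## groups, not the advancement test calibration
  cls <- classify_subpopulations(map_sub, map_sub, axis, meta,
                                 alpha = 0.25)
  got <- stats::setNames(cls$label, cls$cell)
  expect_identical(unname(got[c("c5", "c6")]),
                   rep("differentiating", 2))
  expect_identical(unname(got[c("c11", "c12")]),
                   rep("differentiating", 2))
  ## advanced cluster membership with a sub-centroid score is excluded
  expect_identical(unname(got["c4"]), "excluded")
  expect_match(cls$reason[cls$cell == "c4"], "mismatch")
  expect_true(all(got[c("c1", "c2", "c3", "c7", "c8", "c9", "c10")] ==
                  "embryonic"))
  ## single cluster: everyone embryonic, nothing excluded
  one <- classify_subpopulations(stats::setNames(rep(1, 12), cells),
                                 stats::setNames(rep(1, 12), cells),
                                 axis, meta)
  expect_true(all(one$label == "embryonic"))
  ## the three labels partition every group
  expect_true(all(cls$label %in%
                  c("embryonic", "differentiating", "excluded")))
  expect_equal(nrow(cls), 12L)
})

test_that("raising the margin never increases differentiating calls", {
  sim <- wtko_sim()
  norm <- wtko_norm()
  n_calls <- vapply(c(0, 0.1, 0.3, 0.6), function(m)
    sum(classify_blastomeres(norm, margin = m)$label == "differentiating"),
    1.0)
  expect_true(all(diff(n_calls) <= 0))
})

test_that("labels are invariant to cell order", {
  sim <- wtko_sim()
  norm <- wtko_norm()
  cls <- classify_blastomeres(norm)
  set.seed(2)
  perm <- sample(ncol(norm))
  cls2 <- classify_blastomeres(norm[, perm])
  m <- match(cls$cell, cls2$cell)
  expect_identical(cls$label, cls2$label[m])
})

test_that("fraction test summarizes and compares per-embryo fractions", {
  ## synthetic classification: WT 4-cell half differentiating, KO none
  mk <- function(cond, stage, emb, n, ndiff) {
    data.frame(cell = paste(cond, stage, emb, seq_len(n), sep = "_"),
               condition = cond, stage = stage,
               cluster = 1, score = 0,
               label = rep(c("differentiating", "embryonic"),
                           c(ndiff, n - ndiff)),
               reason = NA, stringsAsFactors = FALSE)
  }
  wt_diff <- c(2, 2, 3, 1, 2, 2, 3, 1)   # varied per-embryo fractions
  cls <- do.call(rbind, c(
    lapply(1:8, function(e) mk("WT", 4L, e, 4, wt_diff[e])),
    lapply(1:8, function(e) mk("KO", 4L, e, 4, 0))))
  meta <- data.frame(condition = cls$condition, stage = cls$stage,
                     embryo_id = sub("_[0-9]+$", "", cls$cell),
                     row.names = cls$cell)
  res <- differentiating_fraction_test(cls, meta)
  cw <- res$counts[res$counts$condition == "WT", ]
  expect_equal(cw$percent_differentiating, 50)
  expect_lt(res$tests[["4"]]$posthoc$p, 0.001)
  ## identical fractions: p = 1
  cls0 <- do.call(rbind, c(
    lapply(1:4, function(e) mk("WT", 4L, e, 4, 2)),
    lapply(1:4, function(e) mk("KO", 4L, e, 4, 2))))
  meta0 <- data.frame(condition = cls0$condition, stage = cls0$stage,
                      embryo_id = sub("_[0-9]+$", "", cls0$cell),
                      row.names = cls0$cell)
  res0 <- differentiating_fraction_test(cls0, meta0)
  expect_gt(res0$tests[["4"]]$p, 0.5)
  ## single condition: counts only, no test
  cls1 <- do.call(rbind, lapply(1:4, function(e) mk("WT", 4L, e, 4, 2)))
  meta1 <- data.frame(condition = cls1$condition, stage = cls1$stage,
                      embryo_id = sub("_[0-9]+$", "", cls1$cell),
                      row.names = cls1$cell)
  res1 <- differentiating_fraction_test(cls1, meta1)
  expect_length(res1$tests, 0)
  expect_equal(nrow(res1$counts), 1L)
})
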