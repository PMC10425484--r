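## cells as columns of a logtpm matrix wrapped into an SCE
logtpm_sce <- function(x) {
  SingleCellExperiment(assays = list(
    counts = matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x)),
    tpm = 2^x - 1, logtpm = x))
}

test_that("correlation matrix matches the direct Pearson formula", {
  x <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
  co <- pearson_correlation_matrix(logtpm_sce(x), paste0("g", 1:4))
  ## duplicated-up-to-scale cell: r = 1; reversed cell: r = -1
  expect_equal(co$r["A", "B"], 1)
  expect_equal(co$r["A", "C"], -1)
  ## hand-computed oracle on a 3-cell x 4-gene table
  y <- matrix(c(0.5, 2.0, 1.0, 3.5,
                1.1, 0.3, 2.2, 0.9,
                2.0, 2.1, 0.1, 1.4), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
  co2 <- pearson_correlation_matrix(logtpm_sce(y), paste0("g", 1:4))
  pear <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(co2$r[i, j], pear(y[, i], y[, j]), tolerance = 1e-12)
  expect_equal(unname(diag(co2$r)), rep(1, 3))
  expect_equal(co2$r, t(co2$r))
})

test_that("zero-variance cells are excluded with a warning", {
  x <- matrix(c(1, 2, 3, 5, 5, 5, 2, 1, 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("A", "flat", "C")))
  expect_warning(co <- pearson_correlation_matrix(logtpm_sce(x),
                                                  paste0("g", 1:3)),
                 "flat")
  expect_setequal(co$cells, c("A", "C"))
  expect_identical(co$excluded, "flat")
})

test_that("correlations are invariant to per-cell affine transforms", {
  set.seed(5)
  x <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  ## positive rescaling plus a per-cell offset leaves r unchanged
  x2 <- sweep(x * 3.7, 2, rnorm(6), `+`)
  co1 <- pearson_correlation_matrix(logtpm_sce(x), paste0("g", 1:10))
  co2 <- pearson_correlation_matrix(logtpm_sce(x2), paste0("g", 1:10))
  expect_equal(co1$r, co2$r, tolerance = 1e-12)
})

test_that("average-linkage agglomeration matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    x <- matrix(rnorm(12 * n), nrow = 12,
                dimnames = list(paste0("g", 1:12), paste0("c", 1:n)))
    co <- pearson_correlation_matrix(logtpm_sce(x), paste0("g", 1:12))
    dend <- hierarchical_cluster(co)
    oracle <- naive_average_linkage(1 - co$r)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-12)
    for (k in 1:n) {
      got <- cut_tree(dend, k)
      want <- if (k == n) seq_len(n) else oracle$partitions[[k]]
      expect_equal(ari_index(got, want), 1)
    }
  }
})

test_that("identical cells merge first at height zero", {
  x <- matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("A", "Adup", "B")))
  co <- pearson_correlation_matrix(logtpm_sce(x), paste0("g", 1:3))
  dend <- hierarchical_cluster(co)
  expect_equal(dend$height[1], 0, tolerance = 1e-12)
  expect_setequal(dend$labels[-dend$merge[1, ]], c("A", "Adup"))
})

test_that("cutting the tree refines hierarchically", {
  sim <- tiny_sim()
  norm <- tpm_normalize(sim)
  co <- pearson_correlation_matrix(norm, expressed_gene_set(norm))
  dend <- hierarchical_cluster(co)
  n <- length(co$cells)
  expect_equal(length(unique(cut_tree(dend, 1))), 1L)
  expect_equal(length(unique(cut_tree(dend, n))), n)
  for (k in c(2, 4, 6)) {
    a <- cut_tree(dend, k); b <- cut_tree(dend, k + 1)
    ## k+1 refines k: cells sharing a (k+1)-cluster share the k-cluster
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
})

test_that("planted two-block correlation structure is recovered at k = 2", {
  ## block correlation matrix built directly
  r <- matrix(0.2, 12, 12)
  r[1:6, 1:6] <- 0.8; r[7:12, 7:12] <- 0.8; diag(r) <- 1
  cells <- paste0("c", 1:12)
  dimnames(r) <- list(cells, cells)
  co <- structure(list(r = r, cells = cells, gene_universe = "x",
                       excluded = character(0)), class = "corr_matrix")
  cl <- cut_tree(hierarchical_cluster(co), 2)
  expect_equal(ari_index(cl, rep(1:2, each = 6)), 1)
})

test_that("stage similarity coefficients behave at the boundaries", {
  x <- matrix(c(1, 2, 3, 1, 2, 3, 3, 1, 2), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("A", "Acopy", "B")))
  co <- pearson_correlation_matrix(logtpm_sce(x), paste0("g", 1:3))
  ## set_b is a duplicate of set_a's cell: mean r = 1
  sim <- stage_similarity(co, "A", "Acopy")
  expect_equal(sim$mean_r, 1)
  expect_error(stage_similarity(co, c("A", "B"), c("B")), "disjoint")
  expect_error(stage_similarity(co, "A", "missing"), "absent")
})

test_that("similarity anova compares per-cell coefficient vectors", {
  set.seed(9)
  mk <- function(mu) structure(list(coefficients = rnorm(20, mu, 0.05),
                                    mean_r = mu), class = "stage_comparison")
  res <- stage_similarity_anova(list(WT = mk(0.5), KO = mk(0.7)),
                                reference = "WT")
  expect_lt(res$posthoc$p, 0.01)
  expect_gt(res$posthoc$delta_vs_ref, 0.1)
  expect_lt(res$anova$p, 0.01)
})
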