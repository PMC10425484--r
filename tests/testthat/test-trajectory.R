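test_that("size factors follow the median-of-ratios definition", {
  counts <- matrix(rpois(300, 50) + 1L, nrow = 50)
  dimnames(counts) <- list(paste0("g", 1:50), paste0("c", 1:6))
  counts[, 2] <- counts[, 1] * 2L
  sf <- estimate_size_factors(counts)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  ## identical cells: all factors 1
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("c", 1:3)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))
  ## geometric mean is 1
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  ## planted depths recovered on a program-free simulation
  sim <- null_sim(12)
  sfs <- estimate_size_factors(sim)
  expect_gte(cor(sfs, sim$true_depth, method = "spearman"), 0.95)
  ## few shared genes: library-size fallback with a message
  sparse <- counts; sparse[1:45, 1] <- 0L
  expect_message(estimate_size_factors(sparse), "library-size")
  expect_error(estimate_size_factors(cbind(counts, zz = 0L)), "all-zero")
})

test_that("ordering-gene selection honours both modes", {
  sim <- tiny_sim()
  expressed <- rownames(sim)[rowSums(assay(sim, "counts")) > 0]
  picked <- select_ordering_genes(sim, "provided",
                                  gene_list = expressed[1:50])
  expect_identical(picked, expressed[1:50])
  expect_error(select_ordering_genes(sim, "provided",
                                     gene_list = c("nope1", "nope2")),
               "empty")
  expect_error(select_ordering_genes(sim, "provided"), "gene_list")
  ## dispersion mode recovers injected variable genes
  inj <- inject_variable_genes(null_sim(9), 100, 4, seed = 99)
  sel <- select_ordering_genes(inj, "dispersion")
  truth <- rownames(inj)[rowData(inj)$true_class == "variable"]
  expect_gte(mean(truth %in% sel), 0.6)
})

test_that("a 1-D gradient gives the path graph with exact ordering", {
  co <- cbind(x = 1:20, y = 0)
  rownames(co) <- paste0("c", 1:20)
  tr <- trajectory_from_coords(co, "c1")
  expect_equal(cor(tr$pseudotime, 1:20, method = "spearman"), 1)
  expect_length(tr$branch_points, 0)
  expect_equal(length(unique(tr$branch)), 1L)
  deg <- igraph::degree(tr$graph)
  expect_equal(sort(unname(deg)), c(1, 1, rep(2, 18)))
  ## pseudotime scales with the coordinates (invariant up to a factor)
  tr2 <- trajectory_from_coords(co * 3, "c1")
  expect_equal(tr2$pseudotime, tr$pseudotime * 3, tolerance = 1e-12)
  expect_identical(tr2$branch, tr$branch)
})

test_that("MST weight equals the exhaustive spanning-tree minimum", {
  set.seed(50)
  for (rep in 1:3) {
    co <- matrix(runif(14), 7, 2)
    rownames(co) <- paste0("p", 1:7)
    tr <- trajectory_from_coords(co, "p1")
    got <- sum(igraph::E(tr$graph)$weight)
    expect_equal(got, mst_weight_oracle(co), tolerance = 1e-10)
    ## tree property: n - 1 edges, connected
    expect_equal(igraph::ecount(tr$graph), 6)
    expect_true(igraph::is_connected(tr$graph))
    expect_equal(length(tr$branch_points),
                 sum(igraph::degree(tr$graph) >= 3))
  }
})

test_that("a planted Y-shape yields one branch point and clean arms", {
  arm <- function(ang, n = 15) cbind(cos(ang) * (1:n), sin(ang) * (1:n))
  co <- rbind(c(0, 0), arm(pi / 2), arm(pi + pi / 6), arm(-pi / 6))
  rownames(co) <- paste0("p", seq_len(nrow(co)))
  set.seed(60)
  co <- co + matrix(rnorm(length(co), 0, 0.05), nrow(co))
  tr <- trajectory_from_coords(co, "p2")
  expect_length(tr$branch_points, 1)
  truth <- rep(c("ctr", "a", "b", "c"), c(1, 15, 15, 15))
  ## arm recovery >= 95 percent (majority label per branch)
  acc <- sum(vapply(split(truth[-1], tr$branch[-1]),
                    function(v) max(table(v)), 1L)) / 45
  expect_gte(acc, 0.95)
})

test_that("duplicate points are jittered deterministically", {
  co <- rbind(a = c(0, 0), b = c(1, 0), b2 = c(1, 0), c = c(2, 0))
  expect_warning(tr1 <- trajectory_from_coords(co, "a"), "jitter")
  expect_warning(tr2 <- trajectory_from_coords(co, "a"), "jitter")
  expect_identical(tr1$pseudotime, tr2$pseudotime)
})

test_that("trajectory over simulated counts orders stages", {
  sim <- wtko_sim()
  wt <- sim[, sim$condition == "WT"]
  genes <- rownames(wt)[rowData(wt)$true_class %in%
                        c("stage-program", "diff-program")]
  tr <- build_trajectory(wt, genes)
  rho <- cor(tr$pseudotime[colnames(wt)], wt$stage, method = "spearman")
  expect_gte(rho, 0.8)
  ## centroid granularity gives the same coarse ordering
  trc <- build_trajectory(wt, genes, centers = 20, seed = 1)
  rhoc <- cor(trc$pseudotime[colnames(wt)], wt$stage,
              method = "spearman")
  expect_gte(rhoc, 0.7)
})

test_that("branch composition flags only real label concentrations", {
  ## uniform labels across two branches: nothing enriched
  co <- cbind(x = c(1:10, 1:10), y = rep(c(0, 5), each = 10))
  rownames(co) <- paste0("c", 1:20)
  tr <- trajectory_from_coords(co, "c1")
  lab <- stats::setNames(rep(c("u", "v"), 10), rownames(co))
  res <- branch_composition_test(tr, lab)
  expect_false(any(res$table$enriched))
  ## single branch: composition only, no test
  co1 <- cbind(x = 1:10, y = 0); rownames(co1) <- paste0("c", 1:10)
  tr1 <- trajectory_from_coords(co1, "c1")
  res1 <- branch_composition_test(tr1, stats::setNames(rep("u", 10),
                                                       rownames(co1)))
  expect_false(res1$tested)
  expect_true(all(is.na(res1$table$p)))
  expect_error(branch_composition_test(tr1, c(x = "u")), "cover")
})
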