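## Independent oracles and shared fixtures for the test suite.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

## adjusted Rand index between two partitions
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (abs(denom) < 1e-12)   # degenerate (all-one-cluster / all-singletons)
    return(if (abs(sij - e) < 1e-12) 1 else 0)
  (sij - e) / denom
}

## naive Benjamini-Hochberg step-up, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## naive average-linkage agglomeration: returns merge heights and the
## partition at every k, by exhaustive pairwise-distance recomputation
naive_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = rev(partitions))
}

## exhaustive hypergeometric upper tail by enumerating all draws
hyper_tail_oracle <- function(k, n_vg, n_de, N) {
  universe <- seq_len(N)
  vg <- seq_len(n_vg)
  draws <- utils::combn(universe, n_de)
  hits <- apply(draws, 2, function(dr) sum(dr %in% vg))
  mean(hits >= k)
}

## exhaustive minimum spanning tree total weight via Prufer sequences
mst_weight_oracle <- function(coords) {
  n <- nrow(coords)
  stopifnot(n >= 3, n <= 7)
  d <- as.matrix(dist(coords))
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 0L
    seq2 <- seq
    for (i in seq_along(seq2)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, seq2[i])
      degree[leaf] <- 0L
      degree[seq2[i]] <- degree[seq2[i]] - 1L
    }
    last <- which(degree == 1L)
    edges[n - 1, ] <- last
    edges
  }
  grids <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (row in seq_len(nrow(grids))) {
    e <- prufer_to_edges(grids[row, ])
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

## small cached simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

## a 2000 x 100 null simulation with the planted trend (no programs)
null_sim <- function(seed) {
  cfg <- sim_config(conditions = "WT", stages = 2L,
                    n_embryos_per_group = 50L, stage_program_size = 0,
                    diff_program_size = 0, diff_fraction = numeric(0),
                    marker_profiles = NULL, heterogeneity_scale = c(WT = 1),
                    n_lowdepth_cells = 0, seed = seed)
  simulate_counts(cfg)
}

## tiny SCE with hand-set tpm values
toy_tpm_sce <- function(tpm) {
  sce <- SingleCellExperiment(assays = list(
    counts = matrix(0L, nrow(tpm), ncol(tpm), dimnames = dimnames(tpm)),
    tpm = tpm, logtpm = log2(tpm + 1)))
  sce
}

## shared two-condition simulation (WT vs suppressed-heterogeneity KO)
wtko_sim <- function() {
  cached_sim("wtko", function()
    simulate_counts(sim_config(conditions = c("WT", "KO"),
                               heterogeneity_scale = c(WT = 1, KO = 0.5),
                               n_lowdepth_cells = 0, seed = 3)))
}
wtko_norm <- function() {
  cached_sim("wtko_norm", function() tpm_normalize(wtko_sim()))
}

## shared small simulation for cheap structural tests
tiny_sim <- function() {
  cached_sim("tiny", function()
    simulate_counts(sim_config(n_genes = 600, n_embryos_per_group = 2,
                               stage_program_size = 100,
                               diff_program_size = 50, seed = 11)))
}

## default nine-group design with planted low-depth cells
default14_sim <- function() {
  cached_sim("default14", function()
    simulate_counts(sim_config(n_lowdepth_cells = 14)))
}
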