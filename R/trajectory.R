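#' Median-of-ratios size factors
#'
#' Per-cell scaling factors equalizing sequencing depth: the median, over
#' genes expressed in every cell, of the ratio of the cell's count to the
#' gene-wise geometric mean, rescaled to geometric mean 1. When fewer than
#' 50 genes are expressed in all cells the estimate falls back to
#' library-size scaling (with a message).
#'
#' @param counts genes x cells count matrix, or a `SingleCellExperiment`.
#' @return Named positive numeric vector, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (any(colSums(counts) == 0)) stop("all-zero cell(s) present")
  allpos <- rowSums(counts == 0) == 0
  if (sum(allpos) >= 50) {
    lg <- log(counts[allpos, , drop = FALSE])
    ref <- rowMeans(lg)                       # log geometric mean
    sf <- exp(apply(lg - ref, 2, stats::median))
  } else {
    message("fewer than 50 genes expressed in all cells; ",
            "using library-size factors")
    sf <- colSums(counts)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Select genes for trajectory ordering
#'
#' `dispersion` mode keeps genes whose CV^2 significantly exceeds the
#' fitted overdispersion trend (FDR below `fdr_threshold`); `provided` mode
#' intersects a user gene list (e.g. the union of pathway sets and variable
#' genes) with the expressed genes of the matrix.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param mode `"dispersion"` or `"provided"`.
#' @param gene_list required in `provided` mode.
#' @param fdr_threshold variable-gene FDR cutoff in dispersion mode.
#' @return Character vector of gene ids (error when empty).
#' @export
select_ordering_genes <- function(sce, mode = c("dispersion", "provided"),
                                  gene_list = NULL, fdr_threshold = 0.1) {
  mode <- match.arg(mode)
  if (mode == "provided") {
    if (is.null(gene_list)) stop("provided mode requires gene_list")
    expressed <- rownames(sce)[rowSums(
      SummarizedExperiment::assay(sce, "counts")) > 0]
    sel <- intersect(gene_list, expressed)
  } else {
    mom <- gene_moments(sce)
    fit <- fit_cv2_trend(mom)
    hv <- call_variable_genes(mom, fit, fdr_threshold = fdr_threshold)
    sel <- hv$gene[hv$is_variable]
  }
  if (!length(sel)) stop("empty ordering gene selection")
  sel
}

## deterministic jitter keyed by cell id (stable across sessions)
.id_jitter <- function(ids, scale) {
  h <- vapply(ids, function(s)
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 9973L, 1L)
  scale * (h / 9973 - 0.5)
}

#' Build a minimum-spanning-tree trajectory
#'
#' Orders cells along a principal tree: size-factor-normalized log counts
#' of the selected genes are reduced to `d` principal components, a minimum
#' spanning tree is built over the cells (or over `centers` k-means
#' centroids) in that space, the root is set to the node nearest the
#' centroid of the root stage, pseudotime is the tree path length from the
#' root, and branches are the tree segments delimited by nodes of degree
#' >= 3 (branch points). Duplicate points are deterministically jittered
#' (keyed by cell id) with a warning.
#'
#' @param sce a `SingleCellExperiment` with `counts`; `colData` column
#'   `stage` is used for rooting.
#' @param genes ordering gene set.
#' @param d number of principal components (default 2).
#' @param centers `NULL` for per-cell granularity (default), else the
#'   number of k-means centroids.
#' @param root_stage stage code whose centroid anchors the root (default
#'   the smallest stage present).
#' @param seed seed for k-means (centroid mode only).
#' @return A list of class `trajectory_graph`: `graph` (igraph tree over
#'   nodes), `nodes`, `cell_node` (cell -> node), `root`, `pseudotime`
#'   (per cell), `branch` (per cell), `branch_points` (node names),
#'   `coords` (node coordinates).
#' @export
build_trajectory <- function(sce, genes, d = 2, centers = NULL,
                             root_stage = NULL, seed = 0L) {
  stopifnot(ncol(sce) >= 3, length(genes) >= 2)
  counts <- SummarizedExperiment::assay(sce, "counts")
  sf <- estimate_size_factors(counts)
  x <- log2(sweep(counts[genes, , drop = FALSE], 2, sf, `/`) + 1)
  d <- min(d, length(genes), ncol(x) - 1)
  pc <- stats::prcomp(t(x), rank. = d)
  coords <- pc$x[, seq_len(d), drop = FALSE]
  stage <- SummarizedExperiment::colData(sce)$stage
  if (is.null(root_stage)) root_stage <- min(stage)

  if (is.null(centers)) {
    node_coords <- coords
    cell_node <- stats::setNames(rownames(coords), rownames(coords))
  } else {
    set.seed(seed)
    km <- stats::kmeans(coords, centers = centers, nstart = 5)
    node_coords <- km$centers
    rownames(node_coords) <- paste0("centroid", seq_len(nrow(node_coords)))
    cell_node <- stats::setNames(rownames(node_coords)[km$cluster],
                                 rownames(coords))
  }
  root_cells <- colnames(sce)[stage == root_stage]
  if (!length(root_cells)) stop("no cells at root stage ", root_stage)
  root_centroid <- colMeans(coords[root_cells, , drop = FALSE])
  root <- rownames(node_coords)[which.min(
    colSums((t(node_coords) - root_centroid)^2))]
  trajectory_from_coords(node_coords, root, cell_node = cell_node)
}

#' Build an MST trajectory from explicit coordinates
#'
#' Lower-level constructor behind [build_trajectory()]: minimum spanning
#' tree over the Euclidean complete graph of the given points, pseudotime
#' as tree path length from the root node, branch points as nodes of
#' degree >= 3, and branch labels as the tree segments they delimit (each
#' branch point inherits the label of its rootward neighbor).
#'
#' @param coords nodes x dimensions numeric matrix with unique rownames.
#' @param root rowname of the root node.
#' @param cell_node named map cell id -> node name (default: nodes are the
#'   cells themselves).
#' @return A `trajectory_graph`; see [build_trajectory()].
#' @export
trajectory_from_coords <- function(coords, root,
                                   cell_node =
                                     stats::setNames(rownames(coords),
                                                     rownames(coords))) {
  stopifnot(nrow(coords) >= 2, !is.null(rownames(coords)),
            root %in% rownames(coords))
  node_coords <- as.matrix(coords)
  dup <- duplicated(node_coords)
  if (any(dup)) {
    warning(sum(dup), " duplicate point(s) jittered deterministically")
    rng <- max(apply(node_coords, 2, function(v) diff(range(v))), 1e-6)
    for (j in seq_len(ncol(node_coords)))
      node_coords[dup, j] <- node_coords[dup, j] +
        .id_jitter(rownames(node_coords)[dup], 1e-6 * rng) * j
  }

  dm <- as.matrix(stats::dist(node_coords))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)

  pt_nodes <- igraph::distances(mst, v = root,
                                weights = igraph::E(mst)$weight)[1, ]
  deg <- igraph::degree(mst)
  bp <- names(deg)[deg >= 3]

  ## branch labels: components after removing branch points; each branch
  ## point inherits the label of its rootward neighbor
  node_branch <- rep(NA_integer_, nrow(node_coords))
  names(node_branch) <- rownames(node_coords)
  keep <- setdiff(rownames(node_coords), bp)
  if (length(keep)) {
    sub <- igraph::induced_subgraph(mst, keep)
    comp <- igraph::components(sub)$membership
    node_branch[names(comp)] <- comp
  }
  for (b in bp[order(pt_nodes[bp])]) {
    nbrs <- names(igraph::neighbors(mst, b))
    parent <- nbrs[which.min(pt_nodes[nbrs])]
    node_branch[b] <- if (!is.na(node_branch[parent])) node_branch[parent]
                      else max(node_branch, na.rm = TRUE) + 1L
  }
  if (anyNA(node_branch)) node_branch[is.na(node_branch)] <- 1L

  pseudotime <- pt_nodes[cell_node]
  branch <- node_branch[cell_node]
  names(pseudotime) <- names(branch) <- names(cell_node)
  structure(list(graph = mst, nodes = rownames(node_coords),
                 cell_node = cell_node, root = root,
                 pseudotime = pseudotime, branch = branch,
                 branch_points = bp, coords = node_coords),
            class = "trajectory_graph")
}

#' Branch composition enrichment
#'
#' Tests, per branch x label, whether the branch is enriched for cells of
#' that label (hypergeometric upper tail over all cells in the trajectory),
#' with Benjamini-Hochberg adjustment over all branch-label pairs. With a
#' single branch no test is run and only the composition table is
#' returned.
#'
#' @param traj a `trajectory_graph`.
#' @param labels named character vector, cell id -> label (e.g. a
#'   classification label or `<stage>:<subpop>`).
#' @param bh_threshold FDR threshold for the `enriched` flag.
#' @return A list: `table` (data frame `branch`, `label`, `n_branch`,
#'   `n_label`, `n_overlap`, `p`, `fdr`, `enriched`), `tested` (logical).
#' @export
branch_composition_test <- function(traj, labels, bh_threshold = 0.05) {
  stopifnot(inherits(traj, "trajectory_graph"))
  cells <- names(traj$branch)
  if (!all(cells %in% names(labels)))
    stop("labels must cover every cell in the trajectory")
  lab <- labels[cells]
  br <- traj$branch
  N <- length(cells)
  grid <- expand.grid(branch = sort(unique(br)),
                      label = sort(unique(lab)),
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$branch[i]; l <- grid$label[i]
    nb <- sum(br == b); nl <- sum(lab == l)
    k <- sum(br == b & lab == l)
    data.frame(branch = b, label = l, n_branch = nb, n_label = nl,
               n_overlap = k,
               p = stats::phyper(k - 1, nl, N - nl, nb,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  tested <- length(unique(br)) > 1
  if (tested) {
    tab$fdr <- bh_adjust(tab$p)
    tab$enriched <- tab$fdr < bh_threshold
  } else {
    tab$p <- NA_real_; tab$fdr <- NA_real_; tab$enriched <- FALSE
  }
  list(table = tab, tested = tested)
}
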