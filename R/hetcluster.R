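#' Cell-cell Pearson correlation matrix
#'
#' Pairwise Pearson correlation of log-transformed expression between all
#' cells, over a stated gene universe (e.g. the expressed set from
#' [expressed_gene_set()]). Cells with zero variance over the universe
#' cannot be correlated; they are excluded with a warning and recorded.
#'
#' @param sce a normalized object from [tpm_normalize()].
#' @param genes character vector, the gene universe (>= 2 genes).
#' @param cells optional subset of cell ids.
#' @return A list of class `corr_matrix`: `r` (symmetric cells x cells
#'   matrix, unit diagonal), `cells`, `gene_universe`, `excluded`.
#' @export
pearson_correlation_matrix <- function(sce, genes, cells = NULL) {
  stopifnot(length(genes) >= 2)
  x <- SummarizedExperiment::assay(sce, "logtpm")[genes, , drop = FALSE]
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 cells")
  sds <- apply(x, 2, stats::sd)
  excluded <- colnames(x)[sds == 0]
  if (length(excluded)) {
    warning("excluding zero-variance cell(s): ",
            paste(excluded, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(x)
  structure(list(r = r, cells = colnames(x), gene_universe = genes,
                 excluded = excluded),
            class = "corr_matrix")
}

#' Hierarchical clustering of cells with 1 - r distance
#'
#' Agglomerative clustering of the cells of a correlation matrix using
#' `1 - Pearson's r` as the distance.
#'
#' @param corr a `corr_matrix`.
#' @param linkage `"average"` (default), `"complete"` or `"ward.D2"`.
#' @return An [stats::hclust] tree (leaves labeled by cell id).
#' @export
hierarchical_cluster <- function(corr,
                                 linkage = c("average", "complete",
                                             "ward.D2")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(corr, "corr_matrix"))
  n <- length(corr$cells)
  if (n < 2) stop("need at least 2 cells to cluster")
  d <- stats::as.dist(1 - corr$r)
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Wraps [stats::cutree()], relabeling clusters 1..k in order of first
#' appearance along the dendrogram's leaf order so ids are stable.
#'
#' @param dend an `hclust` tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector, cell id -> cluster id.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$labels)
  stopifnot(k >= 1, k <= n)
  cl <- stats::cutree(dend, k = k)
  ord <- dend$labels[dend$order]
  first_seen <- unique(cl[ord])
  remap <- stats::setNames(seq_along(first_seen), first_seen)
  out <- remap[as.character(cl)]
  names(out) <- names(cl)
  out
}

#' Export a dendrogram as Newick
#'
#' @param dend an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Per-cell cross-set correlation coefficients
#'
#' For each cell of `set_a`, the mean Pearson correlation to all cells of
#' `set_b` — the unit of the between-stage similarity comparison (e.g.
#' 4-cell cells against the 2-cell cluster: higher mean r means the two
#' stages are more similar, i.e. the population is less heterogeneous).
#'
#' @param corr a `corr_matrix` containing all involved cells.
#' @param set_a,set_b disjoint, nonempty cell id sets.
#' @return A list of class `stage_comparison`: `set_a`, `set_b`,
#'   `coefficients` (named, length `|set_a|`), `mean_r`.
#' @export
stage_similarity <- function(corr, set_a, set_b) {
  stopifnot(inherits(corr, "corr_matrix"),
            length(set_a) >= 1, length(set_b) >= 1)
  if (length(intersect(set_a, set_b)))
    stop("set_a and set_b must be disjoint")
  missing <- setdiff(c(set_a, set_b), corr$cells)
  if (length(missing))
    stop("cells absent from the correlation matrix: ",
         paste(missing, collapse = ", "))
  coef <- rowMeans(corr$r[set_a, set_b, drop = FALSE])
  structure(list(set_a = set_a, set_b = set_b, coefficients = coef,
                 mean_r = mean(coef)),
            class = "stage_comparison")
}

#' Compare between-stage similarity across conditions
#'
#' One-way ANOVA over the per-cell coefficient vectors of several
#' [stage_similarity()] comparisons (one per condition), followed by
#' pairwise two-sided Welch t-tests of every condition against the
#' reference.
#'
#' @param comparisons named list of `stage_comparison` objects, one per
#'   condition.
#' @param reference name of the reference condition (default first).
#' @return List with `anova` (`statistic`, `p`), `posthoc` (data frame:
#'   `condition`, `mean_r`, `delta_vs_ref`, `p`), `reference`.
#' @export
stage_similarity_anova <- function(comparisons,
                                   reference = names(comparisons)[1]) {
  stopifnot(length(comparisons) >= 2, !is.null(names(comparisons)),
            reference %in% names(comparisons))
  vals <- unlist(lapply(comparisons, `[[`, "coefficients"))
  grp <- factor(rep(names(comparisons),
                    vapply(comparisons,
                           function(x) length(x$coefficients), 1L)))
  fit <- stats::anova(stats::lm(vals ~ grp))
  ref <- comparisons[[reference]]$coefficients
  others <- setdiff(names(comparisons), reference)
  posthoc <- do.call(rbind, lapply(others, function(cond) {
    x <- comparisons[[cond]]$coefficients
    tt <- stats::t.test(x, ref)
    data.frame(condition = cond, mean_r = mean(x),
               delta_vs_ref = mean(x) - mean(ref), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(anova = list(statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1]),
       posthoc = posthoc, reference = reference)
}

## mean cross-set Pearson r on a logtpm matrix restricted to a gene universe
.mean_cross_r <- function(x, cells_a, cells_b) {
  mean(stats::cor(x[, cells_a, drop = FALSE], x[, cells_b, drop = FALSE]))
}

#' Permutation test for condition differences in between-stage similarity
#'
#' Calibrated alternative to the per-cell ANOVA of
#' [stage_similarity_anova()]: the per-cell cross-set coefficients within a
#' condition are positively correlated (every cell of stage A is compared
#' against the same realized stage-B set), so cell-level t-tests overstate
#' significance. Here the observed statistic is the difference in mean
#' stage-A-vs-stage-B correlation between each condition and the reference
#' (correlation matrices computed within condition), and its null
#' distribution is generated by permuting embryo condition labels within
#' stage — embryos being the independent sampling unit.
#'
#' @param sce a normalized object with `condition`, `stage`, `embryo_id` in
#'   `colData`.
#' @param genes gene universe for the correlations.
#' @param stage_a,stage_b the two stages compared (coefficients are stage-A
#'   cells vs stage-B cells).
#' @param reference reference condition (default `"WT"` when present).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return Data frame: `condition`, `mean_r`, `ref_mean_r`, `delta`, `p`
#'   (two-sided permutation p-value).
#' @export
stage_similarity_permutation_test <- function(sce, genes, stage_a, stage_b,
                                              reference = NULL,
                                              n_perm = 199, seed = 0L) {
  cd <- SummarizedExperiment::colData(sce)
  keep <- cd$stage %in% c(stage_a, stage_b)
  x <- SummarizedExperiment::assay(sce, "logtpm")[genes, keep, drop = FALSE]
  meta <- data.frame(cell = colnames(sce)[keep],
                     condition = cd$condition[keep], stage = cd$stage[keep],
                     embryo_id = cd$embryo_id[keep],
                     stringsAsFactors = FALSE)
  conds <- unique(meta$condition)
  if (length(conds) < 2) stop("need at least two conditions")
  if (is.null(reference))
    reference <- if ("WT" %in% conds) "WT" else conds[1]
  mean_r_of <- function(cond_of_cell) {
    vapply(conds, function(cn) {
      a <- meta$cell[cond_of_cell == cn & meta$stage == stage_a]
      b <- meta$cell[cond_of_cell == cn & meta$stage == stage_b]
      .mean_cross_r(x, a, b)
    }, 1.0)
  }
  obs <- mean_r_of(meta$condition)
  delta_obs <- obs - obs[reference]
  ## permute embryo condition labels within stage
  emb <- unique(meta[, c("embryo_id", "condition", "stage")])
  set.seed(seed)
  exceed <- numeric(length(conds)); names(exceed) <- conds
  for (i in seq_len(n_perm)) {
    pe <- emb
    for (st in unique(emb$stage)) {
      j <- which(emb$stage == st)
      pe$condition[j] <- sample(emb$condition[j])
    }
    perm_cond <- pe$condition[match(meta$embryo_id, pe$embryo_id)]
    pr <- mean_r_of(perm_cond)
    pd <- pr - pr[reference]
    exceed <- exceed + (abs(pd) >= abs(delta_obs))
  }
  p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(condition = setdiff(conds, reference),
                    mean_r = obs[setdiff(conds, reference)],
                    ref_mean_r = obs[reference],
                    delta = delta_obs[setdiff(conds, reference)],
                    p = p[setdiff(conds, reference)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
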