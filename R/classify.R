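#' Embed cells in three dimensions
#'
#' Low-dimensional embedding of cells over a chosen gene universe. `pca`
#' (the deterministic default) takes the first three principal components of
#' log expression; `tsne` runs seeded Barnes-Hut t-SNE (requires the
#' `Rtsne` package) with configurable perplexity.
#'
#' @param sce a normalized object from [tpm_normalize()].
#' @param genes gene universe (>= 3 genes).
#' @param method `"pca"` or `"tsne"`.
#' @param seed integer seed (t-SNE is stochastic; PCA ignores it).
#' @param perplexity t-SNE perplexity.
#' @param cells optional cell subset.
#' @return A list of class `embedding`: `coords` (cells x 3), `cells`,
#'   `method`, `seed`.
#' @export
embed_cells <- function(sce, genes, method = c("pca", "tsne"), seed = 0L,
                        perplexity = 10, cells = NULL) {
  method <- match.arg(method)
  stopifnot(length(genes) >= 3)
  x <- SummarizedExperiment::assay(sce, "logtpm")[genes, , drop = FALSE]
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  if (ncol(x) < 4) stop("need more cells than embedding dimensions")
  if (method == "pca") {
    pc <- stats::prcomp(t(x), rank. = 3)
    coords <- pc$x[, 1:3, drop = FALSE]
  } else {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("method 'tsne' requires the Rtsne package")
    set.seed(seed)
    ts <- Rtsne::Rtsne(t(x), dims = 3, perplexity = perplexity,
                       check_duplicates = FALSE, pca = TRUE)
    coords <- ts$Y
    rownames(coords) <- colnames(x)
  }
  colnames(coords) <- paste0("dim", 1:3)
  structure(list(coords = coords, cells = colnames(x), method = method,
                 seed = as.integer(seed)),
            class = "embedding")
}

#' Fit a developmental axis through an embedding
#'
#' Least-squares regression of the numeric stage codes (2/4/8) onto the
#' embedding coordinates; the normalized coefficient vector is the
#' developmental direction and each cell's *advancement score* is its
#' projection onto it. The fit fails unless the per-stage mean scores are
#' strictly increasing with stage.
#'
#' @param embedding an `embedding` object.
#' @param stages numeric stage code per cell (named by cell id, or in the
#'   embedding's cell order).
#' @return A list of class `dev_axis`: `direction` (unit 3-vector), `score`
#'   (named per-cell), `centroids` (named per-stage mean score, increasing).
#' @export
fit_developmental_axis <- function(embedding, stages) {
  stopifnot(inherits(embedding, "embedding"))
  if (!is.null(names(stages))) stages <- stages[embedding$cells]
  stages <- as.numeric(stages)
  if (length(unique(stages)) < 2) stop("need at least two stages")
  coords <- embedding$coords
  if (any(apply(coords, 2, stats::sd) == 0) && all(apply(coords, 2, stats::sd) == 0))
    stop("degenerate embedding: zero variance")
  beta <- stats::coef(stats::lm(stages ~ coords))[-1]
  beta[is.na(beta)] <- 0
  if (sum(beta^2) == 0) stop("degenerate fit: no direction")
  direction <- beta / sqrt(sum(beta^2))
  score <- drop(coords %*% direction)
  names(score) <- embedding$cells
  cent <- tapply(score, stages, mean)
  cent <- cent[order(as.numeric(names(cent)))]
  if (any(diff(cent) <= 0))
    stop("developmental axis fit failed: stage centroids are not strictly ",
         "increasing (", paste(signif(cent, 4), collapse = " -> "), ")")
  structure(list(direction = direction, score = score, centroids = cent),
            class = "dev_axis")
}

## threshold and centroid gap for one stage on the fitted axis
.stage_gap <- function(centroids, stage) {
  sts <- as.numeric(names(centroids))
  i <- match(stage, sts)
  if (is.na(i)) stop("stage ", stage, " absent from axis centroids")
  if (i < length(sts)) centroids[i + 1] - centroids[i]
  else centroids[i] - centroids[i - 1]
}

#' Classify blastomeres as embryonic or differentiating
#'
#' Consensus rule combining cluster membership and position on the
#' developmental axis, applied independently within every condition x stage
#' group:
#'
#' 1. Each stage's cells take their cluster assignment from
#'    `cluster_map_substage` for all but the highest stage and from
#'    `cluster_map_allstage` for the highest stage.
#' 2. If a group's cells span more than one cluster, the candidate
#'    *advanced* cluster is the one with the highest mean advancement score;
#'    it is only declared advanced when its scores significantly exceed the
#'    rest of the group (one-sided Welch test, `p < alpha`).
#' 3. A cell is `differentiating` when it sits in the advanced cluster *and*
#'    its own score exceeds its stage centroid by at least
#'    `margin * (between-stage centroid gap)`; `embryonic` when both
#'    indicators are negative; `excluded` when the two disagree.
#'
#' Groups whose cells fall into a single cluster, or in which no cluster
#' passes the advancement test, have no advanced cluster: all their cells
#' are `embryonic`.
#'
#' @param cluster_map_allstage,cluster_map_substage named cell -> cluster id
#'   maps (e.g. from [cut_tree()]); the substage map must cover all but the
#'   highest stage, the all-stage map every cell.
#' @param axis a `dev_axis` covering the same cells.
#' @param meta data frame with rownames = cell ids and columns `condition`,
#'   `stage`.
#' @param margin nonnegative stringency on the positional indicator.
#' @param alpha significance level for declaring an advanced cluster.
#' @return Data frame (one row per cell): `cell`, `condition`, `stage`,
#'   `cluster`, `score`, `label`, `reason`.
#' @export
classify_subpopulations <- function(cluster_map_allstage,
                                    cluster_map_substage, axis, meta,
                                    margin = 0, alpha = 0.01) {
  stopifnot(inherits(axis, "dev_axis"), margin >= 0)
  cells <- rownames(meta)
  if (!all(cells %in% names(axis$score)))
    stop("axis does not cover all cells in meta")
  top_stage <- max(meta$stage)
  out <- data.frame(cell = cells, condition = meta$condition,
                    stage = meta$stage, cluster = NA_integer_,
                    score = unname(axis$score[cells]),
                    label = "embryonic", reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (cond in unique(meta$condition)) {
    for (st in unique(meta$stage[meta$condition == cond])) {
      idx <- which(out$condition == cond & out$stage == st)
      grp_cells <- out$cell[idx]
      map <- if (st == top_stage) cluster_map_allstage else
        cluster_map_substage
      if (!all(grp_cells %in% names(map)))
        stop("cluster map does not cover cells of group ", cond, ":", st)
      cl <- map[grp_cells]
      out$cluster[idx] <- unname(cl)
      if (length(unique(cl)) < 2) next      # single cluster: all embryonic
      sc <- out$score[idx]
      cl_means <- tapply(sc, cl, mean)
      cand <- names(cl_means)[which.max(cl_means)]
      in_cand <- cl == cand
      if (sum(in_cand) < 2 || sum(!in_cand) < 2) next
      p_adv <- stats::t.test(sc[in_cand], sc[!in_cand],
                             alternative = "greater")$p.value
      if (p_adv >= alpha) next              # no advanced cluster declared
      thr <- axis$centroids[as.character(st)] +
        margin * .stage_gap(axis$centroids, st)
      high <- sc >= thr
      lab <- ifelse(in_cand & high, "differentiating",
                    ifelse(!in_cand & !high, "embryonic", "excluded"))
      out$label[idx] <- lab
      out$reason[idx][lab == "excluded"] <- "cluster/position mismatch"
    }
  }
  out
}

#' End-to-end blastomere classification
#'
#' Convenience driver: per condition, builds correlation matrices over the
#' expressed-gene universe (all stages; all-but-highest stages), cuts them
#' at `k`, fits the developmental axis on a pooled embedding, and runs
#' [classify_subpopulations()].
#'
#' @param sce a normalized object with `condition` and `stage` in `colData`.
#' @param genes gene universe for correlations and the embedding; defaults
#'   to the expressed set (TPM >= 1).
#' @param k clusters per within-condition dendrogram cut. The default is
#'   deliberately granular: loose outlying cells otherwise absorb the cut's
#'   splits and a real subcluster can go undetected, while surplus clusters
#'   are harmless because a cluster is only treated as advanced after
#'   passing the advancement test.
#' @param margin,alpha passed to [classify_subpopulations()].
#' @param method,seed passed to [embed_cells()].
#' @return As [classify_subpopulations()].
#' @export
classify_blastomeres <- function(sce, genes = NULL, k = 8, margin = 0,
                                 alpha = 0.01, method = "pca", seed = 0L) {
  if (is.null(genes)) genes <- expressed_gene_set(sce)
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  emb <- embed_cells(sce, genes, method = method, seed = seed)
  axis <- fit_developmental_axis(emb,
                                 stats::setNames(meta$stage, rownames(meta)))
  top_stage <- max(meta$stage)
  map_all <- integer(0)
  map_sub <- integer(0)
  for (cond in unique(meta$condition)) {
    cl_cells <- rownames(meta)[meta$condition == cond]
    corr <- pearson_correlation_matrix(sce, genes, cells = cl_cells)
    kk <- min(k, length(corr$cells))
    m <- cut_tree(hierarchical_cluster(corr), kk)
    map_all <- c(map_all, m + length(map_all) + length(map_sub))
    sub_cells <- rownames(meta)[meta$condition == cond &
                                meta$stage < top_stage]
    if (length(sub_cells) >= 2) {
      corr2 <- pearson_correlation_matrix(sce, genes, cells = sub_cells)
      kk2 <- min(k, length(corr2$cells))
      m2 <- cut_tree(hierarchical_cluster(corr2), kk2)
      map_sub <- c(map_sub, m2 + length(map_all) + length(map_sub))
    }
  }
  classify_subpopulations(map_all, map_sub, axis, meta,
                          margin = margin, alpha = alpha)
}

#' Subpopulation counts and cross-condition fraction tests
#'
#' Summarizes a classification into per-group counts and percent
#' differentiating cells, then — treating the embryo as the sampling unit —
#' tests, per stage, whether the per-embryo differentiating fraction differs
#' across conditions (one-way ANOVA) with post-hoc two-sided Welch t-tests
#' of each condition against the reference.
#'
#' @param classification output of [classify_subpopulations()].
#' @param meta data frame with rownames = cell ids and columns `condition`,
#'   `stage`, `embryo_id`.
#' @param reference reference condition (default `"WT"` when present).
#' @return List with `counts` (per group: `n_embryonic`,
#'   `n_differentiating`, `n_excluded`, `percent_differentiating`) and
#'   `tests` (per stage: ANOVA `F`, `p`, and post-hoc data frame), plus
#'   `embryo_fractions`.
#' @export
differentiating_fraction_test <- function(classification, meta,
                                          reference = NULL) {
  cls <- classification
  meta <- meta[cls$cell, , drop = FALSE]
  cls$embryo_id <- meta$embryo_id
  counts <- do.call(rbind, lapply(
    split(cls, paste(cls$condition, cls$stage, sep = ":")),
    function(g) data.frame(condition = g$condition[1], stage = g$stage[1],
                           n_embryonic = sum(g$label == "embryonic"),
                           n_differentiating =
                             sum(g$label == "differentiating"),
                           n_excluded = sum(g$label == "excluded"),
                           percent_differentiating =
                             100 * mean(g$label == "differentiating"),
                           stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  fr <- do.call(rbind, lapply(split(cls, cls$embryo_id), function(e)
    data.frame(embryo_id = e$embryo_id[1], condition = e$condition[1],
               stage = e$stage[1],
               fraction = mean(e$label == "differentiating"),
               stringsAsFactors = FALSE)))
  rownames(fr) <- NULL
  conds <- unique(cls$condition)
  if (is.null(reference))
    reference <- if ("WT" %in% conds) "WT" else conds[1]
  tests <- list()
  for (st in unique(cls$stage)) {
    sub <- fr[fr$stage == st, ]
    ok_conds <- names(which(table(sub$condition) >= 2))
    if (length(ok_conds) < 2 || !(reference %in% ok_conds)) {
      if (length(unique(sub$condition)) >= 2)
        warning("stage ", st, ": fewer than 2 embryos in some condition; ",
                "comparison skipped")
      next
    }
    sub <- sub[sub$condition %in% ok_conds, ]
    if (stats::var(sub$fraction) == 0) {
      ## identical fractions everywhere: no evidence of a difference
      tests[[as.character(st)]] <- list(
        F = 0, p = 1,
        posthoc = data.frame(condition = setdiff(ok_conds, reference),
                             mean_fraction = mean(sub$fraction),
                             ref_fraction = mean(sub$fraction), p = 1,
                             stringsAsFactors = FALSE))
      next
    }
    ## near-perfect fits (e.g. one condition uniformly zero) trigger a
    ## precision warning from anova.lm; the exact-zero case is handled above
    fit <- suppressWarnings(
      stats::anova(stats::lm(fraction ~ condition, data = sub)))
    posthoc <- do.call(rbind, lapply(setdiff(ok_conds, reference),
                                     function(cond) {
      x <- sub$fraction[sub$condition == cond]
      y <- sub$fraction[sub$condition == reference]
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else stats::t.test(x, y)$p.value
      data.frame(condition = cond, mean_fraction = mean(x),
                 ref_fraction = mean(y), p = p, stringsAsFactors = FALSE)
    }))
    tests[[as.character(st)]] <- list(F = fit$`F value`[1],
                                      p = fit$`Pr(>F)`[1],
                                      posthoc = posthoc)
  }
  list(counts = counts, tests = tests, embryo_fractions = fr,
       reference = reference)
}
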