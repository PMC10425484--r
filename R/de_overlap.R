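#' Differential expression between two cell groups
#'
#' Per-gene two-sided test on `log2(TPM + pseudocount)` between two cell
#' sets: Welch's t-test (default, vectorized) or Wilcoxon rank-sum.
#' Log fold change is `mean_a - mean_b` in log2 TPM units. Genes with zero
#' variance on both sides get `p = 1` when the means agree and `p = 0`
#' otherwise (never `NA`). FDR is Benjamini-Hochberg across tested genes.
#'
#' @param sce a normalized object from [tpm_normalize()].
#' @param cells_a,cells_b disjoint cell id sets, >= 2 cells each.
#' @param method `"welch_t"` or `"wilcoxon"`.
#' @param genes optional gene universe (default all genes).
#' @return Data frame (class `de_result`): `gene`, `mean_a`, `mean_b`,
#'   `lfc`, `p`, `fdr`.
#' @export
differential_expression <- function(sce, cells_a, cells_b,
                                    method = c("welch_t", "wilcoxon"),
                                    genes = NULL) {
  method <- match.arg(method)
  stopifnot(length(cells_a) >= 2, length(cells_b) >= 2)
  if (length(intersect(cells_a, cells_b)))
    stop("cells_a and cells_b must be disjoint")
  x <- SummarizedExperiment::assay(sce, "logtpm")
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  a <- x[, cells_a, drop = FALSE]
  b <- x[, cells_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  if (method == "welch_t") {
    va <- rowSums((a - ma)^2) / (na - 1)
    vb <- rowSums((b - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  } else {
    p <- vapply(seq_len(nrow(x)), function(i) {
      if (stats::sd(a[i, ]) == 0 && stats::sd(b[i, ]) == 0)
        return(if (ma[i] == mb[i]) 1 else 0)
      suppressWarnings(stats::wilcox.test(a[i, ], b[i, ])$p.value)
    }, 1.0)
  }
  out <- data.frame(gene = rownames(x), mean_a = unname(ma),
                    mean_b = unname(mb), lfc = unname(ma - mb),
                    p = unname(p), fdr = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; monotone in p and never below the raw p.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of drawing at least the observed overlap:
#' `p = P[X >= |vg & de|]` with `X ~ Hypergeometric(N, |vg|, |de|)` over a
#' stated universe — e.g. the significance of the variable-gene /
#' differentially-expressed-gene intersection.
#'
#' @param vg,de gene sets, both subsets of `universe`.
#' @param universe the gene universe.
#' @return A list of class `overlap_result`: `n_vg`, `n_de`, `n_overlap`,
#'   `n_universe`, `p`.
#' @export
overlap_test <- function(vg, de, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  vg <- unique(vg); de <- unique(de)
  if (length(setdiff(vg, universe)) || length(setdiff(de, universe)))
    stop("vg and de must be subsets of the universe")
  k <- length(intersect(vg, de))
  N <- length(universe)
  p <- stats::phyper(k - 1, length(vg), N - length(vg), length(de),
                     lower.tail = FALSE)
  structure(list(n_vg = length(vg), n_de = length(de), n_overlap = k,
                 n_universe = N, p = p),
            class = "overlap_result")
}

#' Per-gene group statistics: ANOVA plus post-hoc contrasts
#'
#' For one gene, a one-way ANOVA of `log2(TPM + pseudocount)` across the
#' given grouping, followed by two-sided Welch t-tests for a list of named
#' pairwise contrasts (e.g. the dot-plot comparison codes: each condition's
#' bulk vs the reference bulk, a stage vs its precedent stage, a
#' differentiating subpopulation vs its embryonic sibling). Contrasts whose
#' groups are missing or have fewer than 2 cells are skipped with a note.
#'
#' @param sce a normalized object from [tpm_normalize()].
#' @param gene gene id.
#' @param grouping named factor/character vector, cell id -> group.
#' @param contrasts named list of two-element group-name vectors.
#' @return A list of class `group_stats`: `gene`, `group_means`, `F`, `p`,
#'   `posthoc` (data frame `contrast`, `group_a`, `group_b`, `delta`, `p`),
#'   `skipped`.
#' @export
groupwise_anova <- function(sce, gene, grouping, contrasts = list()) {
  x <- SummarizedExperiment::assay(sce, "logtpm")[gene, names(grouping)]
  g <- factor(grouping)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 cells")
  fit <- stats::anova(stats::lm(x ~ g))
  means <- tapply(x, g, mean)
  skipped <- character(0)
  posthoc <- NULL
  for (nm in names(contrasts)) {
    pair <- contrasts[[nm]]
    if (!all(pair %in% levels(g)) ||
        any(table(g)[pair] < 2)) {
      skipped <- c(skipped, nm)
      next
    }
    xa <- x[g == pair[1]]; xb <- x[g == pair[2]]
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xa) == mean(xb)) 1 else 0
    } else stats::t.test(xa, xb)$p.value
    posthoc <- rbind(posthoc,
                     data.frame(contrast = nm, group_a = pair[1],
                                group_b = pair[2],
                                delta = mean(xa) - mean(xb), p = p,
                                stringsAsFactors = FALSE))
  }
  structure(list(gene = gene, group_means = means,
                 F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
                 posthoc = posthoc, skipped = skipped),
            class = "group_stats")
}

#' Dot-plot contrast presets
#'
#' Builds the named pairwise contrasts used in marker dot plots from group
#' labels of the form `<condition>:<stage>` (bulk) or
#' `<condition>:<stage>:<subpop>`:
#' * `*<cond>:<stage>` — condition bulk vs reference bulk, same stage;
#' * `#<cond>:<stage>` — bulk vs the precedent stage's bulk, same condition.
#'
#' @param groups character vector of group labels present.
#' @param reference reference condition (default `"WT"`).
#' @param stages ordered stage codes.
#' @return Named list of two-element group-name vectors.
#' @export
preset_contrasts <- function(groups, reference = "WT",
                             stages = c(2, 4, 8)) {
  out <- list()
  parts <- strsplit(groups, ":", fixed = TRUE)
  conds <- unique(vapply(parts, `[[`, "", 1))
  for (st in stages) {
    for (cond in setdiff(conds, reference)) {
      a <- paste(cond, st, sep = ":"); b <- paste(reference, st, sep = ":")
      if (all(c(a, b) %in% groups))
        out[[paste0("*", a)]] <- c(a, b)
    }
    prev <- stages[match(st, stages) - 1]
    if (length(prev) && !is.na(prev)) {
      for (cond in conds) {
        a <- paste(cond, st, sep = ":"); b <- paste(cond, prev, sep = ":")
        if (all(c(a, b) %in% groups))
          out[[paste0("#", a)]] <- c(a, b)
      }
    }
  }
  out
}
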