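#' Per-gene mean and squared coefficient of variation
#'
#' Computes, per gene over a set of cells, the mean `mu` and
#' `CV^2 = sample variance / mu^2` of size-factor-normalized counts (counts
#' divided by [estimate_size_factors()] factors), the scale on which the
#' overdispersion trend CV^2 = a1/mu + a0 is modeled. Genes with `mu = 0`
#' have undefined CV^2 (`NA`).
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param cells optional subset of cell ids (>= 3 cells).
#' @param size_factors optional precomputed per-cell factors.
#' @return Data frame: `gene`, `mu`, `cv2`, `n_cells`.
#' @export
gene_moments <- function(sce, cells = NULL, size_factors = NULL) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  if (ncol(counts) < 3) stop("need at least 3 cells")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, `/`)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  data.frame(gene = rownames(counts), mu = unname(mu), cv2 = unname(cv2),
             n_cells = ncol(counts), stringsAsFactors = FALSE)
}

#' Fit the CV^2-mean overdispersion trend
#'
#' Fits the parametric trend `CV^2 = a1/mu + a0` over genes whose mean lies
#' above a quantile floor, by a gamma-family generalized linear model of
#' CV^2 on 1/mu with identity link (robust to the heavy right tail of
#' CV^2); an ordinary least squares fit is available as a fallback method.
#' If the fitted trend is non-positive anywhere over the fitted mean range
#' the floor is raised and the fit retried.
#'
#' @param moments output of [gene_moments()].
#' @param min_mean_quantile quantile of positive means used as the fitting
#'   floor (default 0.25).
#' @param method `"gamma"` (default) or `"ols"`.
#' @return A list of class `cv2_fit`: `a0`, `a1`, `mean_floor`,
#'   `fit_genes`, `method`.
#' @export
fit_cv2_trend <- function(moments, min_mean_quantile = 0.25,
                          method = c("gamma", "ols")) {
  method <- match.arg(method)
  ok <- is.finite(moments$cv2) & moments$cv2 > 0 & moments$mu > 0
  floor_q <- min_mean_quantile
  repeat {
    mean_floor <- stats::quantile(moments$mu[ok], floor_q, names = FALSE)
    use <- ok & moments$mu >= mean_floor
    if (sum(use) < 10)
      stop("fewer than 10 genes above the mean floor; cannot fit trend")
    x <- 1 / moments$mu[use]
    y <- moments$cv2[use]
    ls <- stats::coef(stats::lm(y ~ x))
    co <- if (method == "gamma") {
      fit <- tryCatch(
        stats::glm(y ~ x, family = stats::Gamma(link = "identity"),
                   start = pmax(ls, c(1e-4, 1e-4))),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) {
        fit <- tryCatch(
          suppressWarnings(
            stats::glm(y ~ x, family = stats::Gamma(link = "identity"),
                       start = pmax(ls, c(1e-4, 1e-4)))),
          error = function(e) NULL)
      }
      if (is.null(fit)) ls else stats::coef(fit)
    } else ls
    a0 <- unname(co[1]); a1 <- unname(co[2])
    ## trend must be positive over the fitted range
    lo <- a1 / max(moments$mu[use]) + a0
    hi <- a1 / min(moments$mu[use]) + a0
    if (min(lo, hi) > 0)
      return(structure(list(a0 = a0, a1 = a1, mean_floor = mean_floor,
                            fit_genes = moments$gene[use], method = method),
                       class = "cv2_fit"))
    floor_q <- floor_q + 0.1
    if (floor_q > 0.9)
      stop("could not obtain a positive fitted trend")
  }
}

#' Evaluate the fitted trend at given means
#'
#' @param fit a `cv2_fit`.
#' @param mu vector of means.
#' @return Trend CV^2 values `a1/mu + a0`.
#' @export
cv2_trend <- function(fit, mu) fit$a1 / mu + fit$a0

#' Call significantly variable genes against the trend
#'
#' Tests each gene's observed CV^2 against the fitted trend using the
#' chi-square ratio statistic `(n - 1) * CV2_obs / CV2_trend ~ chi^2(n - 1)`
#' (upper tail), adjusts across tested genes by Benjamini-Hochberg, and
#' flags genes with FDR below the threshold.
#'
#' @param moments output of [gene_moments()].
#' @param fit a `cv2_fit`.
#' @param fdr_threshold FDR cutoff (default 0.1).
#' @return Data frame (class `hvg_table`): `gene`, `mu`, `cv2`, `trend_cv2`,
#'   `ratio`, `p`, `fdr`, `is_variable`.
#' @export
call_variable_genes <- function(moments, fit, fdr_threshold = 0.1) {
  stopifnot(inherits(fit, "cv2_fit"))
  n <- moments$n_cells[1]
  if (n < 3) stop("need at least 3 cells")
  trend <- cv2_trend(fit, moments$mu)
  testable <- is.finite(moments$cv2) & moments$mu > 0 & trend > 0
  stat <- (n - 1) * moments$cv2 / trend
  p <- rep(NA_real_, nrow(moments))
  p[testable] <- stats::pchisq(stat[testable], df = n - 1,
                               lower.tail = FALSE)
  fdr <- rep(NA_real_, nrow(moments))
  fdr[testable] <- bh_adjust(p[testable])
  out <- data.frame(gene = moments$gene, mu = moments$mu, cv2 = moments$cv2,
                    trend_cv2 = trend,
                    ratio = moments$cv2 / trend, p = p, fdr = fdr,
                    is_variable = !is.na(fdr) & fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("hvg_table", "data.frame")
  out
}

#' Compare variable-gene counts across groups
#'
#' Counts flagged variable genes per group and runs a two-proportion z-test
#' (no continuity correction) of every group against the reference group,
#' over the shared gene universe.
#'
#' @param tables named list of `hvg_table` objects (same gene universe).
#' @param reference name of the reference group (default first).
#' @return Data frame: `group`, `n_variable`, `n_tested`, `proportion`,
#'   `z`, `p` (reference row has `z = 0`, `p = 1` against itself; tests vs
#'   empty pairs are `NA` with a note attribute).
#' @export
compare_hvg_counts <- function(tables, reference = names(tables)[1]) {
  stopifnot(length(tables) >= 2, !is.null(names(tables)),
            reference %in% names(tables))
  universes <- lapply(tables, function(t) sort(t$gene[!is.na(t$fdr)]))
  if (!all(vapply(universes, identical, TRUE, y = universes[[1]])))
    stop("hvg tables have mismatched gene universes")
  n_tested <- length(universes[[1]])
  counts <- vapply(tables, function(t) sum(t$is_variable), 1L)
  ref_k <- counts[[reference]]
  note <- NULL
  res <- do.call(rbind, lapply(names(tables), function(g) {
    k <- counts[[g]]
    if (g == reference) {
      z <- 0; p <- 1
    } else if (k == 0 && ref_k == 0) {
      z <- NA_real_; p <- NA_real_
      note <<- c(note, paste0(g, ": both variable sets empty; test skipped"))
    } else {
      p1 <- k / n_tested; p2 <- ref_k / n_tested
      pool <- (k + ref_k) / (2 * n_tested)
      se <- sqrt(pool * (1 - pool) * (2 / n_tested))
      z <- (p1 - p2) / se
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group = g, n_variable = k, n_tested = n_tested,
               proportion = k / n_tested, z = z, p = p,
               stringsAsFactors = FALSE)
  }))
  attr(res, "note") <- note
  attr(res, "reference") <- reference
  res
}
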