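#' Simulation configuration for synthetic blastomere counts
#'
#' Builds the parameter set for [simulate_counts()]. Defaults emulate the
#' design of a nine-group cleavage-stage experiment: three conditions
#' (wild type `WT`, receptor knockout `KO`, dioxin-exposed `TCDD`) crossed
#' with three developmental stages (2-, 4- and 8-cell), eight embryos per
#' group, and as many cells per embryo as the stage number, i.e.
#' 3 * (16 + 32 + 64) = 336 cells in total.
#'
#' Gene-wise counts are negative binomial. Gene means are log-normal and the
#' NB size parameter is set per gene so that the marginal squared coefficient
#' of variation of normalized expression follows the overdispersion trend
#' CV^2 = a1/mu + a0 with the planted coefficients `cv2_a0` and `cv2_a1`.
#'
#' Stage programs are cumulative: one gene block is up-regulated from the
#' 4-cell stage on, a second from the 8-cell stage on. Cells labeled
#' *differentiating* (sampled per group according to `diff_fraction`)
#' additionally receive `diff_lfc` on a dedicated differentiation-program
#' block plus a fractional dose (`diff_advance_dose`) of the next stage's
#' program, which advances them along the developmental axis.
#'
#' Inter-cell heterogeneity is a per-cell, per-program-gene log-normal
#' perturbation of the mean with standard deviation
#' `heterogeneity_sd * heterogeneity_scale[condition]` (log2 scale); values
#' of `heterogeneity_scale` below 1 therefore make same-condition cells more
#' similar (higher pairwise Pearson correlation), emulating a suppressed
#' heterogeneity state.
#'
#' @param n_genes number of genes.
#' @param n_embryos_per_group embryos simulated per condition-stage group.
#' @param conditions character vector of condition labels.
#' @param stages integer vector of cleavage stages; each embryo of stage s
#'   contributes s cells.
#' @param baseline_mean_log,baseline_mean_sdlog meanlog/sdlog of the
#'   log-normal distribution of gene base means (count scale).
#' @param cv2_a0,cv2_a1 planted coefficients of the CV^2 = a1/mu + a0 trend
#'   (`cv2_a1 >= 1`).
#' @param stage_program_size genes per stage-program block (two blocks).
#' @param stage_lfc log2 fold change applied by each stage transition.
#' @param late_program_multiplier amplification of the late (8-cell)
#'   program block's activation relative to `stage_lfc`, making the final
#'   transition the largest transcriptome shift.
#' @param diff_program_size genes in the differentiation-program block.
#' @param diff_lfc log2 fold change on diff-program genes in differentiating
#'   cells.
#' @param diff_advance_dose fraction of the next stage's program (in units of
#'   `stage_lfc`) that differentiating cells receive.
#' @param diff_fraction named numeric vector, names `"<condition>:<stage>"`,
#'   giving the fraction of differentiating cells per group; groups not named
#'   get 0.
#' @param heterogeneity_scale named numeric vector (one entry per condition)
#'   multiplying the per-cell program noise.
#' @param heterogeneity_sd baseline log2-scale SD of the per-cell program
#'   noise.
#' @param size_factor_sdlog sdlog of the log-normal cell depth factors.
#' @param n_lowdepth_cells number of cells planted at `lowdepth_factor` times
#'   normal depth (QC casualties).
#' @param lowdepth_factor depth multiplier for planted low-quality cells.
#' @param marker_profiles data frame from [default_marker_profiles()], or
#'   `NULL` for no marker genes.
#' @param gene_length_range two-element base-pair interval for simulated gene
#'   lengths.
#' @param seed integer seed; a fixed seed makes the output reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_embryos_per_group = 8,
                       conditions = c("WT", "KO", "TCDD"),
                       stages = c(2L, 4L, 8L),
                       baseline_mean_log = log(60),
                       baseline_mean_sdlog = 1.2,
                       cv2_a0 = 0.25,
                       cv2_a1 = 4,
                       stage_program_size = 300,
                       stage_lfc = 1.5,
                       late_program_multiplier = 2,
                       diff_program_size = 200,
                       diff_lfc = 2,
                       diff_advance_dose = 0.5,
                       diff_fraction = c("WT:4" = 0.25, "TCDD:4" = 0.125,
                                         "WT:8" = 0.5, "KO:8" = 0.5,
                                         "TCDD:8" = 0.5),
                       heterogeneity_scale = c(WT = 1, KO = 0.5, TCDD = 0.5),
                       heterogeneity_sd = 0.6,
                       size_factor_sdlog = 0.2,
                       n_lowdepth_cells = 0,
                       lowdepth_factor = 0.01,
                       marker_profiles = default_marker_profiles(conditions,
                                                                 stages),
                       gene_length_range = c(500L, 5000L),
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_embryos_per_group >= 1,
            length(conditions) >= 1, length(stages) >= 1,
            cv2_a0 > 0, cv2_a1 >= 1,
            stage_program_size >= 0, diff_program_size >= 0,
            heterogeneity_sd >= 0, size_factor_sdlog >= 0,
            lowdepth_factor > 0,
            length(gene_length_range) == 2,
            gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1])
  if (any(diff_fraction < 0 | diff_fraction > 1))
    stop("diff_fraction values must lie in [0, 1]")
  n_marker <- if (is.null(marker_profiles)) 0L else
    length(unique(marker_profiles$gene))
  n_program <- 2L * stage_program_size + diff_program_size + n_marker
  if (n_genes < n_program + 1)
    stop("n_genes must exceed the total program size (", n_program, ")")
  grid <- as.vector(outer(conditions, stages, paste, sep = ":"))
  if (missing(diff_fraction)) {
    ## default profile: keep only the groups present in this design
    diff_fraction <- diff_fraction[names(diff_fraction) %in% grid]
  } else {
    bad <- setdiff(names(diff_fraction), grid)
    if (length(bad))
      stop("diff_fraction names outside the condition x stage grid: ",
           paste(bad, collapse = ", "))
  }
  if (!all(conditions %in% names(heterogeneity_scale)))
    stop("heterogeneity_scale must name every condition")
  cfg <- list(n_genes = as.integer(n_genes),
              n_embryos_per_group = as.integer(n_embryos_per_group),
              conditions = conditions, stages = as.integer(stages),
              baseline_mean_log = baseline_mean_log,
              baseline_mean_sdlog = baseline_mean_sdlog,
              cv2_a0 = cv2_a0, cv2_a1 = cv2_a1,
              stage_program_size = as.integer(stage_program_size),
              stage_lfc = stage_lfc,
              late_program_multiplier = late_program_multiplier,
              diff_program_size = as.integer(diff_program_size),
              diff_lfc = diff_lfc, diff_advance_dose = diff_advance_dose,
              diff_fraction = diff_fraction,
              heterogeneity_scale = heterogeneity_scale,
              heterogeneity_sd = heterogeneity_sd,
              size_factor_sdlog = size_factor_sdlog,
              n_lowdepth_cells = as.integer(n_lowdepth_cells),
              lowdepth_factor = lowdepth_factor,
              marker_profiles = marker_profiles,
              gene_length_range = as.integer(gene_length_range),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default marker-gene expression profiles
#'
#' Qualitative mean-expression profiles (count scale) of three marker genes
#' across condition, stage and subpopulation:
#' * `Ahr` — highest at the 2-cell stage, declining thereafter; absent in KO.
#' * `Oct4` — high at 2-cell, dipping at 4-cell (maternal-to-zygotic
#'   transition), strongly re-induced at 8-cell; the 8-cell induction is
#'   reduced in KO and TCDD, and differentiating 8-cell cells express more
#'   than their embryonic siblings.
#' * `Cdx2` — essentially off before the 8-cell stage, high at 8-cell
#'   (higher in differentiating cells), reduced in KO.
#'
#' @param conditions,stages the grid the profile must cover.
#' @return data frame with columns `gene`, `condition`, `stage`, `subpop`
#'   (`"embryonic"` or `"differentiating"`), `mean`.
#' @export
default_marker_profiles <- function(conditions = c("WT", "KO", "TCDD"),
                                    stages = c(2L, 4L, 8L)) {
  grid <- expand.grid(condition = conditions, stage = stages,
                      subpop = c("embryonic", "differentiating"),
                      stringsAsFactors = FALSE)
  ahr <- function(cond, stage, sub) {
    if (cond == "KO") return(0.5)
    base <- c(`2` = 120, `4` = 50, `8` = 15)[as.character(stage)]
    if (sub == "differentiating") base <- base * 0.5
    unname(base)
  }
  oct4 <- function(cond, stage, sub) {
    base <- c(`2` = 150, `4` = 60, `8` = 400)[as.character(stage)]
    if (stage == 8 && cond != "WT") base <- base * 0.5
    if (cond == "KO" && stage == 2) base <- base * 0.6
    if (stage == 8 && sub == "differentiating") base <- base * 1.5
    unname(base)
  }
  cdx2 <- function(cond, stage, sub) {
    if (stage < 8) return(1)
    base <- 200
    if (cond == "KO") base <- base * 0.5
    if (sub == "differentiating" && cond != "TCDD") base <- base * 1.8
    unname(base)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    data.frame(gene = c("Ahr", "Oct4", "Cdx2"),
               condition = g$condition, stage = g$stage, subpop = g$subpop,
               mean = c(ahr(g$condition, g$stage, g$subpop),
                        oct4(g$condition, g$stage, g$subpop),
                        cdx2(g$condition, g$stage, g$subpop)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## NB size giving marginal CV^2 = a1/mu + a0 for a gene of mean mu:
## CV^2_NB = 1/mu + 1/size  =>  1/size = a0 + (a1 - 1)/mu
.nb_size_for_trend <- function(mu, a0, a1) 1 / (a0 + (a1 - 1) / mu)

#' Simulate a synthetic blastomere count matrix
#'
#' Draws a genes x cells negative-binomial count matrix under the design
#' described in [sim_config()], together with ground-truth labels for every
#' cell (embryonic vs differentiating, planted low-depth flag) and gene
#' (stage-program / diff-program / marker / null).
#'
#' @param config a `sim_config` object.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`; `colData` columns `condition`, `stage`, `embryo_id`,
#'   `true_subpop`, `true_lowdepth`, `true_depth`; `rowData` columns
#'   `gene_length`, `true_class`; the config stored in `metadata(sce)$config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes

  ## gene identities and classes
  genes <- sprintf("gene%05d", seq_len(ng))
  cls <- rep("null", ng)
  s1 <- seq_len(config$stage_program_size)
  s2 <- config$stage_program_size + seq_len(config$stage_program_size)
  dd <- 2L * config$stage_program_size + seq_len(config$diff_program_size)
  cls[s1] <- "stage-program"
  cls[s2] <- "stage-program"
  cls[dd] <- "diff-program"
  marker_genes <- character(0)
  if (!is.null(config$marker_profiles)) {
    marker_genes <- unique(config$marker_profiles$gene)
    mk <- ng - length(marker_genes) + seq_along(marker_genes)
    genes[mk] <- marker_genes
    cls[mk] <- "marker"
  }

  ## baseline means and trend-matched NB sizes
  mu <- rlnorm(ng, meanlog = config$baseline_mean_log,
               sdlog = config$baseline_mean_sdlog)
  mu <- pmax(mu, 0.05)
  nb_size <- .nb_size_for_trend(mu, config$cv2_a0, config$cv2_a1)

  ## cell sheet
  sheet <- do.call(rbind, lapply(config$conditions, function(cond) {
    do.call(rbind, lapply(config$stages, function(st) {
      do.call(rbind, lapply(seq_len(config$n_embryos_per_group), function(e) {
        data.frame(condition = cond, stage = st,
                   embryo_id = sprintf("%s_s%d_e%02d", cond, st, e),
                   cell = sprintf("%s_s%d_e%02d_c%d", cond, st, e,
                                  seq_len(st)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  nc <- nrow(sheet)

  ## differentiating assignment per group
  sheet$true_subpop <- "embryonic"
  for (nm in names(config$diff_fraction)) {
    fr <- config$diff_fraction[[nm]]
    if (fr <= 0) next
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    idx <- which(sheet$condition == parts[1] &
                 sheet$stage == as.integer(parts[2]))
    k <- round(fr * length(idx))
    if (k > 0)
      sheet$true_subpop[sample(idx, k)] <- "differentiating"
  }

  ## log2 mean matrix: base + cumulative stage programs + diff effects
  logm <- matrix(log2(mu), nrow = ng, ncol = nc)
  stage_sorted <- sort(config$stages)
  ## cumulative programs: the early block keeps rising at every
  ## transition, the late block switches on at the last one, so the
  ## 8-cell transcriptome is the most distinct (largest shift)
  prog_dose <- function(pos) {
    dose <- numeric(ng)
    dose[s1] <- (pos - 1) * config$stage_lfc
    if (pos >= 3) dose[s2] <- config$late_program_multiplier *
      config$stage_lfc
    dose
  }
  for (j in seq_len(nc)) {
    st <- sheet$stage[j]
    pos <- match(st, stage_sorted)
    logm[, j] <- logm[, j] + prog_dose(pos)
    if (sheet$true_subpop[j] == "differentiating") {
      logm[dd, j] <- logm[dd, j] + config$diff_lfc
      ## advance a fraction of the way toward the next stage's program
      nxt_pos <- min(pos + 1, length(stage_sorted) + 1)
      step <- prog_dose(nxt_pos) - prog_dose(pos)
      logm[, j] <- logm[, j] + config$diff_advance_dose * step
    }
  }

  ## per-cell program noise (heterogeneity), scaled by condition
  prog <- c(s1, s2, dd)
  if (length(prog) && config$heterogeneity_sd > 0) {
    sds <- config$heterogeneity_sd *
      config$heterogeneity_scale[sheet$condition]
    eps <- matrix(rnorm(length(prog) * nc), nrow = length(prog))
    eps <- sweep(eps, 2, sds, `*`)
    logm[prog, ] <- logm[prog, ] + eps
  }

  ## marker override: deterministic mean per (condition, stage, subpop)
  if (length(marker_genes)) {
    mp <- config$marker_profiles
    for (g in marker_genes) {
      gi <- match(g, genes)
      sub <- mp[mp$gene == g, ]
      key <- paste(sub$condition, sub$stage, sub$subpop)
      cellkey <- paste(sheet$condition, sheet$stage, sheet$true_subpop)
      hit <- match(cellkey, key)
      if (anyNA(hit))
        stop("marker profile for ", g, " does not cover every ",
             "(condition, stage) pair")
      logm[gi, ] <- log2(pmax(sub$mean[hit], 2^-10))
      nb_size[gi] <- .nb_size_for_trend(max(mean(sub$mean), 0.05),
                                        config$cv2_a0, config$cv2_a1)
    }
  }

  ## cell depth factors, planted low-depth cells
  depth <- rlnorm(nc, 0, config$size_factor_sdlog)
  sheet$true_lowdepth <- FALSE
  if (config$n_lowdepth_cells > 0) {
    low <- sample(nc, config$n_lowdepth_cells)
    depth[low] <- depth[low] * config$lowdepth_factor
    sheet$true_lowdepth[low] <- TRUE
  }

  mean_mat <- sweep(2^logm, 2, depth, `*`)
  counts <- matrix(rnbinom(ng * nc, mu = mean_mat,
                           size = rep(nb_size, nc)),
                   nrow = ng, dimnames = list(genes, sheet$cell))

  lens <- as.integer(round(runif(ng, config$gene_length_range[1],
                                 config$gene_length_range[2])))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = sheet$condition,
                                   stage = sheet$stage,
                                   embryo_id = sheet$embryo_id,
                                   true_subpop = sheet$true_subpop,
                                   true_lowdepth = sheet$true_lowdepth,
                                   true_depth = depth,
                                   row.names = sheet$cell),
    rowData = S4Vectors::DataFrame(gene_length = lens, true_class = cls,
                                   row.names = genes))
  S4Vectors::metadata(sce)$config <- config
  sce
}

#' Inject super-trend variable genes into a simulated matrix
#'
#' Replaces the counts of `n` randomly chosen null genes with draws whose
#' realized CV^2 is approximately `cv2_inflation` times the planted
#' overdispersion trend value at the gene's mean, and relabels those genes
#' `"variable"` in the truth annotation. Counts are Poisson draws around
#' per-cell log-normal means whose extra variance supplies the inflation;
#' genes at very low mean keep their `"variable"` label even though the
#' inflation is then dominated by shot noise and may be undetectable.
#'
#' @param sce a simulation from [simulate_counts()].
#' @param n number of genes to inflate (must not exceed the null genes
#'   available).
#' @param cv2_inflation multiplicative target on the trend CV^2; must be > 1.
#' @param seed integer seed.
#' @return The modified `SingleCellExperiment`.
#' @export
inject_variable_genes <- function(sce, n, cv2_inflation, seed = 1L) {
  stopifnot(methods::is(sce, "SingleCellExperiment"))
  if (n == 0) return(sce)
  if (cv2_inflation <= 1)
    stop("cv2_inflation must exceed 1 (values <= 1 are not super-trend)")
  cfg <- S4Vectors::metadata(sce)$config
  if (is.null(cfg)) stop("sce lacks a sim_config in metadata")
  nulls <- which(SummarizedExperiment::rowData(sce)$true_class == "null")
  if (n > length(nulls))
    stop("requested ", n, " genes but only ", length(nulls),
         " null genes are available")
  set.seed(seed)
  pick <- sample(nulls, n)
  depth <- sce$true_depth
  counts <- SummarizedExperiment::assay(sce, "counts")
  for (gi in pick) {
    mu <- mean(counts[gi, ] / depth)
    mu <- max(mu, 0.05)
    target <- cv2_inflation * (cfg$cv2_a1 / mu + cfg$cv2_a0)
    w <- max(target - 1 / mu, 1e-6)   # extra-Poisson CV^2 carried by the mean
    sdl <- sqrt(log1p(w))
    fac <- rlnorm(ncol(sce), meanlog = -sdl^2 / 2, sdlog = sdl)
    counts[gi, ] <- rpois(ncol(sce), lambda = mu * fac * depth)
  }
  SummarizedExperiment::assay(sce, "counts") <- counts
  rd <- SummarizedExperiment::rowData(sce)
  rd$true_class[pick] <- "variable"
  SummarizedExperiment::rowData(sce) <- rd
  sce
}
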