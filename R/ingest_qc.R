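#' Read a count matrix plus cell metadata into a SingleCellExperiment
#'
#' Two on-disk layouts are supported:
#' * `format = "mtx"`: a directory containing `matrix.mtx` (MatrixMarket,
#'   genes x cells), `genes.tsv`, `cells.tsv`, `cell_meta.tsv` and optionally
#'   `gene_lengths.tsv`.
#' * `format = "tsv"`: `<path>.counts.tsv` (genes x cells with header and a
#'   `gene` id column), `<path>.cell_meta.tsv`, optionally
#'   `<path>.gene_lengths.tsv`.
#'
#' `cell_meta.tsv` must carry columns `cell_id`, `condition`, `stage`,
#' `embryo_id` covering exactly the cells of the matrix.
#'
#' @param path directory (`mtx`) or file prefix (`tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    counts <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "cells.tsv"))
    dimnames(counts) <- list(genes, cells)
    meta <- utils::read.delim(file.path(path, "cell_meta.tsv"),
                              stringsAsFactors = FALSE)
    lens_file <- file.path(path, "gene_lengths.tsv")
  } else {
    tab <- utils::read.delim(paste0(path, ".counts.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
    meta <- utils::read.delim(paste0(path, ".cell_meta.tsv"),
                              stringsAsFactors = FALSE)
    lens_file <- paste0(path, ".gene_lengths.tsv")
  }
  storage.mode(counts) <- "integer"
  missing_cells <- setdiff(colnames(counts), meta$cell_id)
  extra_cells <- setdiff(meta$cell_id, colnames(counts))
  if (length(missing_cells) || length(extra_cells))
    stop("cell metadata does not match matrix columns; missing: [",
         paste(missing_cells, collapse = ", "), "], extra: [",
         paste(extra_cells, collapse = ", "), "]")
  meta <- meta[match(colnames(counts), meta$cell_id), ]
  cd <- S4Vectors::DataFrame(meta[, setdiff(colnames(meta), "cell_id"),
                                  drop = FALSE],
                             row.names = meta$cell_id)
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (file.exists(lens_file)) {
    lt <- utils::read.delim(lens_file, stringsAsFactors = FALSE)
    rd$gene_length <- lt$gene_length[match(rownames(counts), lt$gene)]
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
}

#' Write a SingleCellExperiment's counts and metadata to disk
#'
#' Inverse of [read_expression()]; `read_expression(write_expression(x))`
#' restores counts, identifiers and metadata.
#'
#' @param sce the object to write (assay `counts`).
#' @param path directory (`mtx`) or file prefix (`tsv`); directories are
#'   created.
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(sce, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd <- SummarizedExperiment::colData(sce)
  meta_cols <- intersect(c("condition", "stage", "embryo_id",
                           "true_subpop", "true_lowdepth"), colnames(cd))
  meta <- data.frame(cell_id = colnames(sce),
                     as.data.frame(cd[, meta_cols, drop = FALSE]),
                     row.names = NULL)
  rd <- SummarizedExperiment::rowData(sce)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "genes.tsv"))
    writeLines(colnames(counts), file.path(path, "cells.tsv"))
    utils::write.table(meta, file.path(path, "cell_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if ("gene_length" %in% colnames(rd))
      utils::write.table(data.frame(gene = rownames(counts),
                                    gene_length = rd$gene_length),
                         file.path(path, "gene_lengths.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene = rownames(counts), counts,
                                  check.names = FALSE),
                       paste0(path, ".counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(meta, paste0(path, ".cell_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if ("gene_length" %in% colnames(rd))
      utils::write.table(data.frame(gene = rownames(counts),
                                    gene_length = rd$gene_length),
                         paste0(path, ".gene_lengths.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Quality-control filter on cells
#'
#' Drops cells with fewer detected genes than `min_detected_genes`, cells
#' whose log10 library size deviates from the median by more than
#' `outlier_mad` median absolute deviations, and (optionally) cells whose
#' mitochondrial count fraction exceeds `max_mito_fraction` (genes matched by
#' `mito_pattern`). Genes are never dropped here.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param min_detected_genes minimum number of genes with count > 0.
#' @param outlier_mad MAD multiplier for the log-library-size outlier rule;
#'   `Inf` disables it.
#' @param max_mito_fraction maximum mitochondrial fraction, or `NULL` (off).
#' @param mito_pattern regular expression identifying mitochondrial genes.
#' @return A list with `sce` (kept cells) and `report`, a data frame with one
#'   row per dropped cell (`cell`, `reason`, `detected_genes`,
#'   `library_size`).
#' @export
qc_filter_cells <- function(sce, min_detected_genes = 1000,
                            outlier_mad = 5, max_mito_fraction = NULL,
                            mito_pattern = "^mt-") {
  stopifnot(min_detected_genes >= 0, outlier_mad >= 0)
  counts <- SummarizedExperiment::assay(sce, "counts")
  detected <- colSums(counts > 0)
  libsize <- colSums(counts)
  reason <- rep(NA_character_, ncol(sce))
  low <- detected < min_detected_genes
  reason[low] <- "too few detected genes"
  if (is.finite(outlier_mad) && outlier_mad > 0) {
    ll <- log10(pmax(libsize, 1))
    dev <- abs(ll - stats::median(ll))
    out <- dev > outlier_mad * stats::mad(ll)
    reason[out & is.na(reason)] <- "library size outlier"
  }
  if (!is.null(max_mito_fraction)) {
    mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
    if (any(mito)) {
      frac <- colSums(counts[mito, , drop = FALSE]) / pmax(libsize, 1)
      reason[frac > max_mito_fraction & is.na(reason)] <-
        "high mitochondrial fraction"
    }
  }
  drop <- !is.na(reason)
  if (all(drop)) stop("QC would drop every cell; thresholds too stringent")
  report <- data.frame(cell = colnames(sce)[drop], reason = reason[drop],
                       detected_genes = unname(detected[drop]),
                       library_size = unname(libsize[drop]),
                       stringsAsFactors = FALSE)
  list(sce = sce[, !drop], report = report)
}

#' TPM normalization and log transform
#'
#' Computes transcripts per million,
#' `tpm[g,c] = 1e6 * (counts[g,c]/length[g]) / sum_g'(counts[g',c]/length[g'])`,
#' and `log2(TPM + pseudocount)`, stored as assays `tpm` and `logtpm`.
#' Without gene lengths the length term is dropped (counts per million) with
#' a warning.
#'
#' @param sce a `SingleCellExperiment`; gene lengths are taken from
#'   `rowData(sce)$gene_length` when present.
#' @param pseudocount positive offset for the log transform.
#' @return The input with `tpm` and `logtpm` assays added.
#' @export
tpm_normalize <- function(sce, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (any(colSums(counts) == 0))
    stop("zero-count cell(s) present: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         "; run qc_filter_cells() first")
  lens <- SummarizedExperiment::rowData(sce)$gene_length
  if (is.null(lens)) {
    warning("no gene lengths available; computing counts per million")
    rate <- counts
  } else {
    rate <- counts / lens
  }
  tpm <- sweep(rate, 2, colSums(rate), `/`) * 1e6
  SummarizedExperiment::assay(sce, "tpm") <- tpm
  SummarizedExperiment::assay(sce, "logtpm") <- log2(tpm + pseudocount)
  sce
}

#' Expressed gene set at a TPM threshold
#'
#' Genes whose maximum (default) or mean TPM across the given cells is at
#' least `threshold` (inclusive).
#'
#' @param sce a normalized object from [tpm_normalize()].
#' @param threshold TPM threshold (default 1).
#' @param mode `"max"` or `"mean"` summary across cells.
#' @param cells optional subset of cell ids.
#' @return Character vector of gene ids.
#' @export
expressed_gene_set <- function(sce, threshold = 1, mode = c("max", "mean"),
                               cells = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  tpm <- SummarizedExperiment::assay(sce, "tpm")
  if (!is.null(cells)) tpm <- tpm[, cells, drop = FALSE]
  stat <- if (mode == "max") apply(tpm, 1, max) else rowMeans(tpm)
  rownames(tpm)[stat >= threshold]
}
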