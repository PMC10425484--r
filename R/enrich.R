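#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Duplicate genes within a set are deduplicated with a warning; an empty
#' set (no genes) or a line with fewer than three fields is an error naming
#' the offending line.
#'
#' @param path GMT file.
#' @return A list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions`, `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need name, description and at ",
           "least one gene")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    if (f[1] %in% names(sets)) stop("duplicate set name '", f[1], "'")
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc, source = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation
#'
#' One-sided Fisher exact test of each set against a gene list within a
#' universe, with Benjamini-Hochberg adjustment across sets. Set members
#' outside the universe are ignored. An empty gene list yields `p = 1`
#' everywhere.
#'
#' @param genes gene list (subset of `universe`).
#' @param universe gene universe.
#' @param collection a `gene_set_collection`.
#' @return Data frame (class `enrichment_result`): `set`, `n_overlap`,
#'   `n_set`, `n_list`, `n_universe`, `p`, `fdr`.
#' @export
overrepresentation <- function(genes, universe, collection) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  genes <- unique(genes)
  if (length(setdiff(genes, universe)))
    stop("gene list must be a subset of the universe")
  N <- length(universe)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(genes, set))
    p <- if (!length(genes)) 1 else
      stats::phyper(k - 1, length(set), N - length(set), length(genes),
                    lower.tail = FALSE)
    data.frame(set = nm, n_overlap = k, n_set = length(set),
               n_list = length(genes), n_universe = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_adjust(res$p)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Multi-cutoff consensus enrichment
#'
#' Applies the consensus rule for calling a gene set differentially
#' enriched: the differential-expression gene list is regenerated at each
#' of six statistical cutoff levels (FDR, |lfc|) and a set is
#' consensus-enriched only when its one-sided Fisher p-value is below
#' `p_threshold` at *all* cutoffs. A cutoff yielding an empty DE list marks
#' every set non-hit at that cutoff (with a note).
#'
#' @param de a `de_result` from [differential_expression()].
#' @param collection a `gene_set_collection`.
#' @param cutoffs data frame with columns `fdr` and `lfc`, six rows by
#'   default (`fdr` in \{0.05, 0.1, 0.2\} x `lfc` in \{0.5, 1\}).
#' @param universe gene universe (default: all genes in `de`).
#' @param p_threshold per-cutoff enrichment significance level.
#' @return Data frame: `set`, per-cutoff hit flags (`hit1` ... `hit6`),
#'   `n_hits`, `consensus`; attribute `notes` lists empty cutoffs.
#' @export
consensus_enrichment <- function(de, collection,
                                 cutoffs = expand.grid(
                                   fdr = c(0.05, 0.1, 0.2),
                                   lfc = c(0.5, 1)),
                                 universe = NULL, p_threshold = 0.05) {
  stopifnot(nrow(cutoffs) >= 1, all(c("fdr", "lfc") %in% colnames(cutoffs)))
  if (is.null(universe)) universe <- de$gene
  notes <- character(0)
  hits <- sapply(seq_len(nrow(cutoffs)), function(i) {
    list_i <- de$gene[de$fdr < cutoffs$fdr[i] &
                      abs(de$lfc) >= cutoffs$lfc[i]]
    if (!length(list_i)) {
      notes <<- c(notes, sprintf(
        "cutoff %d (FDR<%g, |lfc|>=%g): empty DE list; all sets non-hit",
        i, cutoffs$fdr[i], cutoffs$lfc[i]))
      return(rep(FALSE, length(collection$sets)))
    }
    er <- overrepresentation(list_i, universe, collection)
    er$p < p_threshold
  })
  hits <- matrix(hits, nrow = length(collection$sets),
                 dimnames = list(names(collection$sets),
                                 paste0("hit", seq_len(nrow(cutoffs)))))
  out <- data.frame(set = names(collection$sets), hits,
                    n_hits = rowSums(hits),
                    consensus = rowSums(hits) == nrow(cutoffs),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "notes") <- notes
  out
}
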