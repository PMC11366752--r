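#' Read a UMI count matrix with cell and gene annotations
#'
#' Reads either a MatrixMarket triplet file (10x convention: genes as rows,
#' cells as columns; transposed on load) or a dense delimited matrix with a
#' header (cells as rows), together with one-row-per-gene and
#' one-row-per-cell annotation tables, and returns a validated count
#' object.  The condition column is re-encoded to 0/1 with the
#' lexicographically smaller label as the reference unless
#' `column_map$condition_ref` overrides it.  Cells with missing covariate
#' values are dropped with a message (mixed-model fits require complete
#' cases).
#'
#' @param matrix_path path to a `.mtx` MatrixMarket file or a dense
#'   delimited text matrix.
#' @param genes_path path to a TSV/CSV with one row per gene; first mapped
#'   column is the gene identifier.
#' @param cells_path path to a TSV/CSV with one row per cell containing the
#'   metadata columns.
#' @param column_map named list mapping the package's column roles to the
#'   file's column names: `cell_id`, `gene_id`, `sample`, `condition`,
#'   `cell_type`, optional `cohort`, `covariates` (character vector) and
#'   `condition_ref` (reference label).
#' @return An object of class \code{"celldist_counts"}: \code{counts}
#'   (cells x genes), \code{gene_ids}, \code{cell_ids}, \code{meta} (with
#'   columns `sample`, `condition` in 0/1, `cell_type`, optional `cohort`
#'   and covariates), and attribute `condition_levels` recording the
#'   encoding.
#' @export
read_counts <- function(matrix_path, genes_path, cells_path,
                        column_map = list()) {
  cm <- utils::modifyList(
    list(cell_id = "cell_id", gene_id = "gene_id", sample = "sample",
         condition = "condition", cell_type = "cell_type", cohort = NULL,
         covariates = NULL, condition_ref = NULL),
    column_map)
  genes <- utils::read.delim(genes_path, sep = "", header = TRUE,
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (ncol(cells) == 1L)
    cells <- utils::read.delim(cells_path, sep = "", header = TRUE,
                               stringsAsFactors = FALSE)
  check_meta_cols(genes, cm$gene_id)
  check_meta_cols(cells, c(cm$cell_id, cm$sample, cm$condition, cm$cell_type,
                           cm$cohort, cm$covariates))
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    M <- Matrix::readMM(matrix_path)   # genes x cells (10x dialect)
    Y <- as.matrix(Matrix::t(M))
  } else {
    Y <- as.matrix(utils::read.delim(matrix_path, sep = "", header = TRUE,
                                     row.names = NULL))
    storage.mode(Y) <- "double"
  }
  if (nrow(Y) != nrow(cells) || ncol(Y) != nrow(genes))
    stop_celldist("dimension mismatch between matrix (", nrow(Y), " x ",
                  ncol(Y), ") and annotations (", nrow(cells), " cells, ",
                  nrow(genes), " genes)")
  if (any(Y < 0)) stop_celldist("counts must be non-negative")
  cell_ids <- as.character(cells[[cm$cell_id]])
  gene_ids <- as.character(genes[[cm$gene_id]])
  if (anyDuplicated(cell_ids)) stop_celldist("duplicated cell ids")
  if (anyDuplicated(gene_ids)) stop_celldist("duplicated gene ids")
  dimnames(Y) <- list(cell_ids, gene_ids)

  meta <- data.frame(sample = as.character(cells[[cm$sample]]),
                     cell_type = as.character(cells[[cm$cell_type]]),
                     row.names = cell_ids, stringsAsFactors = FALSE)
  condraw <- as.character(cells[[cm$condition]])
  if (any(is.na(condraw) | is.na(meta$sample) | is.na(meta$cell_type)))
    stop_celldist("missing sample, condition or cell_type values")
  lev <- sort(unique(condraw))
  if (length(lev) != 2L)
    stop_celldist("condition must have exactly two levels, found ",
                  length(lev))
  if (!is.null(cm$condition_ref)) {
    if (!cm$condition_ref %in% lev)
      stop_celldist("condition_ref not among the observed labels")
    lev <- c(cm$condition_ref, setdiff(lev, cm$condition_ref))
  }
  meta$condition <- as.integer(condraw == lev[2L])
  if (!is.null(cm$cohort)) meta$cohort <- as.character(cells[[cm$cohort]])
  for (cv in cm$covariates) meta[[cv]] <- as.numeric(cells[[cv]])
  # a sample must sit in exactly one condition
  nlev <- tapply(meta$condition, meta$sample,
                 function(v) length(unique(v)))
  if (any(nlev > 1L)) stop_celldist("condition not constant within sample")
  # drop incomplete covariate rows
  if (!is.null(cm$covariates)) {
    keep <- stats::complete.cases(meta[, cm$covariates, drop = FALSE])
    if (!all(keep)) {
      message("dropping ", sum(!keep), " cell(s) with missing covariates")
      Y <- Y[keep, , drop = FALSE]
      meta <- meta[keep, , drop = FALSE]
      cell_ids <- cell_ids[keep]
    }
  }
  structure(list(counts = Y, gene_ids = gene_ids, cell_ids = cell_ids,
                 meta = meta),
            class = "celldist_counts",
            condition_levels = lev)
}

#' @export
print.celldist_counts <- function(x, ...) {
  lev <- attr(x, "condition_levels")
  cat(sprintf("count matrix: %d cells x %d genes, %d samples, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$sample)),
              length(unique(x$meta$cell_type))))
  if (!is.null(lev))
    cat(sprintf("condition encoding: 0 = %s (reference), 1 = %s\n",
                lev[1L], lev[2L]))
  invisible(x)
}

#' Write per-cell-type results to a tab-delimited table
#'
#' One row per cell type, in input order, with the columns `cell_type`,
#' `n_cells`, `n_samples_cond0`, `n_samples_cond1`, `dist_median`,
#' `dist_q05`, `dist_q95`, `wald_stat`, `p_value`, `p_adj`.  The file
#' round-trips through [utils::read.delim()].
#'
#' @param results a fitted \code{"celldist"} object or its results
#'   data.frame.
#' @param out_path output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, out_path) {
  df <- if (inherits(results, "celldist")) results$results else
    as.data.frame(results)
  cols <- c("cell_type", "n_cells", "n_samples_cond0", "n_samples_cond1",
            "dist_median", "dist_q05", "dist_q95", "wald_stat", "p_value",
            "p_adj")
  if (nrow(df) == 0L) stop_celldist("no results to write")
  check_meta_cols(df, cols)
  utils::write.table(df[, cols], out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}
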