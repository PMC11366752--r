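#' Gene-level drivers of a cell type's condition distance
#'
#' The k-th importance score of gene g is \eqn{|U_{kg}| \cdot |\beta_g|}:
#' the magnitude of the gene's loading on projection dimension k times the
#' magnitude of its condition effect.  The score is zero exactly when the
#' gene does not load on the dimension or is not differentially expressed.
#' Genes are first screened by the score computed with the moment estimate
#' of \eqn{\beta_g} (raw difference of condition means); the top `top_n`
#' genes per requested dimension are then refitted with the per-gene mixed
#' model to obtain \eqn{\hat\beta_g}, its standard error and a Wald
#' p-value (Satterthwaite df).  The loadings are fixed and known, so
#' multiplicity is adjusted across genes only (Benjamini-Hochberg), not
#' across dimensions.
#'
#' @param basis a \code{"celldist_basis"} for the cell type.
#' @param residuals residual matrix (cells of this cell type only) or
#'   \code{"celldist_residuals"} object.
#' @param meta per-cell metadata (taken from `residuals` when available).
#' @param spec a [model_spec()].
#' @param dims projection dimensions to score (subset of 1..K).
#' @param top_n number of screened genes refitted per dimension; `Inf` for
#'   all genes.
#' @return data.frame of class \code{"celldist_importance"} with one row
#'   per gene and dimension: `gene`, `dim`, `importance`
#'   (\eqn{|U_{kg}||\hat\beta_g|} from the mixed fit), `screen_score`,
#'   `beta`, `se`, `p_value`, `p_adj`, sorted by importance.
#' @export
gene_importance <- function(basis, residuals, meta = NULL,
                            spec = model_spec(), dims = 1L, top_n = 100L) {
  if (length(dims) == 0L) stop_celldist("dims must be non-empty")
  if (any(dims < 1L | dims > nrow(basis$loadings)))
    stop_celldist("dims out of range")
  if (inherits(residuals, "celldist_residuals")) {
    meta <- meta %||% residuals$meta
    Z <- as_dense(residuals$values)
  } else Z <- as_dense(residuals)
  des <- build_design(meta, spec)
  xcond <- des$X[, des$cond]
  # screening: moment estimate of beta_g = raw condition-mean difference
  beta_mom <- colMeans(Z[xcond == 1, , drop = FALSE]) -
    colMeans(Z[xcond == 0, , drop = FALSE])
  genes <- basis$gene_ids %||% colnames(Z) %||% paste0("g", seq_len(ncol(Z)))
  sel <- integer(0)
  for (k in dims) {
    sc <- abs(basis$loadings[k, ]) * abs(beta_mom)
    sel <- union(sel, order(sc, decreasing = TRUE)[seq_len(min(top_n,
                                                               ncol(Z)))])
  }
  gfit <- lapply(sel, function(g)
    fit_dimension_xy(Z[, g], des$X, des$group, des$cond))
  beta_hat <- vapply(gfit, `[[`, 0, "effect")
  se <- vapply(gfit, `[[`, 0, "se")
  df <- vapply(gfit, `[[`, 0, "df")
  p <- 2 * stats::pt(-abs(beta_hat / se), df = df)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- do.call(rbind, lapply(dims, function(k) {
    data.frame(gene = genes[sel], dim = k,
               importance = unname(abs(basis$loadings[k, sel]) *
                                     abs(beta_hat)),
               screen_score = unname(abs(basis$loadings[k, sel]) *
                                       abs(beta_mom[sel])),
               beta = beta_hat, se = se, p_value = p, p_adj = p_adj,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("celldist_importance", "data.frame")
  out
}

#' Differential-expression signature for one cell type
#'
#' Fits the per-gene mixed model (random intercept on the sample, or on the
#' nested cohort-by-sample group when the spec names a cohort column) to
#' every gene of the given cell type and returns the condition coefficients
#' as signature weights.  By default only genes passing a
#' Benjamini-Hochberg threshold are kept; `p_cut = 1` keeps all genes.
#'
#' @param residuals \code{"celldist_residuals"} object or matrix (all cell
#'   types; subset by `cell_type`).
#' @param meta per-cell metadata (taken from `residuals` when available).
#' @param spec a [model_spec()].
#' @param cell_type cell type whose cells enter the fits; `NULL` uses all
#'   cells.
#' @param cell_type_col metadata column holding the annotation.
#' @param p_cut BH-adjusted p-value threshold for inclusion.
#' @return data.frame of class \code{"celldist_signature"}: `gene`,
#'   `weight` (condition coefficient), `se`, `p_value`, `p_adj`.
#' @export
derive_signature <- function(residuals, meta = NULL, spec = model_spec(),
                             cell_type = NULL, cell_type_col = "cell_type",
                             p_cut = 0.05) {
  if (inherits(residuals, "celldist_residuals")) {
    meta <- meta %||% residuals$meta
    Z <- as_dense(residuals$values)
  } else Z <- as_dense(residuals)
  genes <- colnames(Z) %||% paste0("g", seq_len(ncol(Z)))
  if (!is.null(cell_type)) {
    idx <- which(meta[[cell_type_col]] == cell_type)
    if (length(idx) == 0L) stop_celldist("cell type not found")
    Z <- Z[idx, , drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  des <- build_design(meta, spec)
  fits <- lapply(seq_len(ncol(Z)), function(g)
    fit_dimension_xy(Z[, g], des$X, des$group, des$cond))
  w <- vapply(fits, `[[`, 0, "effect")
  se <- vapply(fits, `[[`, 0, "se")
  df <- vapply(fits, `[[`, 0, "df")
  p <- 2 * stats::pt(-abs(w / se), df = df)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, weight = w, se = se, p_value = p,
                    p_adj = p_adj, stringsAsFactors = FALSE)
  out <- out[out$p_adj <= p_cut, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("celldist_signature", "data.frame")
  out
}

#' Score a bulk expression profile against a signature
#'
#' The signature score of a sample is the Spearman rank correlation between
#' its normalized expression vector and the signature's differential
#' expression weights over the shared genes.  Being rank-based, the score
#' is invariant to any strictly monotone transform of the expression
#' values.
#'
#' @param expression named numeric vector of normalized expression (names
#'   are gene identifiers).
#' @param signature a \code{"celldist_signature"} data.frame (or any
#'   data.frame with `gene` and `weight` columns).
#' @return Spearman correlation in \eqn{[-1, 1]}.
#' @export
score_bulk_sample <- function(expression, signature) {
  if (is.null(names(expression)))
    stop_celldist("expression vector must be named by gene")
  common <- intersect(names(expression), signature$gene)
  if (length(common) < 3L)
    stop_celldist("fewer than 3 overlapping genes between expression and ",
                  "signature")
  w <- signature$weight[match(common, signature$gene)]
  stats::cor(expression[common], w, method = "spearman")
}
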