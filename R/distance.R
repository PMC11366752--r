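#' Condition distances per cell type in single-cell RNA-seq
#'
#' For every annotated cell type, estimates the Euclidean distance between
#' the two condition means in normalized expression space.  Within each
#' cell type the residual matrix is projected onto its top-K principal
#' components; a random-intercept mixed model is fitted to each projected
#' dimension (REML, with per-sample intercepts absorbing
#' individual-to-individual variability); the per-dimension condition
#' effects are shrunk with an empirical-Bayes spike-and-slab prior; and the
#' posterior of \eqn{D_K = \sqrt{\sum_k (U\beta)_k^2}} is summarized by its
#' median and 5/95 percent quantiles.  Significance of \eqn{D_K = 0} comes
#' from the sum-of-squared-z Wald statistic against a Monte-Carlo
#' sum-of-F null, with Benjamini-Hochberg adjustment across cell types.
#'
#' @param x normalized expression: a \code{"celldist_residuals"} object, a
#'   \code{"celldist_counts"} object (normalized internally with
#'   [fit_gene_glms()] / [pearson_residuals()]), or a plain cells-by-genes
#'   numeric matrix.
#' @param meta per-cell metadata with at least the columns named in `spec`
#'   plus `cell_type`; taken from `x` when available.
#' @param cell_type_col name of the cell-type column.
#' @param spec a [model_spec()] naming condition/sample/covariate/cohort
#'   columns.
#' @param K number of projection dimensions, or `"auto"` ([default_K()]
#'   from the number of samples, capped at cells - 1 and G per cell type).
#' @param weights optional length-G non-negative gene weights (the weighted
#'   distance \eqn{\sqrt{\beta^\top W \beta}} is then estimated).
#' @param family GLM family for internal normalization of count input.
#' @param clip residual clipping bound for count input (`NULL` to disable).
#' @param min_cells_gene genes expressed in fewer cells are dropped before
#'   normalization.
#' @param n_draws posterior draws for the distance summary.
#' @param mc_draws Monte-Carlo draws for the null distribution (default
#'   1e5).
#' @param p_adjust multiplicity adjustment across cell types.
#' @param seed master seed; per-cell-type seeds are derived from it, and
#'   null draws are shared across cell types only when their
#'   degrees-of-freedom lists are identical.
#' @param min_cells cell types with fewer cells are skipped with a warning.
#' @return An object of class \code{"celldist"}: \code{results} (one row
#'   per cell type), \code{detail} (per-type fits, prior, posterior, basis,
#'   test), \code{K}, \code{spec}, \code{call}.
#' @seealso [fit_projection()], [fit_dimension()], [posterior_distance()],
#'   [wald_statistic()], [gene_importance()]
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(G = 30, J = 3, cells_per_sample = 20,
#'                                    D_true = 2, seed = 1))
#' sim$residuals$meta$cell_type <- "T cells"
#' fit <- celldist(sim$residuals, K = 5, mc_draws = 2000, n_draws = 500)
#' fit
celldist <- function(x, meta = NULL, cell_type_col = "cell_type",
                     spec = model_spec(), K = "auto", weights = NULL,
                     family = "nb", clip = TRUE, min_cells_gene = 5L,
                     n_draws = 10000L, mc_draws = 1e5,
                     p_adjust = c("BH", "bonferroni", "none"), seed = 1L,
                     min_cells = 20L) {
  p_adjust <- match.arg(p_adjust)
  cl <- match.call()
  if (inherits(x, "celldist_counts")) {
    meta <- meta %||% x$meta
    keep <- colSums(as_dense(x$counts) > 0) >= min_cells_gene
    if (!all(keep))
      message("dropping ", sum(!keep), " gene(s) expressed in fewer than ",
              min_cells_gene, " cells")
    Y <- as_dense(x$counts)[, keep, drop = FALSE]
    fits <- fit_gene_glms(Y, family = family, min_cells = min_cells_gene)
    res <- pearson_residuals(Y, fits,
                             clip = if (isTRUE(clip)) sqrt(nrow(Y)) else NULL)
    Z <- res$values
  } else if (inherits(x, "celldist_residuals")) {
    meta <- meta %||% x$meta
    Z <- as_dense(x$values)
  } else {
    Z <- as_dense(x)
  }
  if (is.null(meta)) stop_celldist("per-cell metadata is required")
  if (nrow(Z) != nrow(meta))
    stop_celldist("metadata rows do not match the number of cells")
  if (!cell_type_col %in% colnames(meta)) {
    meta[[cell_type_col]] <- "all cells"
  }
  types <- unique(as.character(meta[[cell_type_col]]))
  detail <- list()
  rows <- list()
  null_cache <- list()
  for (ti in seq_along(types)) {
    ct <- types[ti]
    idx <- which(meta[[cell_type_col]] == ct)
    m <- meta[idx, , drop = FALSE]
    skip <- function(msg) {
      warning("cell type '", ct, "' skipped: ", msg, call. = FALSE)
      NULL
    }
    if (length(idx) < min_cells) { skip("too few cells"); next }
    ok <- tryCatch({ build_design(m, spec); TRUE },
                   error = function(e) { skip(conditionMessage(e)); FALSE })
    if (!ok) next
    Zi <- Z[idx, , drop = FALSE]
    n_samp <- tapply(m[[spec$sample]], m[[spec$condition]],
                     function(s) length(unique(s)))
    Ki <- if (identical(K, "auto"))
      default_K(length(unique(m[[spec$sample]]))) else as.integer(K)
    Ki <- min(Ki, length(idx) - 1L, ncol(Zi))
    if (is.null(weights)) {
      basis <- fit_projection(Zi, K = Ki)
      scores <- project_cells(Zi, basis, meta = m)
    } else {
      wt <- weighted_transform(Zi, weights, K = Ki, meta = m)
      basis <- wt$basis; scores <- wt$scores
    }
    dfits <- fit_all_dimensions(scores, spec = spec)
    dfits <- dfits[vapply(dfits, `[[`, TRUE, "converged")]
    prior <- fit_shrinkage_prior(dfits)
    post <- posterior_distance(dfits, prior, n_draws = n_draws,
                               seed = derive_seed(seed, 2L * ti))
    w_star <- wald_statistic(dfits)
    dof <- vapply(dfits, `[[`, 0, "df")
    key <- paste(signif(sort(dof), 8), collapse = ",")
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- monte_carlo_null(dof, M = mc_draws,
                                            seed = derive_seed(seed,
                                                               2L * ti + 1L))
    }
    p <- empirical_p(w_star, null_cache[[key]])
    detail[[ct]] <- list(fits = dfits, prior = prior, posterior = post,
                         basis = basis, wald = w_star, dof = dof,
                         p_value = p, n_cells = length(idx))
    rows[[ct]] <- data.frame(
      cell_type = ct, n_cells = length(idx),
      n_samples_cond0 = unname(n_samp["0"]),
      n_samples_cond1 = unname(n_samp["1"]),
      dist_median = post$median, dist_q05 = post$q05, dist_q95 = post$q95,
      wald_stat = w_star, p_value = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop_celldist("no cell type could be analyzed")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results$p_adj <- if (p_adjust == "none") results$p_value else
    adjust_pvalues(results$p_value, method = p_adjust)
  structure(list(results = results, detail = detail, K = K, spec = spec,
                 p_adjust = p_adjust, mc_draws = mc_draws, seed = seed,
                 call = cl),
            class = "celldist")
}

#' @export
print.celldist <- function(x, digits = 3, ...) {
  cat("Cell-type condition distances (mixed-model, shrunk posterior)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  df <- x$results
  out <- data.frame(cell_type = df$cell_type, n_cells = df$n_cells,
                    distance = signif(df$dist_median, digits),
                    p_value = signif(df$p_value, digits),
                    p_adj = signif(df$p_adj, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.celldist <- function(object, ...) {
  structure(list(results = object$results, spec = object$spec,
                 p_adjust = object$p_adjust, call = object$call),
            class = "summary.celldist")
}

#' @export
print.summary.celldist <- function(x, digits = 4, ...) {
  cat("Cell-type condition distances\n")
  cat("Call: ", deparse(x$call), "\n")
  print(x$spec)
  cat("multiplicity adjustment:", x$p_adjust, "\n\n")
  df <- x$results
  df[, 5:10] <- signif(df[, 5:10], digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.celldist <- function(object, ...) {
  stats::setNames(object$results$dist_median, object$results$cell_type)
}

#' Plot per-cell-type distance estimates with posterior intervals
#'
#' Dot-and-whisker display of the posterior median distance and 5-95
#' percent interval per cell type, ordered by the estimate; significant
#' cell types (adjusted p below `alpha`) are filled.
#'
#' @param x a \code{"celldist"} object.
#' @param alpha significance threshold on the adjusted p-value.
#' @param ... passed to [graphics::plot()].
#' @export
plot.celldist <- function(x, alpha = 0.05, ...) {
  df <- x$results[order(x$results$dist_median), , drop = FALSE]
  n <- nrow(df)
  graphics::plot(df$dist_median, seq_len(n), xlim = c(0, max(df$dist_q95)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "condition distance (posterior median, 5-95%)",
                 ylab = "", pch = ifelse(df$p_adj < alpha, 19, 1), ...)
  graphics::segments(df$dist_q05, seq_len(n), df$dist_q95, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = df$cell_type, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
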