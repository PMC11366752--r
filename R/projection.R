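#' Default number of projection dimensions
#'
#' Returns the recommended number of principal components for the distance
#' approximation: 20 when the number of samples is small and 50 for large
#' studies.  "Large" is set at more than 30 samples (the boundary between
#' the two regimes is a package choice; both values are standard retained-PC
#' counts for single-cell data).  An explicit user choice always wins.
#'
#' @param n_samples number of biological samples (donors) in the comparison.
#' @param override optional user-chosen K; returned unchanged when supplied.
#' @return A positive integer number of dimensions.
#' @export
#' @examples
#' default_K(10)   # 20
#' default_K(200)  # 50
default_K <- function(n_samples, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (n_samples < 2L) stop_celldist("need at least 2 samples")
  if (n_samples > 30L) 50L else 20L
}

#' Fit an orthonormal projection basis by PCA
#'
#' Computes the rank-K principal component basis of a cells-by-genes
#' residual matrix: the center is the vector of column means and the
#' loadings are the top-K right singular vectors of the centered matrix.
#' Row k of the loadings has its largest-magnitude entry made positive so
#' the basis is reproducible across platforms.
#'
#' @param residuals a \code{"celldist_residuals"} object or a plain
#'   cells-by-genes numeric matrix.
#' @param K number of dimensions, at most \code{min(n - 1, G)}.
#' @return An object of class \code{"celldist_basis"}: \code{loadings}
#'   (K x G, orthonormal rows), \code{center} (length G),
#'   \code{explained_variance} (length K) and \code{gene_ids}.
#' @export
fit_projection <- function(residuals, K) {
  Z <- if (inherits(residuals, "celldist_residuals")) residuals$values else residuals
  Z <- as_dense(Z)
  gene_ids <- colnames(Z) %||%
    (if (inherits(residuals, "celldist_residuals")) residuals$gene_ids else NULL)
  n <- nrow(Z); G <- ncol(Z)
  if (n < 2L) stop_celldist("need at least 2 cells")
  K <- as.integer(K)
  if (K < 1L || K > min(n - 1L, G))
    stop_celldist("K must be between 1 and min(n - 1, G) = ", min(n - 1L, G))
  center <- colMeans(Z)
  Zc <- sweep(Z, 2L, center, "-")
  if (all(abs(Zc) < 1e-12))
    stop_celldist("residual matrix has zero variance")
  sv <- svd(Zc, nu = 0, nv = K)
  loadings <- t(sv$v)
  # deterministic sign: largest-|.| entry of each row positive
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) loadings[k, ] <- -loadings[k, ]
  }
  colnames(loadings) <- gene_ids
  structure(list(loadings = loadings, center = center,
                 explained_variance = sv$d[seq_len(K)]^2 / (n - 1),
                 gene_ids = gene_ids),
            class = "celldist_basis")
}

#' @export
print.celldist_basis <- function(x, ...) {
  cat(sprintf("projection basis: %d dimensions x %d genes\n",
              nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' Project cells onto a fitted basis
#'
#' Maps each cell's residual vector to its K principal-component scores,
#' \eqn{v_{ik} = u_k^\top (z_i - \mu)}.  Metadata travels with the scores.
#'
#' @param residuals a \code{"celldist_residuals"} object or plain matrix.
#' @param basis a \code{"celldist_basis"} from [fit_projection()].
#' @param meta per-cell metadata (taken from `residuals` when available).
#' @return A \code{"celldist_scores"} object: \code{scores} (n x K) and
#'   \code{meta}.
#' @export
project_cells <- function(residuals, basis, meta = NULL) {
  if (inherits(residuals, "celldist_residuals")) {
    meta <- meta %||% residuals$meta
    ids <- residuals$gene_ids
    Z <- residuals$values
  } else {
    Z <- residuals
    ids <- colnames(Z)
  }
  Z <- as_dense(Z)
  if (ncol(Z) != ncol(basis$loadings))
    stop_celldist("gene sets of residuals and basis do not match")
  if (!is.null(ids) && !is.null(basis$gene_ids) &&
      !identical(as.character(ids), as.character(basis$gene_ids)))
    stop_celldist("gene sets of residuals and basis do not match")
  scores <- sweep(Z, 2L, basis$center, "-") %*% t(basis$loadings)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, meta = meta), class = "celldist_scores")
}

#' @export
print.celldist_scores <- function(x, ...) {
  cat(sprintf("score matrix: %d cells x %d dimensions\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
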