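#' Per-gene count GLM fits for Pearson-residual normalization
#'
#' For each gene fits the depth-offset log-linear model
#' \eqn{\log \mu_g = \beta_{0g} + \beta_{1g} \log r_{ij}}, where
#' \eqn{r_{ij}} is the cell's total UMI count, by Poisson maximum
#' likelihood.  For `family = "nb"` the gene-level dispersion \eqn{\alpha_g}
#' (variance \eqn{\mu + \mu^2/\alpha}) is then estimated by method of
#' moments on the Poisson residual overdispersion and floored at a small
#' positive constant; genes with no evidence of overdispersion keep the
#' Poisson limit \eqn{\alpha_g = \infty}.  Genes expressed in fewer than
#' `min_cells` cells (including all-zero genes) receive a degenerate fit
#' whose residuals are zero, keeping the fit list aligned with the gene
#' set.
#'
#' @param counts a \code{"celldist_counts"} object or a cells-by-genes
#'   non-negative integer matrix.
#' @param family `"poisson"` or `"nb"`.
#' @param min_cells minimum number of expressing cells for a non-degenerate
#'   fit.
#' @param alpha_floor lower bound for the estimated dispersion.
#' @return list of class \code{"celldist_glms"}; one fit per gene with
#'   elements `beta0`, `beta1`, `alpha` (`Inf` for Poisson), `degenerate`.
#' @export
fit_gene_glms <- function(counts, family = c("nb", "poisson"),
                          min_cells = 5L, alpha_floor = 1e-2) {
  family <- match.arg(family)
  Y <- if (inherits(counts, "celldist_counts")) counts$counts else counts
  Y <- as_dense(Y)
  if (any(Y < 0)) stop_celldist("counts must be non-negative")
  if (any(Y != round(Y))) stop_celldist("counts must be integers")
  r <- rowSums(Y)
  if (any(r <= 0)) stop_celldist("every cell must have positive total count")
  lr <- log(r)
  X <- cbind(1, lr)
  fits <- vector("list", ncol(Y))
  for (g in seq_len(ncol(Y))) {
    y <- Y[, g]
    if (sum(y > 0) < min_cells) {
      fits[[g]] <- list(beta0 = NA_real_, beta1 = NA_real_, alpha = Inf,
                        degenerate = TRUE)
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::poisson()))
    b <- fit$coefficients
    b[is.na(b)] <- 0   # constant depth aliases the slope; intercept absorbs it
    mu <- as.vector(exp(X %*% b))
    alpha <- Inf
    if (family == "nb") {
      # method of moments: E[(y - mu)^2 - mu] = mu^2 / alpha
      num <- sum((y - mu)^2 - mu)
      if (num > 0) alpha <- max(sum(mu^2) / num, alpha_floor)
    }
    fits[[g]] <- list(beta0 = unname(b[1L]), beta1 = unname(b[2L]),
                      alpha = alpha, degenerate = FALSE)
  }
  n_deg <- sum(vapply(fits, `[[`, TRUE, "degenerate"))
  if (n_deg > 0L)
    message(n_deg, " gene(s) expressed in fewer than ", min_cells,
            " cells: degenerate fit, residuals set to 0")
  structure(fits, class = "celldist_glms", family = family)
}

#' Pearson residuals from per-gene count GLM fits
#'
#' Computes \eqn{z_{ijg} = (y_{ijg} - \hat\mu_g) / \sqrt{\hat\mu_g +
#' \hat\mu_g^2 / \hat\alpha_g}} (the dispersion term vanishes in the
#' Poisson limit \eqn{\alpha = \infty}), optionally clipped symmetrically.
#' The default clip of \eqn{\sqrt{n}} (n = number of cells) bounds the
#' leverage of rare extreme counts; pass `clip = NULL` to disable.
#'
#' @param counts a \code{"celldist_counts"} object or cells-by-genes matrix.
#' @param fits result of [fit_gene_glms()], aligned with the genes.
#' @param clip positive clipping bound, or `NULL` for none.
#' @return A \code{"celldist_residuals"} object (metadata carried over when
#'   the input is a \code{"celldist_counts"} object).
#' @export
pearson_residuals <- function(counts, fits, clip = sqrt(nrow_counts(counts))) {
  Y <- if (inherits(counts, "celldist_counts")) counts$counts else counts
  Y <- as_dense(Y)
  if (length(fits) != ncol(Y))
    stop_celldist("fits are not aligned with the genes")
  lr <- log(rowSums(Y))
  Z <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (g in seq_along(fits)) {
    f <- fits[[g]]
    if (isTRUE(f$degenerate)) next
    mu <- exp(f$beta0 + f$beta1 * lr)
    if (any(mu <= 0)) stop_celldist("fitted mean must be positive")
    v <- mu + if (is.finite(f$alpha)) mu^2 / f$alpha else 0
    Z[, g] <- (Y[, g] - mu) / sqrt(v)
  }
  if (!is.null(clip)) {
    if (clip <= 0) stop_celldist("clip must be positive")
    Z[Z > clip] <- clip
    Z[Z < -clip] <- -clip
  }
  meta <- if (inherits(counts, "celldist_counts")) counts$meta else NULL
  structure(list(values = Z,
                 gene_ids = colnames(Y) %||% paste0("g", seq_len(ncol(Y))),
                 cell_ids = rownames(Y) %||% paste0("c", seq_len(nrow(Y))),
                 meta = meta),
            class = "celldist_residuals")
}

nrow_counts <- function(counts) {
  if (inherits(counts, "celldist_counts")) nrow(counts$counts) else nrow(counts)
}

#' @export
print.celldist_residuals <- function(x, ...) {
  cat(sprintf("normalized residual matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
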