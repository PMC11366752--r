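#' Describe the mixed-model design used for every per-dimension fit
#'
#' A model specification names the metadata columns that define the fixed
#' condition effect, the grouping factor for the random intercept, optional
#' fixed-effect covariates, and an optional cohort column.  When a cohort
#' column is given the random intercept is placed on the cohort-by-sample
#' interaction (a nested \code{(1 | cohort:sample)} term), which absorbs both
#' cohort- and sample-level shifts.
#'
#' @param condition name of the binary condition column (coded 0/1 or a
#'   two-level factor; the first sorted level becomes the reference).
#' @param sample name of the sample / donor identifier column.
#' @param covariates optional character vector of numeric covariate columns
#'   entered as fixed effects.
#' @param cohort optional cohort identifier column; activates the nested
#'   random intercept.
#' @return An object of class \code{"celldist_spec"}.
#' @export
#' @examples
#' model_spec()
model_spec <- function(condition = "condition", sample = "sample",
                       covariates = NULL, cohort = NULL) {
  structure(list(condition = condition, sample = sample,
                 covariates = covariates, cohort = cohort),
            class = "celldist_spec")
}

#' @export
print.celldist_spec <- function(x, ...) {
  rhs <- c(x$condition, x$covariates)
  grp <- if (is.null(x$cohort)) x$sample else paste0(x$cohort, ":", x$sample)
  cat("mixed-model spec: y ~ ", paste(rhs, collapse = " + "),
      " + (1 | ", grp, ")\n", sep = "")
  invisible(x)
}

# Build the fixed-effect design matrix, 0/1 condition vector and grouping
# factor from per-cell metadata.  Returns list(X, group, cond_col_index).
build_design <- function(meta, spec) {
  check_meta_cols(meta, c(spec$condition, spec$sample, spec$covariates,
                          spec$cohort))
  x <- meta[[spec$condition]]
  if (is.factor(x) || is.character(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2L)
      stop_celldist("condition must have exactly two levels, found ",
                    length(lev))
    x <- as.numeric(as.character(x) == lev[2L])
  } else {
    ux <- sort(unique(x))
    if (!all(ux %in% c(0, 1)) || length(ux) < 1L)
      stop_celldist("numeric condition must be coded 0/1")
    x <- as.numeric(x)
  }
  grp_vals <- if (is.null(spec$cohort)) {
    as.character(meta[[spec$sample]])
  } else {
    paste(meta[[spec$cohort]], meta[[spec$sample]], sep = ":")
  }
  group <- factor(grp_vals)
  # condition must be constant within each random-intercept group
  if (any(tapply(x, group, function(v) length(unique(v))) > 1L))
    stop_celldist("condition not constant within sample")
  n_per_cond <- table(tapply(x, group, function(v) v[1L]))
  if (length(n_per_cond) < 2L || any(n_per_cond < 2L))
    stop_celldist("need at least 2 samples in each condition")
  X <- cbind(`(Intercept)` = 1, condition = x)
  for (cv in spec$covariates) {
    v <- meta[[cv]]
    if (!is.numeric(v)) stop_celldist("covariate '", cv, "' must be numeric")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X))
    stop_celldist("singular fixed-effect design (collinear covariates?)")
  list(X = X, group = group, cond = 2L)
}

# Sufficient statistics reused across candidate variance ratios.
reml_stats <- function(y, X, group) {
  group <- as.integer(group)
  J <- max(group)
  SX <- rowsum(X, group)                      # J x p group sums of X
  Sy <- as.vector(rowsum(y, group))
  nj <- as.vector(rowsum(rep(1, length(y)), group))
  list(XtX = crossprod(X), Xty = crossprod(X, y)[, 1L], yty = sum(y * y),
       SX = SX, Sy = Sy, nj = nj, n = length(y), p = ncol(X), J = J)
}

# Full -2 * REML log-likelihood at variance ratio lambda = tau2/sigma2 with
# sigma2 profiled out.  Returns the criterion together with the GLS pieces.
reml_profile_eval <- function(st, lambda) {
  cj <- lambda / (1 + lambda * st$nj)
  A <- st$XtX - crossprod(st$SX, st$SX * cj)
  b <- st$Xty - crossprod(st$SX, st$Sy * cj)[, 1L]
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(crit = Inf))
  beta <- backsolve(R, forwardsolve(t(R), b))
  q <- st$yty - sum(cj * st$Sy^2) - sum(beta * b)
  q <- max(q, 1e-300)
  np <- st$n - st$p
  sigma2 <- q / np
  logdetV <- sum(log1p(lambda * st$nj))
  logdetA <- 2 * sum(log(diag(R)))
  crit <- np * (log(2 * pi) + 1 + log(sigma2)) + logdetV + logdetA
  list(crit = crit, beta = beta, sigma2 = sigma2, cholA = R, lambda = lambda)
}

# -2 * REML log-likelihood at arbitrary (tau2, sigma2); used for the
# observed-information Hessian behind the Satterthwaite approximation.
reml_m2ll <- function(st, tau2, sigma2) {
  lambda <- tau2 / sigma2
  cj <- lambda / (1 + lambda * st$nj)
  A <- st$XtX - crossprod(st$SX, st$SX * cj)
  b <- st$Xty - crossprod(st$SX, st$Sy * cj)[, 1L]
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  beta <- backsolve(R, forwardsolve(t(R), b))
  q <- max(st$yty - sum(cj * st$Sy^2) - sum(beta * b), 1e-300)
  np <- st$n - st$p
  np * log(2 * pi) + np * log(sigma2) + sum(log1p(lambda * st$nj)) +
    2 * sum(log(diag(R))) + q / sigma2
}

# Sampling variance of the condition coefficient at (tau2, sigma2).
cond_var_at <- function(st, tau2, sigma2, cond) {
  lambda <- tau2 / sigma2
  cj <- lambda / (1 + lambda * st$nj)
  A <- st$XtX - crossprod(st$SX, st$SX * cj)
  sigma2 * solve(A)[cond, cond]
}

satterthwaite_df <- function(st, tau2, sigma2, cond) {
  # delta method: df = 2 f^2 / (g' Sigma_theta g), f = Var(beta_cond),
  # Sigma_theta = 2 * inverse observed information of -2 REML loglik.
  h <- c(max(1e-6, 1e-4 * tau2), max(1e-6, 1e-4 * sigma2))
  f0 <- cond_var_at(st, tau2, sigma2, cond)
  g <- c(
    (cond_var_at(st, tau2 + h[1], sigma2, cond) -
       cond_var_at(st, max(tau2 - h[1], 0), sigma2, cond)) /
      (h[1] + min(tau2, h[1])),
    (cond_var_at(st, tau2, sigma2 + h[2], cond) -
       cond_var_at(st, tau2, sigma2 - h[2], cond)) / (2 * h[2]))
  ll <- function(th) reml_m2ll(st, max(th[1], 0), max(th[2], 1e-12))
  th <- c(tau2, sigma2)
  H <- matrix(NA_real_, 2, 2)
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- h[i]
    H[i, i] <- (ll(th + ei) - 2 * ll(th) + ll(th - ei)) / h[i]^2
  }
  e1 <- c(h[1], 0); e2 <- c(0, h[2])
  H[1, 2] <- H[2, 1] <-
    (ll(th + e1 + e2) - ll(th + e1 - e2) - ll(th - e1 + e2) +
       ll(th - e1 - e2)) / (4 * h[1] * h[2])
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(V)) return(NA_real_)
  denom <- drop(t(g) %*% V %*% g)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  2 * f0^2 / denom
}

#' Fit the random-intercept mixed model for one projected dimension
#'
#' Fits, by restricted maximum likelihood, the model
#' \deqn{y_{ij} = \mu + x_j \beta + \sum_l w_{ijl}\gamma_l + \omega_j +
#'   \varepsilon_{ij}}
#' with \eqn{\omega_j \sim N(0, \tau^2)} a per-sample (or per
#' cohort-by-sample) random intercept and \eqn{\varepsilon_{ij} \sim
#' N(0, \sigma^2)} cell-level noise.  The REML criterion is profiled down to
#' the variance ratio \eqn{\lambda = \tau^2/\sigma^2} and minimized by
#' bounded one-dimensional optimization, with the \eqn{\tau^2 = 0} boundary
#' always considered.  The degrees of freedom of the condition coefficient
#' are computed with Satterthwaite's approximation from the
#' observed-information covariance of \eqn{(\hat\tau^2, \hat\sigma^2)}; when
#' the variance-ratio estimate hits the zero boundary the fit degenerates to
#' ordinary least squares with residual degrees of freedom.
#'
#' @param scores_k numeric response vector (one projected dimension, one
#'   value per cell).
#' @param meta per-cell metadata containing the columns named in `spec`.
#' @param spec a [model_spec()].
#' @return A list of class \code{"celldist_dimfit"} with elements
#'   \code{effect} (condition coefficient), \code{se}, \code{df}
#'   (Satterthwaite), \code{tau2}, \code{sigma2}, \code{converged},
#'   \code{reml_crit} (the minimized \eqn{-2} REML log-likelihood) and
#'   \code{coefficients}.
#' @export
#' @examples
#' set.seed(1)
#' meta <- data.frame(sample = rep(paste0("s", 1:6), each = 20),
#'                    condition = rep(c(0, 1), each = 60))
#' y <- 0.5 * meta$condition + rep(rnorm(6, sd = 0.3), each = 20) + rnorm(120)
#' fit_dimension(y, meta, model_spec())
fit_dimension <- function(scores_k, meta, spec = model_spec()) {
  y <- as.numeric(scores_k)
  if (length(y) != nrow(meta))
    stop_celldist("length of scores does not match metadata rows")
  des <- build_design(meta, spec)
  fit_dimension_xy(y, des$X, des$group, cond = des$cond)
}

# Engine entry point on an explicit design; shared by fit_dimension and the
# per-gene fits in the importance module.
fit_dimension_xy <- function(y, X, group, cond = 2L) {
  st <- reml_stats(y, X, group)
  e0 <- reml_profile_eval(st, 0)
  opt <- tryCatch(
    stats::optimize(function(u) reml_profile_eval(st, exp(u))$crit,
                    interval = c(-14, 14), tol = 1e-10),
    error = function(e) NULL)
  use_boundary <- is.null(opt) || e0$crit <= opt$objective + 1e-10
  if (use_boundary) {
    # tau2 on the zero boundary: ordinary least squares, residual df
    ev <- e0
    tau2 <- 0
    df <- st$n - st$p
  } else {
    ev <- reml_profile_eval(st, exp(opt$minimum))
    tau2 <- ev$lambda * ev$sigma2
    df <- satterthwaite_df(st, tau2, ev$sigma2, cond)
    if (!is.finite(df) || df <= 0) df <- max(st$J - st$p, 1)
  }
  Ainv_cc <- sum(forwardsolve(t(ev$cholA), diag(st$p)[, cond])^2)
  se <- sqrt(ev$sigma2 * Ainv_cc)
  converged <- is.finite(ev$crit) && is.finite(se) && se > 0
  structure(list(effect = unname(ev$beta[cond]), se = se, df = df,
                 tau2 = tau2, sigma2 = ev$sigma2, converged = converged,
                 reml_crit = ev$crit,
                 coefficients = stats::setNames(as.vector(ev$beta),
                                                colnames(X)),
                 n = st$n, n_groups = st$J),
            class = "celldist_dimfit")
}

#' @export
print.celldist_dimfit <- function(x, ...) {
  cat(sprintf(
    "dimension fit: effect %.4g (se %.4g, df %.3g), tau2 %.4g, sigma2 %.4g%s\n",
    x$effect, x$se, x$df, x$tau2, x$sigma2,
    if (x$converged) "" else " [not converged: OLS fallback]"))
  invisible(x)
}

#' Fit every projected dimension independently
#'
#' Applies [fit_dimension()] to each column of a score matrix.  Dimensions
#' whose fit fails outright are flagged (`converged = FALSE`) with a warning
#' and should be excluded from downstream testing.
#'
#' @param scores a \code{"celldist_scores"} object from [project_cells()] or
#'   a plain cells-by-K numeric matrix.
#' @param meta per-cell metadata; taken from `scores` when omitted.
#' @param spec a [model_spec()].
#' @return A list of \code{"celldist_dimfit"} objects of length K.
#' @export
fit_all_dimensions <- function(scores, meta = NULL, spec = model_spec()) {
  if (inherits(scores, "celldist_scores")) {
    meta <- meta %||% scores$meta
    scores <- scores$scores
  }
  if (is.null(meta)) stop_celldist("meta is required for plain matrix input")
  scores <- as_dense(scores)
  if (ncol(scores) < 1L) stop_celldist("need at least one dimension")
  des <- build_design(meta, spec)
  fits <- vector("list", ncol(scores))
  for (k in seq_len(ncol(scores))) {
    fits[[k]] <- tryCatch(
      fit_dimension_xy(scores[, k], des$X, des$group, des$cond),
      error = function(e) {
        structure(list(effect = NA_real_, se = NA_real_, df = NA_real_,
                       tau2 = NA_real_, sigma2 = NA_real_, converged = FALSE,
                       reml_crit = NA_real_, coefficients = NULL,
                       n = nrow(scores), n_groups = NA_integer_),
                  class = "celldist_dimfit")
      })
  }
  if (all(!vapply(fits, `[[`, TRUE, "converged")))
    stop_celldist("all dimensions failed to fit")
  if (any(!vapply(fits, `[[`, TRUE, "converged")))
    warning("some dimensions did not converge and are flagged", call. = FALSE)
  fits
}
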