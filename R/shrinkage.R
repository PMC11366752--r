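#' Empirical-Bayes spike-and-slab prior for the projected effects
#'
#' The per-dimension condition effects \eqn{\hat x_k} with standard errors
#' \eqn{s_k} are modeled as \eqn{\hat x_k \sim N(x_k, s_k^2)} with the
#' spike-and-slab prior
#' \deqn{x_k \sim \pi_0 \delta_0 + \sum_t \pi_t N(0, \tau_t^2),}
#' where the \eqn{\tau_t} are a fixed geometric grid of slab standard
#' deviations running from \eqn{\min_k s_k / 10} to \eqn{2 \max_k |\hat
#' x_k|} with ratio \eqn{\sqrt 2}.  The mixture weights maximize the
#' marginal likelihood via expectation-maximization on the probability
#' simplex (no penalization), stopping when the marginal log-likelihood
#' improves by less than `tol` or after `max_iter` iterations.
#'
#' @param fits list of \code{"celldist_dimfit"} objects (non-converged
#'   entries are dropped), or a list with numeric elements `x` and `s`.
#' @param tol EM convergence tolerance on the marginal log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return An object of class \code{"celldist_prior"}: \code{pi0},
#'   \code{component_sds}, \code{component_weights}, \code{loglik}
#'   (per-iteration trace) and the data (\code{x}, \code{s}).
#' @export
fit_shrinkage_prior <- function(fits, tol = 1e-6, max_iter = 1000L) {
  xs <- effects_and_ses(fits)
  x <- xs$x; s <- xs$s
  if (length(x) < 1L) stop_celldist("no converged dimension fits")
  hi <- 2 * max(abs(x))
  lo <- min(s) / 10
  sds <- if (hi <= lo) lo else lo * sqrt(2)^(0:ceiling(2 * log2(hi / lo)))
  sds <- sds[sds <= hi * sqrt(2)]
  if (length(sds) == 0L) sds <- lo
  Tn <- length(sds)
  # K x (T+1) matrix of component likelihoods; column 1 is the spike
  slab <- matrix(vapply(sds, function(t)
    stats::dnorm(x, 0, sqrt(s^2 + t^2)), numeric(length(x))),
    nrow = length(x))
  lik <- cbind(stats::dnorm(x, 0, s), slab)
  # spike-favoring start: when the marginal likelihood is flat (all effects
  # within noise of zero) EM stays at the parsimonious null-dominated
  # solution; informative data move the weights away in the first steps
  w <- c(0.99, rep(0.01 / Tn, Tn))
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    marg <- lik %*% w
    ll <- sum(log(pmax(marg, 1e-300)))
    ll_trace <- c(ll_trace, ll)
    resp <- sweep(lik, 2L, w, "*") / as.vector(pmax(marg, 1e-300))
    w_new <- colMeans(resp)
    w_new <- pmax(w_new, 0); w_new <- w_new / sum(w_new)
    if (it > 1L && ll - ll_trace[it - 1L] < tol) { w <- w_new; break }
    w <- w_new
  }
  structure(list(pi0 = w[1L], component_sds = sds,
                 component_weights = w[-1L], loglik = ll_trace,
                 x = x, s = s),
            class = "celldist_prior")
}

effects_and_ses <- function(fits) {
  if (is.list(fits) && !is.null(fits$x)) return(list(x = fits$x, s = fits$s))
  if (inherits(fits, "celldist_dimfit")) fits <- list(fits)
  keep <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  fits <- fits[keep]
  if (length(fits) == 0L) stop_celldist("no converged dimension fits")
  list(x = vapply(fits, `[[`, 0, "effect"), s = vapply(fits, `[[`, 0, "se"))
}

#' @export
print.celldist_prior <- function(x, ...) {
  cat(sprintf(
    "spike-and-slab prior: pi0 = %.3f over %d slab components (sd %.3g..%.3g)\n",
    x$pi0, length(x$component_sds), min(x$component_sds),
    max(x$component_sds)))
  invisible(x)
}

# Posterior draws of one effect under the fitted spike-and-slab prior.
# Conjugate mixture: spike stays at 0; slab t becomes
# N(x * tau^2/(tau^2+s^2), tau^2 s^2/(tau^2+s^2)) with weight
# proportional to prior weight times marginal likelihood.
posterior_component_draws <- function(x_k, s_k, prior, n_draws) {
  liks <- c(prior$pi0 * stats::dnorm(x_k, 0, s_k),
            prior$component_weights *
              stats::dnorm(x_k, 0, sqrt(s_k^2 + prior$component_sds^2)))
  if (sum(liks) <= 0) liks <- c(1, rep(0, length(prior$component_sds)))
  post_w <- liks / sum(liks)
  comp <- sample.int(length(post_w), n_draws, replace = TRUE, prob = post_w)
  out <- numeric(n_draws)
  slab <- comp > 1L
  if (any(slab)) {
    t2 <- prior$component_sds[comp[slab] - 1L]^2
    mu <- x_k * t2 / (t2 + s_k^2)
    sd <- sqrt(t2 * s_k^2 / (t2 + s_k^2))
    out[slab] <- stats::rnorm(sum(slab), mu, sd)
  }
  out
}

#' Posterior distribution of the projected distance
#'
#' Draws posterior samples of each projected effect under the fitted
#' spike-and-slab prior, combines them into samples of
#' \eqn{D_K = \sqrt{\sum_k x_k^2}}, and summarizes the posterior by its
#' median and 5/95 percent quantiles.  Because the posterior of each effect
#' shrinks harder the larger its standard error, noisy dimensions
#' contribute little to the distance.
#'
#' @param fits list of \code{"celldist_dimfit"} objects (or `x`/`s` list).
#' @param prior a \code{"celldist_prior"}; fitted from `fits` when `NULL`.
#' @param n_draws number of posterior draws (at least 100).
#' @param seed optional integer seed for reproducible draws.
#' @return An object of class \code{"celldist_posterior"}: \code{draws},
#'   \code{median}, \code{q05}, \code{q95} and \code{naive}
#'   (\eqn{\sqrt{\sum_k \hat x_k^2}}, the unshrunk plug-in estimate).
#' @export
posterior_distance <- function(fits, prior = NULL, n_draws = 10000L,
                               seed = NULL) {
  if (n_draws < 100L) stop_celldist("n_draws must be at least 100")
  xs <- effects_and_ses(fits)
  prior <- prior %||% fit_shrinkage_prior(fits)
  if (!inherits(prior, "celldist_prior")) stop_celldist("invalid prior")
  if (!is.null(seed)) set.seed(seed)
  ss <- 0
  for (k in seq_along(xs$x)) {
    ss <- ss + posterior_component_draws(xs$x[k], xs$s[k], prior, n_draws)^2
  }
  draws <- sqrt(ss)
  qs <- stats::quantile(draws, c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(draws = draws, median = qs[2L], q05 = qs[1L], q95 = qs[3L],
                 naive = sqrt(sum(xs$x^2))),
            class = "celldist_posterior")
}

#' @export
print.celldist_posterior <- function(x, ...) {
  cat(sprintf("posterior distance: median %.4g [5%%: %.4g, 95%%: %.4g]\n",
              x$median, x$q05, x$q95))
  invisible(x)
}

#' Reweight genes before projection
#'
#' Estimates the weighted distance \eqn{\sqrt{\beta^\top W \beta}} for a
#' diagonal non-negative weight matrix \eqn{W} by rescaling each gene's
#' residuals by \eqn{\sqrt{w_g}} and refitting the projection; estimation
#' downstream of the transform is unchanged.  The result is reported on the
#' square-root scale so it is unit-comparable with the unweighted distance.
#'
#' @param residuals a \code{"celldist_residuals"} object or plain matrix.
#' @param weights length-G non-negative vector of gene weights.
#' @param K number of projection dimensions.
#' @param meta per-cell metadata (taken from `residuals` when available).
#' @return list with the reweighted \code{basis} and \code{scores}.
#' @export
weighted_transform <- function(residuals, weights, K, meta = NULL) {
  if (inherits(residuals, "celldist_residuals")) {
    meta <- meta %||% residuals$meta
    Z <- as_dense(residuals$values)
    ids <- residuals$gene_ids
  } else {
    Z <- as_dense(residuals); ids <- colnames(Z)
  }
  weights <- as.numeric(weights)
  if (length(weights) != ncol(Z))
    stop_celldist("weights must have one entry per gene")
  if (any(weights < 0)) stop_celldist("weights must be non-negative")
  if (all(weights == 0)) stop_celldist("weights must not be all zero")
  Zw <- sweep(Z, 2L, sqrt(weights), "*")
  colnames(Zw) <- ids
  basis <- fit_projection(Zw, K = K)
  scores <- project_cells(Zw, basis, meta = meta)
  list(basis = basis, scores = scores)
}
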