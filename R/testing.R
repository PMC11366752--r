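#' Wald statistic for the null hypothesis of zero distance
#'
#' Sums the squared z-ratios of the per-dimension condition effects,
#' \eqn{W = \sum_k (\hat x_k / \widehat{se}_k)^2}.  Non-converged
#' dimensions must be excluded upstream.
#'
#' @param fits list of \code{"celldist_dimfit"} objects (or `x`/`s` list).
#' @return Non-negative scalar test statistic.
#' @export
wald_statistic <- function(fits) {
  xs <- effects_and_ses(fits)
  if (length(xs$x) == 0L) stop_celldist("empty fit list")
  sum((xs$x / xs$s)^2)
}

#' Monte-Carlo draws from the sum-of-F null distribution
#'
#' Under the null each per-dimension statistic \eqn{W_k} is a squared
#' t-variate with Satterthwaite denominator degrees of freedom
#' \eqn{\nu_k}, i.e. an \eqn{F(1, \nu_k)} variate, and the \eqn{W_k} are
#' treated as independent (the projected noise covariances are multiples of
#' the identity).  The null distribution of \eqn{W = \sum_k W_k} has no
#' closed form; this draws `M` independent realizations of the sum.
#'
#' @param dof_list positive per-dimension degrees of freedom \eqn{\nu_k}.
#' @param M number of Monte-Carlo draws (default 1e5).
#' @param seed optional integer seed.
#' @return Numeric vector of `M` draws.
#' @export
monte_carlo_null <- function(dof_list, M = 1e5, seed = NULL) {
  dof_list <- as.numeric(dof_list)
  if (length(dof_list) == 0L) stop_celldist("empty degrees-of-freedom list")
  if (any(!is.finite(dof_list) | dof_list <= 0))
    stop_celldist("degrees of freedom must be positive")
  if (M < 1) stop_celldist("M must be positive")
  if (!is.null(seed)) set.seed(seed)
  draws <- numeric(M)
  for (nu in dof_list) draws <- draws + stats::rf(M, df1 = 1, df2 = nu)
  draws
}

#' Empirical p-value against Monte-Carlo null draws
#'
#' Computes \eqn{p = (\sum_i I(W_i > W^*) + 1) / (M + 1)} with a strict
#' inequality, so the smallest attainable p-value is \eqn{1/(M+1)}.
#'
#' @param w_star observed test statistic.
#' @param null_draws vector of Monte-Carlo null draws.
#' @return p-value in \eqn{(0, 1]}.
#' @export
empirical_p <- function(w_star, null_draws) {
  if (length(null_draws) == 0L) stop_celldist("null_draws must be non-empty")
  (sum(null_draws > w_star) + 1) / (length(null_draws) + 1)
}

#' Multiple-testing adjustment across cell types
#'
#' Benjamini-Hochberg step-up adjustment by default; Bonferroni and "none"
#' are available.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param method one of `"BH"`, `"bonferroni"`, `"none"`.
#' @return Adjusted p-values, same length.
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(p_values) == 0L) stop_celldist("empty p-value vector")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop_celldist("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = method)
}
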