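make_fits <- function(x, s) lapply(seq_along(x), function(k)
  structure(list(effect = x[k], se = s[k], df = 10, tau2 = 0, sigma2 = 1,
                 converged = TRUE), class = "celldist_dimfit"))

test_that("pure-null effects put essentially all prior mass on the spike", {
  pr <- fit_shrinkage_prior(make_fits(rep(0, 50), rep(1, 50)))
  expect_gte(pr$pi0, 0.99)
  post <- posterior_distance(make_fits(rep(0, 5), rep(1, 5)),
                             prior = structure(list(pi0 = 1,
                                                    component_sds = 1,
                                                    component_weights = 0),
                                               class = "celldist_prior"),
                             n_draws = 500, seed = 1)
  expect_equal(post$median, 0)
  expect_true(all(post$draws == 0))
})

test_that("strong well-measured signals drive the spike weight to zero", {
  set.seed(20)
  x <- rnorm(50, sd = 10)
  pr <- fit_shrinkage_prior(make_fits(x, rep(0.1, 50)))
  expect_lte(pr$pi0, 0.05)
})

test_that("EM marginal log-likelihood is non-decreasing on random inputs", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.1, 5))
    s <- runif(length(x), 0.05, 2)
    pr <- fit_shrinkage_prior(make_fits(x, s))
    expect_true(all(diff(pr$loglik) >= -1e-8))
  }
})

test_that("posterior medians respect the noiseless limit and Pythagoras", {
  # single dimension, tiny se: essentially no shrinkage
  f <- make_fits(2.5, 1e-4)
  post <- posterior_distance(f, n_draws = 2000, seed = 2)
  expect_equal(post$median, 2.5, tolerance = 1e-3)
  # two precise dimensions combine as sqrt(3^2 + 4^2) = 5
  f2 <- make_fits(c(3, 4), c(1e-4, 1e-4))
  post2 <- posterior_distance(f2, n_draws = 2000, seed = 3)
  expect_equal(post2$median, 5, tolerance = 1e-3)
})

test_that("shrinkage is monotone in the standard error and never exceeds
           the naive estimate", {
  set.seed(22)
  # fixed effect, growing se: posterior median of |effect| non-increasing
  pr <- fit_shrinkage_prior(make_fits(rnorm(30), runif(30, 0.3, 1)))
  meds <- sapply(c(0.05, 0.2, 0.5, 1, 2), function(s) {
    median(abs(celldist:::posterior_component_draws(1.5, s, pr, 20000)))
  })
  expect_true(all(diff(meds) <= 0.02))
  # naive-vs-shrunk ordering on random inputs in the model-typical regime
  # (comparable standard errors across dimensions, as per-dimension fits on
  # one dataset produce); 0.01 allowance for Monte-Carlo quantile error
  for (i in 1:50) {
    K <- sample(3:25, 1)
    x <- rnorm(K, sd = runif(1, 0.05, 4))
    s <- rep(runif(1, 0.1, 2), K)
    f <- make_fits(x, s)
    post <- posterior_distance(f, n_draws = 2000, seed = i)
    expect_lte(post$median, sqrt(sum(x^2)) + 0.01)
  }
})

test_that("posterior sampling is reproducible under a fixed seed", {
  f <- make_fits(c(1, -2, 0.3), c(0.5, 0.2, 1))
  a <- posterior_distance(f, n_draws = 500, seed = 99)
  b <- posterior_distance(f, n_draws = 500, seed = 99)
  expect_identical(a$draws, b$draws)
})

test_that("identity weights reproduce the unweighted estimate and
           zero weights erase the signal", {
  set.seed(23)
  sim <- simulate_dataset(sim_config(G = 40, J = 4, cells_per_sample = 25,
                                     tau2 = 0.01, seed = 31,
                                     beta_mode = "sparse_normal",
                                     sparse_p = 0.25))
  Z <- sim$residuals$values
  meta <- sim$residuals$meta
  K <- 10
  base <- estimate_subset(Z, meta, K = K, seed = 5)
  wt1 <- weighted_transform(Z, rep(1, 40), K = K, meta = meta)
  f1 <- fit_all_dimensions(wt1$scores)
  p1 <- posterior_distance(f1, n_draws = 5000, seed = 5)
  expect_equal(p1$median, base$posterior$median, tolerance = 1e-6)
  # zeroing out every truly perturbed gene removes the distance
  w0 <- as.numeric(sim$true_beta == 0)
  wt0 <- weighted_transform(Z, w0, K = K, meta = meta)
  f0 <- fit_all_dimensions(wt0$scores)
  p0 <- posterior_distance(f0, n_draws = 5000, seed = 6)
  # residual null bias is a small fraction of the planted distance
  expect_lt(p0$median, 0.25 * sim$true_D)
  expect_gt(p1$median, 4 * p0$median)
  expect_error(weighted_transform(Z, rep(-1, 40), K = K, meta = meta),
               "non-negative")
})
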