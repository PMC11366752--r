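test_that("Pearson residual arithmetic follows the GLM variance function", {
  # y = 4, mu = 1: Poisson residual 3; NB with alpha = 1 gives (4-1)/sqrt(2)
  fits <- list(list(beta0 = 0, beta1 = 0, alpha = Inf, degenerate = FALSE))
  Y <- matrix(c(4), 1, 1)
  # depth enters through log r; with beta1 = 0 the fitted mean is exp(beta0)
  expect_equal(as.vector(pearson_residuals(Y, fits, clip = NULL)$values), 3)
  fits[[1]]$alpha <- 1
  expect_equal(as.vector(pearson_residuals(Y, fits, clip = NULL)$values),
               3 / sqrt(2))
  # exact fit means zero residuals
  fits2 <- list(list(beta0 = log(2), beta1 = 0, alpha = Inf,
                     degenerate = FALSE))
  Y2 <- matrix(2, 5, 1)
  expect_equal(as.vector(pearson_residuals(Y2, fits2, clip = NULL)$values),
               rep(0, 5))
})

test_that("constant-depth constant-count gene is fitted saturated", {
  Y <- cbind(gene = rep(7, 20), other = rep(3, 20))  # equal depth everywhere
  fits <- suppressMessages(fit_gene_glms(Y, family = "poisson"))
  mu <- exp(fits[[1]]$beta0 + fits[[1]]$beta1 * log(rowSums(Y)[1]))
  expect_equal(mu, 7, tolerance = 1e-6)
  res <- pearson_residuals(Y, fits, clip = NULL)
  expect_equal(max(abs(res$values)), 0, tolerance = 1e-6)
})

test_that("all-zero and low-coverage genes get degenerate zero residuals", {
  set.seed(3)
  Y <- cbind(a = rpois(30, 5), zero = 0L, rare = c(1L, rep(0L, 29)),
             b = rpois(30, 2) + 1L)
  expect_message(fits <- fit_gene_glms(Y, family = "nb", min_cells = 5),
                 "degenerate")
  expect_true(fits[[2]]$degenerate && fits[[3]]$degenerate)
  res <- pearson_residuals(Y, fits, clip = NULL)
  expect_equal(unname(res$values[, 2]), rep(0, 30))
  expect_equal(unname(res$values[, 3]), rep(0, 30))
  expect_error(fit_gene_glms(Y - 1L), "non-negative")
})

test_that("Poisson GLM recovers simulated depth-response coefficients", {
  # counts from log mu = 1 + 0.8 log r; oracle = generic ML optimizer
  set.seed(42)
  n <- 2000
  r <- round(runif(n, 2000, 20000))
  mu <- exp(1 + 0.8 * log(r))
  y <- rpois(n, mu)
  Y <- cbind(g = y, filler = r - y)  # row sums equal the design depth r
  fits <- suppressMessages(fit_gene_glms(Y, family = "poisson"))
  lr <- log(rowSums(Y))
  nll <- function(b) sum(exp(b[1] + b[2] * lr) - y * (b[1] + b[2] * lr))
  grad <- function(b) {
    mu_b <- exp(b[1] + b[2] * lr)
    c(sum(mu_b - y), sum((mu_b - y) * lr))
  }
  opt <- optim(c(0, 1), nll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(fits[[1]]$beta0, opt$par[1], tolerance = 1e-4)
  expect_equal(fits[[1]]$beta1, opt$par[2], tolerance = 1e-4)
  expect_equal(fits[[1]]$beta1, 0.8, tolerance = 0.05)
})

test_that("residuals of a correctly specified Poisson model standardize", {
  set.seed(7)
  n <- 1500
  # per-cell depth factor drives every gene; a high-count filler gene keeps
  # each test gene a small share of the total so depth is effectively
  # external to it
  depth <- exp(rnorm(n, 0, 0.3))
  lam <- c(2, 5, 10)
  Y <- sapply(lam, function(l) rpois(n, l * depth))
  Y <- cbind(Y, filler = rpois(n, 400 * depth))
  colnames(Y)[1:3] <- paste0("g", seq_along(lam))
  fits <- suppressMessages(fit_gene_glms(Y, family = "poisson"))
  res <- pearson_residuals(Y, fits, clip = NULL)
  mns <- colMeans(res$values[, 1:3])
  vrs <- apply(res$values[, 1:3], 2, var)
  expect_lt(max(abs(mns)), 3 / sqrt(n))
  expect_lt(max(abs(vrs - 1)), 0.15)
})

test_that("normalization commutes with gene permutation and clips", {
  set.seed(5)
  Y <- matrix(rpois(200, 6), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  fits <- suppressMessages(fit_gene_glms(Y, family = "nb"))
  res <- pearson_residuals(Y, fits, clip = NULL)
  perm <- sample(10)
  fits_p <- suppressMessages(fit_gene_glms(Y[, perm], family = "nb"))
  res_p <- pearson_residuals(Y[, perm], fits_p, clip = NULL)
  expect_equal(res_p$values, res$values[, perm])
  clipped <- pearson_residuals(Y, fits, clip = 0.5)
  expect_lte(max(abs(clipped$values)), 0.5)
})
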