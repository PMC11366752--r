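test_that("balanced one-cell-per-sample design collapses to two-sample OLS", {
  set.seed(10)
  J <- 8
  meta <- data.frame(sample = paste0("s", 1:(2 * J)),
                     condition = rep(c(0L, 1L), each = J))
  y <- rnorm(2 * J) + 0.3 * meta$condition
  f <- fit_dimension(y, meta)
  expect_equal(f$effect, mean(y[meta$condition == 1]) -
                 mean(y[meta$condition == 0]), tolerance = 1e-10)
  expect_equal(f$df, 2 * J - 2)   # tau2 unidentified: OLS with residual df
})

test_that("balanced replicated design gives the sample-mean contrast and
           Satterthwaite df near J - 2", {
  set.seed(11)
  J <- 6; nc <- 200
  meta <- make_meta(J, nc)
  y <- 0.5 * meta$condition + rep(rnorm(2 * J, sd = 1), each = nc) +
    rnorm(2 * J * nc)
  f <- fit_dimension(y, meta)
  sm <- tapply(y, meta$sample, mean)
  cond_of <- tapply(meta$condition, meta$sample, `[`, 1)
  expect_equal(f$effect, mean(sm[cond_of == 1]) - mean(sm[cond_of == 0]),
               tolerance = 1e-8)
  # with heavy within-sample replication the effective df approach J - 2
  expect_equal(f$df, 2 * J - 2, tolerance = 0.2)
})

test_that("REML recovers the variance components on average", {
  set.seed(12)
  reps <- 100
  est <- t(replicate(reps, {
    d <- sim_mixed(J = 10, nc = 50, effect = 0, tau2 = 0.5, sigma2 = 1)
    f <- fit_dimension(d$y, d$meta)
    c(f$tau2, f$sigma2)
  }))
  # MC tolerance: tau2 estimator sd ~ tau2*sqrt(2/J) / sqrt(reps)
  expect_equal(mean(est[, 1]), 0.5, tolerance = 0.05)
  expect_equal(mean(est[, 2]), 1.0, tolerance = 0.01)
})

test_that("REML criterion and effect match a dense grid-search oracle", {
  set.seed(13)
  for (i in 1:6) {
    J <- sample(2:4, 1)
    d <- sim_mixed(J = J, nc = sample(3:6, 1), effect = rnorm(1),
                   tau2 = runif(1, 0, 1), sigma2 = runif(1, 0.3, 2),
                   unbalanced = TRUE)
    f <- fit_dimension(d$y, d$meta)
    X <- cbind(1, d$meta$condition)
    or <- grid_reml_oracle(d$y, X, d$meta$sample)
    expect_lte(f$reml_crit, or$crit + 1e-4)
    expect_lt(abs(f$effect - or$effect), 1e-6)
  }
})

test_that("engine agrees with the reference mixed-model implementation", {
  skip_if_not_installed("lmerTest")
  set.seed(14)
  for (i in 1:3) {
    d <- sim_mixed(J = 6, nc = 12, effect = 0.6, tau2 = 0.4,
                   unbalanced = TRUE)
    f <- fit_dimension(d$y, d$meta)
    m <- lmerTest::lmer(y ~ condition + (1 | sample),
                        data = cbind(d$meta, y = d$y), REML = TRUE)
    s <- summary(m)$coefficients["condition", ]
    expect_equal(f$effect, unname(s["Estimate"]), tolerance = 1e-6)
    expect_equal(f$se, unname(s["Std. Error"]), tolerance = 1e-4)
    expect_equal(f$df, unname(s["df"]), tolerance = 1e-3)
  }
})

test_that("standard error shrinks as samples per condition double", {
  set.seed(15)
  ses <- sapply(c(4, 8, 16), function(J) {
    mean(replicate(20, {
      d <- sim_mixed(J = J, nc = 20, tau2 = 0.5)
      fit_dimension(d$y, d$meta)$se
    }))
  })
  expect_true(all(diff(ses) < 0))
})

test_that("covariates and nested cohort groupings are honored", {
  set.seed(16)
  meta <- make_meta(4, 15)
  age <- rnorm(nrow(meta))
  y <- 0.4 * meta$condition + 0.8 * age + rnorm(nrow(meta))
  meta$age <- age
  f <- fit_dimension(y, meta, model_spec(covariates = "age"))
  expect_equal(unname(f$coefficients["age"]), 0.8, tolerance = 0.15)
  # collinear covariate is rejected
  meta$dup <- meta$condition
  expect_error(fit_dimension(y, meta, model_spec(covariates = "dup")),
               "singular")
  # sample labels reused across 2 cohorts x 4 donors: when cohort shifts are
  # present, the nested (cohort:sample) grouping separates the donors that the
  # cohort-ignorant grouping wrongly pools, and the standard error widens
  set.seed(17)
  coh <- data.frame(
    sample = rep(rep(paste0("s", 1:4), each = 25), times = 2),
    condition = rep(rep(c(0L, 0L, 1L, 1L), each = 25), times = 2),
    cohort = rep(c("c1", "c2"), each = 100))
  ses <- replicate(30, {
    donor <- interaction(coh$cohort, coh$sample)
    ycoh <- rnorm(nrow(coh), sd = 0.5) +
      (rnorm(8, sd = 0.7))[as.integer(donor)] +
      c(c1 = 0, c2 = rnorm(1, sd = 1.5))[coh$cohort]
    f_flat <- fit_dimension(ycoh, coh, model_spec())
    f_nest <- fit_dimension(ycoh, coh, model_spec(cohort = "cohort"))
    c(f_flat$se, f_nest$se)
  })
  expect_gt(mean(ses[2, ]), mean(ses[1, ]))
})

test_that("fit_all_dimensions is deterministic and flags failures", {
  set.seed(18)
  meta <- make_meta(3, 10)
  S <- matrix(rnorm(60 * 3), 60, 3)
  f1 <- fit_all_dimensions(S, meta)
  f2 <- fit_all_dimensions(S, meta)
  expect_identical(f1, f2)
  expect_length(f1, 3)
  expect_lt(max(abs(vapply(f1, `[[`, 0, "effect"))), 1)  # null data
  expect_error(fit_dimension(S[, 1], meta[1:10, ]), "does not match")
  # fewer than 2 samples per condition is rejected
  m1 <- data.frame(sample = rep(c("a", "b"), each = 10),
                   condition = rep(c(0L, 1L), each = 10))
  expect_error(fit_dimension(rnorm(20), m1), "at least 2 samples")
})
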