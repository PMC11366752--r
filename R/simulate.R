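#' Configuration for the generative simulation model
#'
#' Describes one synthetic dataset drawn from the random-intercept model on
#' the normalized-expression scale:
#' \deqn{z_{ij} = x_j \beta + \omega_j + \varepsilon_{ij},}
#' with \eqn{\omega_j \sim N(0, \tau^2 I_G)} per sample and
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2 I_G)} per cell (the baseline is
#' zero; the pipeline centers the data, so a nonzero baseline has no effect
#' on the distance).  The condition-shift vector \eqn{\beta} is drawn either
#' uniformly from the sphere of radius `D_true` in G dimensions, or sparsely
#' (`beta_mode = "sparse_normal"`) with each gene non-null with probability
#' `sparse_p` and non-null effects standard normal.  With
#' `variance_mode = "gene_gamma"` the shared variances are replaced by
#' per-gene draws \eqn{\sigma_g \sim \Gamma(r, r)} and
#' \eqn{\tau_g \sim \Gamma(r/2, r)} (shape/rate), the model-misspecification
#' stress design.
#'
#' @param G number of genes.
#' @param J number of samples per condition.
#' @param cells_per_sample cells per sample.
#' @param D_true true condition distance (radius of the sphere for
#'   `beta_mode = "sphere"`).
#' @param tau2,sigma2 sample- and cell-level variances.
#' @param seed integer seed; the draw is bit-reproducible given the config.
#' @param variance_mode `"shared"` or `"gene_gamma"`.
#' @param beta_mode `"sphere"` or `"sparse_normal"`.
#' @param sparse_p non-null probability for `beta_mode = "sparse_normal"`.
#' @param gamma_r rate parameter r of the gene-specific variance draws.
#' @return list of class \code{"celldist_simconfig"}.
#' @export
sim_config <- function(G = 100, J = 5, cells_per_sample = 50, D_true = 0,
                       tau2 = 0.5, sigma2 = 1, seed = 1,
                       variance_mode = c("shared", "gene_gamma"),
                       beta_mode = c("sphere", "sparse_normal"),
                       sparse_p = 0.1, gamma_r = 1) {
  variance_mode <- match.arg(variance_mode)
  beta_mode <- match.arg(beta_mode)
  stopifnot(G >= 1, J >= 2, cells_per_sample >= 1, D_true >= 0, tau2 >= 0,
            sigma2 > 0, sparse_p > 0, sparse_p < 1, gamma_r > 0)
  structure(list(G = G, J = J, cells_per_sample = cells_per_sample,
                 D_true = D_true, tau2 = tau2, sigma2 = sigma2, seed = seed,
                 variance_mode = variance_mode, beta_mode = beta_mode,
                 sparse_p = sparse_p, gamma_r = gamma_r),
            class = "celldist_simconfig")
}

# Uniform draw from the sphere of radius D in G dimensions via a normalized
# Gaussian vector (exact for every G).
runif_sphere <- function(G, D) {
  v <- stats::rnorm(G)
  D * v / sqrt(sum(v^2))
}

#' Simulate a normalized-expression dataset from the generative model
#'
#' @param cfg a [sim_config()].
#' @return list: \code{residuals} (a \code{"celldist_residuals"} object with
#'   per-cell `sample`, `condition` metadata), \code{true_beta},
#'   \code{true_D}, and the per-gene standard deviations actually used.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(G = 20, J = 3, cells_per_sample = 5))
#' dim(sim$residuals$values)
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "celldist_simconfig")) stop_celldist("invalid config")
  set.seed(cfg$seed)
  G <- cfg$G
  beta <- switch(cfg$beta_mode,
    sphere = if (cfg$D_true > 0) runif_sphere(G, cfg$D_true) else numeric(G),
    sparse_normal = stats::rnorm(G) *
      (stats::runif(G) < cfg$sparse_p))
  if (cfg$variance_mode == "gene_gamma") {
    sigma_g <- stats::rgamma(G, shape = cfg$gamma_r, rate = cfg$gamma_r)
    tau_g <- stats::rgamma(G, shape = cfg$gamma_r / 2, rate = cfg$gamma_r)
  } else {
    sigma_g <- rep(sqrt(cfg$sigma2), G)
    tau_g <- rep(sqrt(cfg$tau2), G)
  }
  J2 <- 2L * cfg$J
  nc <- cfg$cells_per_sample
  n <- J2 * nc
  sample_id <- rep(paste0("s", seq_len(J2)), each = nc)
  condition <- rep(rep(c(0L, 1L), each = cfg$J), each = nc)
  omega <- matrix(stats::rnorm(J2 * G), J2, G) *
    matrix(tau_g, J2, G, byrow = TRUE)
  Z <- matrix(stats::rnorm(n * G), n, G) * matrix(sigma_g, n, G, byrow = TRUE)
  Z <- Z + omega[rep(seq_len(J2), each = nc), , drop = FALSE]
  Z <- Z + outer(as.numeric(condition), beta)
  gene_ids <- paste0("g", seq_len(G))
  cell_ids <- paste0("c", seq_len(n))
  dimnames(Z) <- list(cell_ids, gene_ids)
  meta <- data.frame(sample = sample_id, condition = condition,
                     row.names = cell_ids, stringsAsFactors = FALSE)
  res <- structure(list(values = Z, gene_ids = gene_ids, cell_ids = cell_ids,
                        meta = meta),
                   class = "celldist_residuals")
  list(residuals = res, true_beta = beta, true_D = sqrt(sum(beta^2)),
       sigma_g = sigma_g, tau_g = tau_g)
}

#' Simulate two latent cell types with a planted condition shift
#'
#' Generates the two-cell-type design used to study annotation and
#' "double dipping": `n_cells` cells and `G` genes, two true cell types
#' separated in expression space, and a condition shift of Euclidean size
#' `D_true` within each type.  Cells are spread over `2 * J` samples (J per
#' condition); each sample contributes an equal number of cells of each
#' type.  The between-type separation is large relative to the noise
#' (default 10) so that 2-means clustering on the data recovers the true
#' types essentially perfectly; its value is recorded in the returned truth.
#'
#' The default has no sample-level variance: the realized condition
#' contrast has squared norm about \eqn{D^2 + 2\tau^2 G/J + 2\sigma^2 G/n_c}
#' (per condition size \eqn{n_c}), so with G large even a small \eqn{\tau^2}
#' would move the recoverable distance well away from the planted value;
#' samples here exist to carry the random-intercept structure of the
#' estimator, not to inject donor variability.
#'
#' @param n_cells total number of cells (must be divisible by `4 * J`).
#' @param G number of genes.
#' @param D_true true within-type condition distance.
#' @param seed integer seed.
#' @param J samples per condition.
#' @param type_sep Euclidean separation between the two type means.
#' @param tau2,sigma2 sample- and cell-level variances.
#' @return list: \code{residuals} (with `sample`, `condition` metadata),
#'   \code{true_type} (latent labels), \code{true_beta} (per-type list),
#'   \code{true_D}, \code{type_sep}.
#' @export
simulate_two_celltypes <- function(n_cells = 4000, G = 1000, D_true = 4,
                                   seed = 1, J = 5, type_sep = 10,
                                   tau2 = 0, sigma2 = 1) {
  if (n_cells %% (4L * J) != 0L)
    stop_celldist("n_cells must be divisible by 4 * J")
  set.seed(seed)
  J2 <- 2L * J
  per_sample <- n_cells %/% J2
  per_type <- per_sample %/% 2L
  delta <- runif_sphere(G, type_sep)       # type-2 mean offset
  beta <- list(t1 = runif_sphere(G, D_true), t2 = runif_sphere(G, D_true))
  sample_id <- rep(paste0("s", seq_len(J2)), each = per_sample)
  condition <- rep(rep(c(0L, 1L), each = J), each = per_sample)
  type <- rep(rep(c("A", "B"), each = per_type), times = J2)
  omega <- matrix(stats::rnorm(J2 * G, sd = sqrt(tau2)), J2, G)
  Z <- matrix(stats::rnorm(n_cells * G, sd = sqrt(sigma2)), n_cells, G)
  Z <- Z + omega[rep(seq_len(J2), each = per_sample), , drop = FALSE]
  isB <- type == "B"
  Z[isB, ] <- sweep(Z[isB, , drop = FALSE], 2L, delta, "+")
  x <- as.numeric(condition)
  Z[!isB & x == 1, ] <- sweep(Z[!isB & x == 1, , drop = FALSE], 2L,
                              beta$t1, "+")
  Z[isB & x == 1, ] <- sweep(Z[isB & x == 1, , drop = FALSE], 2L,
                             beta$t2, "+")
  gene_ids <- paste0("g", seq_len(G)); cell_ids <- paste0("c", seq_len(n_cells))
  dimnames(Z) <- list(cell_ids, gene_ids)
  meta <- data.frame(sample = sample_id, condition = condition,
                     row.names = cell_ids, stringsAsFactors = FALSE)
  res <- structure(list(values = Z, gene_ids = gene_ids, cell_ids = cell_ids,
                        meta = meta),
                   class = "celldist_residuals")
  list(residuals = res, true_type = type, true_beta = beta, true_D = D_true,
       type_sep = type_sep, tau2 = tau2, sigma2 = sigma2)
}

# Run the per-cell-type estimation pipeline on one subset of cells:
# projection (K dims), per-dimension REML fits, shrinkage, posterior.
# Returns the posterior object plus fits, or NULL when the subset cannot
# support the model (fewer than 2 samples in a condition).
estimate_subset <- function(Z, meta, K = 20, spec = model_spec(),
                            n_draws = 5000, seed = NULL) {
  ok <- tryCatch({ build_design(meta, spec); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(NULL)
  K <- min(K, nrow(Z) - 1L, ncol(Z))
  basis <- fit_projection(Z, K = K)
  scores <- project_cells(Z, basis, meta = meta)
  fits <- fit_all_dimensions(scores, spec = spec)
  fits <- fits[vapply(fits, `[[`, TRUE, "converged")]
  prior <- fit_shrinkage_prior(fits)
  post <- posterior_distance(fits, prior, n_draws = n_draws, seed = seed)
  list(posterior = post, fits = fits, prior = prior, basis = basis)
}

#' Cluster cells and estimate per-cluster condition distances
#'
#' Re-runs the distance estimator inside clusters produced from the same
#' expression data, the "double dipping" experiment.  Strategy `"joint"`
#' k-means-clusters all cells together; `"anchor"` clusters only the
#' reference-condition cells and assigns the remaining cells to the nearest
#' centroid, which protects the within-cluster condition contrast from
#' being split away.  Clusters in which either condition contributes fewer
#' than 2 samples or fewer than `min_cells` cells exhibit no measurable
#' within-cluster condition contrast; they enter the summary with distance
#' 0, which is precisely the false-negative signature of over-clustering.
#'
#' @param sim output of [simulate_two_celltypes()] (or any list with a
#'   `residuals` component carrying `sample`/`condition` metadata).
#' @param k number of clusters.
#' @param strategy `"joint"` or `"anchor"`.
#' @param K projection dimensions per cluster.
#' @param seed integer seed (k-means and posterior draws).
#' @param min_cells minimum cells per condition within a cluster; defaults
#'   to `K`, since a K-dimensional contrast cannot be estimated from fewer
#'   minority-condition cells.
#' @return list: \code{median} (median posterior-median distance across
#'   estimable clusters), \code{per_cluster} estimates, \code{cluster}
#'   assignments.
#' @export
cluster_then_estimate <- function(sim, k, strategy = c("joint", "anchor"),
                                  K = 20, seed = 1, min_cells = K) {
  strategy <- match.arg(strategy)
  if (k < 1L) stop_celldist("k must be at least 1")
  Z <- as_dense(sim$residuals$values)
  meta <- sim$residuals$meta
  if (k > nrow(Z)) stop_celldist("k larger than the number of cells")
  set.seed(seed)
  if (strategy == "joint") {
    cl <- stats::kmeans(Z, centers = k, nstart = 5, iter.max = 50)$cluster
  } else {
    ref <- meta$condition == 0
    km <- stats::kmeans(Z[ref, , drop = FALSE], centers = k, nstart = 5,
                        iter.max = 50)
    cl <- integer(nrow(Z))
    cl[ref] <- km$cluster
    d2 <- outer(rowSums(Z[!ref, , drop = FALSE]^2),
                rowSums(km$centers^2), "+") -
      2 * Z[!ref, , drop = FALSE] %*% t(km$centers)
    cl[!ref] <- max.col(-d2)
  }
  ests <- rep(0, k)
  for (g in seq_len(k)) {
    idx <- which(cl == g)
    m <- meta[idx, , drop = FALSE]
    if (min(table(factor(m$condition, levels = c(0, 1)))) < min_cells) next
    est <- estimate_subset(Z[idx, , drop = FALSE], m, K = K,
                           seed = derive_seed(seed, g))
    if (!is.null(est)) ests[g] <- est$posterior$median
  }
  list(median = stats::median(ests), per_cluster = ests, cluster = cl)
}
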