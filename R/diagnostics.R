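#' Pairwise distances between cell types
#'
#' For every unordered pair of cell types, runs the full distance pipeline
#' treating the two type labels as the two "conditions".  Because a
#' biological sample contributes cells to both types, the random intercept
#' is placed on the sample-by-type pseudo-sample so that the condition is
#' constant within each random-effect group.  The resulting symmetric
#' matrix (zero diagonal) can be clustered to check that annotation
#' recapitulates known lineage structure.
#'
#' @param residuals \code{"celldist_residuals"} object or cells-by-genes
#'   matrix.
#' @param meta per-cell metadata with `sample` and cell-type columns.
#' @param cell_type_col name of the annotation column.
#' @param sample_col name of the sample column.
#' @param K projection dimensions per pair.
#' @param seed master seed for posterior draws.
#' @return list of class \code{"celldist_pairwise"}: \code{distance}
#'   (symmetric matrix of posterior medians), \code{p_value} (symmetric).
#' @export
pairwise_celltype_distances <- function(residuals, meta = NULL,
                                        cell_type_col = "cell_type",
                                        sample_col = "sample", K = 20,
                                        seed = 1) {
  if (inherits(residuals, "celldist_residuals")) {
    meta <- meta %||% residuals$meta
    Z <- as_dense(residuals$values)
  } else Z <- as_dense(residuals)
  types <- sort(unique(as.character(meta[[cell_type_col]])))
  if (length(types) < 2L) stop_celldist("need at least 2 cell types")
  D <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  P <- matrix(1, length(types), length(types),
              dimnames = list(types, types))
  pair_id <- 0L
  for (a in seq_along(types)) for (b in seq_along(types)) {
    if (b <= a) next
    pair_id <- pair_id + 1L
    idx <- which(meta[[cell_type_col]] %in% types[c(a, b)])
    m <- data.frame(
      condition = as.integer(meta[[cell_type_col]][idx] == types[b]),
      sample = paste(meta[[sample_col]][idx],
                     meta[[cell_type_col]][idx], sep = "."),
      stringsAsFactors = FALSE)
    est <- estimate_subset(Z[idx, , drop = FALSE], m, K = K,
                           seed = derive_seed(seed, pair_id))
    if (is.null(est))
      stop_celldist("cell type pair ", types[a], "/", types[b],
                    " has fewer than 2 contributing samples")
    w <- wald_statistic(est$fits)
    nd <- monte_carlo_null(vapply(est$fits, `[[`, 0, "df"), M = 1e4,
                           seed = derive_seed(seed, 1000L + pair_id))
    D[a, b] <- D[b, a] <- est$posterior$median
    P[a, b] <- P[b, a] <- empirical_p(w, nd)
  }
  structure(list(distance = D, p_value = P), class = "celldist_pairwise")
}

#' @export
print.celldist_pairwise <- function(x, digits = 3, ...) {
  cat("pairwise cell-type distances (posterior medians):\n")
  print(signif(x$distance, digits))
  invisible(x)
}

#' Multi-resolution cell-type tree with per-node condition distances
#'
#' Builds a binary merge tree over the cell types (Ward linkage on
#' Euclidean distances between per-type mean score vectors in a pooled
#' principal-component basis) and computes the condition-distance result on
#' the union of each node's descendant cells, leaves included.  Internal
#' nodes that are significant while none of their children are get flagged:
#' a large parent distance over quiet children is the signature of
#' over-clustering, where a real condition shift has been split across
#' annotation boundaries.
#'
#' @param residuals \code{"celldist_residuals"} object or matrix.
#' @param meta per-cell metadata.
#' @param spec a [model_spec()].
#' @param cell_type_col annotation column name.
#' @param K pooled-basis and per-node projection dimensions.
#' @param alpha significance level used for flagging.
#' @param mc_draws Monte-Carlo null draws per node.
#' @param seed master seed.
#' @return list of class \code{"celldist_tree"}: \code{hclust}, \code{nodes}
#'   (data.frame: node id, members, distance, p-value, flag),
#'   \code{newick} (annotated newick string).
#' @export
multiresolution_tree <- function(residuals, meta = NULL,
                                 spec = model_spec(),
                                 cell_type_col = "cell_type", K = 20,
                                 alpha = 0.05, mc_draws = 1e4, seed = 1) {
  if (inherits(residuals, "celldist_residuals")) {
    meta <- meta %||% residuals$meta
    Z <- as_dense(residuals$values)
  } else Z <- as_dense(residuals)
  types <- sort(unique(as.character(meta[[cell_type_col]])))
  if (length(types) < 2L) stop_celldist("need at least 2 cell types")
  K_pool <- min(K, nrow(Z) - 1L, ncol(Z))
  pooled <- fit_projection(Z, K = K_pool)
  sc <- project_cells(Z, pooled, meta = meta)$scores
  centers <- rowsum(sc, meta[[cell_type_col]]) /
    as.vector(table(meta[[cell_type_col]])[types])
  hc <- stats::hclust(stats::dist(centers), method = "ward.D2")

  node_result <- function(members, salt) {
    idx <- which(meta[[cell_type_col]] %in% members)
    est <- tryCatch(
      estimate_subset(Z[idx, , drop = FALSE], meta[idx, , drop = FALSE],
                      K = K, spec = spec, seed = derive_seed(seed, salt)),
      error = function(e) NULL)
    if (is.null(est)) return(c(NA_real_, NA_real_))
    w <- wald_statistic(est$fits)
    nd <- monte_carlo_null(vapply(est$fits, `[[`, 0, "df"), M = mc_draws,
                           seed = derive_seed(seed, 500L + salt))
    c(est$posterior$median, empirical_p(w, nd))
  }

  n_leaf <- length(types)
  labels <- hc$labels
  # member sets: leaves are negative indices, internal nodes rows of merge
  members_of <- function(i) {
    if (i < 0) return(labels[-i])
    c(members_of(hc$merge[i, 1]), members_of(hc$merge[i, 2]))
  }
  rows <- list()
  for (leaf in seq_len(n_leaf)) {
    r <- node_result(labels[leaf], leaf)
    rows[[length(rows) + 1L]] <- data.frame(
      node = paste0("leaf:", labels[leaf]), internal = FALSE,
      members = labels[leaf], distance = r[1], p_value = r[2],
      flagged = FALSE, stringsAsFactors = FALSE)
  }
  child_p <- function(i) {
    # p-values of the two children of internal node i
    vapply(hc$merge[i, ], function(ch) {
      id <- if (ch < 0) paste0("leaf:", labels[-ch]) else paste0("node", ch)
      res <- rows[[match(id, vapply(rows, `[[`, "", "node"))]]
      res$p_value
    }, 0)
  }
  for (i in seq_len(nrow(hc$merge))) {
    mem <- members_of(i)
    r <- node_result(mem, n_leaf + i)
    cp <- child_p(i)
    flag <- isTRUE(!is.na(r[2]) && r[2] < alpha &&
                     all(is.na(cp) | cp >= alpha))
    rows[[length(rows) + 1L]] <- data.frame(
      node = paste0("node", i), internal = TRUE,
      members = paste(mem, collapse = ","), distance = r[1],
      p_value = r[2], flagged = flag, stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, rows)
  phy <- ape::as.phylo(hc)
  ints <- nodes[nodes$internal, , drop = FALSE]
  # ape internal-node order: root = node of last merge; match by member sets
  phy$node.label <- vapply(seq_len(phy$Nnode), function(j) {
    tips <- ape::extract.clade(phy, n_leaf + j)$tip.label
    hit <- which(vapply(strsplit(ints$members, ","), function(mm)
      setequal(mm, tips), TRUE))
    if (length(hit) == 1L)
      sprintf("D=%.3g|p=%.3g%s", ints$distance[hit], ints$p_value[hit],
              if (ints$flagged[hit]) "|flag" else "")
    else ""
  }, "")
  structure(list(hclust = hc, nodes = nodes,
                 newick = ape::write.tree(phy)),
            class = "celldist_tree")
}

#' @export
print.celldist_tree <- function(x, digits = 3, ...) {
  cat("multi-resolution cell-type tree\n")
  df <- x$nodes
  df$distance <- signif(df$distance, digits)
  df$p_value <- signif(df$p_value, digits)
  print(df[, c("node", "members", "distance", "p_value", "flagged")],
        row.names = FALSE)
  if (any(x$nodes$flagged, na.rm = TRUE))
    cat("flagged nodes: significant parent over non-significant children",
        "(possible over-clustering)\n")
  invisible(x)
}

#' Cell-number variation of a study design
#'
#' The ratio of the largest sample's cell count to the total cell count, a
#' design-imbalance diagnostic in (0, 1]: 1/J for J equally sized samples,
#' 1 when a single sample contributes every cell.  Invariant to rescaling
#' all counts.
#'
#' @param meta per-cell metadata (or a vector of per-cell sample ids).
#' @param sample_col sample column name when `meta` is a data.frame.
#' @return scalar in (0, 1].
#' @export
#' @examples
#' cell_number_variation(rep(c("a", "b", "c", "d"), c(100, 100, 100, 700)))
cell_number_variation <- function(meta, sample_col = "sample") {
  s <- if (is.data.frame(meta)) meta[[sample_col]] else meta
  if (length(s) == 0L) stop_celldist("empty metadata")
  n <- table(s)
  max(n) / sum(n)
}

#' Reference distance from condition-mean expression profiles
#'
#' Computes the ground-truth perturbation measure used when a full cohort
#' is available to define truth: per-gene log-fold-changes
#' \eqn{L_g} between the mean log-transformed expressions of the two
#' conditions, summed as \eqn{\sum_g L_g^2}.  This quantity is a squared
#' distance; set `sqrt = TRUE` for the Euclidean-scale value comparable
#' with the model-based distance.
#'
#' @param expr_cond0,expr_cond1 aligned per-gene mean log-expression
#'   vectors (log(1 + x) scale) for the two conditions.
#' @param sqrt return the square root (Euclidean scale) instead.
#' @return non-negative scalar.
#' @export
#' @examples
#' ground_truth_distance(c(0, 0), c(3, 4))                 # 25
#' ground_truth_distance(c(0, 0), c(3, 4), sqrt = TRUE)    # 5
ground_truth_distance <- function(expr_cond0, expr_cond1, sqrt = FALSE) {
  if (length(expr_cond0) != length(expr_cond1))
    stop_celldist("gene sets do not match")
  d <- sum((expr_cond1 - expr_cond0)^2)
  if (sqrt) base::sqrt(d) else d
}
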