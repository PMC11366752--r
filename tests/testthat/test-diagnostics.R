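sim_three_types <- function(seed = 50, G = 60, J = 4, nc = 30,
                            sep_close = 3, sep_far = 12) {
  # planted hierarchy: types T1 and T2 close, T3 far from both
  set.seed(seed)
  d12 <- celldist:::runif_sphere(G, sep_close)
  d3 <- celldist:::runif_sphere(G, sep_far)
  n <- 2 * J * nc
  meta <- data.frame(sample = rep(paste0("s", 1:(2 * J)), each = nc),
                     condition = 0L)
  build <- function(shift) {
    Z <- matrix(rnorm(n * G), n, G) +
      rep(rnorm(2 * J, sd = 0.3), each = nc)
    sweep(Z, 2, shift, "+")
  }
  Z <- rbind(build(rep(0, G)), build(d12), build(d3))
  colnames(Z) <- paste0("g", seq_len(G))
  meta <- rbind(meta, meta, meta)
  meta$cell_type <- rep(c("T1", "T2", "T3"), each = n)
  list(Z = Z, meta = meta)
}

test_that("pairwise distances are symmetric, zero-diagonal, and track the
           planted separations", {
  s <- sim_three_types()
  pw <- pairwise_celltype_distances(s$Z, s$meta, K = 10, seed = 1)
  D <- pw$distance
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["T1", "T2"], 3, tolerance = 0.35)
  expect_gt(D["T1", "T3"], D["T1", "T2"])
  # one true type split in half at random: distance indistinguishable from 0
  idx1 <- which(s$meta$cell_type == "T1")
  m2 <- s$meta[idx1, ]
  m2$cell_type <- rep(c("T1", "T1b"), length.out = length(idx1))
  pw2 <- pairwise_celltype_distances(s$Z[idx1, ], m2, K = 10, seed = 2)
  # null self-comparison: small relative to the real separations and
  # non-significant
  expect_lt(pw2$distance["T1", "T1b"], 1)
  expect_gt(pw2$p_value["T1", "T1b"], 0.05)
  # average-linkage clustering recovers the planted topology
  hc <- hclust(as.dist(D), method = "average")
  ct <- cutree(hc, 2)
  expect_equal(unname(ct["T1"]), unname(ct["T2"]))
  expect_false(ct["T3"] == ct["T1"])
})

test_that("multi-resolution tree flags a split of one true type under a
           condition shift", {
  set.seed(51)
  G <- 60; J <- 4; nc <- 40; n <- 2 * J * nc
  beta <- celldist:::runif_sphere(G, 4)
  meta <- data.frame(sample = rep(paste0("s", 1:(2 * J)), each = nc),
                     condition = rep(rep(c(0L, 1L), each = J), each = nc))
  Z <- matrix(rnorm(n * G), n, G) + rep(rnorm(2 * J, sd = 0.1), each = nc) +
    outer(as.numeric(meta$condition), beta)
  colnames(Z) <- paste0("g", seq_len(G))
  # annotation splits the single true type by condition (double dipping)
  meta$cell_type <- ifelse(meta$condition == 1, "X-hi", "X-lo")
  tr <- multiresolution_tree(Z, meta, K = 10, mc_draws = 2000, seed = 3)
  expect_s3_class(tr$hclust, "hclust")
  expect_setequal(tr$nodes$members[!tr$nodes$internal], c("X-hi", "X-lo"))
  root <- tr$nodes[tr$nodes$internal, ]
  # children are condition-pure (no within-type contrast -> NA), parent
  # carries the full shift and is significant: flagged
  expect_lt(root$p_value, 0.05)
  expect_equal(root$distance, 4, tolerance = 0.3)
  expect_true(root$flagged)
  expect_match(tr$newick, "flag")
})

test_that("cell-number variation is the max-share ratio and scale-free", {
  expect_equal(cell_number_variation(rep(c("a", "b", "c", "d"),
                                         c(100, 100, 100, 700))), 0.7)
  expect_equal(cell_number_variation(rep("only", 5)), 1)
  expect_equal(cell_number_variation(rep(letters[1:4], each = 9)), 0.25)
  expect_equal(cell_number_variation(rep(c("a", "b"), c(30, 70))),
               cell_number_variation(rep(c("a", "b"), c(3, 7))))
  expect_error(cell_number_variation(character(0)), "empty")
})

test_that("reference distance is the sum of squared log fold changes", {
  expect_equal(ground_truth_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(ground_truth_distance(c(0, 1), c(1, 0)), 2)
  expect_equal(ground_truth_distance(c(0, 0), c(3, 4)), 25)
  expect_equal(ground_truth_distance(c(0, 0), c(3, 4), sqrt = TRUE), 5)
  expect_error(ground_truth_distance(1:3, 1:2), "match")
})
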