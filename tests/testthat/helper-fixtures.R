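# Small in-code fixtures shared across tests.

# Balanced two-condition metadata: J samples per condition, nc cells each.
make_meta <- function(J = 5, nc = 10) {
  data.frame(sample = rep(paste0("s", seq_len(2 * J)), each = nc),
             condition = rep(rep(c(0L, 1L), each = J), each = nc),
             stringsAsFactors = FALSE)
}

# Random-intercept data on an explicit design (for engine-level tests).
sim_mixed <- function(J = 6, nc = 8, effect = 0, tau2 = 0.5, sigma2 = 1,
                      unbalanced = FALSE) {
  njs <- if (unbalanced) sample(3:(2 * nc), 2 * J, replace = TRUE)
         else rep(nc, 2 * J)
  samp <- rep(paste0("s", seq_len(2 * J)), njs)
  cond <- rep(rep(c(0L, 1L), each = J), njs)
  y <- effect * cond + rep(rnorm(2 * J, sd = sqrt(tau2)), njs) +
    rnorm(sum(njs), sd = sqrt(sigma2))
  list(y = y, meta = data.frame(sample = samp, condition = cond,
                                stringsAsFactors = FALSE))
}

# Write a tiny 10x-style triplet dataset (genes x cells mtx + TSVs) and
# return the three paths.
write_mtx_fixture <- function(dir, counts_cells_by_genes, meta,
                              gene_ids = colnames(counts_cells_by_genes)) {
  m <- Matrix::Matrix(t(counts_cells_by_genes), sparse = TRUE)
  mp <- file.path(dir, "counts.mtx")
  Matrix::writeMM(m, mp)
  gp <- file.path(dir, "genes.tsv")
  write.table(data.frame(gene_id = gene_ids), gp, sep = "\t",
              row.names = FALSE, quote = FALSE)
  cp <- file.path(dir, "cells.tsv")
  write.table(cbind(cell_id = rownames(counts_cells_by_genes), meta), cp,
              sep = "\t", row.names = FALSE, quote = FALSE)
  list(matrix = mp, genes = gp, cells = cp)
}
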