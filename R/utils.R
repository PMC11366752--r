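# internal helpers shared across modules

# Derive a reproducible child seed from a master seed and an integer salt.
# Kept strictly below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + as.double(salt) * 7919 + 12345) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dense numeric matrix from possibly sparse input.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else if (is.matrix(x)) x else as.matrix(x)
}

stop_celldist <- function(...) stop(..., call. = FALSE)

check_meta_cols <- function(meta, cols) {
  miss <- setdiff(cols, colnames(meta))
  if (length(miss) > 0L) {
    stop_celldist("missing column(s) in cell metadata: ",
                  paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
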