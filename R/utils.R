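# Internal helpers shared across modules.

# Deterministic sub-seed from a parent seed and a label, so each analysis
# stage (and each sample pair within a stage) gets its own reproducible
# stream and adding a stage never perturbs another stage's randomness.
# Kept strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# seed = NULL uses (and advances) the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce dist or matrix to a labelled square matrix, checking symmetry.
as_dist_matrix <- function(d, arg = "d") {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) stop(arg, " must be a square distance matrix")
  if (max(abs(m - t(m))) > 1e-12) stop(arg, " is not symmetric")
  if (any(!is.finite(m))) stop(arg, " has non-finite entries")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  m
}

pair_index <- function(n) {
  idx <- combn(n, 2L)
  tibble(i = idx[1L, ], j = idx[2L, ])
}
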