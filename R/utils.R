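# Shared numeric helpers and condition classes.

abort_vitelm <- function(message, class) {
  abort(message, class = c(paste0("vitelm_", class), "vitelm_error"))
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Exact (erf-based) GELU.
gelu <- function(x) x * pnorm(x)

# Row-wise layer normalisation: standardise each row (population variance),
# then apply a learned per-column scale and offset.
layer_norm <- function(x, scale, offset, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  sweep(sweep((x - mu) / sqrt(v + eps), 2L, scale, "*"), 2L, offset, "+")
}

# Run `expr` under `seed` when given, without disturbing the caller's RNG;
# with seed = NULL the current stream is used.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

# Feature columns follow the f1, f2, ... naming convention.
feature_cols_of <- function(data) {
  grep("^f[0-9]+$", names(data), value = TRUE)
}

feature_matrix <- function(data, feature_cols = NULL) {
  cols <- feature_cols %||% feature_cols_of(data)
  if (length(cols) == 0L) {
    abort_vitelm("no feature columns (named f1, f2, ...) found", "invalid_input")
  }
  as.matrix(data[cols])
}
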