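# Internal helpers shared across modules: classed error conditions, seeded
# parameter initialisation, and small numerical primitives.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers/tests can distinguish failure modes.
nf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "nf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

nf_config_error     <- function(msg, ...) nf_stop("nf_config_error", msg, ...)
nf_shape_error      <- function(msg, ...) nf_stop("nf_shape_error", msg, ...)
nf_input_error      <- function(msg, ...) nf_stop("nf_input_error", msg, ...)
nf_degenerate_error <- function(msg, ...) nf_stop("nf_degenerate_error", msg, ...)
nf_numeric_error    <- function(msg, ...) nf_stop("nf_numeric_error", msg, ...)
nf_io_error         <- function(msg, ...) nf_stop("nf_io_error", msg, ...)

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All package randomness flows through this.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream label, staying < 2^31.
derive_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

# Gaussian init scaled by 1/sqrt(fan_in), the usual dense-layer scheme.
init_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(max(1, n_in))), n_in, n_out)
}

l2_normalize_rows <- function(M, eps = 1e-12) {
  nrm <- sqrt(rowSums(M^2))
  M / pmax(nrm, eps)
}

# Row-wise softmax with max subtraction; -Inf entries get exactly zero mass.
row_softmax <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E[is.nan(E)] <- 0 # rows that are all -Inf
  E / pmax(rowSums(E), .Machine$double.xmin)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

gelu <- function(x) x * stats::pnorm(x)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) nf_numeric_error("non-finite values in %s", what)
  invisible(x)
}
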