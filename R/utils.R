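# Small shared helpers: argument checks, seeded RNG scoping, vector algebra on
# n x 3 matrices (time along rows). All internal.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Evaluate `expr` with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards so package functions never disturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (stable, < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Rowwise cross product of n x 3 matrices (either may be a length-3 vector).
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = max(1, NROW(b)), ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, nrow = nrow(a), ncol = 3, byrow = TRUE)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# Rowwise dot product of n x 3 matrices.
dot3 <- function(a, b) rowSums(a * b)

mat3_const <- function(v, n) matrix(v, nrow = n, ncol = 3, byrow = TRUE)

# Truncated-normal draws by rejection (bounds in the same units as mean/sd).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd < 0) abort("`sd` must be >= 0.")
  if (lower > upper) abort("truncation bounds are inverted.")
  if (sd == 0) {
    if (mean < lower || mean > upper) abort("degenerate mean outside truncation bounds.")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# Round half away from zero (display convention for BW conversions).
round_half_out <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
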