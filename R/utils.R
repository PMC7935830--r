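# Internal helpers: seed derivation, argument checks, finite differences.

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  for (k in seq_along(stream)) {
    s <- (s * 48271 + as.double(stream[k]) * 9739 + 1) %% m
  }
  as.integer(s)
}

# Run code with a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), mode = "integer"))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

# Central finite-difference Jacobian of a vector-valued function, relative
# step `rel` (absolute step floor `abs_min` for arguments near zero).
fd_jacobian <- function(fn, x, rel = 1e-4, abs_min = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- max(abs(x[k]) * rel, abs_min)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}
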