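# Internal numeric helpers shared across modules.

# Cumulative trapezoidal integral of each column of Y over uniform grid t.
# Returns a matrix of the same shape with value 0 at the first row.
cumtrapz_uniform <- function(dt, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2L) return(Y * 0)
  inc <- (Y[-1L, , drop = FALSE] + Y[-n, , drop = FALSE]) * (dt / 2)
  rbind(matrix(0, 1L, ncol(Y)), apply(inc, 2L, cumsum))
}

# Trapezoidal integral of vector y over (possibly non-uniform) grid t.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(t) / 2)
}

# Minimum-jerk interpolant and derivatives on normalized time tau in [0, 1].
minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
minjerk_d1 <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
minjerk_d2 <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

# Smooth bump with continuous value, slope and curvature at both ends:
# b(0)=b(1)=0, b(1/2)=1, b'(0)=b'(1)=0, b''(0)=b''(1)=0.
bump3 <- function(tau) sin(pi * tau)^3
bump3_d1 <- function(tau) 3 * pi * sin(pi * tau)^2 * cos(pi * tau)
bump3_d2 <- function(tau) {
  3 * pi^2 * (2 * sin(pi * tau) * cos(pi * tau)^2 - sin(pi * tau)^3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run an expression with a locally seeded RNG, restoring the caller's
# generator state afterwards.  seed = NULL leaves the global stream alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
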