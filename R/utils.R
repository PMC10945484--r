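# Internal numerics shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  seed = NULL leaves the stream untouched (still consumes it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopif_not_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

# Trapezoidal integral of y over x (x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Sub-grid refinement of an extremum: 3-point parabola through
# (x0 - h, y1), (x0, y2), (x0 + h, y3) on a uniform local grid.
# Returns c(x, y) of the vertex; falls back to the grid point when the
# parabola degenerates.
parabolic_vertex <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(c(x = x[i], y = y[i]))
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(abs(c(y1, y2, y3)), 1))
    return(c(x = x[i], y = y[i]))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- (x[i + 1L] - x[i - 1L]) / 2
  c(x = x[i] + delta * h, y = y2 - 0.25 * (y1 - y3) * delta)
}

# Adaptive Cash-Karp Runge-Kutta 4(5) for a scalar (or small vector) ODE.
# f(t, y) -> dy/dt.  Returns a matrix of states at the requested `times`
# (first element must be the initial time).  Errors on non-finite state.
rk45_integrate <- function(f, y0, times, rtol = 1e-8, atol = NULL) {
  if (length(times) < 1L) stop("`times` must be non-empty", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (is.null(atol)) atol <- rtol * max(abs(y0), 1)

  # Cash-Karp tableau
  a <- c(1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
  b21 <- 1 / 5
  b31 <- 3 / 40;        b32 <- 9 / 40
  b41 <- 3 / 10;        b42 <- -9 / 10;     b43 <- 6 / 5
  b51 <- -11 / 54;      b52 <- 5 / 2;       b53 <- -70 / 27;    b54 <- 35 / 27
  b61 <- 1631 / 55296;  b62 <- 175 / 512;   b63 <- 575 / 13824
  b64 <- 44275 / 110592; b65 <- 253 / 4096
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  out[1L, ] <- y0
  y <- y0
  t <- times[1L]
  h <- if (length(times) > 1L) (times[2L] - times[1L]) / 4 else 0
  nstep <- 0L

  for (k in seq_along(times)[-1L]) {
    tk <- times[k]
    while (t < tk) {
      h <- min(h, tk - t)
      repeat {
        nstep <- nstep + 1L
        if (nstep > 1e6L)
          stop("integration failure: step limit exceeded at t = ", signif(t, 6),
               call. = FALSE)
        k1 <- f(t, y)
        k2 <- f(t + a[1] * h, y + h * b21 * k1)
        k3 <- f(t + a[2] * h, y + h * (b31 * k1 + b32 * k2))
        k4 <- f(t + a[3] * h, y + h * (b41 * k1 + b42 * k2 + b43 * k3))
        k5 <- f(t + a[4] * h, y + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4))
        k6 <- f(t + a[5] * h, y + h * (b61 * k1 + b62 * k2 + b63 * k3 +
                                         b64 * k4 + b65 * k5))
        y5 <- y + h * (c5[1] * k1 + c5[3] * k3 + c5[4] * k4 + c5[6] * k6)
        y4 <- y + h * (c4[1] * k1 + c4[3] * k3 + c4[4] * k4 +
                         c4[5] * k5 + c4[6] * k6)
        if (any(!is.finite(y5)))
          stop("integration failure: non-finite state at step ", nstep,
               " (t = ", signif(t, 6), ")", call. = FALSE)
        err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
        if (err <= 1 || h <= .Machine$double.eps * max(abs(t), 1)) {
          t <- t + h
          y <- y5
          # step-size update, clipped growth
          h <- h * min(5, max(0.2, 0.9 * if (err > 0) err^(-0.2) else 5))
          break
        }
        h <- h * max(0.2, 0.9 * err^(-0.25))
      }
    }
    out[k, ] <- y
  }
  out
}
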