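# Independent numerical oracles. These deliberately avoid the package's
# closed-form machinery: the compartment ODEs are integrated with a
# fixed-step classical RK4, convolutions with adaptive quadrature, frame
# averages with a brute-force fine grid.

# RK4 integration of dCf/dt = K1 Ca - (k2+k3) Cf, dCm/dt = k3 Cf from
# state0 at t0 to t1. ca_fun is a function of time. h must divide the
# input-grid spacing so derivative kinks fall on step boundaries.
ode_oracle <- function(p, ca_fun, t0, t1, state0 = c(0, 0), h = 1 / 240) {
  lam <- p$k2 + p$k3
  deriv <- function(t, s) c(p$k1 * ca_fun(t) - lam * s[1L], p$k3 * s[1L])
  n <- round((t1 - t0) / h)
  s <- state0
  t <- t0
  for (i in seq_len(n)) {
    k1 <- deriv(t, s)
    k2 <- deriv(t + h / 2, s + h / 2 * k1)
    k3 <- deriv(t + h / 2, s + h / 2 * k2)
    k4 <- deriv(t + h, s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * h
  }
  s
}

# High-resolution quadrature oracle for the exponential convolution
# integral: brute-force trapezoid at ~1 ms steps (the integrand is
# piecewise smooth, so the error is far below the comparison tolerance).
conv_quad_oracle <- function(input_fn, lam, t, step = 1 / 60000) {
  u <- seq(0, t, by = step)
  f <- stats::approx(input_fn$time, input_fn$ca, xout = u)$y
  g <- exp(-lam * (t - u)) * f
  sum((g[-1] + g[-length(g)]) / 2) * step
}

# Brute-force frame average of a curve on a very fine grid (default ~1 ms).
frame_avg_oracle <- function(time, values, start, end, step = 1 / 60000) {
  f <- stats::approxfun(time, values)
  vapply(seq_along(start), function(i) {
    g <- seq(start[i], end[i], by = step)
    mean(f(g))
  }, numeric(1))
}

# Brute-force physical-space dilation: voxel joins if its centre is within
# radius of any source-voxel centre.
dilate_oracle <- function(mask, radius_mm, vs) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    dd <- ((x - src[, 1]) * vs[1])^2 + ((y - src[, 2]) * vs[2])^2 +
      ((z - src[, 3]) * vs[3])^2
    if (any(dd <= radius_mm^2 + 1e-9)) out[x, y, z] <- TRUE
  }
  out
}
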