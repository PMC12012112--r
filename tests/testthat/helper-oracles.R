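# Independent oracles used across the suite.

# Density of the symmetric stable law by numeric Fourier inversion of the
# characteristic function: f(x) = (1/pi) Int_0^inf cos(ux) exp(-(gamma u)^alpha) du.
# Independent of the closed forms it checks.
sas_pdf_inversion <- function(x, alpha, gamma) {
  vapply(x, function(xx) {
    stats::integrate(function(u) cos(u * xx) * exp(-(gamma * u)^alpha),
                     0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 400L)$value / pi
  }, numeric(1))
}

# Exponential decay rate of a deterministic trajectory toward a fixed point,
# by least squares on log|x(t) - x*|.
fitted_decay_rate <- function(t, x, x_star) {
  r <- log(abs(x - x_star))
  keep <- is.finite(r)
  -unname(stats::coef(stats::lm(r[keep] ~ t[keep]))[2])
}

# Noise sequence with all-zero increments (deterministic flow).
zero_noise <- function(n, alpha = 2, dt = 0.004) {
  noise_increments(n, alpha = alpha, gamma_n = 0, dt = dt, seed = 1)
}

# Inject a single large negative jump into an otherwise quiet sequence.
jump_noise <- function(n, at, size, alpha = 2, dt = 0.004) {
  nz <- zero_noise(n, alpha, dt)
  nz$increments[at] <- size
  nz
}

# Relative-error expectation: |actual/expected - 1| < tol. Used instead of
# expect_equal() for small-magnitude quantities, whose tolerance would
# otherwise be interpreted absolutely.
expect_rel <- function(actual, expected, tol, label = NULL) {
  testthat::expect_lt(abs(actual / expected - 1), tol, label = label)
}
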