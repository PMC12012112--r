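test_that("noise increments: scaling, degenerate case, reproducibility", {
  expect_identical(noise_increments(100, 1.5, 0, seed = 1)$increments,
                   rep(0, 100))
  nz <- noise_increments(1e5, 2, 0.1, dt = 0.004, seed = 21)
  expect_rel(var(nz$increments), 2 * 0.1^2 * 0.004, 0.05)
  nz2 <- noise_increments(1e5, 2, 0.1, dt = 0.004, seed = 21)
  expect_identical(nz$increments, nz2$increments)
})

test_that("window sums of increments follow the self-similar law", {
  # sum of m increments ~ SaS(gamma_n * (m dt)^(1/alpha))
  m <- 50
  for (a in c(2, 1.5)) {
    nz <- noise_increments(1e5, a, 0.1, dt = 0.004, seed = 9)
    sums <- colSums(matrix(nz$increments, nrow = m))
    fit <- fit_sas_quantile(sums, fixed_alpha = a)
    expect_rel(fit$gamma, 0.1 * (m * 0.004)^(1 / a), 0.06,
               label = sprintf("window-sum scale (alpha=%g)", a))
  }
})

test_that("same seed aligns extreme increments across heavy-tailed alpha", {
  n1 <- noise_increments(1e5, 1.8, 0.1, seed = 33)
  n2 <- noise_increments(1e5, 1.5, 0.1, seed = 33)
  top <- function(v) order(abs(v), decreasing = TRUE)[1:10]
  expect_gte(length(intersect(top(n1$increments), top(n2$increments))), 5)
})

test_that("tamed scheme: deterministic flows reach the fixed points", {
  cfg <- sim_config(1000, x0 = 0.5)
  tr_ou <- tamed_euler_maruyama(potential_model("ou", 1), 1, cfg,
                                zero_noise(1000))
  expect_true(all(diff(tr_ou$x) < 0))
  expect_true(all(tr_ou$x > 0))
  expect_lt(abs(tr_ou$x[1000]), 0.01)

  tr_f <- tamed_euler_maruyama(potential_model("fold", 1), 1, cfg,
                               zero_noise(1000))
  expect_lt(abs(tr_f$x[1000] - 1), 1e-3)
})

test_that("taming bounds the per-step drift displacement by dt/epsilon", {
  # start far from equilibrium: |U'| huge, displacement must stay bounded
  cfg <- sim_config(5, dt = 0.004, epsilon = 4e-5, x0 = 1e6)
  tr <- tamed_euler_maruyama(potential_model("fold", 1), 1, cfg, zero_noise(5))
  disp <- abs(diff(c(1e6, tr$x)))
  expect_true(all(disp <= 0.004 / 4e-5 + 1e-9))
})

test_that("plain and tamed schemes agree for bounded drift", {
  cfg <- sim_config(1e4, epsilon = 4e-5, x0 = 0.5)
  nz <- zero_noise(1e4)
  a <- tamed_euler_maruyama(potential_model("ou", 1), 1, cfg, nz)
  b <- plain_euler_maruyama(potential_model("ou", 1), 1, cfg, nz)
  expect_lt(max(abs(a$x - b$x)), 1e-4)
})

test_that("plain scheme diverges on the fold blow-up; tamed does not", {
  nz <- jump_noise(100, at = 10, size = -1000)
  cfg <- sim_config(100, x0 = 0.5)
  pl <- plain_euler_maruyama(potential_model("fold", 1), 1, cfg, nz)
  expect_false(is.na(attr(pl, "diverged_at")))
  expect_true(all(is.finite(pl$x)))  # states recorded only while finite
  tm <- tamed_euler_maruyama(potential_model("fold", 1), 1, cfg, nz)
  expect_true(is.na(attr(tm, "diverged_at")))
  expect_true(all(is.finite(tm$x)))
})

test_that("escape rule fires exactly at -sqrt(k) - k/10 on the post-update state", {
  expect_true(escape_stop(-1.2, 1))    # threshold -1.1
  expect_false(escape_stop(-1.05, 1))
  expect_true(escape_stop(-0.102, 0.01))
  expect_false(escape_stop(-1.1, 1))   # boundary itself does not fire

  # trajectory-level: a jump to just above the threshold continues,
  # just below stops
  cfg <- sim_config(50, x0 = 0.5, stop_on_escape = TRUE)
  below <- jump_noise(50, at = 20, size = -1.7)  # lands well below -1.1
  tr <- tamed_euler_maruyama(potential_model("fold", 1), 1, cfg, below)
  expect_equal(attr(tr, "truncated_at"), 20L)
  expect_equal(nrow(tr), 20)
  above <- jump_noise(50, at = 20, size = -1.3)  # lands near -0.65, inside
  tr2 <- tamed_euler_maruyama(potential_model("fold", 1), 1, cfg, above)
  expect_true(is.na(attr(tr2, "truncated_at")))
  expect_equal(nrow(tr2), 50)
})

test_that("k ramps are arithmetic, exclusive of the bifurcation value", {
  r <- k_ramp(5, 0, 1e-4)
  expect_length(r, 50000)
  expect_equal(r[1], 5)
  expect_equal(r[50000], 1e-4)
  expect_equal(k_ramp(1, 0.5, 0.25), c(1, 0.75))
  expect_true(all(diff(r) < 0))
  expect_error(k_ramp(1, 1, 0.1), class = "alphaews_error_domain")
  expect_error(k_ramp(1, 2, 0.1), class = "alphaews_error_domain")
  expect_error(k_ramp(1, 0, -0.1), class = "alphaews_error_domain")
})

test_that("trajectories are bit-identical under the same config and seed", {
  cfg <- sim_config(5000, stop_on_escape = TRUE)
  nz <- noise_increments(5000, 1.3, 0.1, seed = 77)
  a <- tamed_euler_maruyama(potential_model("fold", 0.5), 0.5, cfg, nz)
  b <- tamed_euler_maruyama(potential_model("fold", 0.5), 0.5, cfg,
                            noise_increments(5000, 1.3, 0.1, seed = 77))
  expect_identical(a$x, b$x)
  expect_identical(attr(a, "truncated_at"), attr(b, "truncated_at"))
})

test_that("stationary OU samples recover the theoretical scale and exponent", {
  n <- 2e6
  cfg <- sim_config(n)
  for (a in c(2, 1.8, 1.5, 1.3)) {
    for (k in c(1, 10)) {
      nz <- noise_increments(n, a, 0.1, seed = 100 + round(10 * a) + k)
      tr <- tamed_euler_maruyama(potential_model("ou", k), k, cfg, nz)
      burn <- 2e5
      spacing <- max(25, round(250 / k))
      xs <- tr$x[seq(burn, n, by = spacing)]
      fit <- fit_sas_quantile(xs)
      theo <- gamma_x_limit(k, a, 0.1)
      expect_rel(fit$gamma, theo, 0.1,
                 label = sprintf("gamma (alpha=%g, k=%g)", a, k))
      expect_lt(abs(fit$alpha - a), 0.1)
    }
  }
})

test_that("Gaussian OU variance matches the closed form across k", {
  n <- 2e6
  cfg <- sim_config(n)
  for (k in c(0.1, 1, 10)) {
    nz <- noise_increments(n, 2, 0.1, seed = 300 + k)
    tr <- tamed_euler_maruyama(potential_model("ou", k), k, cfg, nz)
    v <- var(tr$x[2e5:n])
    expect_rel(v, ou_variance(Inf, k, 0.1), 0.1,
               label = sprintf("variance at k=%g", k))
  }
})
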