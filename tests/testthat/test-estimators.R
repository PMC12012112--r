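test_that("quantile fitter recovers Gaussian parameters and the IQR factor", {
  gs <- vapply(1:20, function(s) {
    fit_sas_quantile(sas_sample(1e5, stable_params(2, 0.1), seed = s))$gamma
  }, numeric(1))
  expect_equal(mean(gs), 0.1, tolerance = 0.02)
  # at alpha = 2 the IQR-to-scale factor is 2 * 0.6745 * sqrt(2) = 1.908
  z <- sas_sample(1e5, stable_params(2, 0.1), seed = 101)
  f <- fit_sas_quantile(z, fixed_alpha = 2)
  expect_equal(f$gamma, unname(diff(quantile(z, c(0.25, 0.75)))) / 1.9077,
               tolerance = 1e-3)
})

test_that("quantile fitter recovers Cauchy parameters", {
  fits <- lapply(1:20, function(s) {
    fit_sas_quantile(sas_sample(1e5, stable_params(1, 1), seed = 200 + s))
  })
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "alpha")), 1,
               tolerance = 0.05)
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "gamma")), 1,
               tolerance = 0.03)
})

test_that("fitters reject inadequate input", {
  expect_error(fit_sas_quantile(rnorm(50)), class = "alphaews_error_toofew")
  expect_error(fit_sas_quantile(rep(1, 500)),
               class = "alphaews_error_degenerate")
  expect_error(fit_sas_ecf(rep(2, 500)), class = "alphaews_error_degenerate")
  expect_error(fit_sas_ecf(rnorm(500), u_grid = c(-1, 1)),
               class = "alphaews_error_domain")
})

test_that("ECF regression on exact characteristic values is exact", {
  u <- c(0.5, 1, 2, 4, 8)
  phi <- sas_cf(u, stable_params(1.5, 0.1))
  fit <- alphaews:::ecf_regress(u, phi)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-8)
  expect_equal(fit$gamma, 0.1, tolerance = 1e-8)
})

test_that("ECF fitter recovers heavy-tail parameters from samples", {
  fits <- lapply(1:20, function(s) {
    fit_sas_ecf(sas_sample(1e5, stable_params(1.3, 0.1), seed = 300 + s))
  })
  expect_lt(abs(mean(vapply(fits, `[[`, numeric(1), "alpha")) - 1.3), 0.05)
  expect_equal(mean(vapply(fits, `[[`, numeric(1), "gamma")), 0.1,
               tolerance = 0.05)
})

test_that("quantile and ECF fits agree on the same draw", {
  z <- sas_sample(1e5, stable_params(1.5, 0.1), seed = 17)
  fq <- fit_sas_quantile(z)
  fe <- fit_sas_ecf(z)
  expect_lt(abs(fq$alpha - fe$alpha), 0.1)
  expect_lt(abs(fq$gamma - fe$gamma) / fq$gamma, 0.1)
})

test_that("both fitters are scale-equivariant", {
  z <- sas_sample(5000, stable_params(1.5, 0.1), seed = 23)
  for (cc in c(0.1, 10)) {
    fq0 <- fit_sas_quantile(z); fq1 <- fit_sas_quantile(cc * z)
    expect_equal(fq1$alpha, fq0$alpha, tolerance = 1e-10)
    expect_equal(fq1$gamma, cc * fq0$gamma, tolerance = 1e-10)
    fe0 <- fit_sas_ecf(z); fe1 <- fit_sas_ecf(cc * z)
    expect_equal(fe1$alpha, fe0$alpha, tolerance = 1e-6)
    expect_equal(fe1$gamma, cc * fe0$gamma, tolerance = 1e-6)
  }
})

test_that("tidy and glance expose the fitted parameters", {
  f <- fit_sas_quantile(sas_sample(1000, stable_params(1.5, 0.1), seed = 1),
                        fixed_alpha = 1.5)
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "gamma"))
  expect_equal(td$estimate[1], 1.5)
  expect_true(td$fixed[1])
  gl <- glance(f)
  expect_equal(gl$method, "quantile")
  expect_equal(gl$n, 1000L)
})

test_that("classical indicators: variance and lag-1 autocorrelation", {
  expect_equal(variance_estimator(c(1, -1, 1, -1)), 4 / 3)
  expect_equal(lag1_autocorr(c(1, -1, 1, -1)), -1)
  expect_error(variance_estimator(1), class = "alphaews_error_toofew")
  expect_error(lag1_autocorr(c(1, 2)), class = "alphaews_error_toofew")
  expect_error(lag1_autocorr(rep(3, 10)), class = "alphaews_error_degenerate")
})

test_that("rolling series: anchor arithmetic and degenerate propagation", {
  set.seed(14)
  tr <- tibble::tibble(step = 1:600, t = (1:600) * 0.004, k = 1,
                       x = sin(1:600) + rnorm(600))
  ser <- rolling_ews(tr, window = 300, stride = 150)
  expect_equal(ser$anchor, c(300, 450, 600))
  expect_equal(nrow(ser), 3)
  const <- tibble::tibble(step = 1:400, t = (1:400) * 0.004, k = 1, x = 1)
  expect_error(rolling_ews(const), class = "alphaews_error_degenerate")
  expect_error(rolling_ews(tr[1:100, ]), class = "alphaews_error_toofew")
})

test_that("rolling scale on a stationary heavy-tailed OU tracks theory", {
  # A 300-point window must span enough correlation times (tau = 1/k in
  # steps: 250/k) for the window IQR to see the marginal law. At k = 10 the
  # window covers 12 correlation times and the median across windows tracks
  # the stationary scale; at k = 1 it covers ~1.2 and is biased low — both
  # behaviors are asserted.
  n <- 5e4
  run <- function(k) {
    nz <- noise_increments(n, 1.5, 0.1, seed = 55)
    tr <- tamed_euler_maruyama(potential_model("ou", k), k, sim_config(n), nz)
    rolling_ews(tr[tr$step > 5000, ], window = 300, stride = 150)
  }
  ser10 <- run(10)
  expect_gte(nrow(ser10), 100)
  expect_rel(median(ser10$gamma_hat), gamma_x_limit(10, 1.5, 0.1), 0.25)
  ser1 <- run(1)
  expect_lt(median(ser1$gamma_hat), gamma_x_limit(1, 1.5, 0.1))
})

test_that("expanding series: anchors and running-statistic behavior", {
  set.seed(15)
  tr <- tibble::tibble(step = 1:1200, t = (1:1200) * 0.004, k = 1,
                       x = rnorm(1200))
  ser <- expanding_ews(tr, every = 300)
  expect_equal(ser$anchor, c(300, 600, 900, 1200))
  # running variance of iid Gaussian settles
  expect_lt(abs(ser$variance_hat[4] - ser$variance_hat[3]) /
              ser$variance_hat[3], 0.05)
})

test_that("smoothing: identity, constancy, direct average, edge shrink", {
  expect_equal(smooth_series(c(3, 1, 4, 1, 5), window = 1), c(3, 1, 4, 1, 5))
  expect_equal(smooth_series(rep(2, 10), window = 100), rep(2, 10))
  expect_equal(smooth_series(c(0, 0, 0, 10, 0, 0, 0), window = 3),
               c(0, 0, 10 / 3, 10 / 3, 10 / 3, 0, 0))
  v <- rnorm(50)
  sm <- smooth_series(v, window = 7)
  expect_length(sm, 50)
  expect_equal(sm[1], v[1])   # edges pass through
  expect_equal(sm[50], v[50])
})
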