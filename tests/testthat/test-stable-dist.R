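test_that("parameter validation enforces the symmetric centered family", {
  expect_s3_class(stable_params(2, 0.1), "stable_params")
  expect_error(stable_params(0, 1), class = "alphaews_error_domain")
  expect_error(stable_params(2.1, 1), class = "alphaews_error_domain")
  expect_error(stable_params(1.5, -1), class = "alphaews_error_domain")
  expect_error(stable_params(1.5, 1, beta = 0.5), class = "alphaews_error_domain")
  expect_error(stable_params(1.5, 1, delta = 1), class = "alphaews_error_domain")
})

test_that("characteristic function matches its closed form and is symmetric", {
  expect_equal(sas_cf(0, stable_params(1.7, 3)), 1)
  expect_equal(sas_cf(1, stable_params(2, 1)), exp(-1))
  expect_equal(sas_cf(0.5, stable_params(1, 2)), exp(-1))
  u <- c(0.3, 1.2, 4)
  p <- stable_params(1.4, 0.7)
  expect_equal(sas_cf(u, p), sas_cf(-u, p))
  expect_true(all(sas_cf(u, p) > 0 & sas_cf(u, p) <= 1))
})

test_that("closed-form densities are correct, even, and normalized", {
  expect_equal(sas_pdf(0, stable_params(2, 1)), 1 / (2 * sqrt(pi)))
  expect_equal(sas_pdf(0, stable_params(1, 1)), 1 / pi)
  for (a in c(1, 2)) {
    p <- stable_params(a, 1.3)
    expect_equal(sas_pdf(c(0.3, 1.7), p), sas_pdf(-c(0.3, 1.7), p))
    total <- integrate(function(x) sas_pdf(x, p), -Inf, Inf)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_error(sas_pdf(0, stable_params(1.5, 1)),
               class = "alphaews_error_unsupported_alpha")
})

test_that("numeric inversion of the characteristic function reproduces the closed forms", {
  for (a in c(1, 2)) {
    p <- stable_params(a, 1)
    x <- c(0, 0.5, 1, 2)
    expect_equal(sas_pdf_inversion(x, a, 1), sas_pdf(x, p), tolerance = 1e-6)
  }
})

test_that("sampler matches the law: degenerate case, moments, quartiles", {
  expect_identical(sas_sample(5, stable_params(1.5, 0), seed = 1), rep(0, 5))
  z2 <- sas_sample(1e5, stable_params(2, 1), seed = 42)
  expect_equal(var(z2), 2, tolerance = 0.03)
  z1 <- sas_sample(1e5, stable_params(1, 1), seed = 42)
  expect_equal(mean(abs(z1) <= 1), 0.5, tolerance = 0.02)
})

test_that("empirical characteristic function of samples matches the law", {
  for (a in c(2, 1.8, 1.5, 1.3)) {
    z <- sas_sample(1e5, stable_params(a, 0.1), seed = 7)
    for (u in c(0.5, 1, 2, 5)) {
      expect_equal(mean(cos(u * z)), sas_cf(u, stable_params(a, 0.1)),
                   tolerance = 0.011,
                   label = sprintf("ecf(alpha=%g, u=%g)", a, u))
    }
  }
})

test_that("partial sums recover the scale gamma * m^(1/alpha)", {
  for (a in c(2, 1.5, 1.3)) {
    for (m in c(2, 10)) {
      n <- 1e5
      z <- sas_sample(n, stable_params(a, 0.1), seed = 11)
      sums <- colSums(matrix(z, nrow = m))
      fit <- fit_sas_quantile(sums, fixed_alpha = a)
      expect_equal(fit$gamma, 0.1 * m^(1 / a), tolerance = 0.05,
                   label = sprintf("sum-stability(alpha=%g, m=%d)", a, m))
    }
  }
})

test_that("moment existence encodes the tail rule with the Gaussian exception", {
  expect_true(abs_moment_exists(1.5, 1))
  expect_false(abs_moment_exists(1.5, 2))
  expect_false(abs_moment_exists(1.5, 1.5))
  expect_true(abs_moment_exists(2, 7))
  expect_error(abs_moment_exists(2.5, 1), class = "alphaews_error_domain")
  expect_error(abs_moment_exists(1.5, 0), class = "alphaews_error_domain")
})

test_that("empirical absolute moment is the mean of |x|^eta", {
  expect_equal(empirical_abs_moment(c(1, -1, 1, -1), 2), 1)
  expect_equal(empirical_abs_moment(c(0, 0, 0), 3.7), 0)
  expect_equal(empirical_abs_moment(3, 1), 3)
  expect_error(empirical_abs_moment(numeric(0), 1),
               class = "alphaews_error_empty")
})

test_that("empirical second moments diverge for heavy tails but settle for Gaussian", {
  prefixes <- c(1e3, 1e4, 1e5, 1e6)
  ratio <- function(alpha, seed) {
    z <- sas_sample(max(prefixes), stable_params(alpha, 1), seed = seed)
    cs <- cumsum(z^2)
    m <- cs[prefixes] / prefixes
    max(m) / min(m)
  }
  r15 <- vapply(1:100, function(s) ratio(1.5, s), numeric(1))
  r20 <- vapply(1:100, function(s) ratio(2, s), numeric(1))
  expect_gte(sum(r15 > 2), 80)
  expect_gte(sum(r20 < 1.5), 95)
})

test_that("the same seed shares extreme-event indices across heavy-tailed alpha", {
  # Shared base draws align the angle-edge events that drive the extremes of
  # every heavy-tailed member; the Gaussian endpoint has no such events (its
  # extremes are large-exponential draws), so the contract is asserted
  # within alpha < 2.
  top <- function(z) order(abs(z), decreasing = TRUE)[1:10]
  for (pair in list(c(1.8, 1.3), c(1.5, 1.3), c(1.8, 1.5))) {
    z1 <- sas_sample(1e5, stable_params(pair[1], 1), seed = 5)
    z2 <- sas_sample(1e5, stable_params(pair[2], 1), seed = 5)
    expect_gte(length(intersect(top(z1), top(z2))), 5)
  }
  # and the base draws themselves are bit-identical across alpha
  b1 <- alphaews:::sas_base_draws(1000, seed = 9)
  b2 <- alphaews:::sas_base_draws(1000, seed = 9)
  expect_identical(b1, b2)
})

test_that("sampling is seed-deterministic and preserves the caller's RNG state", {
  expect_identical(sas_sample(1000, stable_params(1.5, 1), seed = 3),
                   sas_sample(1000, stable_params(1.5, 1), seed = 3))
  set.seed(99)
  before <- .Random.seed
  invisible(sas_sample(10, stable_params(1.8, 1), seed = 123))
  expect_identical(.Random.seed, before)
})
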