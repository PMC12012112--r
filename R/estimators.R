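#' Quantile-based fit of a symmetric stable law
#'
#' McCulloch-style quantile estimator, symmetric case. The scale-free ratio
#' \eqn{\nu_\alpha = (q_{.95} - q_{.05}) / (q_{.75} - q_{.25})} is inverted
#' to \eqn{\hat\alpha} through a tabulated map (linearly interpolated,
#' clipped to `[0.6, 2]`, the table's validity range), and the scale follows
#' from the interquartile range, \eqn{\hat\gamma = \mathrm{IQR} /
#' c(\hat\alpha)}, with \eqn{c(\cdot)} the tabulated IQR-to-scale factor
#' (1.908 at the Gaussian end, 2 at the Cauchy point). Quantiles use linear
#' interpolation between order statistics. Fast, robust, and free of tuning
#' parameters — the package's default early-warning estimator.
#'
#' @param x Numeric sample, at least 100 points, not all identical.
#' @param fixed_alpha If supplied, the exponent is not estimated; only the
#'   scale is fit at this alpha.
#' @return An object of class `"sas_fit"`: list with `alpha`, `gamma`,
#'   `method`, `n`, `alpha_fixed`.
#' @examples
#' z <- sas_sample(5000, stable_params(1.5, 0.1), seed = 7)
#' fit_sas_quantile(z)
#' @export
fit_sas_quantile <- function(x, fixed_alpha = NULL) {
  check_fit_input(x)
  q <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  iqr <- q[3] - q[2]
  if (iqr <= 0) {
    rlang::abort("Degenerate data: zero interquartile range.",
                 class = "alphaews_error_degenerate")
  }
  if (is.null(fixed_alpha)) {
    nu <- (q[4] - q[1]) / iqr
    # nu is strictly decreasing in alpha; invert by interpolation, clipping
    # to the table range [0.6, 2].
    alpha_hat <- stats::approx(.sas_tab$nu, .sas_tab$alpha, xout = nu,
                               rule = 2)$y
    fixed <- FALSE
  } else {
    stable_params(fixed_alpha, 1)
    alpha_hat <- fixed_alpha
    fixed <- TRUE
  }
  c_a <- stats::approx(.sas_tab$alpha, .sas_tab$c,
                       xout = min(max(alpha_hat, 0.6), 2), rule = 2)$y
  new_sas_fit(alpha_hat, iqr / c_a, "quantile", length(x), fixed)
}

#' Empirical-characteristic-function fit of a symmetric stable law
#'
#' Regresses \eqn{\log(-\log|\hat\varphi(u)|)} on \eqn{\log u}: under the
#' stable characteristic function \eqn{\exp(-\gamma^\alpha u^\alpha)} this is
#' exactly linear with slope \eqn{\alpha} and intercept
#' \eqn{\alpha \log\gamma}. Serves as an independent cross-check of the
#' quantile fitter. Only grid points where the empirical characteristic
#' function lies in `(0.05, 0.95)` are informative and used; fewer than two
#' such points is an error.
#'
#' @param x Numeric sample, at least 100 points.
#' @param u_grid Positive frequencies; defaults to a geometric grid matched
#'   to the sample's interquartile scale.
#' @param fixed_alpha If supplied, only the scale is estimated (moment-style
#'   inversion of the characteristic function at the fixed exponent).
#' @return A `"sas_fit"` object.
#' @export
fit_sas_ecf <- function(x, u_grid = NULL, fixed_alpha = NULL) {
  check_fit_input(x)
  if (is.null(u_grid)) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    s0 <- (q[2] - q[1]) / 2
    if (s0 <= 0) {
      rlang::abort("Degenerate data: zero interquartile range.",
                   class = "alphaews_error_degenerate")
    }
    u_grid <- exp(seq(log(0.1), log(3), length.out = 10)) / s0
  }
  if (any(u_grid <= 0)) {
    rlang::abort("`u_grid` must be positive.", class = "alphaews_error_domain")
  }
  phi <- vapply(u_grid, function(u) mean(cos(u * x)), numeric(1))
  keep <- phi > 0.05 & phi < 0.95
  if (sum(keep) < 2L) {
    rlang::abort(
      "Ill-conditioned grid: fewer than 2 frequencies with |phi| in (0.05, 0.95).",
      class = "alphaews_error_illconditioned"
    )
  }
  ecf_regress(u_grid[keep], phi[keep], fixed_alpha = fixed_alpha,
              n = length(x))
}

# Core of the ECF fit, separated so exact characteristic-function values can
# be fed in directly (regression on exact linear data recovers parameters to
# machine precision).
ecf_regress <- function(u, phi, fixed_alpha = NULL, n = NA_integer_) {
  y <- log(-log(phi))
  if (is.null(fixed_alpha)) {
    co <- stats::coef(stats::lm(y ~ log(u)))
    alpha_hat <- min(max(unname(co[2]), 0.1), 2)
    gamma_hat <- exp(unname(co[1]) / alpha_hat)
    fixed <- FALSE
  } else {
    stable_params(fixed_alpha, 1)
    alpha_hat <- fixed_alpha
    gamma_hat <- mean(exp((y - alpha_hat * log(u)) / alpha_hat))
    fixed <- TRUE
  }
  new_sas_fit(alpha_hat, gamma_hat, "ecf", n, fixed)
}

check_fit_input <- function(x) {
  if (!is.numeric(x) || length(x) < 100L) {
    rlang::abort("Need at least 100 samples to fit a stable law.",
                 class = "alphaews_error_toofew")
  }
  if (anyNA(x)) {
    rlang::abort("`x` must not contain missing values.",
                 class = "alphaews_error_domain")
  }
  invisible(x)
}

new_sas_fit <- function(alpha, gamma, method, n, alpha_fixed) {
  structure(
    list(alpha = as.numeric(alpha), gamma = as.numeric(gamma),
         method = method, n = as.integer(n), alpha_fixed = alpha_fixed),
    class = "sas_fit"
  )
}

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("<SaS fit (%s)>  alpha = %.4f%s, gamma = %.6g, n = %d\n",
              x$method, x$alpha, if (x$alpha_fixed) " (fixed)" else "",
              x$gamma, x$n))
  invisible(x)
}

#' Tidy a stable fit
#'
#' @param x A `"sas_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `fixed`).
#' @export
tidy.sas_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "gamma"),
    estimate = c(x$alpha, x$gamma),
    fixed = c(x$alpha_fixed, FALSE)
  )
}

#' Glance at a stable fit
#'
#' @param x A `"sas_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with `alpha`, `gamma`, `method`, `n`.
#' @export
glance.sas_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, gamma = x$gamma, method = x$method,
                 n = x$n)
}

#' Classical early-warning statistics
#'
#' Unbiased sample variance (mean removed) and lag-1 Pearson
#' autocorrelation, the classical indicators whose theoretical justification
#' breaks down under heavy-tailed forcing.
#'
#' @param x Numeric sample (`>= 2` points for variance, `>= 3` for
#'   autocorrelation; constant series are an error for autocorrelation).
#' @return A single number.
#' @examples
#' variance_estimator(c(1, -1, 1, -1))  # 4/3
#' lag1_autocorr(c(1, -1, 1, -1))       # -1
#' @export
variance_estimator <- function(x) {
  if (length(x) < 2L) {
    rlang::abort("Need at least 2 samples.", class = "alphaews_error_toofew")
  }
  stats::var(x)
}

#' @rdname variance_estimator
#' @export
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 3L) {
    rlang::abort("Need at least 3 samples.", class = "alphaews_error_toofew")
  }
  if (stats::sd(x) == 0) {
    rlang::abort("Autocorrelation undefined for a constant series.",
                 class = "alphaews_error_degenerate")
  }
  stats::cor(x[-n], x[-1])
}

ews_row <- function(xw, fixed_alpha, method) {
  fit <- if (method == "quantile") {
    fit_sas_quantile(xw, fixed_alpha = fixed_alpha)
  } else {
    fit_sas_ecf(xw, fixed_alpha = fixed_alpha)
  }
  tibble::tibble(
    gamma_hat = fit$gamma,
    alpha_hat = fit$alpha,
    variance_hat = variance_estimator(xw),
    ac1_hat = lag1_autocorr(xw)
  )
}

#' Rolling-window early-warning series
#'
#' Computes the early-warning indicators — fitted stable scale
#' \eqn{\hat\gamma_X} and exponent \eqn{\hat\alpha}, sample variance, lag-1
#' autocorrelation — on trailing (causal) windows of the raw states, anchored
#' at the window's last point: anchors sit at steps `window`,
#' `window + stride`, ... The defaults (300 points every 150 steps) are the
#' reference ramp-protocol settings. Windows operate on raw states; within a
#' slow parameter ramp the drift of the fixed point across one window is
#' treated as negligible.
#'
#' @param trajectory An `"ews_trajectory"` (or tibble with columns `step`,
#'   `t`, `k`, `x`) of length `>= window`.
#' @param window Points per estimate.
#' @param stride Steps between anchors.
#' @param fixed_alpha Optional fixed exponent passed to the fitter.
#' @param method `"quantile"` (default) or `"ecf"`.
#' @return An `"ews_series"` tibble with columns `anchor`, `t`, `k`,
#'   `gamma_hat`, `alpha_hat`, `variance_hat`, `ac1_hat`; attributes
#'   `window`, `stride`, `method`, `mode = "rolling"`.
#' @export
rolling_ews <- function(trajectory, window = 300, stride = 150,
                        fixed_alpha = NULL, method = c("quantile", "ecf")) {
  method <- match.arg(method)
  stopifnot(window >= 1, stride >= 1)
  n <- nrow(trajectory)
  if (n < window) {
    rlang::abort("Window exceeds trajectory length.",
                 class = "alphaews_error_toofew")
  }
  anchors <- seq(window, n, by = stride)
  est <- purrr::map_dfr(anchors, function(a) {
    ews_row(trajectory$x[(a - window + 1):a], fixed_alpha, method)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(anchor = anchors,
                   t = trajectory$t[anchors],
                   k = trajectory$k[anchors]),
    est
  )
  structure(out, class = c("ews_series", class(out)),
            window = as.integer(window), stride = as.integer(stride),
            method = method, mode = "rolling")
}

#' Expanding-window (running) early-warning series
#'
#' Computes the indicators on the full prefix `[1, j]` at anchors
#' `j = every, 2 every, ...` — running statistics used to demonstrate
#' convergence (Gaussian case, and \eqn{\hat\gamma_X} for every alpha)
#' versus non-convergence (running variance for `alpha < 2`).
#'
#' @inheritParams rolling_ews
#' @param every Anchor spacing in steps.
#' @return An `"ews_series"` tibble (see [rolling_ews()]),
#'   `mode = "expanding"`.
#' @export
expanding_ews <- function(trajectory, every = 300, fixed_alpha = NULL,
                          method = c("quantile", "ecf")) {
  method <- match.arg(method)
  stopifnot(every >= 1)
  n <- nrow(trajectory)
  if (n < every) {
    rlang::abort("Trajectory shorter than `every`.",
                 class = "alphaews_error_toofew")
  }
  anchors <- seq(every, n, by = every)
  est <- purrr::map_dfr(anchors, function(a) {
    ews_row(trajectory$x[1:a], fixed_alpha, method)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(anchor = anchors,
                   t = trajectory$t[anchors],
                   k = trajectory$k[anchors]),
    est
  )
  structure(out, class = c("ews_series", class(out)),
            window = NA_integer_, stride = as.integer(every),
            method = method, mode = "expanding")
}

#' Centered moving-average smoothing
#'
#' Visualization aid for indicator series: centered moving average with
#' half-width `floor(window / 2)`, shrinking symmetrically at the edges so
#' the output has the same length as the input (the first and last points
#' are returned unchanged). Not a causal statistic — use raw series for
#' decision rules.
#'
#' @param values Numeric vector.
#' @param window Nominal window size, `>= 1` (`1` is the identity).
#' @return Smoothed vector, same length.
#' @examples
#' smooth_series(c(0, 0, 0, 10, 0, 0, 0), window = 3)
#' @export
smooth_series <- function(values, window = 100) {
  stopifnot(window >= 1)
  n <- length(values)
  h <- floor(window / 2)
  if (h == 0 || n == 0) return(values)
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  hi <- pmin(h, i - 1L, n - i)
  (cs[i + hi + 1] - cs[i - hi]) / (2 * hi + 1)
}
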