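#' Symmetric alpha-stable parameter set
#'
#' Constructs the parameter set of a symmetric, centered alpha-stable law
#' \eqn{S\alpha S(\gamma)} with characteristic function
#' \deqn{\varphi(u) = \exp(-\gamma^\alpha |u|^\alpha).}
#' Only the symmetric centered family is supported: the skewness and location
#' parameters are fixed at zero and construction rejects other values.
#'
#' Under this scale convention the law at `alpha = 2` is Gaussian with variance
#' \eqn{2\gamma^2} (not \eqn{\gamma^2}); at `alpha = 1` it is Cauchy with
#' half-width \eqn{\gamma}. Absolute moments of order `eta >= alpha` diverge
#' for `alpha < 2`.
#'
#' @param alpha Characteristic exponent (tail index), in `(0, 2]`.
#' @param gamma Scale parameter, same units as the variate, `>= 0`.
#' @param beta Skewness; must be 0 (symmetric case).
#' @param delta Location; must be 0 (centered case).
#'
#' @return An object of class `"stable_params"`.
#' @examples
#' stable_params(1.5, 0.1)
#' @export
stable_params <- function(alpha, gamma = 1, beta = 0, delta = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 2) {
    rlang::abort("`alpha` must be a single number in (0, 2].",
                 class = "alphaews_error_domain")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    rlang::abort("`gamma` must be a single non-negative number.",
                 class = "alphaews_error_domain")
  }
  if (!identical(as.numeric(beta), 0) || !identical(as.numeric(delta), 0)) {
    rlang::abort(
      "Only the symmetric centered family is supported: `beta` and `delta` must be 0.",
      class = "alphaews_error_domain"
    )
  }
  structure(
    list(alpha = as.numeric(alpha), beta = 0, gamma = as.numeric(gamma),
         delta = 0),
    class = "stable_params"
  )
}

#' @export
print.stable_params <- function(x, ...) {
  cat(sprintf("<SaS law>  alpha = %g, gamma = %g (beta = 0, delta = 0)\n",
              x$alpha, x$gamma))
  if (x$alpha == 2) {
    cat(sprintf("  Gaussian special case: variance = 2*gamma^2 = %g\n",
                2 * x$gamma^2))
  }
  invisible(x)
}

as_stable_params <- function(params) {
  if (inherits(params, "stable_params")) return(params)
  rlang::abort("`params` must be created by `stable_params()`.",
               class = "alphaews_error_domain")
}

#' Characteristic function of the symmetric stable law
#'
#' Evaluates \eqn{\varphi(u) = \exp(-\gamma^\alpha |u|^\alpha)}. Real-valued,
#' symmetric in `u`, equal to 1 at `u = 0`.
#'
#' @param u Real frequency (vectorized).
#' @param params A [stable_params()] object.
#' @return Numeric vector in `(0, 1]`.
#' @examples
#' sas_cf(1, stable_params(2, 1))  # exp(-1)
#' @export
sas_cf <- function(u, params) {
  p <- as_stable_params(params)
  exp(-p$gamma^p$alpha * abs(u)^p$alpha)
}

#' Closed-form stable densities (Gaussian and Cauchy cases)
#'
#' The symmetric stable density has a closed form only at `alpha = 2`
#' (Gaussian, \eqn{f(x) = \exp(-x^2/4\gamma^2) / (2\gamma\sqrt\pi)}) and
#' `alpha = 1` (Cauchy, \eqn{f(x) = \gamma / (\pi(\gamma^2 + x^2))}).
#' Other exponents signal an error; general densities are only available by
#' numeric Fourier inversion of [sas_cf()].
#'
#' @param x Evaluation points (vectorized).
#' @param params A [stable_params()] object with `alpha` 1 or 2 and `gamma > 0`.
#' @return Densities, `>= 0`, even in `x`.
#' @examples
#' sas_pdf(0, stable_params(2, 1))  # 1 / (2 sqrt(pi))
#' sas_pdf(0, stable_params(1, 1))  # 1 / pi
#' @export
sas_pdf <- function(x, params) {
  p <- as_stable_params(params)
  if (p$gamma <= 0) {
    rlang::abort("`gamma` must be > 0 for a density.",
                 class = "alphaews_error_domain")
  }
  if (p$alpha == 2) {
    exp(-x^2 / (4 * p$gamma^2)) / (2 * p$gamma * sqrt(pi))
  } else if (p$alpha == 1) {
    p$gamma / (pi * (p$gamma^2 + x^2))
  } else {
    rlang::abort(
      sprintf(paste0("No closed-form density for alpha = %g; only alpha in ",
                     "{1, 2} is supported (use numeric inversion of sas_cf)."),
              p$alpha),
      class = "alphaews_error_unsupported_alpha"
    )
  }
}

# Base draws behind the Chambers-Mallows-Stuck transform. Drawn as two plain
# uniform vectors so the SAME seed yields the SAME (theta, w) pairs for every
# alpha: an extreme base event then produces an extreme variate at the same
# index across alpha (the cross-alpha seed-sharing contract).
sas_base_draws <- function(n, seed) {
  with_preserved_seed(seed, {
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
  })
  list(theta = pi * (u1 - 0.5), w = -log(u2))
}

# CMS transform of (theta, w) to a standard SaS(alpha, gamma = 1) variate.
# The symmetric-case formula is continuous in alpha and exact at alpha = 1
# (reduces to tan(theta)) and alpha = 2 (2 sin(theta) sqrt(w), variance 2).
cms_transform <- function(theta, w, alpha) {
  if (alpha == 1) return(tan(theta))
  sin(alpha * theta) / cos(theta)^(1 / alpha) *
    (cos((1 - alpha) * theta) / w)^((1 - alpha) / alpha)
}

#' Sample i.i.d. symmetric alpha-stable variates
#'
#' Exact sampling via the Chambers-Mallows-Stuck transform of a uniform angle
#' on \eqn{(-\pi/2, \pi/2)} and an independent unit exponential. The two base
#' draws are generated from `seed` before the alpha-dependent transform, so
#' the same seed consumes the same base randomness for every `alpha`: extreme
#' base events produce extreme variates at the same sample indices across
#' tail indices. The caller's RNG state is left untouched.
#'
#' @param n Number of draws, `>= 1`.
#' @param params A [stable_params()] object.
#' @param seed Integer seed; required, no global RNG state is consumed.
#' @return Numeric vector of `n` i.i.d. \eqn{S\alpha S(\gamma)} draws.
#' @examples
#' z <- sas_sample(1e4, stable_params(2, 1), seed = 1)
#' var(z)  # close to 2 = 2 * gamma^2
#' @export
sas_sample <- function(n, params, seed) {
  p <- as_stable_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    rlang::abort("`n` must be a positive count.",
                 class = "alphaews_error_domain")
  }
  n <- as.integer(n)
  if (p$gamma == 0) return(numeric(n))
  b <- sas_base_draws(n, seed)
  p$gamma * cms_transform(b$theta, b$w, p$alpha)
}

#' Does the absolute moment of a stable law exist?
#'
#' For `alpha < 2` absolute moments \eqn{E|Z|^\eta} are finite exactly for
#' `eta < alpha` and infinite for `eta >= alpha`; in the Gaussian case
#' `alpha = 2` all moments exist. In particular the variance (`eta = 2`)
#' diverges for every `alpha < 2` — the root cause of spurious variance-based
#' warning signals under heavy-tailed forcing.
#'
#' @param alpha Characteristic exponent in `(0, 2]`.
#' @param eta Moment order, `> 0`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' abs_moment_exists(1.5, 1)  # TRUE
#' abs_moment_exists(1.5, 2)  # FALSE
#' @export
abs_moment_exists <- function(alpha, eta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 2) {
    rlang::abort("`alpha` must be in (0, 2].", class = "alphaews_error_domain")
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0) {
    rlang::abort("`eta` must be > 0.", class = "alphaews_error_domain")
  }
  alpha == 2 || eta < alpha
}

#' Empirical absolute moment
#'
#' Mean of \eqn{|x|^\eta} over a sample. Used to demonstrate the
#' non-convergence of empirical second moments under heavy tails: for
#' `alpha < 2` and `eta >= alpha` the statistic keeps drifting with sample
#' size instead of settling.
#'
#' @param x Non-empty numeric sample.
#' @param eta Moment order, `> 0`.
#' @return A non-negative number.
#' @examples
#' empirical_abs_moment(c(1, -1, 1, -1), 2)  # 1
#' @export
empirical_abs_moment <- function(x, eta) {
  if (length(x) == 0L) {
    rlang::abort("`x` must be non-empty.", class = "alphaews_error_empty")
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0) {
    rlang::abort("`eta` must be > 0.", class = "alphaews_error_domain")
  }
  mean(abs(x)^eta)
}

# Run `code` under `seed` while preserving the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite integer.",
                 class = "alphaews_error_domain")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
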