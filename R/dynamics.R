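#' Potential models: Ornstein-Uhlenbeck and fold bifurcation
#'
#' Defines the two drift/potential models. The linear Ornstein-Uhlenbeck (OU)
#' model has potential \eqn{U(x, k) = k x^2 / 2} and drift \eqn{-kx}; the fold
#' (saddle-node) model has \eqn{U(x, k) = x^3/3 - kx} and drift
#' \eqn{k - x^2}. Both pass through a bifurcation at `k = 0`. The tail
#' exponent records the growth order \eqn{|x|^c} of the potential at
#' infinity (2 for OU, 3 for fold), which governs whether the stationary
#' variance is finite under alpha-stable forcing (see
#' [variance_is_finite()]).
#'
#' @param name `"ou"` or `"fold"`.
#' @param k Bifurcation parameter (real).
#' @return An object of class `"potential_model"` with fields `name`, `k`,
#'   and `tail_exponent_c`.
#' @examples
#' m <- potential_model("fold", k = 1)
#' drift(m, 1)  # 0: x = sqrt(k) is the stable fixed point
#' @export
potential_model <- function(name = c("ou", "fold"), k) {
  name <- match.arg(name)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k)) {
    rlang::abort("`k` must be a single finite number.",
                 class = "alphaews_error_domain")
  }
  structure(
    list(name = name, k = as.numeric(k),
         tail_exponent_c = if (name == "ou") 2 else 3),
    class = "potential_model"
  )
}

#' @export
print.potential_model <- function(x, ...) {
  form <- if (x$name == "ou") "-k x  (U = k x^2/2)" else "k - x^2  (U = x^3/3 - k x)"
  cat(sprintf("<potential model: %s>  k = %g, drift = %s, c = %d\n",
              x$name, x$k, form, x$tail_exponent_c))
  invisible(x)
}

#' Drift of a potential model
#'
#' Evaluates \eqn{-U'(x, k)}: `-k * x` for the OU model and `k - x^2` for the
#' fold model. Vectorized in `x`, optionally with a per-element `k` override
#' (used by ramped simulations).
#'
#' @param model A [potential_model()].
#' @param x State (vectorized).
#' @param k Optional bifurcation parameter overriding `model$k`.
#' @return Drift values.
#' @export
drift <- function(model, x, k = model$k) {
  stopifnot(inherits(model, "potential_model"))
  if (model$name == "ou") -k * x else k - x^2
}

#' Potential energy of a model
#'
#' @inheritParams drift
#' @return Potential values \eqn{U(x, k)}.
#' @export
potential <- function(model, x, k = model$k) {
  stopifnot(inherits(model, "potential_model"))
  if (model$name == "ou") k * x^2 / 2 else x^3 / 3 - k * x
}

#' Fixed points of the fold model
#'
#' For `k > 0` the fold drift \eqn{k - x^2} has a stable fixed point at
#' \eqn{+\sqrt k} and an unstable one at \eqn{-\sqrt k}; the two collide in a
#' single degenerate point at `k = 0` and annihilate for `k < 0` (the tipping
#' event).
#'
#' @param k Bifurcation parameter.
#' @return A tibble with columns `x` and `stability`
#'   (`"stable"`, `"unstable"`, or `"degenerate"`); zero rows for `k < 0`.
#' @examples
#' fold_fixed_points(4)
#' @export
fold_fixed_points <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k > 0) {
    tibble::tibble(x = c(sqrt(k), -sqrt(k)),
                   stability = c("stable", "unstable"))
  } else if (k == 0) {
    tibble::tibble(x = 0, stability = "degenerate")
  } else {
    tibble::tibble(x = numeric(0), stability = character(0))
  }
}

#' Linearization rate of the fold model
#'
#' Expanding the fold drift around its stable fixed point \eqn{+\sqrt k}
#' yields an OU process in the displacement with effective rate
#' \eqn{\kappa = 2\sqrt k}. All OU theory (stationary scale, variance)
#' applies locally to the fold with `k` replaced by `kappa`.
#'
#' @param k Bifurcation parameter, `> 0`.
#' @return \eqn{\kappa = 2\sqrt k} (vectorized).
#' @examples
#' linearized_rate(4)  # 4
#' @export
linearized_rate <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    rlang::abort("`k` must be > 0: the linearization only exists before the bifurcation.",
                 class = "alphaews_error_domain")
  }
  2 * sqrt(k)
}

#' Is the stationary variance finite under alpha-stable forcing?
#'
#' For a confining potential growing like \eqn{|x|^c} at infinity and
#' symmetric alpha-stable forcing, the stationary variance of the response is
#' finite iff \eqn{c > 4 - \alpha} (always finite in the Gaussian case
#' `alpha = 2`). For the OU model (`c = 2`) the criterion fails for every
#' `alpha < 2`; for the fold (`c = 3`) it fails for `alpha <= 1`; a quartic
#' double well (`c = 4`) always satisfies it.
#'
#' @param tail_exponent_c Growth order of the potential; one of 2, 3, 4.
#' @param alpha Characteristic exponent in `(0, 2]`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' variance_is_finite(2, 1.5)  # FALSE: OU variance diverges
#' variance_is_finite(3, 1.5)  # TRUE
#' @export
variance_is_finite <- function(tail_exponent_c, alpha) {
  if (!tail_exponent_c %in% c(2, 3, 4)) {
    rlang::abort("`tail_exponent_c` must be one of 2, 3, 4.",
                 class = "alphaews_error_domain")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 2) {
    rlang::abort("`alpha` must be in (0, 2].", class = "alphaews_error_domain")
  }
  alpha == 2 || tail_exponent_c > 4 - alpha
}

#' Variance of the Gaussian Ornstein-Uhlenbeck response
#'
#' Closed-form variance of the OU process driven by Gaussian noise whose
#' increments over `dt` have scale \eqn{\gamma_N \sqrt{dt}} (variance
#' \eqn{2\gamma_N^2 dt}):
#' \deqn{\mathrm{Var}\,X(t) = \frac{\gamma_N^2}{k}\left(1 - e^{-2kt}\right)
#'   \xrightarrow{t\to\infty} \frac{\gamma_N^2}{k}.}
#' The prefactor \eqn{\gamma_N^2/k} equals \eqn{2\gamma_X^2} with
#' \eqn{\gamma_X} from [gamma_x_limit()] at `alpha = 2`, so variance and
#' scale theory agree exactly (variance of a Gaussian stable law is
#' \eqn{2\gamma^2}). Defined for the Gaussian case only; for `alpha < 2`
#' the variance does not exist.
#'
#' @param t Time, `>= 0`; `Inf` gives the stationary limit.
#' @param k OU rate, `> 0`.
#' @param gamma_n Driving noise scale, `>= 0`.
#' @return Variance of `X(t)` (vectorized over `t` or `k`).
#' @examples
#' ou_variance(Inf, k = 1, gamma_n = 0.1)          # 0.01
#' 2 * gamma_x_limit(1, alpha = 2, gamma_n = 0.1)^2  # the same
#' @export
ou_variance <- function(t, k, gamma_n) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    rlang::abort("`k` must be > 0.", class = "alphaews_error_domain")
  }
  if (any(t < 0)) {
    rlang::abort("`t` must be >= 0.", class = "alphaews_error_domain")
  }
  gamma_n^2 / k * ifelse(is.infinite(t), 1, -expm1(-2 * k * t))
}

#' Transient scale of the linear alpha-stable response
#'
#' The OU-type process \eqn{dX = -kX\,dt + dN^{(\alpha)}} started at
#' \eqn{X_0 = 0} is itself symmetric alpha-stable at every time, with scale
#' \deqn{\gamma_X(t) = \gamma_N \left(\frac{1 - e^{-\alpha k t}}{\alpha k}
#'   \right)^{1/\alpha},}
#' continuous at `k = 0` where it equals \eqn{\gamma_N t^{1/\alpha}} (free
#' accumulation of noise). Non-decreasing in `t`; converges to
#' [gamma_x_limit()] for `k > 0`.
#'
#' @param t Time, `>= 0` (vectorized); `Inf` allowed for `k > 0`.
#' @param k Rate, `>= 0` (`k = 0` handled by the analytic limit).
#' @param alpha Characteristic exponent in `(0, 2]`.
#' @param gamma_n Driving noise scale, `>= 0`.
#' @return Scale of `X(t)`.
#' @examples
#' gamma_x_t(4, k = 0, alpha = 2, gamma_n = 1)  # 2 = sqrt(t)
#' @export
gamma_x_t <- function(t, k, alpha, gamma_n) {
  p <- stable_params(alpha, max(gamma_n, 0))  # validates alpha
  if (any(!is.finite(k)) || any(k < 0)) {
    rlang::abort("`k` must be >= 0.", class = "alphaews_error_domain")
  }
  if (any(t < 0)) {
    rlang::abort("`t` must be >= 0.", class = "alphaews_error_domain")
  }
  if (any(gamma_n < 0)) {
    rlang::abort("`gamma_n` must be >= 0.", class = "alphaews_error_domain")
  }
  a <- alpha
  integral <- ifelse(k == 0, t,
                     ifelse(is.infinite(t), 1 / (a * k), -expm1(-a * k * t) / (a * k)))
  gamma_n * integral^(1 / a)
}

#' Stationary scale of the linear response: the early-warning indicator
#'
#' The stationary scale parameter of the alpha-stable OU-type response,
#' \deqn{\gamma_X = \gamma_N \left(\frac{1}{\alpha k}\right)^{1/\alpha},}
#' strictly increasing as `k` decreases toward the bifurcation at `k = 0` —
#' the generalized early-warning signal. At `alpha = 2` it reduces to
#' \eqn{\gamma_N \sqrt{1/(2k)}}, recovering the classical Gaussian variance
#' scaling (`Var = 2 gamma_X^2 = gamma_n^2 / k`). Diverges as
#' \eqn{k \to 0^+}; the function rejects `k <= 0`.
#'
#' For the fold model near its stable fixed point, use the linearization
#' rate: `gamma_x_limit(linearized_rate(k), alpha, gamma_n)`.
#'
#' @param k Rate, `> 0` (vectorized).
#' @param alpha Characteristic exponent in `(0, 2]`.
#' @param gamma_n Driving noise scale, `>= 0`.
#' @return Stationary scale \eqn{\gamma_X}.
#' @examples
#' gamma_x_limit(0.5, alpha = 2, gamma_n = 1)  # 1
#' @export
gamma_x_limit <- function(k, alpha, gamma_n) {
  stable_params(alpha, 1)  # validates alpha
  if (any(!is.finite(k)) || any(k <= 0)) {
    rlang::abort("`k` must be > 0: the indicator diverges at the bifurcation.",
                 class = "alphaews_error_domain")
  }
  if (any(gamma_n < 0)) {
    rlang::abort("`gamma_n` must be >= 0.", class = "alphaews_error_domain")
  }
  gamma_n * (1 / (alpha * k))^(1 / alpha)
}

#' Tabulate closed-form theory over parameter grids
#'
#' Convenience wrapper returning a tibble of the stationary indicator
#' [gamma_x_limit()], the transient [gamma_x_t()] at a given time, and (for
#' `alpha = 2`) the OU variance, over the outer grid of `k` and `alpha`.
#'
#' @param k Vector of rates, `> 0`.
#' @param alpha Vector of exponents in `(0, 2]`.
#' @param gamma_n Driving scale.
#' @param t Time for the transient column (default `Inf`).
#' @return A tibble with columns `k`, `alpha`, `gamma_n`, `t`, `gamma_x_t`,
#'   `gamma_x`, `ou_var` (`NA` for `alpha < 2`).
#' @export
theory_table <- function(k, alpha, gamma_n = 0.1, t = Inf) {
  grid <- tidyr::expand_grid(k = k, alpha = alpha)
  grid$gamma_n <- gamma_n
  grid$t <- t
  grid$gamma_x_t <- purrr::map2_dbl(grid$k, grid$alpha,
                                    ~ gamma_x_t(t, .x, .y, gamma_n))
  grid$gamma_x <- purrr::map2_dbl(grid$k, grid$alpha,
                                  ~ gamma_x_limit(.x, .y, gamma_n))
  grid$ou_var <- ifelse(grid$alpha == 2, gamma_n^2 / grid$k, NA_real_)
  grid
}
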