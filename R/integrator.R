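#' Simulation configuration
#'
#' Discretization settings for the Euler-Maruyama schemes. Defaults are the
#' package's reference study conditions: time step `dt = 0.004`, taming
#' constant `epsilon = dt / 100` (small enough that the tamed drift is within
#' 0.004% of the true drift at `|U'| = 1`, large enough to bound the
#' post-jump drift by `1/epsilon`), initial state `x0 = 0.5` (near, but not
#' at, the stable state for both reference models).
#'
#' @param n_steps Number of integration steps, `>= 1`.
#' @param dt Time step, `> 0`.
#' @param epsilon Taming constant, `> 0`.
#' @param x0 Initial state.
#' @param seed Integer seed used when the noise sequence is generated from
#'   the config rather than supplied.
#' @param stop_on_escape Apply the basin-escape stopping rule (fold model
#'   only).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_steps, dt = 0.004, epsilon = dt / 100, x0 = 0.5,
                       seed = 1L, stop_on_escape = FALSE) {
  stopifnot(is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1,
            is.numeric(dt), dt > 0, is.numeric(epsilon), epsilon > 0)
  structure(
    list(n_steps = as.integer(n_steps), dt = dt, epsilon = epsilon,
         x0 = x0, seed = as.integer(seed),
         stop_on_escape = isTRUE(stop_on_escape)),
    class = "sim_config"
  )
}

#' Pre-scaled alpha-stable noise increments
#'
#' Generates the i.i.d. driving increments of an alpha-stable process over
#' steps of length `dt`: each increment is \eqn{dt^{1/\alpha} N_j} with
#' \eqn{N_j \sim S\alpha S(\gamma_N)}, so the sum over any window of `m`
#' increments is \eqn{S\alpha S(\gamma_N (m\,dt)^{1/\alpha})} in law (the
#' self-similarity of the driving process). Regeneration with the same
#' `(seed, alpha, gamma_n, dt, n)` is bit-identical, and the same `seed`
#' shares base draws across `alpha` (see [sas_sample()]).
#'
#' @param n Number of increments.
#' @param alpha Characteristic exponent in `(0, 2]`.
#' @param gamma_n Driving noise scale, `>= 0`.
#' @param dt Time step, `> 0`.
#' @param seed Integer seed.
#' @return An object of class `"noise_sequence"`: list with `increments`
#'   and the provenance fields `alpha`, `gamma_n`, `dt`, `seed`.
#' @export
noise_increments <- function(n, alpha, gamma_n, dt = 0.004, seed = 1L) {
  stopifnot(dt > 0)
  inc <- dt^(1 / alpha) * sas_sample(n, stable_params(alpha, gamma_n), seed)
  structure(
    list(increments = inc, alpha = alpha, gamma_n = gamma_n, dt = dt,
         seed = as.integer(seed)),
    class = "noise_sequence"
  )
}

#' @export
print.noise_sequence <- function(x, ...) {
  cat(sprintf("<noise sequence> n = %d, alpha = %g, gamma_n = %g, dt = %g, seed = %d\n",
              length(x$increments), x$alpha, x$gamma_n, x$dt, x$seed))
  invisible(x)
}

#' Linear ramp of the bifurcation parameter
#'
#' Arithmetic sequence from `k_start` toward `k_end` in decrements of `step`,
#' one value per integration step. The final value `k_end` itself is
#' excluded: the sequence has length `ceiling((k_start - k_end) / step)` and
#' its last element is the last grid value strictly above `k_end`. The
#' reference ramp `k_ramp(5, 0, 1e-4)` therefore has 50 000 entries ending at
#' `1e-4` — the bifurcation value `k = 0` is never simulated.
#'
#' @param k_start Starting value.
#' @param k_end Target value, `< k_start`.
#' @param step Decrement per integration step, `> 0`.
#' @return Strictly decreasing numeric vector.
#' @examples
#' k_ramp(1, 0.5, 0.25)  # 1.00 0.75
#' @export
k_ramp <- function(k_start, k_end, step) {
  if (!is.numeric(step) || step <= 0) {
    rlang::abort("`step` must be > 0.", class = "alphaews_error_domain")
  }
  if (k_start == k_end) {
    rlang::abort("Degenerate ramp: `k_start` equals `k_end`.",
                 class = "alphaews_error_domain")
  }
  if (k_start < k_end) {
    rlang::abort("`k_start` must exceed `k_end`.",
                 class = "alphaews_error_domain")
  }
  len <- ceiling((k_start - k_end) / step - 1e-9)
  k_start - step * (seq_len(len) - 1)
}

#' Basin-escape stopping rule for the fold model
#'
#' The fold model's basin of attraction of \eqn{+\sqrt k} is bounded below by
#' the unstable fixed point \eqn{-\sqrt k}. A simulation is stopped once the
#' post-update state falls below \eqn{-\sqrt k - k/10} (a small buffer past
#' the basin edge), after which the deterministic flow runs to \eqn{-\infty}.
#'
#' @param x_next Post-update state (vectorized).
#' @param k Bifurcation parameter, `>= 0`.
#' @return Logical: should the simulation stop?
#' @examples
#' escape_stop(-1.2, k = 1)   # TRUE  (threshold -1.1)
#' escape_stop(-1.05, k = 1)  # FALSE
#' @export
escape_stop <- function(x_next, k) {
  stopifnot(all(k >= 0))
  x_next < -sqrt(k) - k / 10
}

em_path <- function(model, k_schedule, config, noise, tamed) {
  stopifnot(inherits(model, "potential_model"),
            inherits(config, "sim_config"))
  if (is.null(noise)) {
    noise <- noise_increments(config$n_steps, alpha = 2, gamma_n = 0.1,
                              dt = config$dt, seed = config$seed)
  }
  stopifnot(inherits(noise, "noise_sequence"))
  n <- config$n_steps
  if (length(noise$increments) < n) {
    rlang::abort("Noise sequence shorter than `n_steps`.",
                 class = "alphaews_error_domain")
  }
  if (!length(k_schedule) %in% c(1L, n)) {
    rlang::abort("`k_schedule` must be a scalar or have length `n_steps`.",
                 class = "alphaews_error_domain")
  }
  if (abs(noise$dt - config$dt) > 1e-12) {
    rlang::abort("Noise sequence was generated for a different `dt`.",
                 class = "alphaews_error_domain")
  }
  res <- em_path_cpp(model = if (model$name == "ou") 0L else 1L,
                     k_schedule = as.numeric(k_schedule),
                     increments = noise$increments[seq_len(n)],
                     dt = config$dt, eps = config$epsilon, x0 = config$x0,
                     tamed = tamed,
                     stop_on_escape = config$stop_on_escape && model$name == "fold")
  taken <- length(res$x)
  ks <- if (length(k_schedule) == 1L) rep(k_schedule, taken) else k_schedule[seq_len(taken)]
  out <- tibble::tibble(
    step = seq_len(taken),
    t = seq_len(taken) * config$dt,
    k = ks,
    x = res$x
  )
  structure(
    out,
    class = c("ews_trajectory", class(out)),
    model = model$name,
    alpha = noise$alpha,
    gamma_n = noise$gamma_n,
    dt = config$dt,
    epsilon = config$epsilon,
    x0 = config$x0,
    seed = noise$seed,
    scheme = if (tamed) "tamed" else "plain",
    truncated_at = res$truncated_at,
    diverged_at = res$diverged_at
  )
}

#' Tamed Euler-Maruyama integration
#'
#' Integrates \eqn{dX = -U'(X, k)\,dt + dN^{(\alpha)}} with the tamed drift
#' \deqn{X_j = X_{j-1} - \frac{U'(X_{j-1})}{1 + \epsilon |U'(X_{j-1})|}\,
#'   \Delta t + dt^{1/\alpha} N_j.}
#' The tamed drift term is bounded by \eqn{1/\epsilon} in magnitude
#' regardless of the state, which keeps the explicit scheme stable under the
#' large jumps of heavy-tailed noise and the superlinear fold drift. `k` may
#' be a scalar or a per-step schedule (held constant within a step). With
#' `config$stop_on_escape` and the fold model, the trajectory is truncated
#' when [escape_stop()] fires on the post-update state, and the attribute
#' `truncated_at` records the step.
#'
#' @param model A [potential_model()].
#' @param k_schedule Scalar `k` or vector of length `config$n_steps`.
#' @param config A [sim_config()].
#' @param noise A [noise_increments()] sequence of length `>= n_steps`; if
#'   `NULL`, a Gaussian sequence is generated from `config$seed`.
#' @return An `"ews_trajectory"`: a tibble with columns `step`, `t`, `k`,
#'   `x` and provenance attributes (`model`, `alpha`, `gamma_n`, `dt`,
#'   `epsilon`, `x0`, `seed`, `scheme`, `truncated_at`, `diverged_at`).
#' @examples
#' m <- potential_model("fold", 1)
#' cfg <- sim_config(1000)
#' quiet <- noise_increments(1000, alpha = 2, gamma_n = 0)
#' tr <- tamed_euler_maruyama(m, 1, cfg, quiet)
#' tail(tr$x, 1)  # ~ +1, the stable fixed point sqrt(k)
#' @export
tamed_euler_maruyama <- function(model, k_schedule, config, noise = NULL) {
  em_path(model, k_schedule, config, noise, tamed = TRUE)
}

#' Plain (untamed) Euler-Maruyama integration
#'
#' The classical explicit scheme, provided as a reference and to demonstrate
#' its documented instability: under the superlinear fold drift, a single
#' large noise jump drives the state to a region where \eqn{x^2} feedback
#' explodes and the trajectory diverges. Divergence is flagged on the
#' returned trajectory (`diverged_at` attribute), not thrown.
#'
#' @inheritParams tamed_euler_maruyama
#' @return An `"ews_trajectory"` (see [tamed_euler_maruyama()]).
#' @export
plain_euler_maruyama <- function(model, k_schedule, config, noise = NULL) {
  em_path(model, k_schedule, config, noise, tamed = FALSE)
}

#' @export
print.ews_trajectory <- function(x, ...) {
  a <- attributes(x)
  cat(sprintf("<trajectory> model = %s, alpha = %g, gamma_n = %g, dt = %g, scheme = %s, steps = %d\n",
              a$model, a$alpha, a$gamma_n, a$dt, a$scheme, nrow(x)))
  if (!is.na(a$truncated_at))
    cat(sprintf("  stopped by basin escape at step %d\n", a$truncated_at))
  if (!is.na(a$diverged_at))
    cat(sprintf("  diverged (non-finite state) at step %d\n", a$diverged_at))
  NextMethod()
}
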