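#' Experiment specification for the reference protocols
#'
#' Builds a validated, fully seeded specification for one of the three study
#' protocols. Defaults are the reference study conditions:
#'
#' * `equilibrium` — constant-`k` runs over
#'   `k = {100, 10, 1, 0.1, 0.01}`, 100 independent estimations
#'   (replicates), each pooling 70 thinned points from each of 5 independent
#'   trajectories of 10 000 steps. Within a replicate the identical noise
#'   sequence is reused across the whole `k` range, and the same base seed is
#'   shared across `alpha`, so that differences reflect the drift response,
#'   not the noise realization.
#' * `nonequilibrium` — 15 trajectories per `alpha`; 10 000 equilibration
#'   steps at `k = 5`, then `k` ramped from 5 toward 0 in decrements of
#'   0.0001 (50 000 steps); indicators on trailing windows of 300 points
#'   every 150 steps; 100-point smoothing for presentation.
#' * `divergence` — 100 trajectories of the OU model at constant `k = 1`
#'   (10 000 equilibration + 10 000 measurement steps), running (expanding)
#'   indicators every 300 steps, contrasting the convergence of the fitted
#'   scale with the non-convergence of the running variance for
#'   `alpha < 2`.
#'
#' All protocols use `dt = 0.004`, `gamma_n = 0.1`, `x0 = 0.5`,
#' `epsilon = dt / 100`, and `alphas = {2, 1.8, 1.5, 1.3}` (divergence:
#' `{2, 1.3}`) unless overridden.
#'
#' @param protocol `"equilibrium"`, `"nonequilibrium"`, or `"divergence"`.
#' @param model `"ou"` or `"fold"` (divergence is OU-only).
#' @param alphas Characteristic exponents to run.
#' @param gamma_n Driving noise scale.
#' @param dt Time step.
#' @param epsilon Taming constant.
#' @param x0 Initial state.
#' @param master_seed Integer master seed; all per-trajectory streams are
#'   derived from it by a fixed counter scheme.
#' @param k_values Equilibrium `k` grid.
#' @param n_replicates Equilibrium replicate count (independent
#'   estimations).
#' @param n_traj Trajectories per estimation (equilibrium), per `alpha`
#'   (nonequilibrium, divergence).
#' @param n_steps Steps per trajectory (equilibrium) / measurement steps
#'   (divergence).
#' @param burn_in_frac Fraction of each equilibrium trajectory discarded
#'   before thinning.
#' @param n_keep Thinned points kept per equilibrium trajectory.
#' @param fixed_alpha Optional fixed exponent for the fits (default: jointly
#'   estimated).
#' @param k_start,k_end,k_step Nonequilibrium ramp (see [k_ramp()]).
#' @param n_equil_steps Equilibration steps before the ramp / measurement.
#' @param window,stride Rolling-window settings (nonequilibrium).
#' @param smooth_window Smoothing window for the presentation series.
#' @param k Constant `k` for the divergence protocol.
#' @param every Expanding-anchor spacing (divergence).
#' @return An object of class `"ews_experiment"`.
#' @export
ews_experiment <- function(protocol = c("equilibrium", "nonequilibrium",
                                        "divergence"),
                           model = "ou",
                           alphas = NULL,
                           gamma_n = 0.1, dt = 0.004, epsilon = dt / 100,
                           x0 = 0.5, master_seed = 1L,
                           k_values = c(100, 10, 1, 0.1, 0.01),
                           n_replicates = 100L, n_traj = NULL,
                           n_steps = 10000L, burn_in_frac = 0.3,
                           n_keep = 70L, fixed_alpha = NULL,
                           k_start = 5, k_end = 0, k_step = 1e-4,
                           n_equil_steps = 10000L,
                           window = 300L, stride = 150L,
                           smooth_window = 100L,
                           k = 1, every = 300L) {
  protocol <- match.arg(protocol)
  model <- match.arg(model, c("ou", "fold"))
  if (is.null(alphas)) {
    alphas <- if (protocol == "divergence") c(2, 1.3) else c(2, 1.8, 1.5, 1.3)
  }
  for (a in alphas) stable_params(a, 1)
  if (protocol == "divergence" && model != "ou") {
    rlang::abort("The divergence protocol is defined for the OU model.",
                 class = "alphaews_error_config")
  }
  if (is.null(n_traj)) {
    n_traj <- switch(protocol, equilibrium = 5L, nonequilibrium = 15L,
                     divergence = 100L)
  }
  stopifnot(dt > 0, epsilon > 0, gamma_n >= 0, n_traj >= 1,
            n_steps >= 1, n_replicates >= 1,
            burn_in_frac >= 0, burn_in_frac < 1)
  structure(
    list(protocol = protocol, model = model, alphas = alphas,
         gamma_n = gamma_n, dt = dt, epsilon = epsilon, x0 = x0,
         master_seed = as.integer(master_seed),
         k_values = k_values, n_replicates = as.integer(n_replicates),
         n_traj = as.integer(n_traj), n_steps = as.integer(n_steps),
         burn_in_frac = burn_in_frac, n_keep = as.integer(n_keep),
         fixed_alpha = fixed_alpha,
         k_start = k_start, k_end = k_end, k_step = k_step,
         n_equil_steps = as.integer(n_equil_steps),
         window = as.integer(window), stride = as.integer(stride),
         smooth_window = as.integer(smooth_window),
         k = k, every = as.integer(every)),
    class = "ews_experiment"
  )
}

#' @export
print.ews_experiment <- function(x, ...) {
  cat(sprintf("<experiment: %s>  model = %s, alphas = {%s}, gamma_n = %g, dt = %g, seed = %d\n",
              x$protocol, x$model, paste(x$alphas, collapse = ", "),
              x$gamma_n, x$dt, x$master_seed))
  invisible(x)
}

# Derived per-trajectory seed stream: deterministic in (master_seed,
# protocol, replicate, trajectory), independent of alpha and k by design so
# that noise realizations are shared across both. Kept below 2^31.
derive_seed <- function(master_seed, protocol, replicate, traj) {
  off <- switch(protocol, equilibrium = 0, nonequilibrium = 1,
                divergence = 2)
  base <- as.numeric(master_seed) %% 1000003
  as.integer((base * 1009 + off * 499979 + replicate * 131 + traj) %%
               2147483629 + 1)
}

# Evenly thin the post-burn-in portion of a trajectory to at most n_keep
# points; trajectories truncated at or before the burn-in contribute none.
thin_trajectory <- function(x, burn, n_keep) {
  avail <- length(x) - burn
  if (avail < 1) return(numeric(0))
  idx <- unique(round(seq(burn + 1, length(x), length.out = min(n_keep, avail))))
  x[idx]
}

theory_gamma <- function(model, k, alpha, gamma_n) {
  rate <- if (model == "fold") linearized_rate(k) else k
  gamma_x_limit(rate, alpha, gamma_n)
}

#' Run the equilibrium protocol
#'
#' For every combination of `alpha`, `k`, and replicate: simulate `n_traj`
#' constant-`k` trajectories with the tamed scheme (fold runs honor the
#' basin-escape rule), discard the burn-in, thin each trajectory to `n_keep`
#' evenly spaced points, pool across trajectories, and fit the stable
#' parameters. The same noise sequences are reused across the whole `k`
#' range within a replicate, and base seeds are shared across `alpha`.
#' Replicates containing a stopped trajectory are flagged (`stopped`), not
#' dropped; [summarise_equilibrium()] excludes them from theory
#' comparisons.
#'
#' @param spec An `"ews_experiment"` with `protocol = "equilibrium"`.
#' @return A tibble with one row per (alpha, k, replicate): `protocol`,
#'   `model`, `alpha`, `k`, `replicate`, `n_points`, `stopped`,
#'   `gamma_hat`, `alpha_hat`, `variance_hat`, `ac1_hat`,
#'   `theory_gamma_x`, `relative_error`.
#' @export
run_equilibrium <- function(spec) {
  check_protocol(spec, "equilibrium")
  cfg <- sim_config(spec$n_steps, dt = spec$dt, epsilon = spec$epsilon,
                    x0 = spec$x0,
                    stop_on_escape = spec$model == "fold")
  mdl <- function(k) potential_model(spec$model, k)
  burn <- floor(spec$burn_in_frac * spec$n_steps)

  rows <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    seeds <- vapply(seq_len(spec$n_traj),
                    function(i) derive_seed(spec$master_seed, "equilibrium", r, i),
                    integer(1))
    purrr::map_dfr(spec$alphas, function(a) {
      noises <- lapply(seeds, function(s) {
        noise_increments(spec$n_steps, alpha = a, gamma_n = spec$gamma_n,
                         dt = spec$dt, seed = s)
      })
      purrr::map_dfr(spec$k_values, function(k) {
        pooled <- numeric(0)
        stopped <- FALSE
        for (nz in noises) {
          tr <- tamed_euler_maruyama(mdl(k), k, cfg, nz)
          if (!is.na(attr(tr, "truncated_at"))) stopped <- TRUE
          pooled <- c(pooled, thin_trajectory(tr$x, burn, spec$n_keep))
        }
        est <- if (length(pooled) >= 100) {
          ews_row_safe(pooled, spec$fixed_alpha)
        } else {
          na_ews_row()
        }
        theo <- theory_gamma(spec$model, k, a, spec$gamma_n)
        dplyr::bind_cols(
          tibble::tibble(protocol = "equilibrium", model = spec$model,
                         alpha = a, k = k, replicate = r,
                         n_points = length(pooled), stopped = stopped),
          est,
          tibble::tibble(theory_gamma_x = theo,
                         relative_error = (est$gamma_hat - theo) / theo)
        )
      })
    })
  })
  rows
}

ews_row_safe <- function(x, fixed_alpha) {
  tryCatch(ews_row(x, fixed_alpha, "quantile"),
           alphaews_error_degenerate = function(e) na_ews_row())
}

na_ews_row <- function() {
  tibble::tibble(gamma_hat = NA_real_, alpha_hat = NA_real_,
                 variance_hat = NA_real_, ac1_hat = NA_real_)
}

#' Summarise equilibrium results against theory
#'
#' Per (alpha, k): mean and dispersion of the fitted scale and the mean
#' relative error against the closed-form stationary scale. Replicates
#' flagged `stopped` are excluded from the theory comparison by default
#' (their estimates are computed from basin-truncated data).
#'
#' @param results Output of [run_equilibrium()].
#' @param include_stopped Keep stopped replicates in the summary?
#' @return A tibble with columns `model`, `alpha`, `k`, `n_replicates`,
#'   `mean_gamma`, `sd_gamma`, `mean_alpha`, `theory_gamma_x`,
#'   `mean_rel_error`.
#' @export
summarise_equilibrium <- function(results, include_stopped = FALSE) {
  res <- if (include_stopped) results else dplyr::filter(results, !.data$stopped)
  res |>
    dplyr::filter(!is.na(.data$gamma_hat)) |>
    dplyr::group_by(.data$model, .data$alpha, .data$k) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_gamma = mean(.data$gamma_hat),
      sd_gamma = stats::sd(.data$gamma_hat),
      mean_alpha = mean(.data$alpha_hat),
      theory_gamma_x = .data$theory_gamma_x[1],
      mean_rel_error = mean(.data$relative_error),
      .groups = "drop"
    )
}

#' Run the non-equilibrium (ramp) protocol
#'
#' Per trajectory: equilibrate at `k_start` for `n_equil_steps`, then ramp
#' `k` toward `k_end` in decrements of `k_step` (one per integration step),
#' computing rolling-window indicators on the ramp portion and a smoothed
#' presentation series. Fold trajectories that escape the basin are
#' truncated and contribute only their pre-escape anchors. The closed-form
#' stationary scale at each anchor's `k` (via the linearization rate for the
#' fold) is attached for comparison.
#'
#' @param spec An `"ews_experiment"` with `protocol = "nonequilibrium"`.
#' @return A tibble with per-trajectory anchor rows: `protocol`, `model`,
#'   `alpha`, `traj`, `anchor`, `t`, `k`, `gamma_hat`, `gamma_smooth`,
#'   `alpha_hat`, `variance_hat`, `ac1_hat`, `theory_gamma_x`. Use
#'   [summarise_nonequilibrium()] for the cross-trajectory mean series.
#' @export
run_nonequilibrium <- function(spec) {
  check_protocol(spec, "nonequilibrium")
  ramp <- k_ramp(spec$k_start, spec$k_end, spec$k_step)
  n_total <- spec$n_equil_steps + length(ramp)
  sched <- c(rep(spec$k_start, spec$n_equil_steps), ramp)
  cfg <- sim_config(n_total, dt = spec$dt, epsilon = spec$epsilon,
                    x0 = spec$x0, stop_on_escape = spec$model == "fold")
  mdl <- potential_model(spec$model, spec$k_start)

  purrr::map_dfr(spec$alphas, function(a) {
    purrr::map_dfr(seq_len(spec$n_traj), function(i) {
      s <- derive_seed(spec$master_seed, "nonequilibrium", 0L, i)
      nz <- noise_increments(n_total, alpha = a, gamma_n = spec$gamma_n,
                             dt = spec$dt, seed = s)
      tr <- tamed_euler_maruyama(mdl, sched, cfg, nz)
      seg <- dplyr::filter(tr, .data$step > spec$n_equil_steps)
      if (nrow(seg) < spec$window) return(NULL)
      ser <- rolling_ews(seg, window = spec$window, stride = spec$stride,
                         fixed_alpha = spec$fixed_alpha)
      theo <- vapply(ser$k,
                     function(kk) theory_gamma(spec$model, kk, a, spec$gamma_n),
                     numeric(1))
      tibble::tibble(
        protocol = "nonequilibrium", model = spec$model, alpha = a,
        traj = i, anchor = ser$anchor, t = ser$t, k = ser$k,
        gamma_hat = ser$gamma_hat,
        gamma_smooth = smooth_series(ser$gamma_hat, spec$smooth_window),
        alpha_hat = ser$alpha_hat, variance_hat = ser$variance_hat,
        ac1_hat = ser$ac1_hat, theory_gamma_x = theo
      )
    })
  })
}

#' Cross-trajectory mean of the non-equilibrium series
#'
#' @param results Output of [run_nonequilibrium()].
#' @return A tibble per (model, alpha, anchor): number of contributing
#'   trajectories and means of the raw and smoothed indicator, with the
#'   theory curve.
#' @export
summarise_nonequilibrium <- function(results) {
  results |>
    dplyr::group_by(.data$model, .data$alpha, .data$anchor) |>
    dplyr::summarise(
      k = .data$k[1],
      n_traj = dplyr::n(),
      mean_gamma = mean(.data$gamma_hat),
      mean_gamma_smooth = mean(.data$gamma_smooth),
      mean_variance = mean(.data$variance_hat),
      theory_gamma_x = .data$theory_gamma_x[1],
      .groups = "drop"
    )
}

#' Run the divergence demonstration
#'
#' Simulates `n_traj` OU trajectories at constant `k` (equilibration
#' followed by a measurement segment) and computes expanding-window running
#' indicators on the measurement segment: the running variance versus the
#' running fitted scale. Under Gaussian forcing both settle; for
#' `alpha < 2` the running variance keeps drifting (its population value
#' does not exist) while the fitted scale converges — the false-positive
#' mechanism of variance-based warning signals.
#'
#' @param spec An `"ews_experiment"` with `protocol = "divergence"`.
#' @return A tibble with per-trajectory anchor rows: `protocol`, `alpha`,
#'   `traj`, `anchor`, `gamma_hat`, `alpha_hat`, `variance_hat`,
#'   `ac1_hat`.
#' @export
run_divergence <- function(spec) {
  check_protocol(spec, "divergence")
  n_total <- spec$n_equil_steps + spec$n_steps
  cfg <- sim_config(n_total, dt = spec$dt, epsilon = spec$epsilon,
                    x0 = spec$x0)
  mdl <- potential_model("ou", spec$k)

  purrr::map_dfr(spec$alphas, function(a) {
    purrr::map_dfr(seq_len(spec$n_traj), function(i) {
      s <- derive_seed(spec$master_seed, "divergence", 0L, i)
      nz <- noise_increments(n_total, alpha = a, gamma_n = spec$gamma_n,
                             dt = spec$dt, seed = s)
      tr <- tamed_euler_maruyama(mdl, spec$k, cfg, nz)
      seg <- dplyr::filter(tr, .data$step > spec$n_equil_steps)
      ser <- expanding_ews(seg, every = spec$every,
                           fixed_alpha = spec$fixed_alpha)
      tibble::tibble(
        protocol = "divergence", alpha = a, traj = i,
        anchor = ser$anchor, gamma_hat = ser$gamma_hat,
        alpha_hat = ser$alpha_hat, variance_hat = ser$variance_hat,
        ac1_hat = ser$ac1_hat
      )
    })
  })
}

#' Run any protocol from its specification
#'
#' @param spec An `"ews_experiment"`.
#' @return The protocol's results tibble.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "ews_experiment"))
  switch(spec$protocol,
         equilibrium = run_equilibrium(spec),
         nonequilibrium = run_nonequilibrium(spec),
         divergence = run_divergence(spec))
}

check_protocol <- function(spec, protocol) {
  stopifnot(inherits(spec, "ews_experiment"))
  if (spec$protocol != protocol) {
    rlang::abort(sprintf("Spec protocol is '%s', expected '%s'.",
                         spec$protocol, protocol),
                 class = "alphaews_error_config")
  }
  invisible(spec)
}
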