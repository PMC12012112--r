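# Render double columns at full round-trip precision (17 significant digits)
# so CSV files re-read bit-exactly.
fmt_doubles <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' Write / read a trajectory as CSV with sidecar metadata
#'
#' The trajectory table (`step`, `t`, `k`, `x`) is written as CSV with
#' shortest-round-trip float formatting (bit-exact on re-read) and the
#' provenance attributes (`model`, `alpha`, `gamma_n`, `dt`, `epsilon`,
#' `x0`, `seed`, `scheme`, `truncated_at`, `diverged_at`) as a JSON sidecar
#' at `<path>.json`.
#'
#' @param trajectory An `"ews_trajectory"`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the reconstructed `"ews_trajectory"`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ews_trajectory"))
  readr::write_csv(fmt_doubles(as.data.frame(trajectory)), path)
  meta <- attributes(trajectory)[c("model", "alpha", "gamma_n", "dt",
                                   "epsilon", "x0", "seed", "scheme",
                                   "truncated_at", "diverged_at")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  # base-R reader: correctly rounded strtod parsing for bit-exact round-trips
  tab <- tibble::as_tibble(utils::read.csv(path, colClasses = c(
    step = "integer", t = "numeric", k = "numeric", x = "numeric"
  )))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  int_or_na <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  structure(tab, class = c("ews_trajectory", class(tab)),
            model = meta$model, alpha = meta$alpha, gamma_n = meta$gamma_n,
            dt = meta$dt, epsilon = meta$epsilon, x0 = meta$x0,
            seed = int_or_na(meta$seed), scheme = meta$scheme,
            truncated_at = int_or_na(meta$truncated_at),
            diverged_at = int_or_na(meta$diverged_at))
}

#' Write / read an early-warning series as CSV with sidecar metadata
#'
#' @param series An `"ews_series"` from [rolling_ews()] or
#'   [expanding_ews()].
#' @param path CSV file path.
#' @return `write_ews()` returns `path` invisibly; `read_ews()` the
#'   reconstructed series.
#' @export
write_ews <- function(series, path) {
  stopifnot(inherits(series, "ews_series"))
  readr::write_csv(fmt_doubles(as.data.frame(series)), path)
  meta <- attributes(series)[c("window", "stride", "method", "mode")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ews
#' @export
read_ews <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path))
  tab$anchor <- as.integer(tab$anchor)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(tab, class = c("ews_series", class(tab)),
            window = if (is.null(meta$window)) NA_integer_ else as.integer(meta$window),
            stride = as.integer(meta$stride), method = meta$method,
            mode = meta$mode)
}

#' Declarative run configuration
#'
#' A flat key-value mirror of the experiment specification, loadable from
#' YAML. Every field has a default from the reference study conditions;
#' unknown keys are rejected with the offending name. `resolve_run_config()`
#' merges a partial config over the defaults and returns the fully resolved
#' list (suitable for writing back next to run outputs, so every run is
#' replayable).
#'
#' @param path YAML file path.
#' @param config A (partial) named list of settings.
#' @return `default_run_config()` and `resolve_run_config()` return the full
#'   named list; `read_run_config()` the resolved list from file;
#'   `write_run_config()` the path, invisibly.
#' @export
default_run_config <- function() {
  list(
    protocol = "equilibrium",
    model = "ou",
    alphas = c(2, 1.8, 1.5, 1.3),
    gamma_n = 0.1,
    dt = 0.004,
    epsilon = 4e-05,
    x0 = 0.5,
    master_seed = 1L,
    k_values = c(100, 10, 1, 0.1, 0.01),
    n_replicates = 100L,
    n_traj = NA_integer_,
    n_steps = 10000L,
    burn_in_frac = 0.3,
    n_keep = 70L,
    fixed_alpha = NA_real_,
    k_start = 5,
    k_end = 0,
    k_step = 1e-04,
    n_equil_steps = 10000L,
    window = 300L,
    stride = 150L,
    smooth_window = 100L,
    k = 1,
    every = 300L
  )
}

#' @rdname default_run_config
#' @export
resolve_run_config <- function(config = list()) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown config field(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "alphaews_error_config")
  }
  utils::modifyList(defaults, config)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  resolve_run_config(yaml::read_yaml(path))
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(resolve_run_config(config), path)
  invisible(path)
}

#' Build an experiment specification from a resolved config
#'
#' @param config A named list as returned by [resolve_run_config()].
#' @return An `"ews_experiment"`.
#' @export
config_to_experiment <- function(config) {
  cf <- resolve_run_config(config)
  ews_experiment(
    protocol = cf$protocol, model = cf$model, alphas = cf$alphas,
    gamma_n = cf$gamma_n, dt = cf$dt, epsilon = cf$epsilon, x0 = cf$x0,
    master_seed = cf$master_seed, k_values = cf$k_values,
    n_replicates = cf$n_replicates,
    n_traj = if (is.na(cf$n_traj)) NULL else cf$n_traj,
    n_steps = cf$n_steps, burn_in_frac = cf$burn_in_frac,
    n_keep = cf$n_keep,
    fixed_alpha = if (is.na(cf$fixed_alpha)) NULL else cf$fixed_alpha,
    k_start = cf$k_start, k_end = cf$k_end, k_step = cf$k_step,
    n_equil_steps = cf$n_equil_steps, window = cf$window,
    stride = cf$stride, smooth_window = cf$smooth_window,
    k = cf$k, every = cf$every
  )
}
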