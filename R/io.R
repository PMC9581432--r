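# Config parsing and result serialization (YAML config, CSV trajectories
# and sweeps, JSON R0 reports).

config_keys <- function() {
  c(rate_names(),
    "init_s", "init_e1", "init_e2", "population", "horizon",
    "rel_tol", "abs_tol", "rate_eps", "extinct_eps", "window_frac",
    "seed", "label")
}

config_defaults <- function() {
  list(init_s = 1 / 3, init_e1 = 1 / 3, init_e2 = 1 / 3,
       population = 1000, horizon = 500,
       rel_tol = 1e-8, abs_tol = 1e-10,
       rate_eps = 1e-8, extinct_eps = 1e-3, window_frac = 0.2,
       seed = 1L, label = "")
}

#' Load a run configuration from a flat YAML file
#'
#' The file holds flat scalar keys: the twelve rate constants by name
#' (`r1 ... alpha2`; missing rates default to 0 with a notice), the initial
#' fractions `init_s`, `init_e1`, `init_e2` (must sum to 1 within 1e-6;
#' default 1/3 each), `population` (persons, default 1000), `horizon`
#' (weeks), solver tolerances `rel_tol`/`abs_tol`, plateau thresholds
#' `rate_eps`/`extinct_eps`/`window_frac`, `seed`, and `label`. Unknown
#' keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An `exersist_config`: validated named list of all settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat key: value mapping", call. = FALSE)
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- config_defaults()
  rates <- stats::setNames(as.list(numeric(12)), rate_names())
  missing_rates <- setdiff(rate_names(), names(raw))
  if (length(missing_rates) < 12 && length(missing_rates) > 0) {
    message("rates not in config default to 0: ",
            paste(missing_rates, collapse = ", "))
  }
  cfg <- utils::modifyList(c(rates, cfg), raw)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (nm in rate_names()) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("config field '%s' must be a finite nonnegative rate", nm),
           call. = FALSE)
    }
  }
  fr <- c(cfg$init_s, cfg$init_e1, cfg$init_e2)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("initial fractions init_s/init_e1/init_e2 must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-6) {
    stop(sprintf("initial fractions must sum to 1 (got %.8f)", sum(fr)),
         call. = FALSE)
  }
  if (!is.finite(cfg$population) || cfg$population <= 0) {
    stop("config field 'population' must be positive", call. = FALSE)
  }
  if (!is.finite(cfg$horizon) || cfg$horizon <= 0) {
    stop("config field 'horizon' must be positive", call. = FALSE)
  }
  structure(cfg, class = "exersist_config")
}

#' Build a scenario from a loaded configuration
#'
#' @param cfg An `exersist_config` from [load_config()].
#' @return An `exersist_scenario`.
#' @export
config_to_scenario <- function(cfg) {
  if (!inherits(cfg, "exersist_config")) {
    stop("`cfg` must come from load_config()", call. = FALSE)
  }
  pars <- as_model_params(unlist(cfg[rate_names()]))
  N <- cfg$population
  scenario(pars,
           population_state(S = cfg$init_s * N, E1 = cfg$init_e1 * N,
                            E2 = cfg$init_e2 * N),
           horizon = cfg$horizon, label = cfg$label)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]; a write-then-load round trip reproduces the
#' configuration.
#'
#' @param cfg An `exersist_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "exersist_config")) {
    stop("`cfg` must come from load_config()", call. = FALSE)
  }
  yaml::write_yaml(unclass(cfg), path, precision = 17L)
  invisible(path)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a trajectory to CSV at full float precision
#'
#' Header `t,S,E1,E2,N`, one row per output point, 17 significant digits so
#' that a write-then-read round trip reproduces every value bitwise.
#'
#' @param traj An `exersist_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "exersist_trajectory")) {
    stop("`traj` must be an exersist_trajectory", call. = FALSE)
  }
  lines <- c("t,S,E1,E2,N",
             paste(fmt_full(traj$t), fmt_full(traj$S), fmt_full(traj$E1),
                   fmt_full(traj$E2), fmt_full(traj$N), sep = ","))
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write trajectory CSV to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `t, S, E1, E2, N`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("trajectory CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("t", "S", "E1", "E2", "N")
  if (!identical(names(df), need)) {
    stop("trajectory CSV must have header t,S,E1,E2,N", call. = FALSE)
  }
  df
}

#' Write an R0 result as a JSON report
#'
#' Report shape: `{value, method, classification, coefficients: {A, B, C}}`
#' (coefficients present only for the closed-form method).
#'
#' @param result An `exersist_r0`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_r0_json <- function(result, path) {
  if (!inherits(result, "exersist_r0")) {
    stop("`result` must be an exersist_r0", call. = FALSE)
  }
  rep <- list(value = result$value, method = result$method,
              classification = result$classification)
  if (!is.null(result$coefficients)) rep$coefficients <- result$coefficients
  ok <- try(jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write R0 JSON to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a sensitivity sweep to CSV
#'
#' Columns `parameter,value,plateau_S,pct_change_vs_baseline`, full float
#' precision.
#'
#' @param sweep An `exersist_sweep` from [oat_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  if (!inherits(sweep, "exersist_sweep")) {
    stop("`sweep` must be an exersist_sweep", call. = FALSE)
  }
  num <- function(x) ifelse(is.na(x), "NA", fmt_full(x))
  lines <- c("parameter,value,plateau_S,pct_change_vs_baseline",
             paste(sweep$parameter, num(sweep$value), num(sweep$plateau_S),
                   num(sweep$pct_change_vs_baseline), sep = ","))
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write sweep CSV to ", path, call. = FALSE)
  }
  invisible(path)
}
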