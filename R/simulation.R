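# Forward integration of scenarios and plateau/extinction detection.

#' Integrate a scenario forward in time
#'
#' Solves the three-equation system over `[0, horizon]` with
#' [deSolve::lsoda()] (adaptive step, automatic stiff/non-stiff switching)
#' and returns the trajectory sampled at `n_out` evenly spaced times. The
#' closed system conserves `S + E1 + E2`; integration is rejected if the
#' total drifts by more than `1e-6 * N(0)` anywhere along the trajectory.
#' Tiny negative excursions (within integrator noise) are clamped to zero
#' in the output.
#'
#' @param scn An `exersist_scenario`.
#' @param rel_tol,abs_tol Positive solver tolerances (defaults 1e-8, 1e-10).
#' @param n_out Number of evenly spaced output points (>= 2).
#' @return An `exersist_trajectory`: a data frame with columns
#'   `t, S, E1, E2, N` and the scenario attached as attribute `"scenario"`.
#' @export
#' @examples
#' scn <- scenario(model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'                              alpha1 = 0.005, alpha2 = 0.005),
#'                 population_state(S = 500, E1 = 300, E2 = 200),
#'                 horizon = 300)
#' traj <- integrate_scenario(scn)
#' tail(traj, 3)
integrate_scenario <- function(scn, rel_tol = 1e-8, abs_tol = 1e-10,
                               n_out = 501L) {
  if (!inherits(scn, "exersist_scenario")) {
    stop("`scn` must be an exersist_scenario", call. = FALSE)
  }
  if (!is.finite(rel_tol) || rel_tol <= 0 || !is.finite(abs_tol) || abs_tol <= 0) {
    stop("solver tolerances must be positive", call. = FALSE)
  }
  if (n_out < 2) stop("n_out must be at least 2", call. = FALSE)
  y0 <- c(S = scn$initial$S, E1 = scn$initial$E1, E2 = scn$initial$E2)
  N0 <- scn$initial$N
  times <- seq(0, scn$horizon, length.out = n_out)
  deriv <- function(t, y, p) list(rhs_raw(p, y))
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv,
                        parms = scn$params, rtol = rel_tol, atol = abs_tol)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1L] < 0) {
    stop(sprintf("integration failed (istate = %d) near t = %g weeks",
                 istate[1L], max(sol[, "time"])), call. = FALSE)
  }
  if (nrow(sol) < n_out) {
    stop(sprintf("integration stopped early at t = %g of %g weeks",
                 max(sol[, "time"]), scn$horizon), call. = FALSE)
  }
  comps <- sol[, c("S", "E1", "E2"), drop = FALSE]
  worst_neg <- min(comps)
  if (worst_neg < -1e-6 * N0) {
    stop(sprintf("trajectory left the nonnegative orthant (min = %.3g)",
                 worst_neg), call. = FALSE)
  }
  comps[comps < 0] <- 0
  drift <- max(abs(rowSums(comps) - N0))
  if (drift > 1e-6 * N0) {
    stop(sprintf("population total drifted by %.3g persons (> 1e-6 * N)",
                 drift), call. = FALSE)
  }
  out <- data.frame(t = sol[, "time"], S = comps[, "S"],
                    E1 = comps[, "E1"], E2 = comps[, "E2"],
                    N = rowSums(comps))
  structure(out, scenario = scn, rel_tol = rel_tol, abs_tol = abs_tol,
            class = c("exersist_trajectory", "data.frame"))
}

#' @export
print.exersist_trajectory <- function(x, ...) {
  scn <- attr(x, "scenario")
  last <- x[nrow(x), ]
  cat(sprintf("Trajectory over %g weeks (%d points)%s\n",
              max(x$t), nrow(x),
              if (nzchar(scn$label)) paste0(", scenario '", scn$label, "'")
              else ""))
  cat(sprintf("  final fractions: S %.4f, E1 %.4f, E2 %.4f\n",
              last$S / last$N, last$E1 / last$N, last$E2 / last$N))
  invisible(x)
}

#' Detect a plateau and extinct compartments in a trajectory
#'
#' The trajectory has settled when, over the trailing `window_frac` of the
#' horizon, every component of the right-hand side stays below
#' `rate_eps * N` in magnitude (i.e. flows have effectively stopped). A
#' compartment is reported extinct when its final fraction of the
#' population is below `extinct_eps`.
#'
#' @param traj An `exersist_trajectory`.
#' @param rate_eps Rate threshold, week^-1, relative to N (default 1e-8).
#' @param extinct_eps Extinction threshold on final fractions (default 1e-3).
#' @param window_frac Trailing fraction of the horizon examined, in (0, 1)
#'   (default 0.2).
#' @return An `exersist_plateau`: list with `settled` (logical),
#'   `final_fractions` (named S/E1/E2 fractions summing to 1), `extinct`
#'   (character vector of compartment labels), and `max_rate` (the largest
#'   RHS magnitude seen in the window, persons week^-1).
#' @export
detect_plateau <- function(traj, rate_eps = 1e-8, extinct_eps = 1e-3,
                           window_frac = 0.2) {
  if (!inherits(traj, "exersist_trajectory") || nrow(traj) == 0L) {
    stop("`traj` must be a nonempty exersist_trajectory", call. = FALSE)
  }
  if (!is.finite(window_frac) || window_frac <= 0 || window_frac >= 1) {
    stop("window_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  scn <- attr(traj, "scenario")
  t_end <- max(traj$t)
  in_window <- traj$t >= (1 - window_frac) * t_end
  rates <- apply(traj[in_window, c("S", "E1", "E2"), drop = FALSE], 1L,
                 function(y) max(abs(rhs_raw(scn$params, y))))
  N0 <- scn$initial$N
  last <- traj[nrow(traj), ]
  fr <- c(S = last$S, E1 = last$E1, E2 = last$E2) / last$N
  structure(list(settled = max(rates) < rate_eps * N0,
                 final_fractions = fr,
                 extinct = names(fr)[fr < extinct_eps],
                 max_rate = max(rates)),
            class = "exersist_plateau")
}

#' @export
print.exersist_plateau <- function(x, ...) {
  cat(sprintf("Plateau report: %s\n",
              if (x$settled) "settled" else "NOT settled"))
  cat(sprintf("  final fractions: S %.4f, E1 %.4f, E2 %.4f\n",
              x$final_fractions[["S"]], x$final_fractions[["E1"]],
              x$final_fractions[["E2"]]))
  cat("  extinct compartments:",
      if (length(x$extinct)) paste(x$extinct, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Integrate a scenario until its plateau criterion is met
#'
#' Runs [integrate_scenario()] at the scenario's horizon and, if the
#' trailing-window rate criterion of [detect_plateau()] is not yet met,
#' doubles the horizon and repeats, up to `max_horizon`. The last attempt is
#' returned in either case; inspect `report$settled`.
#'
#' @inheritParams integrate_scenario
#' @inheritParams detect_plateau
#' @param max_horizon Largest horizon tried, weeks (default 8000).
#' @return List with elements `trajectory` and `report`.
#' @export
simulate_to_plateau <- function(scn, rel_tol = 1e-8, abs_tol = 1e-10,
                                n_out = 501L, rate_eps = 1e-8,
                                extinct_eps = 1e-3, window_frac = 0.2,
                                max_horizon = 8000) {
  if (!inherits(scn, "exersist_scenario")) {
    stop("`scn` must be an exersist_scenario", call. = FALSE)
  }
  horizon <- scn$horizon
  repeat {
    run <- scenario(scn$params, scn$initial, horizon, scn$label)
    traj <- integrate_scenario(run, rel_tol = rel_tol, abs_tol = abs_tol,
                               n_out = n_out)
    rep <- detect_plateau(traj, rate_eps = rate_eps,
                          extinct_eps = extinct_eps,
                          window_frac = window_frac)
    if (rep$settled || horizon >= max_horizon) {
      return(list(trajectory = traj, report = rep))
    }
    horizon <- min(2 * horizon, max_horizon)
  }
}

#' Preset scenarios
#'
#' Three published parameterisations of the model:
#'
#' * `"fig3a"` — persistence regime: `k1 = 0.002`, `r1 = 0.015`,
#'   `beta1 = 0.0022`, `alpha1 = alpha2 = 0.005`, all other rates 0;
#'   initial fractions 50% sedentary, 30% moderately active, 20% extremely
#'   active. R0 = (k1 + r1)/beta1 > 1: sedentary behaviour goes extinct.
#' * `"fig3b"` — the same but with social recidivism raised to
#'   `beta1 = 0.035`, so R0 < 1: the active compartments go extinct.
#' * `"sensitivity_baseline"` — all twelve rates 0.001 and initial
#'   fractions 1/3 each; the reference point of the one-at-a-time
#'   sensitivity protocol.
#'
#' @param name One of `"fig3a"`, `"fig3b"`, `"sensitivity_baseline"`.
#' @param N Population size, persons (default 1000). Only the fractions
#'   matter to the dynamics: every contact term is scaled by N.
#' @param horizon Initial horizon in weeks (default 500; extended
#'   automatically by [simulate_to_plateau()]).
#' @return An `exersist_scenario`.
#' @export
#' @examples
#' preset_scenario("fig3a")
preset_scenario <- function(name, N = 1000, horizon = 500) {
  name <- match.arg(name, c("fig3a", "fig3b", "sensitivity_baseline"))
  if (name == "sensitivity_baseline") {
    pars <- as_model_params(stats::setNames(rep(0.001, 12), rate_names()))
    fr <- c(1, 1, 1) / 3
  } else {
    beta1 <- if (name == "fig3a") 0.0022 else 0.035
    pars <- model_params(k1 = 0.002, r1 = 0.015, beta1 = beta1,
                         alpha1 = 0.005, alpha2 = 0.005)
    fr <- c(0.5, 0.3, 0.2)
  }
  scenario(pars,
           population_state(S = fr[1] * N, E1 = fr[2] * N, E2 = fr[3] * N),
           horizon = horizon, label = name)
}

#' Run a preset scenario to plateau
#'
#' Convenience wrapper: builds the preset via [preset_scenario()], runs it
#' with [simulate_to_plateau()], and returns scenario, trajectory and
#' plateau report together.
#'
#' @inheritParams preset_scenario
#' @param ... Passed on to [simulate_to_plateau()].
#' @return List with elements `scenario`, `trajectory`, `report`.
#' @export
#' @examples
#' \donttest{
#' res <- run_preset("fig3b")
#' res$report$extinct  # "E1" "E2": exercising dies out
#' }
run_preset <- function(name, N = 1000, horizon = 500, ...) {
  scn <- preset_scenario(name, N = N, horizon = horizon)
  sim <- simulate_to_plateau(scn, ...)
  list(scenario = scn, trajectory = sim$trajectory, report = sim$report)
}
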