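# One-at-a-time sensitivity: vary a rate (or a group in lockstep) from a
# fixed baseline and record the response of the long-run sedentary fraction.

#' One-at-a-time sweep of a rate constant
#'
#' Holds every rate at its baseline value, sets the named rate (or several
#' named rates in lockstep, for grouped sweeps) to each grid value in turn,
#' integrates the modified scenario to plateau, and records the final
#' sedentary fraction. The direction of the response is read from the
#' first and last grid points with a flatness band of `flat_band`.
#'
#' Grid points whose trajectory has not settled by `max_horizon` are
#' recorded as `NA` with a warning rather than failing the sweep.
#'
#' @param baseline An `exersist_scenario` supplying the fixed rates and
#'   initial state (typically `preset_scenario("sensitivity_baseline")`).
#' @param parameter Character: one or more of [rate_names()], varied
#'   together.
#' @param grid Strictly increasing nonnegative values (week^-1) assigned to
#'   the swept rate(s).
#' @param flat_band Absolute change in plateau fraction below which the
#'   response is called `"flat"` (default 1e-6).
#' @param ... Passed on to [simulate_to_plateau()].
#' @return An `exersist_sweep`: a data frame with columns
#'   `parameter, value, plateau_S, pct_change_vs_baseline` plus attributes
#'   `direction` (`"decreasing"`, `"increasing"` or `"flat"`) and
#'   `baseline_plateau_S`.
#' @export
#' @examples
#' \donttest{
#' base <- preset_scenario("sensitivity_baseline")
#' sw <- oat_sweep(base, "beta1", c(1, 2, 5, 10) * 0.001)
#' attr(sw, "direction")  # "increasing": recidivism raises the sedentary plateau
#' }
oat_sweep <- function(baseline, parameter, grid, flat_band = 1e-6, ...) {
  if (!inherits(baseline, "exersist_scenario")) {
    stop("`baseline` must be an exersist_scenario", call. = FALSE)
  }
  unknown <- setdiff(parameter, rate_names())
  if (length(unknown) || length(parameter) == 0L) {
    stop("unknown parameter name(s): ",
         paste(if (length(unknown)) unknown else "(none given)",
               collapse = ", "), call. = FALSE)
  }
  grid <- as.numeric(grid)
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("grid values must be finite and nonnegative", call. = FALSE)
  }
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }

  base_sim <- simulate_to_plateau(baseline, ...)
  if (!base_sim$report$settled) {
    warning("baseline trajectory did not settle; percent changes are ",
            "relative to its last state")
  }
  base_S <- base_sim$report$final_fractions[["S"]]

  plateau_S <- vapply(grid, function(v) {
    pars <- unclass(baseline$params)
    pars[parameter] <- v
    scn <- scenario(as_model_params(pars), baseline$initial,
                    baseline$horizon, baseline$label)
    sim <- simulate_to_plateau(scn, ...)
    if (!sim$report$settled) {
      warning(sprintf("sweep point %s = %g did not settle; recorded as NA",
                      paste(parameter, collapse = "+"), v))
      return(NA_real_)
    }
    sim$report$final_fractions[["S"]]
  }, numeric(1))

  ok <- !is.na(plateau_S)
  direction <- if (sum(ok) < 2L) "flat" else {
    d <- plateau_S[ok][sum(ok)] - plateau_S[ok][1L]
    if (d > flat_band) "increasing"
    else if (d < -flat_band) "decreasing"
    else "flat"
  }
  out <- data.frame(parameter = paste(parameter, collapse = "+"),
                    value = grid, plateau_S = plateau_S,
                    pct_change_vs_baseline =
                      ifelse(ok, 100 * (plateau_S - base_S) / base_S, NA_real_))
  structure(out, direction = direction, baseline_plateau_S = base_S,
            class = c("exersist_sweep", "data.frame"))
}

#' @export
print.exersist_sweep <- function(x, ...) {
  cat(sprintf("OAT sweep of %s (%s), baseline sedentary plateau %.4f\n",
              x$parameter[1], attr(x, "direction"),
              attr(x, "baseline_plateau_S")))
  print(as.data.frame(x))
  invisible(x)
}

#' Percent change of the sedentary plateau
#'
#' @param baseline_plateau_S Baseline sedentary plateau fraction, > 0.
#' @param varied_plateau_S Plateau fraction under the varied parameter.
#' @return Signed percent change, `100 * (varied - baseline) / baseline`.
#' @export
#' @examples
#' plateau_change_pct(0.5, 0.4)   # -20
#' plateau_change_pct(0.25, 0.32) # +28
plateau_change_pct <- function(baseline_plateau_S, varied_plateau_S) {
  if (!is.finite(baseline_plateau_S) || baseline_plateau_S <= 0) {
    stop("percent change undefined: baseline plateau must be positive",
         call. = FALSE)
  }
  100 * (varied_plateau_S - baseline_plateau_S) / baseline_plateau_S
}
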