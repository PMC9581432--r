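# Core model objects: rate constants, compartment states, scenarios, and the
# right-hand side of the three-equation system.

#' Names of the twelve rate constants
#'
#' The model is governed by twelve nonnegative rate constants, all in units
#' of week^-1:
#'
#' * `r1`, `r2` — social transition S -> E1 driven by contact with E1 (resp. E2)
#' * `k1`, `k2` — social transition S -> E2 driven by contact with E1 (resp. E2)
#' * `gamma1`, `gamma2` — spontaneous transition S -> E1 (resp. S -> E2)
#' * `beta1`, `beta2` — social recidivism E1 -> S (resp. E2 -> S) driven by
#'   contact with S
#' * `delta1`, `delta2` — spontaneous recidivism E1 -> S (resp. E2 -> S)
#' * `alpha1` — transition E2 -> E1; `alpha2` — transition E1 -> E2
#'
#' @return Character vector of the twelve parameter names, in canonical order.
#' @export
#' @examples
#' rate_names()
rate_names <- function() {
  c("r1", "r2", "k1", "k2", "gamma1", "gamma2",
    "beta1", "beta2", "delta1", "delta2", "alpha1", "alpha2")
}

#' Construct a set of model rate constants
#'
#' Builds the twelve nonnegative rate constants of the exercise-behaviour
#' model. Omitted rates default to 0, so a parameter set is specified by
#' naming only its nonzero flows.
#'
#' @param r1,r2 Social uptake rates S -> E1 by contact with E1, E2 (week^-1).
#' @param k1,k2 Social uptake rates S -> E2 by contact with E1, E2 (week^-1).
#' @param gamma1,gamma2 Spontaneous uptake rates S -> E1, S -> E2 (week^-1).
#' @param beta1,beta2 Social recidivism rates E1 -> S, E2 -> S by contact
#'   with S (week^-1).
#' @param delta1,delta2 Spontaneous recidivism rates E1 -> S, E2 -> S
#'   (week^-1).
#' @param alpha1 Exchange rate E2 -> E1 (week^-1).
#' @param alpha2 Exchange rate E1 -> E2 (week^-1).
#'
#' @return An object of class `exersist_params`: a named numeric vector of
#'   length 12 in the order of [rate_names()].
#' @export
#' @examples
#' # The persistence scenario of the published simulations
#' model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'              alpha1 = 0.005, alpha2 = 0.005)
model_params <- function(r1 = 0, r2 = 0, k1 = 0, k2 = 0,
                         gamma1 = 0, gamma2 = 0,
                         beta1 = 0, beta2 = 0,
                         delta1 = 0, delta2 = 0,
                         alpha1 = 0, alpha2 = 0) {
  p <- c(r1 = r1, r2 = r2, k1 = k1, k2 = k2,
         gamma1 = gamma1, gamma2 = gamma2,
         beta1 = beta1, beta2 = beta2,
         delta1 = delta1, delta2 = delta2,
         alpha1 = alpha1, alpha2 = alpha2)
  validate_params(p)
  structure(p, class = "exersist_params")
}

#' Coerce a named list or vector to model parameters
#'
#' @param x Named list or numeric vector whose names are a subset of
#'   [rate_names()]. Missing rates default to 0; unknown names are an error.
#' @return An `exersist_params` object.
#' @export
as_model_params <- function(x) {
  if (inherits(x, "exersist_params")) return(x)
  x <- unlist(x)
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("parameters must be named", call. = FALSE)
  }
  unknown <- setdiff(names(x), rate_names())
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(numeric(12), rate_names())
  full[names(x)] <- as.numeric(x)
  do.call(model_params, as.list(full))
}

validate_params <- function(p) {
  bad <- !is.finite(p) | p < 0
  if (any(bad)) {
    stop("rate constants must be finite and nonnegative; offending: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.exersist_params <- function(x, ...) {
  cat("Model rate constants (week^-1):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Construct a population state
#'
#' A snapshot of the population at one time point: counts of sedentary (`S`),
#' moderately active (`E1`) and extremely active (`E2`) individuals. The
#' total `N = S + E1 + E2` is derived, never supplied; the closed system
#' conserves it along trajectories.
#'
#' @param S,E1,E2 Nonnegative compartment sizes (persons).
#' @param t Time in weeks (default 0).
#' @return An object of class `exersist_state`: a list with elements
#'   `t`, `S`, `E1`, `E2` and the derived total `N`.
#' @export
#' @examples
#' population_state(S = 500, E1 = 300, E2 = 200)
population_state <- function(S, E1, E2, t = 0) {
  comp <- c(S = S, E1 = E1, E2 = E2)
  if (any(!is.finite(comp)) || !is.finite(t)) {
    stop("state components must be finite", call. = FALSE)
  }
  if (any(comp < 0)) {
    stop("compartment sizes must be nonnegative; offending: ",
         paste(names(comp)[comp < 0], collapse = ", "), call. = FALSE)
  }
  N <- S + E1 + E2
  if (N <= 0) stop("total population N must be positive", call. = FALSE)
  structure(list(t = t, S = S, E1 = E1, E2 = E2, N = N),
            class = "exersist_state")
}

#' @export
print.exersist_state <- function(x, ...) {
  cat(sprintf("Population state at t = %g weeks: S = %g, E1 = %g, E2 = %g (N = %g)\n",
              x$t, x$S, x$E1, x$E2, x$N))
  invisible(x)
}

#' Construct a simulation scenario
#'
#' A scenario bundles a parameter set, an initial state at t = 0, and a time
#' horizon; it is the unit handed to the integrator.
#'
#' @param params An `exersist_params` object (or coercible via
#'   [as_model_params()]).
#' @param initial An `exersist_state` with `t = 0`.
#' @param horizon Positive simulation horizon in weeks.
#' @param label Free-text label for reports.
#' @return An object of class `exersist_scenario`.
#' @export
#' @examples
#' scn <- scenario(model_params(gamma1 = 0.01, delta1 = 0.02),
#'                 population_state(S = 900, E1 = 80, E2 = 20),
#'                 horizon = 200, label = "mostly spontaneous flows")
scenario <- function(params, initial, horizon, label = "") {
  params <- as_model_params(params)
  if (!inherits(initial, "exersist_state")) {
    stop("`initial` must be an exersist_state", call. = FALSE)
  }
  if (initial$t != 0) stop("initial state must be at t = 0", call. = FALSE)
  if (!is.finite(horizon) || horizon <= 0) {
    stop("horizon must be a positive number of weeks", call. = FALSE)
  }
  structure(list(params = params, initial = initial,
                 horizon = horizon, label = as.character(label)),
            class = "exersist_scenario")
}

#' @export
print.exersist_scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: horizon %g weeks, N = %g\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$horizon, x$initial$N))
  nz <- x$params[x$params != 0]
  if (length(nz)) {
    cat("  nonzero rates:",
        paste(sprintf("%s = %g", names(nz), nz), collapse = ", "), "\n")
  } else {
    cat("  all rates zero (frozen population)\n")
  }
  cat(sprintf("  initial fractions: S %.3f, E1 %.3f, E2 %.3f\n",
              x$initial$S / x$initial$N, x$initial$E1 / x$initial$N,
              x$initial$E2 / x$initial$N))
  invisible(x)
}

# Bare-metal RHS used inside the integrator: y is c(S, E1, E2), p the
# parameter vector. Kept term-for-term as the model equations are written;
# mass-action contacts are scaled by the current total N = S + E1 + E2.
rhs_raw <- function(p, y) {
  S <- y[[1L]]; E1 <- y[[2L]]; E2 <- y[[3L]]
  N <- S + E1 + E2
  se1 <- S * E1 / N
  se2 <- S * E2 / N
  dS <- p[["beta1"]] * se1 - p[["r1"]] * se1 - p[["r2"]] * se2 -
    p[["gamma1"]] * S + p[["beta2"]] * se2 - p[["k1"]] * se1 -
    p[["k2"]] * se2 - p[["gamma2"]] * S +
    p[["delta1"]] * E1 + p[["delta2"]] * E2
  dE1 <- p[["r1"]] * se1 + p[["r2"]] * se2 + p[["gamma1"]] * S -
    p[["beta1"]] * se1 - p[["alpha2"]] * E1 + p[["alpha1"]] * E2 -
    p[["delta1"]] * E1
  dE2 <- p[["k1"]] * se1 + p[["k2"]] * se2 + p[["gamma2"]] * S -
    p[["alpha1"]] * E2 + p[["alpha2"]] * E1 - p[["beta2"]] * se2 -
    p[["delta2"]] * E2
  c(dS, dE1, dE2)
}

#' Evaluate the right-hand side of the model equations
#'
#' Computes the instantaneous rates of change (dS/dt, dE1/dt, dE2/dt), in
#' persons per week, at a given state. Social-contact flows follow the law
#' of mass action scaled by the current total N = S + E1 + E2; spontaneous
#' flows and the E1/E2 exchange are linear. The three components sum to
#' zero: the population is closed, with no births, deaths or migration.
#'
#' @param params An `exersist_params` object.
#' @param state An `exersist_state` object.
#' @return Named numeric vector `c(dS, dE1, dE2)` in persons week^-1.
#' @export
#' @examples
#' p <- model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'                   alpha1 = 0.005, alpha2 = 0.005)
#' rhs(p, population_state(S = 50, E1 = 30, E2 = 20))
rhs <- function(params, state) {
  params <- as_model_params(params)
  if (!inherits(state, "exersist_state")) {
    stop("`state` must be an exersist_state", call. = FALSE)
  }
  comp <- c(state$S, state$E1, state$E2)
  if (any(!is.finite(comp))) stop("state components must be finite", call. = FALSE)
  if (any(comp < 0)) stop("state components must be nonnegative", call. = FALSE)
  if (sum(comp) <= 0) stop("degenerate population: N must be positive", call. = FALSE)
  stats::setNames(rhs_raw(params, comp), c("dS", "dE1", "dE2"))
}

#' Test whether a state is an equilibrium of the model
#'
#' @param params An `exersist_params` object.
#' @param state An `exersist_state` object.
#' @param tol Nonnegative tolerance on the rate magnitude (persons week^-1).
#' @return `TRUE` iff every component of [rhs()] has magnitude at most `tol`.
#' @export
#' @examples
#' p <- model_params(beta1 = 0.01, delta1 = 0.02)
#' is_equilibrium(p, population_state(S = 1000, E1 = 0, E2 = 0))
is_equilibrium <- function(params, state, tol = 1e-10) {
  if (!is.finite(tol) || tol < 0) stop("tol must be nonnegative", call. = FALSE)
  max(abs(rhs(params, state))) <= tol
}
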