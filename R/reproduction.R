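# Basic reproduction number: closed form, special-case reductions, and the
# numerical next-generation-matrix route used to cross-check the closed form.

r0_result <- function(value, method, extra = list()) {
  stopifnot(is.finite(value), value >= 0)
  out <- c(list(value = value, method = method,
                classification = classify_persistence(value)),
           extra)
  structure(out, class = "exersist_r0")
}

#' @export
print.exersist_r0 <- function(x, ...) {
  cat(sprintf("R0 = %.6g (%s): %s\n", x$value, x$method, x$classification))
  if (!is.null(x$coefficients)) {
    cat(sprintf("  quadratic coefficients: A = %.6g, B = %.6g, C = %.6g\n",
                x$coefficients$A, x$coefficients$B, x$coefficients$C))
  }
  invisible(x)
}

#' Quadratic coefficients of the R0 characteristic equation
#'
#' The basic reproduction number solves A x^2 - B x + C = 0, where A, B, C
#' are the following combinations of the rate constants, the initial
#' sedentary count S0 and the total population N:
#'
#' \deqn{A = N^2(\alpha_1\delta_1 + \delta_2(\alpha_2+\delta_1))
#'        + N S_0(\beta_1(\alpha_1+\delta_2) + \beta_2(\alpha_2+\delta_1))
#'        + S_0^2 \beta_1\beta_2}
#' \deqn{B = S_0[N(\alpha_1 k_1 + \delta_1 k_2)
#'        + N(\alpha_2(k_2+r_2) + r_1(\alpha_1+\delta_2))
#'        + S_0(\beta_1 k_2 + \beta_2 r_1)]}
#' \deqn{C = (r_1 k_2 - r_2 k_1) S_0^2}
#'
#' The spontaneous-uptake rates `gamma1`, `gamma2` do not enter any
#' coefficient. A is nonnegative for nonnegative rates.
#'
#' @param params An `exersist_params` object.
#' @param S0 Initial sedentary count (persons), `0 <= S0 <= N`.
#' @param N Total population (persons), positive.
#' @return A list with numeric elements `A`, `B`, `C`.
#' @export
#' @examples
#' p <- model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'                   alpha1 = 0.005, alpha2 = 0.005)
#' r0_coefficients(p, S0 = 1000, N = 1000)
r0_coefficients <- function(params, S0, N) {
  params <- as_model_params(params)
  if (!is.finite(N) || N <= 0) {
    stop("degenerate population: N must be positive", call. = FALSE)
  }
  if (!is.finite(S0) || S0 < 0 || S0 > N) {
    stop("S0 must satisfy 0 <= S0 <= N", call. = FALSE)
  }
  p <- as.list(params)
  A <- N^2 * (p$alpha1 * p$delta1 + p$delta2 * (p$alpha2 + p$delta1)) +
    N * S0 * (p$beta1 * (p$alpha1 + p$delta2) +
                p$beta2 * (p$alpha2 + p$delta1)) +
    S0^2 * p$beta1 * p$beta2
  B <- S0 * (N * (p$alpha1 * p$k1 + p$delta1 * p$k2) +
               N * (p$alpha2 * (p$k2 + p$r2) + p$r1 * (p$alpha1 + p$delta2)) +
               S0 * (p$beta1 * p$k2 + p$beta2 * p$r1))
  C <- (p$r1 * p$k2 - p$r2 * p$k1) * S0^2
  list(A = A, B = B, C = C)
}

#' Basic reproduction number from the general closed form
#'
#' Evaluates \eqn{R_0 = (B + \sqrt{B^2 - 4AC}) / (2A)}, the larger root of
#' the quadratic with coefficients given by [r0_coefficients()]. The
#' degenerate case A = 0 (all recidivism and exchange rates zero) is an
#' error: the formula is undefined there and one of the special-case
#' routes should be used instead. A discriminant within `1e-12 * max(1, B^2)`
#' of zero is clamped to zero to absorb floating-point noise; a genuinely
#' negative discriminant is an error reporting the offending coefficients.
#'
#' @inheritParams r0_coefficients
#' @return An `exersist_r0` object with elements `value`, `method`
#'   (`"closed_form"`), `classification`, and `coefficients`.
#' @export
#' @examples
#' p <- model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'                   alpha1 = 0.005, alpha2 = 0.005)
#' r0_closed_form(p, S0 = 1000, N = 1000)  # (k1 + r1) / beta1 here
r0_closed_form <- function(params, S0, N) {
  co <- r0_coefficients(params, S0, N)
  if (co$A == 0) {
    stop("degenerate formula: A = 0 (no recidivism or exchange flows); ",
         "use r0_case2() or r0_case3() for the reduced model",
         call. = FALSE)
  }
  disc <- co$B^2 - 4 * co$A * co$C
  if (disc < 0 && abs(disc) <= 1e-12 * max(1, co$B^2)) disc <- 0
  if (disc < 0) {
    stop(sprintf(paste0("negative discriminant B^2 - 4AC = %.6g ",
                        "(A = %.6g, B = %.6g, C = %.6g)"),
                 disc, co$A, co$B, co$C), call. = FALSE)
  }
  value <- (co$B + sqrt(disc)) / (2 * co$A)
  r0_result(value, "closed_form", list(coefficients = co))
}

check_case_zeroing <- function(params, zeroed, case) {
  nz <- zeroed[params[zeroed] != 0]
  if (length(nz)) {
    stop(sprintf("%s requires %s = 0; nonzero: %s",
                 case, paste(zeroed, collapse = ", "),
                 paste(sprintf("%s = %g", nz, params[nz]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reduced-contact R0: no sedentary/extremely-active interaction, no return flows
#'
#' Under the reduction `r2 = k2 = beta2 = gamma1 = gamma2 = delta1 = delta2 = 0`
#' (sedentary and extremely active individuals never interact, and all
#' spontaneous flows are switched off), the reproduction number collapses to
#' \deqn{R_0 = (k_1 + r_1) / \beta_1,}
#' so activity persists exactly when the social draw into exercise,
#' `k1 + r1`, exceeds the social recidivism rate `beta1`.
#'
#' @param params An `exersist_params` object satisfying the zeroing exactly.
#' @return An `exersist_r0` object with `method = "case2"`.
#' @export
#' @examples
#' r0_case2(model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'                       alpha1 = 0.005, alpha2 = 0.005))
r0_case2 <- function(params) {
  params <- as_model_params(params)
  check_case_zeroing(params,
                     c("r2", "k2", "beta2", "gamma1", "gamma2",
                       "delta1", "delta2"),
                     "case 2 reduction")
  if (params[["beta1"]] == 0) {
    stop("case 2 reduction requires beta1 > 0 (R0 = (k1 + r1)/beta1)",
         call. = FALSE)
  }
  value <- (params[["k1"]] + params[["r1"]]) / params[["beta1"]]
  r0_result(value, "case2")
}

#' Reduced-contact R0 with spontaneous recidivism of the moderately active
#'
#' Under the reduction `r2 = k2 = beta2 = gamma1 = gamma2 = delta2 = 0`
#' (as the two-compartment-contact case, but moderately active individuals
#' may also drop out spontaneously at rate `delta1`), with `p = S0/N` the
#' sedentary fraction,
#' \deqn{R_0 = (k_1 + r_1)\,p / (\beta_1 p + \delta_1).}
#' Persistence holds when \eqn{(k_1+r_1)p > \beta_1 p + \delta_1}; the
#' boolean is returned alongside the value (element `condition_met`) and is
#' equivalent to `value > 1`.
#'
#' @inheritParams r0_coefficients
#' @return An `exersist_r0` object with `method = "case3"` and the extra
#'   element `condition_met`.
#' @export
#' @examples
#' p <- model_params(k1 = 0.02, r1 = 0.03, beta1 = 0.01, delta1 = 0.005)
#' r0_case3(p, S0 = 800, N = 1000)
r0_case3 <- function(params, S0, N) {
  params <- as_model_params(params)
  check_case_zeroing(params,
                     c("r2", "k2", "beta2", "gamma1", "gamma2", "delta2"),
                     "case 3 reduction")
  if (!is.finite(N) || N <= 0) {
    stop("degenerate population: N must be positive", call. = FALSE)
  }
  if (!is.finite(S0) || S0 < 0 || S0 > N) {
    stop("S0 must satisfy 0 <= S0 <= N", call. = FALSE)
  }
  p <- S0 / N
  denom <- params[["beta1"]] * p + params[["delta1"]]
  if (denom == 0) {
    stop("case 3 reduction requires beta1 * (S0/N) + delta1 > 0", call. = FALSE)
  }
  value <- (params[["k1"]] + params[["r1"]]) * p / denom
  r0_result(value, "case3",
            list(condition_met =
                   (params[["k1"]] + params[["r1"]]) * p >
                   params[["beta1"]] * p + params[["delta1"]]))
}

#' Basic reproduction number by the next-generation matrix
#'
#' Computes R0 numerically as the spectral radius of \eqn{F V^{-1}}, with
#' the linearization taken at the all-sedentary equilibrium. New active
#' individuals are created from the sedentary pool by the contact terms
#' (`r1`, `r2`, `k1`, `k2`), which populate the 2x2 gain matrix F;
#' recidivism (`beta1`, `beta2`, `delta1`, `delta2`) and the inter-exerciser
#' exchange (`alpha1`, `alpha2`) are transitions and populate V. With
#' `p = S0/N`,
#' \deqn{F = p \begin{pmatrix} r_1 & r_2 \\ k_1 & k_2 \end{pmatrix}, \quad
#'       V = \begin{pmatrix} \beta_1 p + \alpha_2 + \delta_1 & -\alpha_1 \\
#'                           -\alpha_2 & \beta_2 p + \alpha_1 + \delta_2
#'           \end{pmatrix}.}
#'
#' The all-sedentary state is an equilibrium only without spontaneous
#' uptake, so `gamma1 = gamma2 = 0` is required. This route is an
#' independent numerical check of [r0_closed_form()]: the two agree to
#' floating-point accuracy whenever A > 0.
#'
#' @inheritParams r0_coefficients
#' @return An `exersist_r0` object with `method = "ngm"` and matrices `F`
#'   and `V` attached.
#' @export
#' @examples
#' p <- model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
#'                   alpha1 = 0.005, alpha2 = 0.005)
#' r0_ngm(p, S0 = 1000, N = 1000)
r0_ngm <- function(params, S0, N) {
  params <- as_model_params(params)
  if (params[["gamma1"]] != 0 || params[["gamma2"]] != 0) {
    stop("the all-sedentary state is not an equilibrium when gamma1 or ",
         "gamma2 > 0; the next-generation matrix is not defined there",
         call. = FALSE)
  }
  if (!is.finite(N) || N <= 0) {
    stop("degenerate population: N must be positive", call. = FALSE)
  }
  if (!is.finite(S0) || S0 < 0 || S0 > N) {
    stop("S0 must satisfy 0 <= S0 <= N", call. = FALSE)
  }
  pr <- S0 / N
  p <- as.list(params)
  Fm <- matrix(c(p$r1 * pr, p$r2 * pr,
                 p$k1 * pr, p$k2 * pr), nrow = 2, byrow = TRUE)
  Vm <- matrix(c(p$beta1 * pr + p$alpha2 + p$delta1, -p$alpha1,
                 -p$alpha2, p$beta2 * pr + p$alpha1 + p$delta2),
               nrow = 2, byrow = TRUE)
  dV <- det(Vm)
  if (!is.finite(dV) || abs(dV) < .Machine$double.xmin) {
    stop("transition matrix V is singular: no recidivism/exchange flows ",
         "remove active individuals", call. = FALSE)
  }
  K <- Fm %*% solve(Vm)
  value <- max(Mod(eigen(K, only.values = TRUE)$values))
  r0_result(value, "ngm", list(F = Fm, V = Vm))
}

#' Classify a reproduction number against the persistence threshold
#'
#' Below 1 the physically active compartments decay to zero; above 1 they
#' plateau at a nonzero level ("physical activity persists"). Values within
#' `eps` of 1 are reported as `"threshold"` rather than forced onto either
#' side.
#'
#' @param r0_value Finite nonnegative reproduction number.
#' @param eps Absolute half-width of the threshold band (default 1e-9).
#' @return One of `"extinction"`, `"persistence"`, `"threshold"`.
#' @export
#' @examples
#' classify_persistence(7.7)   # persistence
#' classify_persistence(0.49)  # extinction
classify_persistence <- function(r0_value, eps = 1e-9) {
  if (!is.numeric(r0_value) || length(r0_value) != 1L ||
      !is.finite(r0_value) || r0_value < 0) {
    stop("r0_value must be a single finite nonnegative number", call. = FALSE)
  }
  if (r0_value < 1 - eps) "extinction"
  else if (r0_value > 1 + eps) "persistence"
  else "threshold"
}
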