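# Random draw helpers shared across test files.

# Random nonnegative parameter set; selected rates can be pinned to zero.
rand_params <- function(lo = 0.001, hi = 0.05, zero = character()) {
  v <- stats::runif(12, lo, hi)
  names(v) <- rate_names()
  v[zero] <- 0
  as_model_params(v)
}

# Random interior state with total N.
rand_state <- function(N = 1000) {
  f <- stats::runif(3, 0.05, 1)
  f <- f / sum(f)
  population_state(S = f[1] * N, E1 = f[2] * N, E2 = f[3] * N)
}

# Relative difference, guarded for near-zero reference values.
rel_diff <- function(x, ref) abs(x - ref) / max(abs(ref), 1e-300)

# Swap the roles of the two active compartments: relabelling E1 <-> E2
# maps r1 <-> k2, r2 <-> k1, gamma1 <-> gamma2, beta1 <-> beta2,
# delta1 <-> delta2, alpha1 <-> alpha2 and exchanges the initial E1/E2.
swap_active_roles <- function(scn) {
  p <- unclass(scn$params)
  q <- p
  q["r1"] <- p["k2"]; q["k2"] <- p["r1"]
  q["r2"] <- p["k1"]; q["k1"] <- p["r2"]
  q["gamma1"] <- p["gamma2"]; q["gamma2"] <- p["gamma1"]
  q["beta1"] <- p["beta2"]; q["beta2"] <- p["beta1"]
  q["delta1"] <- p["delta2"]; q["delta2"] <- p["delta1"]
  q["alpha1"] <- p["alpha2"]; q["alpha2"] <- p["alpha1"]
  scenario(as_model_params(q),
           population_state(S = scn$initial$S, E1 = scn$initial$E2,
                            E2 = scn$initial$E1),
           scn$horizon, scn$label)
}
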