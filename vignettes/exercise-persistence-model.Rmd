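---
title: "A compartmental model of social influence on exercise persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of social influence on exercise persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exersist)
```

## The model

A closed population of $N$ people is split by weekly exercise volume into
sedentary ($S$, under 150 min/week), moderately active ($E_1$, 150–300
min/week) and extremely active ($E_2$, over 300 min/week) compartments.
Physical activity is treated as socially transmissible, in the spirit of
Kermack–McKendrick epidemic models: contact between a sedentary person and
an active one can recruit the sedentary person into activity, and contact
with sedentary peers can pull an active person back. Social flows follow
the law of mass action scaled by the total (for example $r_1 S E_1 / N$);
spontaneous flows — a physician's advice, an injury — are linear.

$$
\begin{aligned}
S' &= \beta_1 \tfrac{E_1 S}{N} + \beta_2 \tfrac{S E_2}{N}
   + \delta_1 E_1 + \delta_2 E_2
   - (r_1 + k_1)\tfrac{S E_1}{N} - (r_2 + k_2)\tfrac{S E_2}{N}
   - (\gamma_1 + \gamma_2) S \\
E_1' &= r_1 \tfrac{S E_1}{N} + r_2 \tfrac{S E_2}{N} + \gamma_1 S
   - \beta_1 \tfrac{E_1 S}{N} - \delta_1 E_1 - \alpha_2 E_1 + \alpha_1 E_2 \\
E_2' &= k_1 \tfrac{S E_1}{N} + k_2 \tfrac{S E_2}{N} + \gamma_2 S
   - \beta_2 \tfrac{E_2 S}{N} - \delta_2 E_2 + \alpha_2 E_1 - \alpha_1 E_2
\end{aligned}
$$

All twelve rate constants are nonnegative and carry units of week$^{-1}$:
$r_{1,2}$ and $k_{1,2}$ are social recruitment into $E_1$ and $E_2$ by
contact with $E_1$ (subscript 1) or $E_2$ (subscript 2); $\gamma_{1,2}$
are spontaneous uptake; $\beta_{1,2}$ social recidivism of $E_1$, $E_2$
by contact with $S$; $\delta_{1,2}$ spontaneous recidivism; and
$\alpha_1$ ($E_2 \to E_1$), $\alpha_2$ ($E_1 \to E_2$) exchange members
between the two active classes.

Three structural facts the implementation leans on:

* **Closure.** Every flow appears once with each sign, so
  $S' + E_1' + E_2' = 0$ and the total is conserved. `rhs()` recomputes
  $N = S + E_1 + E_2$ at every evaluation rather than freezing it at its
  initial value; the two coincide along exact solutions, and recomputing
  makes conservation a checkable property of the integrator rather than an
  assumption.
* **Forward invariance.** At $S = 0$ every remaining term in $S'$ is an
  inflow (and likewise for $E_1$, $E_2$), so the nonnegative orthant is
  invariant and negative compartment values can only arise as integrator
  noise.
* **Linear exchange.** The $\alpha_1 E_2$ and $\alpha_2 E_1$ terms are
  implemented linearly, exactly as the equations are written, even though
  one could argue the exchange between active classes is itself a contact
  process that would warrant a mass-action $E_1 E_2 / N$ product. The
  displayed equations are taken as authoritative; with a mass-action
  exchange none of the closed-form reproduction-number algebra below would
  hold.
* **Continuum states.** Compartments are real-valued; no integer rounding
  is applied. The model is a deterministic mean-field description, not an
  agent simulation.

## The reproduction number and its two routes

The threshold behaviour of the active compartments near the all-sedentary
state is governed by a basic reproduction number: for $R_0 < 1$ the active
compartments decay to zero, for $R_0 > 1$ they plateau at a nonzero level.
`r0_closed_form()` evaluates the closed-form expression

$$ R_0 = \frac{B + \sqrt{B^2 - 4AC}}{2A}, $$

the larger root of $A x^2 - B x + C = 0$ with

$$
\begin{aligned}
A &= N^2(\alpha_1\delta_1 + \delta_2(\alpha_2+\delta_1))
  + N S_0(\beta_1(\alpha_1+\delta_2) + \beta_2(\alpha_2+\delta_1))
  + S_0^2\,\beta_1\beta_2,\\
B &= S_0\left[N(\alpha_1 k_1 + \delta_1 k_2)
  + N(\alpha_2(k_2+r_2) + r_1(\alpha_1+\delta_2))
  + S_0(\beta_1 k_2 + \beta_2 r_1)\right],\\
C &= (r_1 k_2 - r_2 k_1)\,S_0^2 .
\end{aligned}
$$

Rather than trusting a transcription of these coefficients, the package
carries a second, independent route. `r0_ngm()` builds the 2×2
next-generation matrices at the all-sedentary equilibrium with
$p = S_0/N$:

$$
F = p\begin{pmatrix} r_1 & r_2 \\ k_1 & k_2 \end{pmatrix},
\qquad
V = \begin{pmatrix} \beta_1 p + \alpha_2 + \delta_1 & -\alpha_1 \\
                    -\alpha_2 & \beta_2 p + \alpha_1 + \delta_2
\end{pmatrix},
$$

and returns the spectral radius of $F V^{-1}$. The split assigns the
contact-driven creation of active individuals from the sedentary pool
($r$, $k$ terms) to $F$, and recidivism ($\beta$, $\delta$) plus the
inter-exerciser exchange ($\alpha$) to $V$; this is the natural
"new infections vs. transitions" split, and expanding the characteristic
polynomial of $F V^{-1}$ by hand reproduces $A$, $B$, $C$ exactly
(multiply through by $N^2$). The test suite asserts agreement of the two
routes to $10^{-8}$ relative over a thousand random draws; since the NGM
route never touches the coefficient expressions, a typo in either side
would be caught.

Two restrictions are deliberate:

* `r0_ngm()` refuses $\gamma_1, \gamma_2 > 0$: with spontaneous uptake the
  all-sedentary state is not an equilibrium and the linearization point
  does not exist. The closed form, whose coefficients never contain
  $\gamma$, remains callable for any parameters. A related caveat: in the
  transmission-free regime below, $R_0 = 0$ reflects the NGM's
  transmission-only accounting; if $\gamma > 0$ the active compartments
  are nonetheless sustained by spontaneous uptake. The simulation-based
  threshold-consistency tests are therefore restricted to
  $\gamma_1 = \gamma_2 = 0$.
* $A = 0$ (all of $\beta_{1,2}$, $\delta_{1,2}$, $\alpha_1\delta_1$-type
  products vanishing) is an error, not a limit: the quadratic degenerates
  and the formula is undefined. The error message directs users to the
  special-case formulas, which is also how the analysis proceeds on paper.

Floating-point choices: the discriminant $B^2 - 4AC$ is clamped to zero
when within $10^{-12}\max(1, B^2)$ of it — for the reduced cases $C = 0$
exactly and the clamp is never exercised, but generic draws can land a
rounding error below zero. A genuinely negative discriminant raises, with
the coefficients in the message. `classify_persistence()` reports values
within $10^{-9}$ of 1 as `"threshold"` rather than forcing the boundary
onto either side.

## The three tractable regimes

Solving $R_0 > 1$ for general parameters is intractable, so three reduced
regimes delineate persistence from extinction analytically; each is
exposed as its own function with the zeroing enforced exactly (a nonzero
rate in the zeroed list is an error naming the offender, not a silent
approximation).

1. **No social transmission** ($r_1 = r_2 = k_1 = k_2 = 0$): $B = C = 0$,
   so $R_0 = 0$ — without peer influence the exercising population cannot
   sustain itself and the population ends up sedentary.
2. **No sedentary/extremely-active contact, no spontaneous flows**
   ($r_2 = k_2 = \beta_2 = \gamma_1 = \gamma_2 = \delta_1 = \delta_2 = 0$):
   $R_0 = (k_1 + r_1)/\beta_1$ (`r0_case2()`). Persistence is a
   tug-of-war between the social draw into exercise and social
   recidivism.
3. **As 2, but moderately active people may drop out spontaneously**
   ($\delta_1$ free): with $p = S_0/N$,
   $R_0 = (k_1+r_1)p \,/\, (\beta_1 p + \delta_1)$ (`r0_case3()`), and
   persistence requires $(k_1+r_1)p > \beta_1 p + \delta_1$. The function
   returns the inequality alongside the value; the two are equivalent and
   tested to agree on random draws.

Both reductions are also verified against the general closed form (the
zeroings force $C = 0$, so the larger root collapses to $B/A$) to
$10^{-10}$ relative.

## Simulation, plateaus, extinction

`integrate_scenario()` wraps `deSolve::lsoda`: adaptive step with
automatic stiff/non-stiff switching, which comfortably covers the
slow-fast structure that appears when social rates differ by an order of
magnitude. Defaults `rel_tol = 1e-8`, `abs_tol = 1e-10` were chosen so
that halving the relative tolerance moves final fractions by less than
$10^{-5}$ (asserted in the tests); any integrator meeting that refinement
stability would do. Output is sampled at `n_out` evenly spaced times.
Post-conditions are enforced, not assumed: the total must stay within
$10^{-6} N$ of its initial value, and compartments must stay above
$-10^{-6} N$; excursions below zero within that noise band are clamped to
zero in the returned trajectory.

"Plateau" and "extinct" are operationalized by `detect_plateau()`: a
trajectory has settled when every right-hand-side component stays below
`rate_eps * N` (default $10^{-8}$ week$^{-1}$) over the trailing
`window_frac` (default 0.2) of the horizon, and a compartment is extinct
when its final fraction is below `extinct_eps` (default $10^{-3}$). These
thresholds separate the exponential tails of the threshold scenarios from
genuine plateaus at double precision; they are reporting conventions, not
model content. Preset horizons start at 500 weeks and double as needed up
to 8000 — the published simulations do not state a numeric horizon, so the
qualitative outcome (which compartments vanish) is the reproducible
surface, not plateau timestamps.

The two published threshold scenarios ship as presets with their printed
rates ($k_1 = 0.002$, $r_1 = 0.015$, $\alpha_1 = \alpha_2 = 0.005$, and
$\beta_1 = 0.0022$ vs. $0.035$; initial fractions 50/30/20%):

```{r presets, eval = FALSE}
run_preset("fig3a")$report  # R0 = 7.73: sedentary behaviour goes extinct
run_preset("fig3b")$report  # R0 = 0.49: the exercisers go extinct
```

Population size defaults to $N = 1000$; every contact term is scaled by
$N$, so the dynamics of the fractions are independent of $N$ and the
choice is cosmetic.

## One-at-a-time sensitivity

`oat_sweep()` implements the published protocol: all twelve rates fixed at
0.001 week$^{-1}$, initial fractions $1/3$ each, one rate (or a named
group in lockstep) varied, and the long-run sedentary fraction recorded.
The protocol's source states neither the variation magnitudes behind its
quoted plateau-change percentages nor the grid, so those percentages are
treated as directional claims only; the default grid
$\{1, 2, 5, 10\} \times$ baseline is chosen to make directions
unambiguous. The directional findings are reproduced and asserted:
raising any uptake rate ($r$, $k$, $\gamma$) lowers the sedentary plateau,
raising any recidivism rate ($\beta$, $\delta$) raises it, and the
exchange rates $\alpha_{1,2}$ leave it exactly flat. The flatness is
structural at this baseline: with each parameter pair equal, the sedentary
equation depends on the active classes only through $E_1 + E_2$, whose
dynamics do not involve $\alpha$. A grid point whose trajectory has not
settled by the maximum horizon is recorded as `NA` with a warning rather
than failing the sweep.

A relabelling symmetry doubles as a correctness check: swapping the roles
of $E_1$ and $E_2$ together with their parameter pairs
($r_1 \leftrightarrow k_2$, $r_2 \leftrightarrow k_1$,
$\beta_1 \leftrightarrow \beta_2$, $\delta_1 \leftrightarrow \delta_2$,
$\gamma_1 \leftrightarrow \gamma_2$, $\alpha_1 \leftrightarrow \alpha_2$)
leaves the sedentary trajectory invariant.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen to exercise the properties
rather than to stress hardware: a thousand random parameter draws for the
closed-form/NGM equivalence, two hundred reduced-case draws per reduction,
two hundred threshold-consistency simulations at a 4000-week horizon
seeded with 2% active individuals, and the full 12-rate sweep grid. Random
draws use rates in roughly the 0.001–0.1 week$^{-1}$ band, the order of
magnitude of the published scenarios.

## Limitations

The model is deterministic and mean-field: no finite-population
stochasticity, no network structure (everyone contacts everyone in
proportion to compartment sizes), no demography (births, deaths,
migration), and no age or fitness heterogeneity within compartments. The
parameters are not estimated from data here — social-influence rates are
notoriously hard to measure — so the package's claims are structural:
thresholds, directions of response, and the algebraic identities among the
$R_0$ routes. Passing tests show the implementation honours the model's
mathematics under the stated regimes; they say nothing about how well the
model describes any real population.
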