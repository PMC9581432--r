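test_that("frozen dynamics stay put and are reported as settled", {
  scn <- scenario(model_params(), population_state(S = 400, E1 = 350, E2 = 250),
                  horizon = 100, label = "frozen")
  traj <- integrate_scenario(scn, n_out = 11)
  expect_equal(nrow(traj), 11)
  expect_true(all(abs(traj$S - 400) < 1e-9))
  expect_true(all(abs(traj$E1 - 350) < 1e-9))
  expect_true(all(abs(traj$E2 - 250) < 1e-9))

  rep <- detect_plateau(traj)
  expect_true(rep$settled)
  expect_identical(rep$extinct, character(0))
  expect_equal(unname(sum(rep$final_fractions)), 1, tolerance = 1e-12)

  # a compartment starting below the extinction threshold stays extinct
  scn2 <- scenario(model_params(),
                   population_state(S = 999.5, E1 = 0.4, E2 = 0.1),
                   horizon = 50)
  rep2 <- detect_plateau(integrate_scenario(scn2, n_out = 5))
  expect_setequal(rep2$extinct, c("E1", "E2"))
})

test_that("trajectories conserve the total and stay nonnegative", {
  set.seed(31)
  scns <- c(lapply(c("fig3a", "fig3b", "sensitivity_baseline"),
                   preset_scenario),
            lapply(1:10, function(i)
              scenario(rand_params(lo = 0, hi = 0.1), rand_state(),
                       horizon = 300)))
  for (scn in scns) {
    traj <- integrate_scenario(scn, n_out = 201)
    N0 <- scn$initial$N
    expect_lt(max(abs(traj$S + traj$E1 + traj$E2 - N0)), 1e-6 * N0)
    expect_true(all(traj$S >= 0 & traj$E1 >= 0 & traj$E2 >= 0))
  }
})

test_that("the persistence preset drives sedentary behaviour extinct", {
  res <- run_preset("fig3a")
  expect_true(res$report$settled)
  expect_identical(res$report$extinct, "S")
  expect_gt(res$report$final_fractions[["E1"]], 0.01)
  expect_gt(res$report$final_fractions[["E2"]], 0.01)
  expect_identical(r0_case2(res$scenario$params)$classification, "persistence")
  # sedentary fraction decays monotonically after the initial transient
  late <- res$trajectory$S[res$trajectory$t > 100]
  expect_true(all(diff(late) <= 1e-9))
})

test_that("the high-recidivism preset drives the exercisers extinct", {
  res <- run_preset("fig3b")
  expect_true(res$report$settled)
  expect_setequal(res$report$extinct, c("E1", "E2"))
  expect_gt(res$report$final_fractions[["S"]], 0.99)
  expect_identical(r0_case2(res$scenario$params)$classification, "extinction")
})

test_that("the sensitivity baseline preset is as published", {
  scn <- preset_scenario("sensitivity_baseline")
  expect_equal(unname(unclass(scn$params)), rep(0.001, 12))
  expect_equal(scn$initial$S / scn$initial$N, 1 / 3, tolerance = 1e-12)
  expect_equal(scn$initial$E1 / scn$initial$N, 1 / 3, tolerance = 1e-12)
  expect_error(preset_scenario("fig3c"), "arg")
})

test_that("refining the solver tolerance leaves final fractions unchanged", {
  scn <- preset_scenario("fig3a", horizon = 1000)
  coarse <- integrate_scenario(scn, rel_tol = 1e-8, n_out = 51)
  fine <- integrate_scenario(scn, rel_tol = 5e-9, n_out = 51)
  last <- nrow(coarse)
  for (comp in c("S", "E1", "E2")) {
    expect_lt(abs(coarse[[comp]][last] - fine[[comp]][last]) /
                scn$initial$N, 1e-5)
  }
})

test_that("plateau detection validates its inputs", {
  scn <- preset_scenario("fig3a")
  traj <- integrate_scenario(scn, n_out = 21)
  expect_error(detect_plateau(traj, window_frac = 0), "window_frac")
  expect_error(detect_plateau(traj, window_frac = 1), "window_frac")
  expect_error(detect_plateau(data.frame()), "trajectory")
  expect_error(integrate_scenario(scn, rel_tol = -1), "tolerance")
})
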