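test_that("quadratic coefficients match their printed combinations", {
  # Transmission-free: every addend of B and C carries an r or k factor.
  set.seed(21)
  p <- rand_params(zero = c("r1", "r2", "k1", "k2"))
  co <- r0_coefficients(p, S0 = 700, N = 1000)
  expect_identical(co$B, 0)
  expect_identical(co$C, 0)
  expect_gt(co$A, 0)

  # Reduced model with only delta1 kept among the return/spontaneous flows:
  # symbolic substitution gives A = N*a1*(N*d1 + S0*b1),
  # B = S0*N*a1*(k1 + r1), C = 0.
  q <- rand_params(zero = c("r2", "k2", "beta2", "delta2"))
  S0 <- 600; N <- 1000
  co <- r0_coefficients(q, S0, N)
  a1 <- q[["alpha1"]]; d1 <- q[["delta1"]]; b1 <- q[["beta1"]]
  expect_equal(co$A, N * a1 * (N * d1 + S0 * b1), tolerance = 1e-14)
  expect_equal(co$B, S0 * N * a1 * (q[["k1"]] + q[["r1"]]), tolerance = 1e-14)
  expect_identical(co$C, 0)

  # C = (r1*k2 - r2*k1) * S0^2 directly
  r <- rand_params()
  r <- as_model_params(`[<-`(unclass(r), c("r1", "k2", "r2", "k1"),
                             c(1, 1, 0, 0)))
  expect_equal(r0_coefficients(r, S0 = 2, N = 10)$C, 4)

  expect_error(r0_coefficients(rand_params(), S0 = 5, N = 0), "N")
  expect_error(r0_coefficients(rand_params(), S0 = 20, N = 10), "S0")
})

test_that("spontaneous-uptake rates never enter the coefficients", {
  set.seed(22)
  base <- unclass(rand_params())
  perturbed <- base
  perturbed[c("gamma1", "gamma2")] <- base[c("gamma1", "gamma2")] + 5
  expect_identical(r0_coefficients(as_model_params(base), 400, 1000),
                   r0_coefficients(as_model_params(perturbed), 400, 1000))
})

test_that("closed form returns the larger quadratic root and guards A = 0", {
  # transmission-free reduction: R0 is exactly zero
  set.seed(23)
  p <- rand_params(zero = c("r1", "r2", "k1", "k2"))
  res <- r0_closed_form(p, S0 = 1000, N = 1000)
  expect_identical(res$value, 0)
  expect_identical(res$classification, "extinction")

  # persistence/extinction parameterisations reduce to (k1 + r1)/beta1
  pa <- model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022,
                     alpha1 = 0.005, alpha2 = 0.005)
  expect_equal(r0_closed_form(pa, 1000, 1000)$value, 0.017 / 0.0022,
               tolerance = 1e-12)
  pb <- model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.035,
                     alpha1 = 0.005, alpha2 = 0.005)
  expect_equal(r0_closed_form(pb, 1000, 1000)$value, 0.017 / 0.035,
               tolerance = 1e-12)

  expect_error(r0_closed_form(model_params(r1 = 0.1), 1000, 1000),
               "A = 0")
})

test_that("case 2 reduction computes (k1 + r1)/beta1 and enforces zeroing", {
  a <- r0_case2(model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.0022))
  expect_gt(a$value, 1)
  expect_identical(a$classification, "persistence")
  b <- r0_case2(model_params(k1 = 0.002, r1 = 0.015, beta1 = 0.035))
  expect_lt(b$value, 1)
  expect_identical(b$classification, "extinction")
  c0 <- stats::runif(1, 0.01, 1)
  expect_equal(r0_case2(model_params(k1 = c0, r1 = c0, beta1 = c0))$value, 2)
  expect_error(r0_case2(model_params(k1 = 1, beta1 = 1, delta1 = 0.1)),
               "delta1")
  expect_error(r0_case2(model_params(k1 = 1)), "beta1")
})

test_that("case 3 reduction matches its printed form and the general root", {
  # delta1 = 0, S0 = N collapses onto case 2
  p <- model_params(k1 = 0.02, r1 = 0.03, beta1 = 0.01, alpha1 = 0.004)
  expect_equal(r0_case3(p, 1000, 1000)$value, r0_case2(p)$value,
               tolerance = 1e-14)

  # equality case of the persistence inequality: value exactly 1
  # choose p = 0.5, k1 + r1 = 0.03, beta1*0.5 + delta1 = 0.015
  q <- model_params(k1 = 0.01, r1 = 0.02, beta1 = 0.02, delta1 = 0.005)
  res <- r0_case3(q, S0 = 500, N = 1000)
  expect_equal(res$value, 1, tolerance = 1e-14)
  expect_identical(res$classification, "threshold")
  expect_false(res$condition_met)

  # random reduced draws agree with the general closed form (C = 0 there,
  # so the larger root is B/A) and the inequality tracks value > 1
  set.seed(24)
  for (i in 1:100) {
    pr <- rand_params(lo = 0.001, hi = 0.1,
                      zero = c("r2", "k2", "beta2", "gamma1", "gamma2",
                               "delta2"))
    N <- 1000
    S0 <- stats::runif(1, 50, N)
    got <- r0_case3(pr, S0, N)
    ref <- r0_closed_form(pr, S0, N)
    expect_lt(rel_diff(got$value, ref$value), 1e-10)
    expect_identical(got$condition_met, got$value > 1)
  }

  expect_error(r0_case3(model_params(k1 = 1, r2 = 0.1), 500, 1000), "r2")
  expect_error(r0_case3(model_params(k1 = 1), 500, 1000), "delta1")
})

test_that("next-generation matrix agrees with the closed form", {
  # reduced-contact sets: spectral radius equals (k1 + r1)/beta1
  set.seed(25)
  for (i in 1:20) {
    p <- rand_params(lo = 0.001, hi = 0.1,
                     zero = c("r2", "k2", "beta2", "gamma1", "gamma2",
                              "delta1", "delta2"))
    got <- r0_ngm(p, S0 = 1000, N = 1000)
    expect_lt(rel_diff(got$value, r0_case2(p)$value), 1e-10)
  }

  # no transmission: F is the zero matrix
  p0 <- rand_params(zero = c("r1", "r2", "k1", "k2", "gamma1", "gamma2"))
  expect_equal(r0_ngm(p0, 1000, 1000)$value, 0)

  # general random draws against the closed form
  for (i in 1:300) {
    p <- rand_params(lo = 0.002, hi = 0.1, zero = c("gamma1", "gamma2"))
    N <- 1000
    S0 <- stats::runif(1, 100, N)
    expect_lt(rel_diff(r0_ngm(p, S0, N)$value,
                       r0_closed_form(p, S0, N)$value), 1e-8)
  }

  expect_error(r0_ngm(rand_params(), 1000, 1000), "gamma")
  expect_error(r0_ngm(model_params(r1 = 0.1), 1000, 1000), "singular")
})

test_that("case 2 R0 is monotone in its three rates", {
  grid <- seq(0.001, 0.05, length.out = 20)
  up_k <- vapply(grid, function(v)
    r0_case2(model_params(k1 = v, r1 = 0.01, beta1 = 0.02))$value, numeric(1))
  up_r <- vapply(grid, function(v)
    r0_case2(model_params(k1 = 0.01, r1 = v, beta1 = 0.02))$value, numeric(1))
  down_b <- vapply(grid, function(v)
    r0_case2(model_params(k1 = 0.01, r1 = 0.01, beta1 = v))$value, numeric(1))
  expect_true(all(diff(up_k) > 0))
  expect_true(all(diff(up_r) > 0))
  expect_true(all(diff(down_b) < 0))
})

test_that("persistence classification respects the threshold band", {
  expect_identical(classify_persistence(0), "extinction")
  expect_identical(classify_persistence(2), "persistence")
  expect_identical(classify_persistence(1), "threshold")
  expect_identical(classify_persistence(1 + 1e-12), "threshold")
  expect_identical(classify_persistence(1.001), "persistence")
  expect_error(classify_persistence(-0.1), "nonnegative")
  expect_error(classify_persistence(NaN), "finite")
})
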