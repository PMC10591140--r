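# Drift-diffusion membrane stability: Euler-Maruyama pairs, sample Lyapunov
# exponents, and the theoretical bounds.

test_that("the exponent bounds evaluate in closed form", {
  expect_equal(unname(theorem_bounds(-2, 1, 0.5)), c(-3.75, -1.875))
  # additive noise collapses the interval to a1 - a2^2/2
  b <- theorem_bounds(-1.5, 0.8, 0)
  expect_equal(unname(b["LB"]), unname(b["UB"]))
  expect_equal(unname(b["UB"]), -1.5 - 0.32)
  # noise-free lower bound is the drift coefficient itself
  expect_equal(unname(theorem_bounds(-3, 0, 0)["LB"]), -3)
  expect_true(all(theorem_bounds(-1, 0.5, 0.7)["LB"] <=
                    theorem_bounds(-1, 0.5, 0.7)["UB"]))
})

test_that("an unperturbed pair stays identical and deterministic errors decay as exp(a1 t)", {
  sys <- sde_system(-1, a2 = 0.5, b2 = 0.2)
  pr0 <- simulate_pair(sys, eps0 = 0, dt = 1e-3, horizon = 2, seed = 1)
  expect_true(all(pr0$err == 0))
  # noiseless system: closed-form exponential decay
  prd <- simulate_pair(sde_system(-1), eps0 = 1, dt = 1e-4, horizon = 5,
                       seed = 2)
  expect_equal(sample_lyapunov(prd), -1, tolerance = 2e-4)
  th <- exp(-prd$time)
  expect_equal(as.numeric(prd$err), th, tolerance = 1e-3)
})

test_that("the driven membrane is an Ornstein-Uhlenbeck process at stationarity", {
  sys <- sde_system(-1, a2 = 0.5)
  pr <- simulate_pair(sys, u0 = 0, dt = 1e-3, horizon = 50, seed = 4)
  v <- var(pr$u[-(1:10000), 1])
  expect_lt(abs(v - 0.25 / 2) / (0.25 / 2), 0.10)
})

test_that("the slope estimator recovers a synthetic exponential exactly", {
  tt <- seq(0, 10, by = 1e-3)
  err <- 0.3 * exp(-3 * tt)
  expect_equal(sample_lyapunov(err, dt = 1e-3), -3, tolerance = 1e-6)
  expect_error(sample_lyapunov(c(1, 0.5, 0, 0.1), dt = 1), "exactly 0")
})

test_that("additive noise speeds self-correction below the noise-free rate", {
  res <- lyapunov_experiment(-2, 1, 0, dt = 1e-3, horizon = 50, n_pairs = 20,
                             seed = 31)
  expect_lt(abs(res$le_estimate - (-2.5)), 0.15)
  expect_lt(res$le_estimate, -2)    # strictly below the noise-free exponent
  expect_equal(res$LB, res$UB)
})

test_that("exponent estimates respect the bounds for random coefficient triples", {
  set.seed(77)
  for (k in 1:5) {
    a1 <- -runif(1, 0.5, 3); a2 <- runif(1, 0, 1.5); b2 <- runif(1, 0, 0.8)
    r <- lyapunov_experiment(a1, a2, b2, dt = 1e-3, horizon = 20,
                             n_pairs = 10, seed = 500 + k)
    expect_gte(r$le_estimate, r$LB - 0.1)
    expect_lte(r$le_estimate, r$UB + 0.1)
  }
})

test_that("halving the step changes the exponent estimate by little", {
  r1 <- lyapunov_experiment(-2, 1, 0, dt = 1e-3, horizon = 40, n_pairs = 30,
                            seed = 8)
  r2 <- lyapunov_experiment(-2, 1, 0, dt = 5e-4, horizon = 40, n_pairs = 30,
                            seed = 8)
  expect_lt(abs(r1$le_estimate - r2$le_estimate), 0.05)
})

test_that("the literal pair coupling exposes shared-noise cancellation", {
  # with purely additive diffusion, subtracting two trajectories driven by
  # the same Wiener process cancels the noise: the error decays at rate a1,
  # and the diffusion-difference envelope assumed by the bounds is violated
  sys <- sde_system(-2, a2 = 1, b2 = 0)
  pr <- simulate_pair(sys, eps0 = 1e-3, dt = 1e-3, horizon = 10, seed = 5,
                      coupling = "literal")
  expect_equal(sample_lyapunov(pr), -2, tolerance = 5e-3)
  expect_gt(pr$assumption_violated, 0.99)
  # envelope coupling satisfies the assumption by construction
  pr2 <- simulate_pair(sys, eps0 = 1e-3, dt = 1e-3, horizon = 10, seed = 5)
  expect_equal(pr2$assumption_violated, 0)
  expect_lt(sample_lyapunov(pr2), -2)
})
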