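# Escape-noise firing law: cdf/pdf correctness and the single-neuron step.

test_that("firing-probability function matches the noise cdf in closed form", {
  gm <- noise_model("gaussian", 0.3)
  expect_equal(noise_cdf(0, gm), 0.5)
  expect_equal(noise_cdf(0.3, gm), pnorm(1), tolerance = 1e-12)
  lg <- noise_model("logistic", 0.2)
  expect_equal(noise_cdf(0.2 * log(3), lg), 0.75, tolerance = 1e-12)
  un <- noise_model("uniform", 0.4)
  expect_equal(noise_cdf(0, un), 0.5)
  expect_equal(noise_cdf(c(-0.5, 0.5), un), c(0, 1))
  # deterministic limit: strict Heaviside, silent exactly at threshold
  hv <- noise_model("none")
  expect_equal(noise_cdf(c(-1, 0, 1e-12), hv), c(0, 0, 1))
  expect_error(noise_cdf(NaN, gm), "non-finite")
  expect_error(noise_model("gaussian", -1), "positive")
})

test_that("noise density is the cdf derivative and a proper density", {
  xs <- seq(-4.9995, 4.9995, by = 1e-3)  # midpoint grid, avoids kinks
  for (fam in c("gaussian", "logistic", "uniform")) {
    nm <- noise_model(fam, 0.3)
    # quadrature: integrates to 1
    expect_equal(sum(noise_pdf(xs, nm)) * 1e-3, 1, tolerance = 1e-3)
    # centered finite difference of the cdf (skip the uniform kinks)
    h <- 1e-6
    grid <- seq(-1, 1, by = 0.05)
    if (fam == "uniform") grid <- grid[abs(abs(grid) - 0.3) > 1e-9]
    fd <- (noise_cdf(grid + h, nm) - noise_cdf(grid - h, nm)) / (2 * h)
    expect_equal(noise_pdf(grid, nm), fd, tolerance = 1e-6)
    # symmetric, maximal at 0
    expect_equal(noise_pdf(grid, nm), noise_pdf(-grid, nm))
    expect_true(all(noise_pdf(grid, nm) <= noise_pdf(0, nm) + 1e-15))
  }
  expect_equal(noise_pdf(0, noise_model("gaussian", 0.25)),
               1 / (0.25 * sqrt(2 * pi)))
  expect_equal(noise_pdf(0, noise_model("uniform", 0.4)), 1 / 0.8)
  expect_error(noise_pdf(0, noise_model("none")), "no learning factor")
})

test_that("empirical firing frequency matches the firing law (3 binomial SE)", {
  n <- 1e5
  for (fam in c("gaussian", "logistic", "uniform")) {
    nm <- noise_model(fam, 0.3)
    for (x in c(-0.3, 0, 0.3)) {
      p <- noise_cdf(x, nm)
      st <- lif_step(u = rep(0, n), drive = rep(1 + x, n), nm = nm,
                     params = neuron_params(), seed = 42)
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(st$o) - p), 3 * se + 1e-12)
    }
  }
})

test_that("deterministic LIF recursion: integrate, fire strictly above threshold, reset", {
  nm <- noise_model("none")
  pp <- neuron_params()   # tau = 0.5, v_th = 1, u_reset = 0
  s1 <- lif_step(0, 0.6, nm, pp, seed = 1)
  expect_equal(s1$o, 0)
  expect_equal(s1$u, 0.6)
  s2 <- lif_step(s1$u, 0.8, nm, pp, seed = 1)
  expect_equal(s2$p_fire, 1)   # 0.5*0.6 + 0.8 = 1.1 > 1
  expect_equal(s2$o, 1)
  expect_equal(s2$u, 0)        # hard reset
  # at exactly threshold, no spike
  s3 <- lif_step(0, 1, nm, pp, seed = 1)
  expect_equal(s3$o, 0)
})

test_that("vanishing noise reproduces the deterministic spike sequence", {
  pp <- neuron_params()
  set.seed(7)
  for (k in 1:20) {
    drives <- runif(12, 0, 1.4)
    u_n <- 0; u_d <- 0; same <- TRUE
    for (dr in drives) {
      sn <- lif_step(u_n, dr, noise_model("gaussian", 1e-9), pp, seed = k)
      sd_ <- lif_step(u_d, dr, noise_model("none"), pp, seed = k)
      same <- same && identical(sn$o, sd_$o)
      u_n <- sn$u; u_d <- sd_$u
    }
    expect_true(same)
  }
})

test_that("membrane at threshold fires with probability one half and reset is idempotent", {
  nm <- noise_model("gaussian", 0.3)
  pp <- neuron_params(u_reset = 0.4)
  st <- lif_step(0, 1, nm, pp, seed = 3)
  expect_equal(st$p_fire, 0.5)
  # after a (forced) reset, a zero-drive step leaves u = tau * u_reset
  st2 <- lif_step(pp$u_reset, 0, noise_model("gaussian", 10), pp, xi = 1)
  expect_equal(st2$u, pp$tau * pp$u_reset)
  expect_error(lif_step(0, Inf, nm, pp), "non-finite")
})

test_that("sampled-noise mode has the same per-step firing distribution", {
  nm <- noise_model("gaussian", 0.3)
  pp <- neuron_params()
  n <- 4e4
  st <- lif_step(rep(0, n), rep(1.2, n), nm, pp, seed = 9, sample_noise = TRUE)
  p <- noise_cdf(1.2 - 1, nm)
  expect_lt(abs(mean(st$o) - p), 3 * sqrt(p * (1 - p) / n))
})
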