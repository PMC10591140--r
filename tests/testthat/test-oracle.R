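# Enumeration ground truth and the local-marginalization estimator.

# single spiking neuron pinned at threshold: p = 1/2
pinned_neuron <- function(f, grad, n = 1, b = 1) {
  net <- nsnn_network(1, n, head = head_custom(f, grad),
                      noise = noise_model("gaussian", 0.3), seed = 1,
                      init_bias = b)
  net$layers[[1]]$W[] <- 0
  net
}

test_that("enumerated expected losses match closed forms", {
  # E[o] for a Bernoulli(1/2) spike
  net <- pinned_neuron(function(O) O[, 1], function(O) O * 0 + 1)
  en <- enumerate_expected_loss(net, matrix(0, 1, 1))
  expect_equal(en$expected_loss, 0.5, tolerance = 1e-12)
  expect_equal(en$n_config, 2L)
  # two independent neurons, f = o1 * o2 -> 1/4
  net2 <- pinned_neuron(function(O) O[, 1] * O[, 2],
                        function(O) cbind(O[, 2], O[, 1]), n = 2)
  en2 <- enumerate_expected_loss(net2, matrix(0, 1, 1))
  expect_equal(en2$expected_loss, 0.25, tolerance = 1e-12)
  # cap is enforced with the variable count in the message
  big <- tiny_net(sizes = c(5, 5), n_in = 2)
  expect_error(enumerate_expected_loss(big, tiny_input(T_ = 2)), "2\\^20")
})

test_that("Monte-Carlo losses agree with the enumerated expectation (3 SE)", {
  net <- tiny_net(sizes = c(2, 2), n_in = 2, seed = 6)
  xs <- tiny_input()
  en <- enumerate_expected_loss(net, xs, target = 1)
  n <- 1e5
  X <- array(rep(array(t(xs), c(1, 2, 2)), each = n), c(n, 2, 2))
  rec <- nsnn:::nsnn_forward(net, X, seed = 17)
  ls <- nsnn:::head_loss(net, rec, 1, "mean", want_grads = FALSE)$loss
  expect_lt(abs(mean(ls) - en$expected_loss), 3 * sd(ls) / sqrt(n))
})

test_that("the exact gradient agrees with finite differences and closed forms", {
  # constant loss -> zero gradient everywhere
  netc <- pinned_neuron(function(O) rep(2, nrow(O)), function(O) O * 0)
  g0 <- exact_gradient(netc, matrix(0, 1, 1))
  expect_equal(flat_all(g0), rep(0, 2))
  # single Bernoulli, f = o: dE/db is the noise density at u - v_th
  net1 <- pinned_neuron(function(O) O[, 1], function(O) O * 0 + 1, b = 1.1)
  g1 <- exact_gradient(net1, matrix(0, 1, 1))
  expect_equal(g1$layers[[1]]$b, noise_pdf(0.1, noise_model("gaussian", 0.3)),
               tolerance = 1e-12)
  # full finite-difference sweep on a temporal multi-layer network
  net <- tiny_net(seed = 2)
  expect_no_error(exact_gradient(net, tiny_input(), target = 1,
                                 check_fd = TRUE))
})

test_that("local marginalization with exact loss differences is unbiased", {
  net <- tiny_net(sizes = c(2, 2), n_in = 2, seed = 3)
  xs <- tiny_input()
  truth <- exact_gradient(net, xs, target = 1)
  mc <- mc_gradient_estimate(net, xs, target = 1, n_samples = 4e4, seed = 11,
                             estimator = "local_marginal_exact")
  expect_lt(report_z(mc, truth), 4)
})

test_that("first-order loss differences reproduce the three-factor backward pass", {
  net <- tiny_net(seed = 5)
  rec <- rollout(net, tiny_input(), seed = 7)
  lm <- local_marginal_estimate(net, rec, target = 1, exact_delta = FALSE)
  nd <- ndl_backward(net, rec, target = 1)
  expect_equal(lm$estimator, "local_marginal_first_order")
  for (l in 1:3) {
    expect_equal(lm$layers[[l]]$W, nd$layers[[l]]$W, tolerance = 1e-14)
    expect_equal(lm$layers[[l]]$b, nd$layers[[l]]$b, tolerance = 1e-14)
  }
})

test_that("exact and first-order deltas coincide for a multilinear loss", {
  # single spiking stage, one step: the flip difference of a multilinear map
  # is exactly its first-order expansion
  net <- nsnn_network(2, 3, head = multilinear_head(),
                      noise = noise_model("gaussian", 0.3), seed = 9)
  xs <- matrix(c(0.5, 0.8), 1, 2)
  X <- array(rep(array(t(xs), c(1, 2, 1)), each = 200), c(200, 2, 1))
  rec <- nsnn:::nsnn_forward(net, X, seed = 13)
  ex <- local_marginal_estimate(net, rec, exact_delta = TRUE)
  fo <- local_marginal_estimate(net, rec, exact_delta = FALSE)
  expect_equal(ex$layers[[1]]$W, fo$layers[[1]]$W, tolerance = 1e-12)
  expect_equal(ex$layers[[1]]$b, fo$layers[[1]]$b, tolerance = 1e-12)
})

test_that("degenerate firing probabilities are flagged", {
  net <- nsnn_network(1, 1, head = head_custom(function(O) O[, 1],
                                               function(O) O * 0 + 1),
                      noise = noise_model("uniform", 0.2), seed = 1,
                      init_bias = 3)
  net$layers[[1]]$W[] <- 0  # u = 3 >> v_th + half-width: p = 1 exactly
  rec <- rollout(net, matrix(0, 1, 1), seed = 2)
  lm <- local_marginal_estimate(net, rec)
  expect_true(lm$degenerate)
})

test_that("the bias/variance table is deterministic and scales as Monte Carlo", {
  net <- tiny_net(sizes = c(2, 2), n_in = 2, seed = 4)
  xs <- tiny_input()
  t1 <- bias_variance_report(net, xs, target = 1, n_samples = 4000, seed = 3)
  t2 <- bias_variance_report(net, xs, target = 1, n_samples = 4000, seed = 3)
  expect_identical(t1, t2)
  enum_rows <- t1[t1$estimator == "enumeration", ]
  expect_true(all(enum_rows$max_abs_bias == 0 & enum_rows$mean_variance == 0))
  expect_true(all(is.finite(t1$max_abs_bias)))
  # standard error of the mean halves when the sample count quadruples
  m1 <- mc_gradient_estimate(net, xs, target = 1, n_samples = 5000, seed = 2)
  m2 <- mc_gradient_estimate(net, xs, target = 1, n_samples = 20000, seed = 2)
  s1 <- mean(c(m1$se[[1]]$W, m1$se[[2]]$W))
  s2 <- mean(c(m2$se[[1]]$W, m2$se[[2]]$W))
  expect_lt(abs(s1 / s2 - 2), 0.6)
})
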