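# The noise/surrogate correspondence, the three-factor backward pass, and
# the SGD trainer.

test_that("each noise family maps to its surrogate with the density peak", {
  sg <- surrogate_from_noise(noise_model("gaussian", 0.3))
  expect_equal(sg$shape, "erf_like")
  expect_equal(sg$height, 1 / (0.3 * sqrt(2 * pi)))
  sg2 <- surrogate_from_noise(noise_model("logistic", 0.5))
  expect_equal(sg2$shape, "sigmoid_derivative")
  expect_equal(sg2$height, 1 / (4 * 0.5))
  sg3 <- surrogate_from_noise(noise_model("uniform", 0.4))
  expect_equal(sg3$shape, "rectangular")
  expect_equal(sg3$height, 1 / 0.8)
  # surrogate values equal the density everywhere
  x <- seq(-1, 1, 0.1)
  expect_equal(surrogate_value(x, sg), noise_pdf(x, noise_model("gaussian", 0.3)))
  expect_equal(surrogate_value(x, sg2), noise_pdf(x, noise_model("logistic", 0.5)),
               tolerance = 1e-12)
  expect_error(surrogate_from_noise(noise_model("none")), "no matching surrogate")
})

test_that("a surrogate shape inverts to its noise family with a step-size constant", {
  # the common erf surrogate (1/pi) exp(-x^2): Gaussian sigma = 1/sqrt(2)
  r <- noise_from_surrogate(surrogate_spec("erf_like", width = 1 / sqrt(2),
                                           height = 1 / pi))
  expect_equal(r$noise$family, "gaussian")
  expect_equal(r$noise$scale, 1 / sqrt(2))
  expect_equal(r$lr_multiplier, 1 / sqrt(pi), tolerance = 1e-12)
  # normalized rectangle: multiplier 1
  r2 <- noise_from_surrogate(surrogate_spec("rectangular", width = 0.25,
                                            height = 2))
  expect_equal(r2$noise$family, "uniform")
  expect_equal(r2$lr_multiplier, 1)
  # sigmoid derivative with peak 1/4: logistic scale 1, multiplier 1
  r3 <- noise_from_surrogate(surrogate_spec("sigmoid_derivative", width = 1,
                                            height = 0.25))
  expect_equal(r3$noise$family, "logistic")
  expect_equal(r3$lr_multiplier, 1)
})

test_that("noise-driven and matched-surrogate backward passes are identical", {
  net <- tiny_net(seed = 4)
  rec <- rollout(net, tiny_input(), seed = 6)
  g_ndl <- ndl_backward(net, rec, target = 2)
  g_sgl <- surrogate_backward(net, rec, target = 2,
                              sg = surrogate_from_noise(noise_model("gaussian", 0.3)))
  a <- flat_all(g_ndl); b <- flat_all(g_sgl)
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-12)
})

test_that("a zero global learning signal propagates to zero parameter gradients", {
  net <- tiny_net(sizes = c(2, 3), head = head_custom(
    f = function(O) rep(1, nrow(O)), grad = function(O) O * 0))
  rec <- rollout(net, tiny_input(), seed = 2)
  g <- ndl_backward(net, rec)
  expect_equal(flat_all(g), rep(0, length(flat_all(g))))
})

test_that("deterministic layers are rejected by the noise-driven backward", {
  net <- tiny_net()
  net$layers[[2]]$noise <- noise_model("none")
  rec <- rollout(net, tiny_input(), seed = 1)
  expect_error(ndl_backward(net, rec, 1), "surrogate")
})

test_that("training is seed-reproducible and inert at zero learning rate", {
  task <- gen_rate_task(n_samples = 60, seed = 2)
  net <- nsnn_network(20, c(8, 6), head = head_softmax(2),
                      noise = noise_model("gaussian", 0.3), seed = 1)
  f0 <- nsnn_train(net, task, epochs = 3, lr = 0, seed = 5)
  expect_identical(nsnn:::nsnn_get_params(f0$net), nsnn:::nsnn_get_params(net))
  f1 <- nsnn_train(net, task, epochs = 3, lr = 0.3, seed = 5)
  f2 <- nsnn_train(net, task, epochs = 3, lr = 0.3, seed = 5)
  expect_identical(f1$curve, f2$curve)
  expect_identical(coef(f1), coef(f2))
  expect_false(identical(coef(f1), coef(f0)))
})

test_that("noise-driven learning solves the rate-pattern task", {
  task <- gen_rate_task(seed = 10)
  net <- nsnn_network(20, c(24, 16), head = head_softmax(2),
                      noise = noise_model("gaussian", 0.3), seed = 1)
  fit <- nsnn_train(net, task, epochs = 12, lr = 0.5, batch_size = 40, seed = 3)
  expect_gte(utils::tail(fit$curve$accuracy, 1), 0.95)
  # fitted-model interface
  pr <- predict(fit, task$x[1:20, , , drop = FALSE], seed = 9)
  expect_equal(dim(pr$prob), c(20, 2))
  expect_gte(mean(pr$class == task$y[1:20]), 0.9)
})
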