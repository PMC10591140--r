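# Layered composition, rollouts, the Bayesian-network joint probability and
# the softmax head.

test_that("a one-layer, one-step rollout is a single neuron step", {
  net <- nsnn_network(2, 3, head = head_softmax(2), seed = 5)
  x <- c(0.4, 0.7)
  rec <- rollout(net, matrix(x, 1, 2), seed = 11)
  drive <- as.numeric(net$layers[[1]]$W %*% x + net$layers[[1]]$b)
  st <- lif_step(rep(0, 3), drive, net$layers[[1]]$noise,
                 net$layers[[1]]$params, seed = 11)
  expect_equal(as.numeric(rec$layers[[1]]$p), st$p_fire)
  expect_equal(as.numeric(rec$layers[[1]]$o), st$o)
})

test_that("zero transform gives constant firing probability F(-v_th)", {
  net <- nsnn_network(2, c(4), head = head_softmax(2),
                      noise = noise_model("gaussian", 0.3), seed = 1,
                      init_bias = 0)
  net$layers[[1]]$W[] <- 0
  rec <- rollout(net, matrix(0.5, 6, 2), seed = 2)
  expect_equal(as.numeric(rec$layers[[1]]$p),
               rep(noise_cdf(-1, noise_model("gaussian", 0.3)), 4 * 6))
})

test_that("rollouts are reproducible and shape errors name the input contract", {
  net <- tiny_net()
  xs <- tiny_input()
  r1 <- rollout(net, xs, seed = 9)
  r2 <- rollout(net, xs, seed = 9)
  expect_identical(r1$layers, r2$layers)
  expect_error(rollout(net, matrix(0, 2, 5), seed = 1), "layer 1 expects")
})

test_that("joint probabilities normalize and score the sampled configuration", {
  # single neuron held at threshold: p = 1/2
  net <- nsnn_network(1, 1, head = head_softmax(2), seed = 1, init_bias = 1)
  net$layers[[1]]$W[] <- 0
  rec <- rollout(net, matrix(0, 1, 1), seed = 4)
  expect_equal(joint_log_prob(net, rec), log(0.5))
  # all configurations of a 6-variable net sum to probability 1
  net2 <- tiny_net(sizes = c(2, 1), n_in = 2)
  en <- enumerate_expected_loss(net2, tiny_input(), target = 1)
  lp <- joint_log_prob(net2, en$record)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
  expect_true(all(lp <= 0))
  # moving p toward the sampled state never decreases the joint probability
  rec3 <- rollout(net2, tiny_input(), seed = 3)
  l0 <- joint_log_prob(net2, rec3)
  rec3$layers[[1]]$p <- (rec3$layers[[1]]$p + rec3$layers[[1]]$o) / 2
  expect_gte(joint_log_prob(net2, rec3), l0)
})

test_that("predictions are per-step softmaxes with a time-averaged summary", {
  net <- tiny_net()
  net$head$W[] <- 0; net$head$b[] <- 0
  rec <- rollout(net, tiny_input(), seed = 2)
  pr <- nsnn_predict(net, rec)
  expect_equal(as.numeric(pr$average), c(0.5, 0.5))
  net2 <- tiny_net(seed = 8)
  rec2 <- rollout(net2, tiny_input(), seed = 3)
  pr2 <- nsnn_predict(net2, rec2)
  expect_equal(rowSums(pr2$average), 1, tolerance = 1e-12)
  expect_equal(apply(pr2$per_step, c(1, 3), sum),
               matrix(1, 1, rec2$T), tolerance = 1e-12)
})

test_that("sampled marginal firing rates match enumeration (3 SE)", {
  net <- tiny_net(sizes = c(2, 2), n_in = 2, seed = 3)
  xs <- tiny_input()
  en <- enumerate_expected_loss(net, xs, target = 1)
  # enumeration marginal of neuron (l, m, t)
  marg <- function(l, m, t) sum(en$prob * en$record$layers[[l]]$o[, m, t])
  n <- 1e4
  X <- array(rep(array(t(xs), c(1, 2, 2)), each = n), c(n, 2, 2))
  rec <- nsnn:::nsnn_forward(net, X, seed = 21)
  for (l in 1:2) for (m in 1:2) for (t in 1:2) {
    p0 <- marg(l, m, t)
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(rec$layers[[l]]$o[, m, t]) - p0), 3 * se + 1e-9)
  }
})

test_that("the zero-noise network reproduces the deterministic trajectory", {
  for (k in 1:10) {
    netn <- nsnn_network(3, c(5, 4), head = head_softmax(2),
                         noise = noise_model("gaussian", 1e-9), seed = k)
    netd <- netn
    for (l in 1:2) netd$layers[[l]]$noise <- noise_model("none")
    xs <- nsnn:::with_seed(100 + k, matrix(runif(8 * 3, 0, 1.2), 8, 3))
    rn <- rollout(netn, xs, seed = k)
    rd <- rollout(netd, xs, seed = k)
    for (l in 1:2) expect_equal(rn$layers[[l]]$o, rd$layers[[l]]$o)
  }
})

test_that("instantaneous loss is averaged over steps or taken at the last step", {
  net <- tiny_net()
  rec <- rollout(net, tiny_input(T_ = 3), seed = 2)
  hm <- nsnn:::head_loss(net, rec, 1, "mean", want_grads = FALSE)$loss
  hl <- nsnn:::head_loss(net, rec, 1, "last", want_grads = FALSE)$loss
  per_t <- vapply(1:3, function(t) {
    o <- rec$layers[[3]]$o[, , t]
    s <- as.numeric(net$head$W %*% o + net$head$b)
    -log(exp(s[1] - max(s)) / sum(exp(s - max(s))))
  }, 0)
  expect_equal(hm, mean(per_t), tolerance = 1e-12)
  expect_equal(hl, per_t[3], tolerance = 1e-12)
})
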