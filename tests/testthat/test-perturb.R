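# Perturbation operators: identities at zero strength, exact budgets,
# binomial drop/flip statistics, and attack effectiveness.

trained_toy <- function(seed = 1, n_samples = 60, epochs = 8) {
  task <- gen_rate_task(n_samples = n_samples, seed = 100 + seed)
  net <- nsnn_network(20, c(10, 8), head = head_softmax(2),
                      noise = noise_model("gaussian", 0.3), seed = seed)
  list(fit = nsnn_train(net, task, epochs = epochs, lr = 0.5,
                        batch_size = 20, seed = seed),
       task = task)
}

test_that("the sign-gradient attack respects its max-norm budget exactly", {
  tt <- trained_toy()
  xs <- t(matrix(tt$task$x[1, , ], 20, 10))
  y <- tt$task$y[1]
  expect_identical(fgsm(tt$fit, xs, y, gamma = 0), xs)
  xa <- fgsm(tt$fit, xs, y, gamma = 0.1, seed = 3)
  d <- abs(xa - xs)
  expect_true(all(d <= 0.1 + 1e-15))
  g <- nsnn:::input_gradient(tt$fit$net, xs, y, seed = 3)
  expect_true(all(abs(d[g != 0] - 0.1) < 1e-12))
  expect_true(all(d[g == 0] == 0))
})

test_that("the direct-optimization attack lands on the L2 sphere and beats one step", {
  tt <- trained_toy()
  n_try <- 8; wins <- 0; dl_f <- 0; dl_c <- 0
  for (i in seq_len(n_try)) {
    xs <- t(matrix(tt$task$x[i, , ], 20, 10))
    y <- tt$task$y[i]
    gam <- 0.1 * sqrt(length(xs))
    expect_identical(direct_opt_attack(tt$fit, xs, y, gamma = 0), xs)
    xd <- direct_opt_attack(tt$fit, xs, y, gamma = gam, seed = 20 + i)
    expect_lt(abs(sqrt(sum((xd - xs)^2)) - gam), 1e-6)
    xf <- fgsm(tt$fit, xs, y, gamma = 0.1, seed = 20 + i)
    loss_of <- function(x) {
      r <- rollout(tt$fit$net, x, seed = 900 + i)
      mean(nsnn:::head_loss(tt$fit$net, r, y, want_grads = FALSE)$loss)
    }
    lc <- loss_of(xs); lf <- loss_of(xf); ld <- loss_of(xd)
    dl_f <- dl_f + (lf - lc); dl_c <- dl_c + (ld - lc)
    if (ld >= lf) wins <- wins + 1
  }
  expect_gt(dl_f, 0)            # one-step attack raises the mean loss
  expect_gte(wins / n_try, 0.5) # iterated attack is at least comparable
})

test_that("event dropping is a per-event Bernoulli thinning", {
  ev <- gen_event_stream(0.05, sensor = c(50, 40), T_ = 1000, seed = 3)
  expect_identical(event_drop(ev, 0, seed = 1), ev)
  expect_equal(nrow(event_drop(ev, 1, seed = 1)), 0)
  n <- nrow(ev)
  kept <- nrow(event_drop(ev, 0.25, seed = 5))
  se <- sqrt(0.25 * 0.75 * n)
  expect_lt(abs(kept - 0.75 * n), 3 * se)
  # ordering and schema preserved
  out <- event_drop(ev, 0.5, seed = 9)
  expect_true(!is.unsorted(out$t))
  expect_identical(names(out), c("t", "x", "y", "polarity"))
  expect_identical(attr(out, "sensor"), attr(ev, "sensor"))
})

test_that("spike flips are exact at the extremes and binomial in between", {
  ras <- gen_poisson_raster(rep(0.3, 10), T_ = 100, trials = 100, seed = 2)
  expect_identical(spike_flip(ras, 0), ras)
  flipped <- spike_flip(ras, 1, seed = 1)
  expect_equal(as.numeric(flipped), as.numeric(1 - unclass(ras)))
  n <- length(ras)
  beta <- 0.1
  nf <- sum(spike_flip(ras, beta, seed = 7) != ras)
  expect_lt(abs(nf - beta * n), 3 * sqrt(beta * (1 - beta) * n))
  expect_error(spike_flip(c(0, 2, 1), 0.1), "binary")
})

test_that("in-rollout flips enter the dynamics and degrade accuracy gracefully", {
  tt <- trained_toy()
  r0 <- rollout(tt$fit$net, t(matrix(tt$task$x[1, , ], 20, 10)), seed = 5)
  r1 <- rollout(tt$fit$net, t(matrix(tt$task$x[1, , ], 20, 10)), seed = 5,
                flip_prob = 0.5)
  expect_false(identical(r0$layers[[1]]$o, r1$layers[[1]]$o))
  a0 <- perturbed_accuracy(tt$fit, tt$task, 0, seed = 6)
  a1 <- perturbed_accuracy(tt$fit, tt$task, 0.45, seed = 6)
  expect_gte(a0$accuracy, a1$accuracy)
  expect_true(a1$loss >= a0$loss)
})

test_that("noisy networks hold up at least as well as deterministic ones under flips", {
  betas <- c(0.01, 0.02, 0.03, 0.04)
  acc_n <- matrix(0, 3, 4); acc_d <- matrix(0, 3, 4)
  for (s in 1:3) {
    task <- gen_rate_task(seed = 40 + s)
    nn <- nsnn_network(20, c(24, 16), head = head_softmax(2),
                       noise = noise_model("gaussian", 0.3), seed = s)
    nf <- nsnn_train(nn, task, epochs = 12, lr = 0.5, batch_size = 40,
                     seed = 50 + s)
    dn <- nsnn_network(20, c(24, 16), head = head_softmax(2),
                       noise = noise_model("none"), seed = s)
    df <- nsnn_train(dn, task, epochs = 12, lr = 0.5, batch_size = 40,
                     seed = 50 + s, rule = "surrogate",
                     sg = surrogate_from_noise(noise_model("gaussian", 0.3)))
    for (j in seq_along(betas)) {
      acc_n[s, j] <- perturbed_accuracy(nf, task, betas[j], seed = 60 + s)$accuracy
      acc_d[s, j] <- perturbed_accuracy(df, task, betas[j], seed = 60 + s)$accuracy
    }
  }
  # ensemble comparison at the strongest perturbation of the sweep
  expect_gte(mean(acc_n[, 4]), mean(acc_d[, 4]))
})
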