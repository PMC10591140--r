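# Brute-force ground truth for tiny networks: exact expected loss and exact
# gradients by enumerating every spike configuration, plus the unbiased
# local-marginalization Monte-Carlo estimator used to validate the learning
# rule. Everything here is restricted to sum(sizes) * T <= cap binary
# variables (default 16, i.e. at most 65,536 configurations).

enum_check <- function(net, T_, cap) {
  N <- sum(net$sizes) * T_
  if (N > cap) {
    stop(sprintf("enumeration needs 2^%d = %.3g configurations (cap 2^%d); %s",
                 N, 2^N, cap, "reduce the network or the horizon"))
  }
  for (ly in net$layers) {
    if (ly$noise$family == "none") {
      stop("enumeration requires stochastic layers (firing probabilities in (0,1))")
    }
  }
  N
}

as_x_array <- function(net, x_seq) {
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, ncol = net$n_in)
  array(t(x_seq), dim = c(1, ncol(x_seq), nrow(x_seq)))
}

# Build forced-spike arrays covering all 2^N configurations. Variable order:
# t slow, then layer, then neuron (the forward evaluation order).
enum_forced <- function(net, T_) {
  N <- sum(net$sizes) * T_
  B <- 2L^N
  cfg <- seq_len(B) - 1L
  o_forced <- lapply(net$sizes, function(n) array(0, c(B, n, T_)))
  bit <- 0L
  for (t in seq_len(T_)) {
    for (l in seq_along(net$sizes)) {
      for (m in seq_len(net$sizes[l])) {
        o_forced[[l]][, m, t] <- bitwAnd(bitwShiftR(cfg, bit), 1L)
        bit <- bit + 1L
      }
    }
  }
  o_forced
}

#' Exact expected loss by enumeration
#'
#' Sums the loss over every one of the \eqn{2^{N \cdot T}} spike
#' configurations of a tiny network, weighting each by its joint probability
#' under the Bayesian-network factorization. The enumeration respects the
#' temporal structure: the membrane is carried (and reset) along each
#' configuration's own spike history.
#'
#' @param net a small [nsnn_network()] with stochastic layers.
#' @param x_seq `T x n_in` input matrix.
#' @param target target class for a softmax head.
#' @param loss_mode `"mean"` or `"last"`.
#' @param cap maximum number of binary spike variables (default 16).
#' @return list with `expected_loss`, the per-configuration `prob` and `loss`
#'   vectors, the forced-rollout `record`, and `n_config`.
#' @export
enumerate_expected_loss <- function(net, x_seq, target = NULL,
                                    loss_mode = c("mean", "last"), cap = 16) {
  loss_mode <- match.arg(loss_mode)
  X1 <- as_x_array(net, x_seq)
  T_ <- dim(X1)[3]
  enum_check(net, T_, cap)
  o_forced <- enum_forced(net, T_)
  B <- dim(o_forced[[1]])[1]
  X <- array(rep(X1, each = B), dim = c(B, dim(X1)[2], T_))
  rec <- nsnn_forward(net, X, o_forced = o_forced)
  logp <- numeric(B)
  for (l in seq_along(rec$layers)) {
    p <- rec$layers[[l]]$p; o <- rec$layers[[l]]$o
    logp <- logp + apply(log(o * p + (1 - o) * (1 - p)), 1, sum)
  }
  prob <- exp(logp)
  tot <- sum(prob)
  if (abs(tot - 1) > 1e-9) {
    stop(sprintf("enumeration probabilities sum to %.12f, not 1", tot))
  }
  loss <- head_loss(net, rec, target, loss_mode, want_grads = FALSE)$loss
  list(expected_loss = sum(prob * loss), prob = prob, loss = loss,
       record = rec, n_config = B)
}

# Per-sample gradients of the loss w.r.t. softmax-head parameters (pathwise;
# the head sees fixed spikes, so this is an ordinary chain rule).
head_per_sample_grads <- function(net, record, target, loss_mode = "mean") {
  hd <- net$head
  if (hd$type != "softmax") return(NULL)
  B <- record$B; T_ <- record$T
  oL <- record$layers[[length(net$layers)]]$o
  nL <- dim(oL)[2]; K <- hd$n_class
  wts <- if (loss_mode == "mean") rep(1 / T_, T_) else c(rep(0, T_ - 1), 1)
  y <- as.integer(rep_len(target, B))
  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
  psW <- matrix(0, B, K * nL); psb <- matrix(0, B, K)
  for (t in seq_len(T_)) {
    if (wts[t] == 0) next
    Ot <- slab(oL, t)
    P <- row_softmax(tcrossprod(Ot, hd$W) + rep(hd$b, each = B))
    D <- wts[t] * (P - Y)
    for (k in seq_len(K)) {
      psW[, ((k - 1) * nL + 1):(k * nL)] <-
        psW[, ((k - 1) * nL + 1):(k * nL)] + D[, k] * Ot
    }
    psb <- psb + D
  }
  list(W = psW, b = psb)
}

#' Exact gradient of the expected loss by enumeration
#'
#' Differentiates the enumeration sum analytically: each configuration
#' contributes its probability times the pathwise head gradient plus the
#' score-weighted gradients of the firing probabilities (through the noise
#' cdf and the affine transforms, including the exact reset mixing along the
#' fixed spike history).
#'
#' @inheritParams enumerate_expected_loss
#' @param check_fd also compare every parameter's gradient against a central
#'   finite difference of the enumerated expected loss (step `1e-5`) and stop
#'   if the relative discrepancy exceeds `1e-4`.
#' @return a `"gradient_report"` with `estimator = "enumeration"`; the exact
#'   expected loss is attached as attribute `"expected_loss"`.
#' @export
exact_gradient <- function(net, x_seq, target = NULL,
                           loss_mode = c("mean", "last"), cap = 16,
                           check_fd = FALSE) {
  loss_mode <- match.arg(loss_mode)
  en <- enumerate_expected_loss(net, x_seq, target, loss_mode, cap)
  rec <- en$record
  B <- rec$B
  # score-function part: sum_cfg prob * f * d log p(cfg) / d theta
  coef <- lapply(seq_along(net$layers), function(l) {
    ly <- net$layers[[l]]
    rl <- rec$layers[[l]]
    (rl$o - rl$p) / (rl$p * (1 - rl$p)) *
      array(noise_pdf(rl$u - ly$params$v_th, ly$noise), dim(rl$u))
  })
  bw <- nsnn_backward_coef(net, rec, coef, sample_weights = en$prob * en$loss)
  hg <- if (net$head$type == "softmax") {
    hl <- head_loss(net, rec, target, loss_mode, sample_weights = en$prob)
    hl$head_grads
  }
  rep_ <- new_gradient_report(bw$layer_grads, hg, "enumeration", en$n_config)
  attr(rep_, "expected_loss") <- en$expected_loss
  if (check_fd) {
    h <- 1e-5
    v <- nsnn_get_params(net)
    g <- flatten_grads(rep_$layers, rep_$head)
    for (j in seq_along(v)) {
      vp <- v; vp[j] <- v[j] + h
      vm <- v; vm[j] <- v[j] - h
      Ep <- enumerate_expected_loss(nsnn_set_params(net, vp), x_seq, target,
                                    loss_mode, cap)$expected_loss
      Em <- enumerate_expected_loss(nsnn_set_params(net, vm), x_seq, target,
                                    loss_mode, cap)$expected_loss
      fd <- (Ep - Em) / (2 * h)
      if (abs(fd - g[j]) > 1e-4 * max(1, abs(fd))) {
        stop(sprintf("finite-difference check failed at parameter %d: %.8g vs %.8g",
                     j, g[j], fd))
      }
    }
  }
  rep_
}

# ---------------------------------------------------------------------------

# Counterfactual loss: re-propagate the recorded rollout with the spike of
# (layer l, neuron m, step t) clamped to `value` (length-B), reusing the
# record's uniform draws for every other spike decision, and return the
# per-sample loss of the re-evaluated configuration.
counterfactual_loss <- function(net, record, target, l, m, t, value,
                                loss_mode = "mean") {
  xi <- lapply(record$layers, `[[`, "xi")
  if (any(vapply(xi, is.null, TRUE))) {
    stop("record does not store uniform draws; rerun the rollout without o_forced")
  }
  rec2 <- nsnn_forward(net, record$X, xi = xi,
                       clamp = list(l = l, m = m, t = t, value = value))
  head_loss(net, rec2, target, loss_mode, want_grads = FALSE)$loss
}

#' Local-marginalization gradient estimate from one (batched) rollout
#'
#' The unbiased reduced-variance estimator obtained by exact summation over
#' one spike variable at a time: for every neuron and step, the gradient of
#' that variable's firing probability is multiplied by the loss difference
#' `f(o) - f(o with that spike flipped)`. With `exact_delta = TRUE` the
#' flipped loss is obtained by full downstream re-evaluation — the flipped
#' value feeds the same-step downstream layers and all subsequent membranes
#' and resets, with every other spike decision re-drawn from its conditional
#' via the record's stored uniform draws (common random numbers). Its
#' expectation over rollouts equals the enumeration gradient for any loss.
#'
#' With `exact_delta = FALSE` the loss difference is replaced by the
#' first-order form `(2o - 1) * dL/do`, which makes the per-layer estimate
#' identical to the [ndl_backward()] result on the same record (and exact
#' whenever the loss is multilinear in the spikes).
#'
#' @param net the network that produced `record`.
#' @param record a (possibly batched) `"nsnn_rollout"` with stored draws.
#' @param target target class for a softmax head.
#' @param exact_delta see Details.
#' @param loss_mode `"mean"` or `"last"`.
#' @param max_flip_vars guard for `exact_delta = TRUE`: refuse to run the
#'   per-variable re-evaluation on nets with more spike variables than this.
#' @return a `"gradient_report"` (means over the batch, with per-entry
#'   Monte-Carlo standard errors). A `degenerate` flag is set if any firing
#'   probability in the record is exactly 0 or 1.
#' @export
local_marginal_estimate <- function(net, record, target = NULL,
                                    exact_delta = TRUE,
                                    loss_mode = c("mean", "last"),
                                    max_flip_vars = 64) {
  loss_mode <- match.arg(loss_mode)
  if (!exact_delta) {
    rep_ <- ndl_backward(net, record, target, loss_mode, per_sample = TRUE)
    rep_$estimator <- "local_marginal_first_order"
    return(rep_)
  }
  n_vars <- sum(vapply(record$layers, function(l) prod(dim(l$o)[2:3]), 1))
  if (n_vars > max_flip_vars) {
    stop(sprintf("exact-delta re-evaluation over %d spike variables exceeds %d; %s",
                 n_vars, max_flip_vars,
                 "use exact_delta = FALSE on larger nets"))
  }
  B <- record$B; T_ <- record$T
  f_base <- head_loss(net, record, target, loss_mode, want_grads = FALSE)$loss
  degenerate <- FALSE
  coef <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    rl <- record$layers[[l]]
    if (any(rl$p == 0 | rl$p == 1)) degenerate <- TRUE
    cl <- array(0, dim(rl$o))
    for (t in seq_len(T_)) {
      for (m in seq_len(ly$size)) {
        o_s <- rl$o[, m, t]
        f_flip <- counterfactual_loss(net, record, target, l, m, t,
                                      value = 1 - o_s, loss_mode)
        cl[, m, t] <- (2 * o_s - 1) *
          noise_pdf(rl$u[, m, t] - ly$params$v_th, ly$noise) *
          (f_base - f_flip)
      }
    }
    coef[[l]] <- cl
  }
  bw <- nsnn_backward_coef(net, record, coef, per_sample = TRUE)
  dims <- lapply(net$layers, function(ly) dim(ly$W))
  se <- per_sample_se(bw$per_sample, dims, B)
  hg <- NULL; hse <- NULL
  if (net$head$type == "softmax") {
    ps <- head_per_sample_grads(net, record, target, loss_mode)
    K <- net$head$n_class; nL <- utils::tail(net$sizes, 1)
    hg <- list(W = matrix(colMeans(ps$W), K, nL, byrow = TRUE),
               b = colMeans(ps$b))
    hse <- list(W = matrix(apply(ps$W, 2, stats::sd) / sqrt(B), K, nL,
                           byrow = TRUE),
                b = apply(ps$b, 2, stats::sd) / sqrt(B))
  }
  rep_ <- new_gradient_report(bw$layer_grads, hg, "local_marginal_exact", B,
                              se = se)
  rep_$head_se <- hse
  rep_$degenerate <- degenerate
  rep_
}

#' Monte-Carlo mean of a sampled gradient estimator
#'
#' Draws `n_samples` independent rollouts of one input sequence (in chunks,
#' fully vectorized) and accumulates the mean and standard error of the
#' chosen gradient estimator for every parameter. This is the workhorse
#' behind the unbiasedness checks: with `estimator = "local_marginal_exact"`
#' the mean converges to the enumeration gradient for any loss; with
#' `estimator = "ndl"` it does so when the loss is multilinear in the spikes
#' (single spiking stage), and the residual difference otherwise is the
#' estimator's bias.
#'
#' @param net a small [nsnn_network()].
#' @param x_seq `T x n_in` input matrix.
#' @param target target class for a softmax head.
#' @param n_samples number of Monte-Carlo rollouts.
#' @param seed seed; chunk seeds are derived from it.
#' @param estimator `"local_marginal_exact"` or `"ndl"`.
#' @param loss_mode `"mean"` or `"last"`.
#' @param chunk rollouts per vectorized chunk.
#' @return a `"gradient_report"` with per-entry standard errors (`$se` for
#'   layers, `$head_se` for the head).
#' @export
mc_gradient_estimate <- function(net, x_seq, target = NULL, n_samples = 2e5,
                                 seed = 1,
                                 estimator = c("local_marginal_exact", "ndl"),
                                 loss_mode = c("mean", "last"),
                                 chunk = 50000) {
  estimator <- match.arg(estimator)
  loss_mode <- match.arg(loss_mode)
  X1 <- as_x_array(net, x_seq)
  T_ <- dim(X1)[3]
  L <- length(net$layers)
  sizes <- lapply(net$layers, function(ly) dim(ly$W))
  K <- if (net$head$type == "softmax") net$head$n_class else 0L
  nL <- utils::tail(net$sizes, 1)
  acc <- list(layers = lapply(sizes, function(d) {
    list(sW = numeric(d[1] * d[2]), qW = numeric(d[1] * d[2]),
         sb = numeric(d[1]), qb = numeric(d[1]))
  }))
  if (K > 0) acc$head <- list(sW = numeric(K * nL), qW = numeric(K * nL),
                              sb = numeric(K), qb = numeric(K))
  done <- 0L; ci <- 0L
  while (done < n_samples) {
    ci <- ci + 1L
    B <- min(chunk, n_samples - done)
    X <- array(rep(X1, each = B), dim = c(B, dim(X1)[2], T_))
    rec <- nsnn_forward(net, X, seed = derive_seed(seed, ci))
    ps <- if (estimator == "local_marginal_exact") {
      f_base <- head_loss(net, rec, target, loss_mode, want_grads = FALSE)$loss
      coef <- vector("list", L)
      for (l in seq_len(L)) {
        ly <- net$layers[[l]]
        rl <- rec$layers[[l]]
        cl <- array(0, dim(rl$o))
        for (t in seq_len(T_)) {
          for (m in seq_len(ly$size)) {
            o_s <- rl$o[, m, t]
            f_flip <- counterfactual_loss(net, rec, target, l, m, t,
                                          value = 1 - o_s, loss_mode)
            cl[, m, t] <- (2 * o_s - 1) *
              noise_pdf(rl$u[, m, t] - ly$params$v_th, ly$noise) *
              (f_base - f_flip)
          }
        }
        coef[[l]] <- cl
      }
      nsnn_backward_coef(net, rec, coef, per_sample = TRUE)$per_sample
    } else {
      hl <- head_loss(net, rec, target, loss_mode)
      fac <- function(l, x) noise_pdf(x, net$layers[[l]]$noise)
      nsnn_backward(net, rec, hl$dLdoL, fac, per_sample = TRUE)$per_sample
    }
    for (l in seq_len(L)) {
      acc$layers[[l]]$sW <- acc$layers[[l]]$sW + colSums(ps[[l]]$W)
      acc$layers[[l]]$qW <- acc$layers[[l]]$qW + colSums(ps[[l]]$W^2)
      acc$layers[[l]]$sb <- acc$layers[[l]]$sb + colSums(ps[[l]]$b)
      acc$layers[[l]]$qb <- acc$layers[[l]]$qb + colSums(ps[[l]]$b^2)
    }
    if (K > 0) {
      hp <- head_per_sample_grads(net, rec, target, loss_mode)
      acc$head$sW <- acc$head$sW + colSums(hp$W)
      acc$head$qW <- acc$head$qW + colSums(hp$W^2)
      acc$head$sb <- acc$head$sb + colSums(hp$b)
      acc$head$qb <- acc$head$qb + colSums(hp$b^2)
    }
    done <- done + B
  }
  n <- n_samples
  mk <- function(s, q, d) {
    mean_ <- s / n
    se_ <- sqrt(pmax(q / n - mean_^2, 0) / n)
    list(mean = matrix(mean_, d[1], d[2], byrow = TRUE),
         se = matrix(se_, d[1], d[2], byrow = TRUE))
  }
  layers <- vector("list", L); se <- vector("list", L)
  for (l in seq_len(L)) {
    a <- acc$layers[[l]]; d <- sizes[[l]]
    W <- mk(a$sW, a$qW, d)
    layers[[l]] <- list(W = W$mean, b = a$sb / n)
    se[[l]] <- list(W = W$se,
                    b = sqrt(pmax(a$qb / n - (a$sb / n)^2, 0) / n))
  }
  hg <- NULL; hse <- NULL
  if (K > 0) {
    W <- mk(acc$head$sW, acc$head$qW, c(K, nL))
    hg <- list(W = W$mean, b = acc$head$sb / n)
    hse <- list(W = W$se,
                b = sqrt(pmax(acc$head$qb / n - (acc$head$sb / n)^2, 0) / n))
  }
  rep_ <- new_gradient_report(layers, hg, estimator, n, se = se)
  rep_$head_se <- hse
  rep_
}

#' Bias/variance table for the gradient estimators
#'
#' Runs the enumeration gradient as ground truth, then each sampled estimator
#' at `n_samples` rollouts, and tabulates per parameter block the maximum
#' absolute bias, the maximum bias in standard-error units, and the mean
#' Monte-Carlo variance. Deterministic given the seed. The exact-delta
#' local-marginalization rows are expected to be statistically unbiased; the
#' NDL rows report whatever first-order bias the loss induces.
#'
#' @inheritParams mc_gradient_estimate
#' @param estimators subset of
#'   `c("enumeration", "local_marginal_exact", "ndl")`.
#' @return a `data.frame` with columns `estimator`, `block`, `max_abs_bias`,
#'   `max_bias_z`, `mean_variance`, `n_samples`.
#' @export
bias_variance_report <- function(net, x_seq, target = NULL,
                                 estimators = c("enumeration",
                                                "local_marginal_exact", "ndl"),
                                 n_samples = 2e4, seed = 1,
                                 loss_mode = c("mean", "last")) {
  loss_mode <- match.arg(loss_mode)
  estimators <- match.arg(estimators, several.ok = TRUE)
  truth <- exact_gradient(net, x_seq, target, loss_mode)
  rows <- list()
  block_names <- c(sprintf("layer%d", seq_along(net$layers)),
                   if (!is.null(truth$head)) "head")
  for (est in estimators) {
    if (est == "enumeration") {
      for (bn in block_names) {
        rows[[length(rows) + 1]] <- data.frame(
          estimator = est, block = bn, max_abs_bias = 0, max_bias_z = 0,
          mean_variance = 0, n_samples = truth$n_samples)
      }
      next
    }
    mc <- mc_gradient_estimate(net, x_seq, target, n_samples, seed,
                               estimator = est, loss_mode = loss_mode)
    for (l in seq_along(net$layers)) {
      bias <- c(mc$layers[[l]]$W - truth$layers[[l]]$W,
                mc$layers[[l]]$b - truth$layers[[l]]$b)
      ses <- c(mc$se[[l]]$W, mc$se[[l]]$b)
      rows[[length(rows) + 1]] <- data.frame(
        estimator = est, block = sprintf("layer%d", l),
        max_abs_bias = max(abs(bias)),
        max_bias_z = max(abs(bias) / pmax(ses, 1e-12)),
        mean_variance = mean((ses * sqrt(n_samples))^2),
        n_samples = n_samples)
    }
    if (!is.null(truth$head)) {
      bias <- c(mc$head$W - truth$head$W, mc$head$b - truth$head$b)
      ses <- c(mc$head_se$W, mc$head_se$b)
      rows[[length(rows) + 1]] <- data.frame(
        estimator = est, block = "head",
        max_abs_bias = max(abs(bias)),
        max_bias_z = max(abs(bias) / pmax(ses, 1e-12)),
        mean_variance = mean((ses * sqrt(n_samples))^2),
        n_samples = n_samples)
    }
  }
  do.call(rbind, rows)
}
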