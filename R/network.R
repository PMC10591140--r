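#' Predictive heads
#'
#' A head decodes the final spiking layer's output into a loss (and, for the
#' softmax head, class probabilities). `head_softmax` is an affine map to
#' class scores followed by softmax and cross-entropy against an integer
#' target. `head_custom` wraps an arbitrary differentiable loss of the final
#' spike vector; `f` maps a `B x n` spike matrix to a length-`B` vector of
#' losses and `grad` returns the `B x n` matrix of derivatives. Custom heads
#' carry no parameters and ignore targets; they are primarily used by the
#' gradient-estimation oracles (e.g. multilinear losses).
#'
#' @param n_class number of classes for the softmax head.
#' @param f,grad vectorized loss and gradient functions (see Details).
#' @return object of class `"nsnn_head"`.
#' @export
head_softmax <- function(n_class) {
  stopifnot(n_class >= 2)
  structure(list(type = "softmax", n_class = as.integer(n_class),
                 W = NULL, b = NULL), class = "nsnn_head")
}

#' @rdname head_softmax
#' @export
head_custom <- function(f, grad) {
  stopifnot(is.function(f), is.function(grad))
  structure(list(type = "custom", f = f, grad = grad), class = "nsnn_head")
}

#' Construct a layered noisy spiking neural network
#'
#' Builds a feedforward network of noisy LIF layers. Layer `l` applies an
#' affine transform of the previous layer's spike vector (layer 1 transforms
#' the real-valued input) to obtain the synaptic drive, accumulates it into
#' the leaky membrane, and fires stochastically with probability
#' `noise_cdf(u - v_th)`. Spike states across layers, neurons and time
#' factorize as a Bayesian network, which is what makes exact enumeration and
#' local-marginalization gradient estimation possible on small instances.
#'
#' Within a time step, layers are evaluated in order `1..L` and layer `l`
#' consumes the *same-step* spikes of layer `l - 1`; the only unit delay is
#' the membrane recurrence `u^t = tau * u^{t-1} + drive`.
#'
#' @param n_in input dimension.
#' @param layer_sizes integer vector of spiking-layer sizes, `l = 1..L`.
#' @param head a [head_softmax()] or [head_custom()] object.
#' @param noise a [noise_model()] shared by all layers, or a list of one
#'   model per layer.
#' @param params a [neuron_params()] shared by all layers.
#' @param init_gain multiplier on the `1/sqrt(fan_in)` weight-initialization
#'   scale.
#' @param init_bias initial bias value for all spiking layers (a mildly
#'   positive bias puts membranes within reach of threshold at start).
#' @param seed seed for weight initialization.
#' @return object of class `"nsnn"`.
#' @examples
#' net <- nsnn_network(4, c(6, 3), head = head_softmax(2), seed = 1)
#' rec <- rollout(net, matrix(0.5, nrow = 5, ncol = 4), seed = 2)
#' @export
nsnn_network <- function(n_in, layer_sizes, head = head_softmax(2),
                         noise = noise_model(), params = neuron_params(),
                         init_gain = 1, init_bias = 0.2, seed = NULL) {
  stopifnot(length(layer_sizes) >= 1, all(layer_sizes >= 1))
  if (inherits(noise, "noise_model")) {
    noise <- rep(list(noise), length(layer_sizes))
  }
  stopifnot(length(noise) == length(layer_sizes))
  L <- length(layer_sizes)
  fan <- c(n_in, layer_sizes)
  layers <- with_seed(seed, {
    lapply(seq_len(L), function(l) {
      W <- matrix(stats::rnorm(layer_sizes[l] * fan[l],
                               sd = init_gain / sqrt(fan[l])),
                  nrow = layer_sizes[l], ncol = fan[l])
      list(W = W, b = rep(init_bias, layer_sizes[l]),
           noise = noise[[l]], params = params, size = layer_sizes[l])
    })
  })
  if (head$type == "softmax" && is.null(head$W)) {
    head$W <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 1L),
      matrix(stats::rnorm(head$n_class * layer_sizes[L],
                          sd = 1 / sqrt(layer_sizes[L])),
             nrow = head$n_class, ncol = layer_sizes[L]))
    head$b <- rep(0, head$n_class)
  }
  structure(list(n_in = n_in, sizes = as.integer(layer_sizes),
                 layers = layers, head = head),
            class = "nsnn")
}

#' @export
print.nsnn <- function(x, ...) {
  cat(sprintf("Noisy spiking neural network: %d -> %s spiking neurons",
              x$n_in, paste(x$sizes, collapse = " -> ")))
  if (x$head$type == "softmax") cat(sprintf(" -> softmax head (%d classes)", x$head$n_class))
  cat("\n")
  fams <- vapply(x$layers, function(l) {
    if (l$noise$family == "none") "none" else sprintf("%s(%g)", l$noise$family, l$noise$scale)
  }, "")
  cat("  membrane noise per layer:", paste(fams, collapse = ", "), "\n")
  p <- x$layers[[1]]$params
  cat(sprintf("  neuron: tau = %g, v_th = %g, u_reset = %g\n", p$tau, p$v_th, p$u_reset))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Batched forward engine. X is a (B, n_in, T) array. Spiking decisions use
# uniform draws xi (stored in the record) so that counterfactual re-rollouts
# can reuse the same randomness (common random numbers).
#
# o_forced: list per layer of (B,n,T) binary arrays -> teacher-forced pass.
# clamp: list(l, t, m, value) forcing o[, m, t] of layer l to `value`
#   (scalar or length-B), applied before reset, so downstream layers, later
#   membranes and resets all see the clamped value.
# flip_prob: spike-state perturbation level beta; every sampled spike state is
#   flipped independently with probability beta (after sampling, before
#   reset). flip_layers: "all" or "hidden" (exclude final spiking layer).
nsnn_forward <- function(net, X, seed = NULL, xi = NULL, o_forced = NULL,
                         clamp = NULL, flip_prob = 0,
                         flip_layers = c("all", "hidden")) {
  flip_layers <- match.arg(flip_layers)
  d <- dim(X)
  if (length(d) != 3L || d[2] != net$n_in) {
    stop(sprintf("input must be a (B, %d, T) array (layer 1 expects %d inputs)",
                 net$n_in, net$n_in))
  }
  check_finite(X, "input")
  B <- d[1]; T_ <- d[3]; L <- length(net$layers)
  draw_xi <- is.null(xi) && is.null(o_forced)
  rec_layers <- lapply(net$sizes, function(n) {
    list(drive = array(NA_real_, c(B, n, T_)), u = array(NA_real_, c(B, n, T_)),
         p = array(NA_real_, c(B, n, T_)), o = array(NA_real_, c(B, n, T_)),
         xi = if (draw_xi || !is.null(xi)) array(NA_real_, c(B, n, T_)) else NULL)
  })
  run <- function() {
    u_carry <- lapply(net$sizes, function(n) matrix(0, B, n))
    for (t in seq_len(T_)) {
      input <- slab(X, t)
      for (l in seq_len(L)) {
        ly <- net$layers[[l]]
        n <- ly$size
        drive <- tcrossprod(input, ly$W) + rep(ly$b, each = B)
        u_acc <- ly$params$tau * u_carry[[l]] + drive
        p <- matrix(noise_cdf(u_acc - ly$params$v_th, ly$noise), B, n)
        if (!is.null(o_forced)) {
          o <- slab(o_forced[[l]], t)
        } else {
          x_lt <- if (is.null(xi)) matrix(stats::runif(B * n), B, n)
                  else slab(xi[[l]], t)
          rec_layers[[l]]$xi[, , t] <<- x_lt
          o <- (x_lt < p) * 1
        }
        if (!is.null(clamp) && clamp$l == l && clamp$t == t) {
          o[, clamp$m] <- clamp$value
        }
        if (flip_prob > 0 && (flip_layers == "all" || l < L)) {
          fl <- (matrix(stats::runif(B * n), B, n) < flip_prob) * 1
          o <- o + fl * (1 - 2 * o)
        }
        u_carry[[l]] <- (1 - o) * u_acc + o * ly$params$u_reset
        rec_layers[[l]]$drive[, , t] <<- drive
        rec_layers[[l]]$u[, , t] <<- u_acc
        rec_layers[[l]]$p[, , t] <<- p
        rec_layers[[l]]$o[, , t] <<- o
        input <- o
      }
    }
  }
  with_seed(seed, run())
  structure(list(layers = rec_layers, X = X, B = B, T = T_, seed = seed),
            class = "nsnn_rollout")
}

#' Roll a network out over a stimulus sequence
#'
#' Simulates all layers for `T` steps on one input sequence, recording per
#' step and layer the synaptic drive, accumulated membrane potential, firing
#' probability and sampled spikes (plus the underlying uniform draws, which
#' the local-marginalization estimator reuses for counterfactual
#' re-evaluation). Identical seeds give bit-identical records.
#'
#' @param net an [nsnn_network()].
#' @param x_seq `T x n_in` matrix of inputs (rows are time steps 1..T;
#'   a vector is taken as `T` steps of a 1-d input).
#' @param seed integer seed for the spiking randomness.
#' @param flip_prob optional spike-state perturbation level `beta`: every
#'   sampled hidden spike state is flipped independently with probability
#'   `beta`, and downstream layers, membranes and resets consume the flipped
#'   values (the perturbation enters the dynamics, not just the readout).
#' @param flip_layers `"all"` (default, including the final spiking layer) or
#'   `"hidden"`.
#' @return an object of class `"nsnn_rollout"`; arrays are indexed
#'   `[sample, neuron, time]` with a singleton sample dimension.
#' @seealso [rollout_batch()] for many sequences or repeated trials at once.
#' @export
rollout <- function(net, x_seq, seed = NULL, flip_prob = 0,
                    flip_layers = c("all", "hidden")) {
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, ncol = 1)
  X <- array(t(x_seq), dim = c(1, ncol(x_seq), nrow(x_seq)))
  # t(x_seq) is n_in x T; filling a (1, n_in, T) array column-major matches.
  nsnn_forward(net, X, seed = seed, flip_prob = flip_prob,
               flip_layers = match.arg(flip_layers))
}

#' @rdname rollout
#' @param X `(B, n_in, T)` array of `B` input sequences (use identical rows
#'   for repeated trials of one stimulus).
#' @export
rollout_batch <- function(net, X, seed = NULL, flip_prob = 0,
                          flip_layers = c("all", "hidden")) {
  nsnn_forward(net, X, seed = seed, flip_prob = flip_prob,
               flip_layers = match.arg(flip_layers))
}

#' @export
print.nsnn_rollout <- function(x, ...) {
  cat(sprintf("NSNN rollout: %d sample(s), %d step(s), layer sizes %s\n",
              x$B, x$T, paste(vapply(x$layers, function(l) dim(l$o)[2], 1L),
                              collapse = ", ")))
  invisible(x)
}

#' Joint log-probability of a sampled spike configuration
#'
#' The spike states of an NSNN factorize as a Bayesian network: the joint
#' probability of a recorded configuration is the product over layers,
#' neurons and steps of the Bernoulli probabilities of the sampled spike
#' states. If any recorded state has probability exactly 0 under the network
#' (possible only in the deterministic limit), the result is `-Inf`.
#'
#' @param net the network that produced the record (identical parameters).
#' @param record an `"nsnn_rollout"`.
#' @return numeric vector of length `B` (scalar for a single rollout), each
#'   entry `<= 0`.
#' @export
joint_log_prob <- function(net, record) {
  stopifnot(inherits(record, "nsnn_rollout"))
  lp <- numeric(record$B)
  for (l in seq_along(record$layers)) {
    p <- record$layers[[l]]$p
    o <- record$layers[[l]]$o
    po <- o * p + (1 - o) * (1 - p)
    lpo <- ifelse(po > 0, log(po), -Inf)
    lp <- lp + apply(lpo, 1, sum)
  }
  lp
}

# softmax over rows of a B x K matrix
row_softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Class predictions from a rollout
#'
#' Applies the softmax head to the final spiking layer's output at every step
#' and averages the per-step class probabilities over time.
#'
#' @param net network with a softmax head.
#' @param record an `"nsnn_rollout"` from `net`.
#' @return list with `per_step` (`B x K x T` array of probabilities) and
#'   `average` (`B x K`, time-averaged prediction vectors).
#' @export
nsnn_predict <- function(net, record) {
  stopifnot(inherits(record, "nsnn_rollout"))
  if (net$head$type != "softmax") stop("prediction requires a softmax head")
  L <- length(net$layers)
  oL <- record$layers[[L]]$o
  K <- net$head$n_class
  per_step <- array(NA_real_, c(record$B, K, record$T))
  for (t in seq_len(record$T)) {
    S <- tcrossprod(slab(oL, t), net$head$W) + rep(net$head$b, each = record$B)
    per_step[, , t] <- row_softmax(S)
  }
  avg <- matrix(apply(per_step, c(1, 2), mean), record$B, K)
  list(per_step = per_step, average = avg)
}

# ---------------------------------------------------------------------------
# Head loss and its gradient with respect to the final layer's spikes.
# Returns per-sample losses, dLdoL (B, nL, T), and (softmax only) head
# parameter gradients averaged with `sample_weights` (default 1/B each).
# loss_mode "mean": every step weighted 1/T; "last": only the final step.
head_loss <- function(net, record, target = NULL,
                      loss_mode = c("mean", "last"), sample_weights = NULL,
                      want_grads = TRUE) {
  loss_mode <- match.arg(loss_mode)
  B <- record$B; T_ <- record$T
  L <- length(net$layers)
  oL <- record$layers[[L]]$o
  nL <- dim(oL)[2]
  wts <- if (loss_mode == "mean") rep(1 / T_, T_) else c(rep(0, T_ - 1), 1)
  sw <- sample_weights %||% rep(1 / B, B)
  loss <- numeric(B)
  dLdoL <- array(0, c(B, nL, T_))
  hd <- net$head
  if (hd$type == "softmax") {
    if (is.null(target)) stop("softmax head requires a `target` class vector")
    y <- as.integer(rep_len(target, B))
    if (any(y < 1 | y > hd$n_class)) stop("targets must be in 1..n_class")
    gW <- matrix(0, hd$n_class, nL); gb <- numeric(hd$n_class)
    Y <- matrix(0, B, hd$n_class); Y[cbind(seq_len(B), y)] <- 1
    for (t in seq_len(T_)) {
      if (wts[t] == 0) next
      Ot <- slab(oL, t)
      S <- tcrossprod(Ot, hd$W) + rep(hd$b, each = B)
      P <- row_softmax(S)
      loss <- loss - wts[t] * log(pmax(P[cbind(seq_len(B), y)], 1e-300))
      if (want_grads) {
        D <- wts[t] * (P - Y)
        dLdoL[, , t] <- D %*% hd$W
        gW <- gW + crossprod(D * sw, Ot)
        gb <- gb + colSums(D * sw)
      }
    }
    list(loss = loss, dLdoL = dLdoL, head_grads = list(W = gW, b = gb))
  } else {
    for (t in seq_len(T_)) {
      if (wts[t] == 0) next
      Ot <- slab(oL, t)
      loss <- loss + wts[t] * hd$f(Ot)
      if (want_grads) dLdoL[, , t] <- wts[t] * matrix(hd$grad(Ot), B, nL)
    }
    list(loss = loss, dLdoL = dLdoL, head_grads = NULL)
  }
}

# ---------------------------------------------------------------------------
# Backward pass through the unrolled dynamics (BPTT). The derivative of a
# spike with respect to its membrane is replaced by `factor_fun(l, x)`
# evaluated at x = u - v_th (noise density for NDL, surrogate function for
# SGL). The reset path is detached: the carried-state derivative is
# tau * (1 - o^t), with o treated as a constant.
#
# dLdoL: (B, nL, T) loss gradient w.r.t. final-layer spikes.
# Returns layer_grads (weighted means over samples), optionally per-sample
# gradients (B x n_params matrices per block) and the input gradient.
nsnn_backward <- function(net, record, dLdoL, factor_fun,
                          sample_weights = NULL, per_sample = FALSE,
                          want_input_grad = FALSE) {
  B <- record$B; T_ <- record$T; L <- length(net$layers)
  sw <- sample_weights %||% rep(1 / B, B)
  delta_o <- dLdoL
  layer_grads <- vector("list", L)
  per_samp <- if (per_sample) vector("list", L) else NULL
  input_grad <- if (want_input_grad) array(0, dim(record$X)) else NULL
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    n <- ly$size
    rl <- record$layers[[l]]
    delta_u <- array(0, c(B, n, T_))
    nxt <- matrix(0, B, n)
    for (t in rev(seq_len(T_))) {
      fac <- matrix(factor_fun(l, slab(rl$u, t) - ly$params$v_th), B, n)
      d <- slab(delta_o, t) * fac + ly$params$tau * (1 - slab(rl$o, t)) * nxt
      delta_u[, , t] <- d
      nxt <- d
    }
    m <- ncol(ly$W)
    gW <- matrix(0, n, m); gb <- numeric(n)
    if (per_sample) {
      psW <- matrix(0, B, n * m); psb <- matrix(0, B, n)
    }
    below <- if (l > 1) array(0, c(B, dim(record$layers[[l - 1]]$o)[2], T_)) else NULL
    for (t in seq_len(T_)) {
      inp <- if (l == 1) slab(record$X, t) else slab(record$layers[[l - 1]]$o, t)
      d <- slab(delta_u, t)
      gW <- gW + crossprod(d * sw, inp)
      gb <- gb + colSums(d * sw)
      if (per_sample) {
        for (i in seq_len(n)) {
          psW[, ((i - 1) * m + 1):(i * m)] <-
            psW[, ((i - 1) * m + 1):(i * m)] + d[, i] * inp
        }
        psb <- psb + d
      }
      if (l > 1) below[, , t] <- d %*% ly$W
      else if (want_input_grad) input_grad[, , t] <- d %*% ly$W
    }
    layer_grads[[l]] <- list(W = gW, b = gb)
    if (per_sample) per_samp[[l]] <- list(W = psW, b = psb)
    if (l > 1) delta_o <- below
  }
  list(layer_grads = layer_grads, per_sample = per_samp,
       input_grad = input_grad)
}

# ---------------------------------------------------------------------------
# Teacher-forced gradient accumulation: given per-neuron-per-step coefficients
# c[l][, m, t], computes sum_{m,t} c * d u_{l,m}^t / d theta_l exactly along
# the recorded spike path (spikes are conditioned variables here, so the reset
# mixing (1 - o) is an exact derivative, not a detachment). No cross-layer
# propagation: u_l depends only on theta_l once the spikes are fixed.
nsnn_backward_coef <- function(net, record, coef, sample_weights = NULL,
                               per_sample = FALSE) {
  B <- record$B; T_ <- record$T; L <- length(net$layers)
  sw <- sample_weights %||% rep(1 / B, B)
  layer_grads <- vector("list", L)
  per_samp <- if (per_sample) vector("list", L) else NULL
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    n <- ly$size; m <- ncol(ly$W)
    rl <- record$layers[[l]]
    gW <- matrix(0, n, m); gb <- numeric(n)
    if (per_sample) { psW <- matrix(0, B, n * m); psb <- matrix(0, B, n) }
    nxt <- matrix(0, B, n)
    deltas <- vector("list", T_)
    for (t in rev(seq_len(T_))) {
      d <- slab(coef[[l]], t) + ly$params$tau * (1 - slab(rl$o, t)) * nxt
      deltas[[t]] <- d
      nxt <- d
    }
    for (t in seq_len(T_)) {
      inp <- if (l == 1) slab(record$X, t) else slab(record$layers[[l - 1]]$o, t)
      d <- deltas[[t]]
      gW <- gW + crossprod(d * sw, inp)
      gb <- gb + colSums(d * sw)
      if (per_sample) {
        for (i in seq_len(n)) {
          psW[, ((i - 1) * m + 1):(i * m)] <-
            psW[, ((i - 1) * m + 1):(i * m)] + d[, i] * inp
        }
        psb <- psb + d
      }
    }
    layer_grads[[l]] <- list(W = gW, b = gb)
    if (per_sample) per_samp[[l]] <- list(W = psW, b = psb)
  }
  list(layer_grads = layer_grads, per_sample = per_samp)
}

# Flatten / set network parameters (layers + softmax head) as one vector.
# Used by finite-difference checks and the optimizer.
nsnn_get_params <- function(net) {
  v <- numeric(0)
  for (ly in net$layers) v <- c(v, as.numeric(ly$W), ly$b)
  if (net$head$type == "softmax") v <- c(v, as.numeric(net$head$W), net$head$b)
  v
}

nsnn_set_params <- function(net, v) {
  i <- 0L
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    nw <- length(ly$W)
    net$layers[[l]]$W <- matrix(v[i + seq_len(nw)], nrow(ly$W), ncol(ly$W))
    i <- i + nw
    nb <- length(ly$b)
    net$layers[[l]]$b <- v[i + seq_len(nb)]
    i <- i + nb
  }
  if (net$head$type == "softmax") {
    nw <- length(net$head$W)
    net$head$W <- matrix(v[i + seq_len(nw)], nrow(net$head$W), ncol(net$head$W))
    i <- i + nw
    net$head$b <- v[i + seq_len(length(net$head$b))]
  }
  net
}

# Flatten a gradient report's blocks into one vector in the same order as
# nsnn_get_params.
flatten_grads <- function(layer_grads, head_grads = NULL) {
  v <- numeric(0)
  for (g in layer_grads) v <- c(v, as.numeric(g$W), g$b)
  if (!is.null(head_grads)) v <- c(v, as.numeric(head_grads$W), head_grads$b)
  v
}
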