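# Perturbation operators for robustness evaluation: input-level adversarial
# attacks (FGSM and direct optimization on the L2 sphere), event dropping for
# event-stream inputs, and spike-state flips inside the network.

as_net <- function(x) if (inherits(x, "nsnn_fit")) x$net else x

# Gradient of the loss w.r.t. the input sequence from one (seeded) rollout.
input_gradient <- function(net, x_seq, target, seed = NULL, sg = NULL,
                           loss_mode = "mean") {
  net <- as_net(net)
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, ncol = net$n_in)
  rec <- rollout(net, x_seq, seed = seed)
  hl <- head_loss(net, rec, target, loss_mode)
  fac <- if (is.null(sg)) {
    function(l, x) noise_pdf(x, net$layers[[l]]$noise)
  } else {
    sgl <- if (inherits(sg, "surrogate_spec")) rep(list(sg), length(net$layers)) else sg
    function(l, x) surrogate_value(x, sgl[[l]])
  }
  bw <- nsnn_backward(net, rec, hl$dLdoL, fac, want_input_grad = TRUE)
  g <- bw$input_grad            # (1, n_in, T)
  t(matrix(g, dim(g)[2], dim(g)[3]))   # back to T x n_in
}

#' Fast gradient sign method (FGSM) input attack
#'
#' Constructs the adversarial input `x + gamma * sign(grad_x loss)` from a
#' single backward pass. The max-norm of the perturbation is exactly `gamma`
#' wherever the input gradient is nonzero, and the input is untouched where
#' it is zero.
#'
#' @param net an [nsnn_network()] or `"nsnn_fit"`.
#' @param x_seq `T x n_in` input matrix.
#' @param target true class label (the loss being increased).
#' @param gamma attack budget (max-norm).
#' @param seed rollout seed for the gradient evaluation.
#' @param sg optional [surrogate_spec()] for deterministic networks.
#' @param loss_mode `"mean"` or `"last"`.
#' @return perturbed `T x n_in` matrix.
#' @export
fgsm <- function(net, x_seq, target, gamma, seed = 1, sg = NULL,
                 loss_mode = "mean") {
  stopifnot(gamma >= 0)
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, ncol = as_net(net)$n_in)
  if (gamma == 0) return(x_seq)
  g <- input_gradient(net, x_seq, target, seed, sg, loss_mode)
  x_seq + gamma * sign(g)
}

#' Direct-optimization (DO) input attack on the L2 sphere
#'
#' Solves `argmax_{||dx||_2 = gamma} loss(x + dx)` by iterative gradient
#' ascent: the perturbation starts at zero and after every step is
#' renormalized onto the sphere of radius `gamma`. The default solver is
#' adaptive-moment ascent with learning rate 0.002 for 30 iterations; set
#' `adaptive = FALSE` for plain gradient ascent with the same step size. If
#' the gradient vanishes at every iterate the attack returns a random point
#' on the sphere and flags it (attribute `"random_fallback"`).
#'
#' @inheritParams fgsm
#' @param iters,step_size solver settings.
#' @param adaptive use adaptive-moment (Adam-style) ascent.
#' @return perturbed `T x n_in` matrix with `||x_adv - x||_2 = gamma` (to
#'   1e-6); the perturbation itself is attached as attribute `"delta"`.
#' @export
direct_opt_attack <- function(net, x_seq, target, gamma, iters = 30,
                              step_size = 0.002, adaptive = TRUE, seed = 1,
                              sg = NULL, loss_mode = "mean") {
  stopifnot(gamma >= 0, iters >= 1)
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, ncol = as_net(net)$n_in)
  if (gamma == 0) return(x_seq)
  dx <- matrix(0, nrow(x_seq), ncol(x_seq))
  m1 <- dx; m2 <- dx
  any_grad <- FALSE
  for (it in seq_len(iters)) {
    g <- input_gradient(net, x_seq + dx, target, derive_seed(seed, it), sg,
                        loss_mode)
    if (any(g != 0)) any_grad <- TRUE
    if (adaptive) {
      m1 <- 0.9 * m1 + 0.1 * g
      m2 <- 0.999 * m2 + 0.001 * g^2
      step <- step_size * (m1 / (1 - 0.9^it)) /
        (sqrt(m2 / (1 - 0.999^it)) + 1e-8)
    } else {
      step <- step_size * g
    }
    dx <- dx + step
    nrm <- sqrt(sum(dx^2))
    if (nrm > 0) dx <- dx * (gamma / nrm)
  }
  fallback <- FALSE
  if (!any_grad || sqrt(sum(dx^2)) == 0) {
    dx <- with_seed(derive_seed(seed, 999L),
                    matrix(stats::rnorm(length(dx)), nrow(dx), ncol(dx)))
    dx <- dx * (gamma / sqrt(sum(dx^2)))
    fallback <- TRUE
    warning("input gradient vanished at every iterate; returning a random ",
            "point on the attack sphere")
  }
  out <- x_seq + dx
  attr(out, "delta") <- dx
  attr(out, "random_fallback") <- fallback
  out
}

#' Randomly drop events from an event table
#'
#' Input-level perturbation for event-stream data: every event is kept
#' independently with probability `1 - rho` (random drop over space and time
#' jointly, i.e. a uniform per-event Bernoulli). Row order is preserved.
#' Targeted variants restrict the drop to a random time window
#' (`mode = "temporal"`) or a random spatial half (`mode = "spatial"`) but
#' keep the same expected overall drop fraction within the targeted region.
#'
#' @param events an event table (`data.frame` with columns `t, x, y,
#'   polarity`, as from [gen_event_stream()]).
#' @param rho drop probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param mode `"random"` (default), `"temporal"` or `"spatial"`.
#' @return the thinned event table (attributes preserved).
#' @export
event_drop <- function(events, rho, seed = 1,
                       mode = c("random", "temporal", "spatial")) {
  stopifnot(rho >= 0, rho <= 1)
  mode <- match.arg(mode)
  if (rho == 0 || nrow(events) == 0) return(events)
  keep <- with_seed(seed, {
    at_risk <- switch(mode,
      random = rep(TRUE, nrow(events)),
      temporal = {
        tr <- range(events$t)
        w0 <- stats::runif(1, tr[1], tr[2])
        events$t >= w0 & events$t <= w0 + 0.5 * (tr[2] - tr[1])
      },
      spatial = {
        xr <- range(events$x)
        events$x >= stats::runif(1, xr[1], xr[2] / 2) + 0 &
          events$x <= xr[2]
      })
    drop <- at_risk & (stats::runif(nrow(events)) < rho)
    !drop
  })
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(attributes(events)), c("names", "row.names", "class"))) {
    attr(out, a) <- attr(events, a)
  }
  out
}

#' Flip binary spike states at random
#'
#' Each 0/1 entry is flipped independently with probability `beta`
#' (spike-to-silence and silence-to-spike are equally likely to occur, both
#' governed by the single level `beta`). To inject flips *into the dynamics*
#' of a running network — so that downstream layers, membranes and resets
#' consume the flipped states — use the `flip_prob` argument of [rollout()]
#' instead; this function perturbs a stored raster or array.
#'
#' @param spikes binary vector, matrix or array.
#' @param beta flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return perturbed object of the same shape.
#' @export
spike_flip <- function(spikes, beta, seed = 1) {
  stopifnot(beta >= 0, beta <= 1)
  if (!all(spikes %in% c(0, 1))) stop("`spikes` must be binary")
  if (beta == 0) return(spikes)
  fl <- with_seed(seed, stats::runif(length(spikes)) < beta)
  out <- spikes
  out[fl] <- 1 - out[fl]
  out
}

#' Accuracy and loss under spike-state perturbation
#'
#' Evaluates a model on a labelled dataset while flipping hidden spike
#' states during the rollout with probability `beta` (the perturbation
#' enters the dynamics). Used for the robustness comparisons between noisy
#' and deterministic networks.
#'
#' @param net an [nsnn_network()] or `"nsnn_fit"`.
#' @param dataset list with `x` (`(N, n_in, T)` array) and `y` labels.
#' @param beta flip probability.
#' @param seed rollout seed.
#' @param flip_layers `"all"` or `"hidden"`.
#' @return list with `accuracy` and mean `loss`.
#' @export
perturbed_accuracy <- function(net, dataset, beta, seed = 1,
                               flip_layers = c("all", "hidden")) {
  net <- as_net(net)
  flip_layers <- match.arg(flip_layers)
  rec <- nsnn_forward(net, dataset$x, seed = seed, flip_prob = beta,
                      flip_layers = flip_layers)
  y <- as.integer(dataset$y)
  hl <- head_loss(net, rec, y, want_grads = FALSE)
  pred <- nsnn_predict(net, rec)$average
  list(accuracy = mean(max.col(pred, ties.method = "first") == y),
       loss = mean(hl$loss))
}
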