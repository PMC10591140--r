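#' Surrogate-gradient specification
#'
#' A surrogate gradient is the smooth stand-in for the derivative of the
#' spike function used by surrogate-gradient learning (SGL) in deterministic
#' SNNs. Under noise-driven learning these functions are not ad hoc: each
#' shape is the membrane-noise density of a matching noise family, up to a
#' proportionality constant.
#'
#' @param shape `"erf_like"` (Gaussian-bell, matching Gaussian noise),
#'   `"sigmoid_derivative"` (matching logistic noise) or `"rectangular"`
#'   (matching uniform noise).
#' @param width width parameter: the standard deviation / logistic scale /
#'   half-width of the matching noise family.
#' @param height peak value at 0. Defaults to the matching noise density's
#'   peak, in which case the surrogate *is* that density and SGL coincides
#'   with NDL exactly.
#' @return object of class `"surrogate_spec"`.
#' @export
surrogate_spec <- function(shape = c("erf_like", "sigmoid_derivative", "rectangular"),
                           width, height = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(width), width > 0)
  if (is.null(height)) {
    height <- switch(shape,
      erf_like = 1 / (width * sqrt(2 * pi)),
      sigmoid_derivative = 1 / (4 * width),
      rectangular = 1 / (2 * width))
  }
  stopifnot(is.numeric(height), height > 0)
  structure(list(shape = shape, width = width, height = height),
            class = "surrogate_spec")
}

#' Evaluate a surrogate gradient function
#'
#' @param x membrane distance(s) from threshold.
#' @param sg a [surrogate_spec()].
#' @return nonnegative values, symmetric about 0 and maximal at 0.
#' @export
surrogate_value <- function(x, sg) {
  stopifnot(inherits(sg, "surrogate_spec"))
  switch(sg$shape,
    erf_like = sg$height * exp(-x^2 / (2 * sg$width^2)),
    sigmoid_derivative = sg$height * 4 * sg$width *
      stats::dlogis(x, scale = sg$width),
    rectangular = sg$height * as.numeric(abs(x) <= sg$width))
}

#' Noise/surrogate correspondence
#'
#' `surrogate_from_noise` maps a membrane-noise model to the surrogate
#' gradient whose backward pass is identical to noise-driven learning with
#' that noise: the surrogate is the noise density (Gaussian noise gives the
#' erf-like bell, logistic gives the sigmoid derivative, uniform gives the
#' rectangle), with height equal to the density's peak.
#'
#' `noise_from_surrogate` inverts the map: given a surrogate shape it returns
#' the noise family whose density is proportional to it, plus the
#' proportionality constant, which can be absorbed into the learning rate.
#' For example the common erf surrogate \eqn{(1/\pi)\exp(-x^2)} corresponds
#' to Gaussian noise with \eqn{\sigma = 1/\sqrt2} and multiplier
#' \eqn{1/\sqrt\pi}.
#'
#' @param nm a [noise_model()] with `family != "none"`.
#' @param sg a [surrogate_spec()].
#' @return `surrogate_from_noise`: a `surrogate_spec`. `noise_from_surrogate`:
#'   list with the `noise_model` and the scalar `lr_multiplier`.
#' @export
surrogate_from_noise <- function(nm) {
  stopifnot(inherits(nm, "noise_model"))
  if (nm$family == "none") stop("deterministic neurons have no matching surrogate")
  shape <- switch(nm$family, gaussian = "erf_like",
                  logistic = "sigmoid_derivative", uniform = "rectangular")
  surrogate_spec(shape, width = nm$scale, height = noise_pdf(0, nm))
}

#' @rdname surrogate_from_noise
#' @export
noise_from_surrogate <- function(sg) {
  stopifnot(inherits(sg, "surrogate_spec"))
  family <- switch(sg$shape, erf_like = "gaussian",
                   sigmoid_derivative = "logistic", rectangular = "uniform")
  nm <- noise_model(family, scale = sg$width)
  list(noise = nm, lr_multiplier = sg$height / noise_pdf(0, nm))
}

# ---------------------------------------------------------------------------

new_gradient_report <- function(layers, head, estimator, n_samples,
                                se = NULL) {
  structure(list(layers = layers, head = head, estimator = estimator,
                 n_samples = n_samples, se = se),
            class = "gradient_report")
}

#' @export
print.gradient_report <- function(x, ...) {
  cat(sprintf("Gradient report (estimator = %s, n_samples = %d)\n",
              x$estimator, x$n_samples))
  for (l in seq_along(x$layers)) {
    g <- x$layers[[l]]
    cat(sprintf("  layer %d: |gW|_max = %.4g, |gb|_max = %.4g\n",
                l, max(abs(g$W)), max(abs(g$b))))
  }
  if (!is.null(x$head)) {
    cat(sprintf("  head:    |gW|_max = %.4g, |gb|_max = %.4g\n",
                max(abs(x$head$W)), max(abs(x$head$b))))
  }
  invisible(x)
}

# Standard errors of the sample-mean gradient from per-sample gradient blocks.
per_sample_se <- function(per_samp, layer_dims, B) {
  lapply(seq_along(per_samp), function(l) {
    n <- layer_dims[[l]][1]; m <- layer_dims[[l]][2]
    seW <- apply(per_samp[[l]]$W, 2, stats::sd) / sqrt(B)
    list(W = matrix(seW, n, m, byrow = TRUE),
         b = apply(per_samp[[l]]$b, 2, stats::sd) / sqrt(B))
  })
}

# Per-sample W gradients are stored row-major (neuron i block = columns
# (i-1)*m + 1 .. i*m), so byrow = TRUE above reshapes them back.

#' Noise-driven learning backward pass
#'
#' Computes the gradient of the (instantaneous, time-averaged) loss with
#' respect to all network parameters by back-propagation through time, with
#' every spike/membrane derivative replaced by the post-synaptic factor
#' \eqn{F'_\epsilon(u - v_{th})} — the membrane-noise density. The rule is a
#' three-factor product: the pre-synaptic factor \eqn{\nabla_\theta u}, the
#' post-synaptic noise-density factor, and the global learning signal
#' \eqn{\nabla_o f} propagated from the head. The reset path is detached:
#' spikes' effect on later membranes through the reset is not differentiated.
#'
#' @param net an [nsnn_network()] whose layers all have stochastic noise.
#' @param record an `"nsnn_rollout"` of `net` (may be batched).
#' @param target integer class labels (softmax head); ignored by custom heads.
#' @param loss_mode `"mean"` (average the per-step instantaneous loss over
#'   the window, default) or `"last"` (final step only).
#' @param per_sample keep per-sample gradients to attach Monte-Carlo standard
#'   errors (memory grows with batch size).
#' @return a `"gradient_report"` with one `(W, b)` block per layer plus the
#'   head block; gradients are means over the batch.
#' @export
ndl_backward <- function(net, record, target = NULL,
                         loss_mode = c("mean", "last"), per_sample = FALSE) {
  loss_mode <- match.arg(loss_mode)
  for (ly in net$layers) {
    if (ly$noise$family == "none") {
      stop("layer with deterministic neurons has no noise density; ",
           "train it with surrogate_backward() and a surrogate_spec()")
    }
  }
  hl <- head_loss(net, record, target, loss_mode)
  fac <- function(l, x) noise_pdf(x, net$layers[[l]]$noise)
  bw <- nsnn_backward(net, record, hl$dLdoL, fac, per_sample = per_sample)
  se <- if (per_sample) {
    dims <- lapply(net$layers, function(ly) dim(ly$W))
    per_sample_se(bw$per_sample, dims, record$B)
  }
  new_gradient_report(bw$layer_grads, hl$head_grads, "ndl", record$B,
                      se = se)
}

#' Surrogate-gradient backward pass
#'
#' Identical to [ndl_backward()] except that the post-synaptic factor is an
#' explicit surrogate function rather than a noise density. With the
#' surrogate matched to the layer noise (see [surrogate_from_noise()]) the
#' two backward passes agree to machine precision on the same record — the
#' sense in which surrogate-gradient learning is a special case of
#' noise-driven learning. Works for deterministic (`family = "none"`) layers,
#' which is how conventional DSNNs are trained.
#'
#' @inheritParams ndl_backward
#' @param sg a [surrogate_spec()], or a list of one per layer.
#' @export
surrogate_backward <- function(net, record, target = NULL, sg,
                               loss_mode = c("mean", "last"),
                               per_sample = FALSE) {
  loss_mode <- match.arg(loss_mode)
  if (inherits(sg, "surrogate_spec")) sg <- rep(list(sg), length(net$layers))
  stopifnot(length(sg) == length(net$layers))
  hl <- head_loss(net, record, target, loss_mode)
  fac <- function(l, x) surrogate_value(x, sg[[l]])
  bw <- nsnn_backward(net, record, hl$dLdoL, fac, per_sample = per_sample)
  se <- if (per_sample) {
    dims <- lapply(net$layers, function(ly) dim(ly$W))
    per_sample_se(bw$per_sample, dims, record$B)
  }
  new_gradient_report(bw$layer_grads, hl$head_grads, "surrogate", record$B,
                      se = se)
}

# ---------------------------------------------------------------------------

#' Train an NSNN by noise-driven learning
#'
#' Minibatch stochastic gradient descent on the time-averaged instantaneous
#' loss: each update rolls the network out on a batch, runs the NDL (or
#' matched-surrogate) backward pass and takes a plain SGD step (optional
#' classical momentum). Plain SGD is the default for auditability.
#'
#' @param net an [nsnn_network()] with a softmax head.
#' @param dataset list with `x`, a `(N, n_in, T)` array of input sequences,
#'   and `y`, integer class labels in `1..n_class` (as produced by
#'   [gen_rate_task()]).
#' @param epochs,lr,batch_size optimizer settings; `lr = 0` leaves the
#'   parameters bit-identical.
#' @param momentum classical momentum coefficient (0 = plain SGD).
#' @param loss_mode `"mean"` or `"last"`, see [ndl_backward()].
#' @param rule `"ndl"` (default) or `"surrogate"` (requires `sg`; this is the
#'   route for deterministic networks).
#' @param sg a [surrogate_spec()] when `rule = "surrogate"`.
#' @param seed seed governing shuffling and rollout randomness.
#' @param verbose print per-epoch loss/accuracy.
#' @return an object of class `"nsnn_fit"`: the trained network plus a
#'   per-epoch learning curve (`epoch`, `loss`, `accuracy`).
#' @export
nsnn_train <- function(net, dataset, epochs = 30, lr = 0.5, batch_size = 40,
                       momentum = 0, loss_mode = c("mean", "last"),
                       rule = c("ndl", "surrogate"), sg = NULL, seed = 1,
                       verbose = FALSE) {
  loss_mode <- match.arg(loss_mode)
  rule <- match.arg(rule)
  if (rule == "surrogate" && is.null(sg)) stop("rule = \"surrogate\" requires `sg`")
  stopifnot(lr >= 0, epochs >= 1)
  N <- dim(dataset$x)[1]
  y <- as.integer(dataset$y)
  stopifnot(length(y) == N)
  v <- nsnn_get_params(net)
  mom <- numeric(length(v))
  curve <- data.frame(epoch = integer(0), loss = numeric(0),
                      accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(N))
    ep_loss <- 0; ep_correct <- 0
    starts <- seq(1, N, by = batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1, N)]
      Xb <- dataset$x[idx, , , drop = FALSE]
      yb <- y[idx]
      rec <- nsnn_forward(net, Xb, seed = derive_seed(seed, ep * 10000L + bi))
      hl <- head_loss(net, rec, yb, loss_mode, want_grads = FALSE)
      if (!all(is.finite(hl$loss))) {
        stop(sprintf("non-finite loss at epoch %d, batch %d: aborting", ep, bi))
      }
      ep_loss <- ep_loss + sum(hl$loss)
      pred <- nsnn_predict(net, rec)$average
      ep_correct <- ep_correct + sum(max.col(pred, ties.method = "first") == yb)
      gr <- if (rule == "ndl") ndl_backward(net, rec, yb, loss_mode)
            else surrogate_backward(net, rec, yb, sg, loss_mode)
      g <- flatten_grads(gr$layers, gr$head)
      if (lr > 0) {
        mom <- momentum * mom + g
        v <- v - lr * mom
        net <- nsnn_set_params(net, v)
      }
    }
    curve <- rbind(curve, data.frame(epoch = ep, loss = ep_loss / N,
                                     accuracy = ep_correct / N))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  accuracy %.3f",
                      ep, ep_loss / N, ep_correct / N))
    }
  }
  structure(list(net = net, curve = curve,
                 config = list(epochs = epochs, lr = lr,
                               batch_size = batch_size, momentum = momentum,
                               loss_mode = loss_mode, rule = rule,
                               seed = seed)),
            class = "nsnn_fit")
}

#' @export
print.nsnn_fit <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("NSNN fit (%s, %d epochs): final train loss %.4f, accuracy %.3f\n",
              x$config$rule, x$config$epochs, last$loss, last$accuracy))
  print(x$net)
  invisible(x)
}

#' @export
coef.nsnn_fit <- function(object, ...) nsnn_get_params(object$net)

#' @export
plot.nsnn_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$curve$epoch, x$curve$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(x$curve$epoch, x$curve$accuracy, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Predict classes for new input sequences
#'
#' Rolls the fitted network out on each input (optionally several stochastic
#' trials, averaging the prediction vectors) and returns class probabilities
#' and hard labels.
#'
#' @param object an `"nsnn_fit"`.
#' @param x a `(N, n_in, T)` array (or a single `T x n_in` matrix).
#' @param trials number of stochastic rollouts to average per input.
#' @param seed rollout seed.
#' @param ... unused.
#' @return list with `prob` (`N x K`) and `class` (length-`N` integer).
#' @export
predict.nsnn_fit <- function(object, x, trials = 1, seed = NULL, ...) {
  net <- object$net
  if (is.matrix(x)) x <- array(t(x), dim = c(1, ncol(x), nrow(x)))
  N <- dim(x)[1]
  prob <- matrix(0, N, net$head$n_class)
  for (k in seq_len(trials)) {
    rec <- nsnn_forward(net, x,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    prob <- prob + nsnn_predict(net, rec)$average / trials
  }
  list(prob = prob, class = max.col(prob, ties.method = "first"))
}
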