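# Spike-train fitting: first-order postsynaptic-potential (PSP) filtering,
# the PSP-kernel maximum mean discrepancy (MMD) loss over spike-train
# prefixes, and a teacher-student neural-activity-fitting harness.

#' First-order PSP filtering of a spike train
#'
#' Applies the postsynaptic-potential kernel recursion
#' \deqn{PSP_\tau = (1 - 1/\tau_s)\,PSP_{\tau-1} + (1/\tau_s)\, y_\tau,}
#' with `PSP_0 = 0`, along the time axis. The filter is linear in its input,
#' nonnegative for binary trains and bounded by the largest input value.
#'
#' @param spikes `neurons x time` matrix (a vector is one neuron), or a
#'   `neurons x time x trials` array (filtered per trial).
#' @param tau_s synaptic time constant, must exceed 1; default 2.
#' @return filtered trace(s), same shape as the input.
#' @export
psp_transform <- function(spikes, tau_s = 2) {
  if (!is.numeric(tau_s) || tau_s <= 1) stop("`tau_s` must be > 1")
  if (is.vector(spikes)) {
    return(drop(psp_transform(matrix(spikes, nrow = 1), tau_s)))
  }
  if (length(dim(spikes)) == 3) {
    out <- spikes
    for (k in seq_len(dim(spikes)[3])) {
      out[, , k] <- psp_transform(spikes[, , k, drop = TRUE], tau_s)
    }
    return(out)
  }
  a <- 1 - 1 / tau_s
  out <- spikes / tau_s
  for (t in 2:max(ncol(spikes), 2)) {
    if (t > ncol(spikes)) break
    out[, t] <- a * out[, t - 1] + spikes[, t] / tau_s
  }
  out
}

#' PSP-kernel MMD loss between two spike trains
#'
#' The time-averaged sum over prefixes of the squared distance between the
#' PSP-filtered traces:
#' \deqn{L = \frac1T \sum_{t=1}^{T} \sum_{\tau=1}^{t}
#'       \lVert PSP(\hat y_{1:\tau}) - PSP(y_{1:\tau})\rVert^2 .}
#' Because the prefix filter value at `tau` does not depend on `t`, the
#' double sum collapses to a single weighted pass
#' `L = (1/T) * sum_tau (T - tau + 1) * ||d_tau||^2` and is evaluated in
#' `O(T)`; `naive = TRUE` runs the literal double loop instead (used to
#' verify the collapsed form). The loss is symmetric, nonnegative, and zero
#' exactly when the two trains are identical (for `tau_s > 1`).
#'
#' @param pred,target equal-shape `neurons x time` matrices (vectors are one
#'   neuron).
#' @param tau_s synaptic time constant (> 1).
#' @param naive evaluate the literal `O(T^2)` double sum.
#' @return scalar loss `>= 0`.
#' @export
mmd_psp_loss <- function(pred, target, tau_s = 2, naive = FALSE) {
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  if (!all(dim(pred) == dim(target))) {
    stop(sprintf("shape mismatch: pred is %s, target is %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(target), collapse = "x")))
  }
  T_ <- ncol(pred)
  d <- psp_transform(pred, tau_s) - psp_transform(target, tau_s)
  sq <- colSums(d^2)
  if (naive) {
    tot <- 0
    for (t in seq_len(T_)) tot <- tot + sum(sq[seq_len(t)])
    return(tot / T_)
  }
  sum((T_ - seq_len(T_) + 1) * sq) / T_
}

# Gradient of mmd_psp_loss with respect to the predicted spikes: backward
# recursion through the linear PSP filter.
#   dL/dy_s = (1/tau_s) * M_s,  M_s = A_s + (1 - 1/tau_s) * M_{s+1},
#   A_tau = (2/T) * (T - tau + 1) * d_tau.
mmd_psp_grad <- function(pred, target, tau_s = 2) {
  T_ <- ncol(pred)
  d <- psp_transform(pred, tau_s) - psp_transform(target, tau_s)
  A <- d * matrix((2 / T_) * (T_ - seq_len(T_) + 1), nrow(pred), T_,
                  byrow = TRUE)
  G <- A
  a <- 1 - 1 / tau_s
  for (s in rev(seq_len(T_ - 1))) G[, s] <- A[, s] + a * G[, s + 1]
  G / tau_s
}

# Trial-averaged smoothed firing-rate curves: mean spike train over trials,
# then a centered moving average of the given width; columns with incomplete
# windows are dropped.
rate_curve <- function(raster, width = 5) {
  if (length(dim(raster)) == 3) raster <- apply(raster, c(1, 2), mean)
  if (is.vector(raster)) raster <- matrix(raster, nrow = 1)
  T_ <- ncol(raster)
  if (width <= 1 || T_ < width) return(raster)
  sm <- t(apply(raster, 1, function(r) {
    as.numeric(stats::filter(r, rep(1 / width, width), sides = 2))
  }))
  keep <- which(!apply(is.na(sm), 2, any))
  matrix(sm[, keep], nrow(raster))
}

#' Fit a spiking network to target spike trains
#'
#' Teacher-student neural-activity fitting: the network's final spiking
#' layer is trained to reproduce recorded (here: synthetic teacher) spike
#' rasters by stochastic gradient descent on the PSP-kernel MMD loss. The
#' loss gradient flows through the linear PSP filter into the output spikes,
#' then through the noise-density post-synaptic factor (or a surrogate for
#' deterministic students) and back through time.
#'
#' @param net an [nsnn_network()] whose final layer size equals the number of
#'   target neurons (the head is unused).
#' @param stimuli list of `T x n_in` stimulus matrices.
#' @param targets list (parallel to `stimuli`) of `neurons x T x trials`
#'   binary target rasters.
#' @param epochs,lr optimizer settings (plain SGD).
#' @param batch stochastic rollouts per update: the stimulus is rolled out
#'   `batch` times in one vectorized pass, each rollout is compared against
#'   an independently drawn target trial, and the gradients are averaged.
#' @param tau_s PSP time constant of the loss.
#' @param clip maximum L2 norm of each parameter update's gradient; larger
#'   gradients are rescaled. Guards against early overshoot into the
#'   silent regime, where the noise-density factor (and hence the gradient)
#'   vanishes and a unit can never recover.
#' @param sg optional [surrogate_spec()] for a deterministic student.
#' @param seed RNG seed.
#' @param verbose print per-epoch loss.
#' @return object of class `"activity_fit"`: the fitted network and the
#'   per-epoch training-loss curve. Evaluate with [rate_correlation()].
#' @export
fit_activity <- function(net, stimuli, targets, epochs = 30, lr = 0.1,
                         batch = 8, tau_s = 2, clip = 2, sg = NULL, seed = 1,
                         verbose = FALSE) {
  stopifnot(length(stimuli) == length(targets), epochs >= 1, lr >= 0)
  nL <- utils::tail(net$sizes, 1)
  for (tg in targets) {
    if (dim(tg)[1] != nL) {
      stop(sprintf("network output size %d != target neuron count %d",
                   nL, dim(tg)[1]))
    }
  }
  fac <- if (is.null(sg)) {
    for (ly in net$layers) {
      if (ly$noise$family == "none") {
        stop("deterministic layers need a surrogate_spec via `sg`")
      }
    }
    function(l, x) noise_pdf(x, net$layers[[l]]$noise)
  } else {
    sgl <- if (inherits(sg, "surrogate_spec")) rep(list(sg), length(net$layers)) else sg
    function(l, x) surrogate_value(x, sgl[[l]])
  }
  v <- nsnn_get_params(net)
  n_layer_par <- sum(vapply(net$layers, function(ly) length(ly$W) + length(ly$b), 1))
  curve <- numeric(epochs)
  N <- length(stimuli)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(N))
    ep_loss <- 0
    for (i in ord) {
      step <- step + 1L
      tg <- targets[[i]]
      xs <- stimuli[[i]]
      trials_i <- with_seed(derive_seed(seed, 50000L + step),
                            sample.int(dim(tg)[3], batch, replace = TRUE))
      X1 <- array(t(xs), dim = c(1, ncol(xs), nrow(xs)))
      X <- array(rep(X1, each = batch), dim = c(batch, ncol(xs), nrow(xs)))
      rec <- nsnn_forward(net, X, seed = derive_seed(seed, 100000L + step))
      oL <- rec$layers[[length(net$layers)]]$o      # (batch, nL, T)
      dLdoL <- array(0, c(batch, nL, rec$T))
      loss_i <- 0
      for (b in seq_len(batch)) {
        ob <- matrix(oL[b, , ], nL, rec$T)
        tb <- tg[, , trials_i[b]]
        loss_i <- loss_i + mmd_psp_loss(ob, tb, tau_s) / batch
        g <- mmd_psp_grad(ob, tb, tau_s)
        for (t in seq_len(rec$T)) dLdoL[b, , t] <- g[, t]
      }
      if (!is.finite(loss_i)) {
        utils::str(curve[seq_len(ep)])
        stop(sprintf("non-finite fitting loss at epoch %d (stimulus %d)", ep, i))
      }
      ep_loss <- ep_loss + loss_i
      bw <- nsnn_backward(net, rec, dLdoL, fac)
      gv <- flatten_grads(bw$layer_grads, NULL)
      gnorm <- sqrt(sum(gv^2))
      if (is.finite(clip) && gnorm > clip) gv <- gv * (clip / gnorm)
      if (lr > 0) {
        v[seq_len(n_layer_par)] <- v[seq_len(n_layer_par)] - lr * gv
        net <- nsnn_set_params(net, v)
      }
    }
    curve[ep] <- ep_loss / N
    if (verbose) message(sprintf("epoch %3d  MMD loss %.5f", ep, curve[ep]))
  }
  structure(list(net = net, curve = data.frame(epoch = seq_len(epochs),
                                               loss = curve),
                 tau_s = tau_s, seed = seed,
                 mode = if (is.null(sg)) "nsnn" else "surrogate"),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat(sprintf("Spike-train fit (%s student): %d epochs, final MMD loss %.5f\n",
              x$mode, nrow(x$curve), x$curve$loss[nrow(x$curve)]))
  invisible(x)
}

#' Firing-rate correlation between a fitted model and target rasters
#'
#' Rolls the fitted network out `trials` times per held-out stimulus,
#' smooths the trial-averaged spike trains of model and target with a
#' centered moving window, and computes the Pearson correlation per neuron
#' across the concatenated time bins of all stimuli. Also reports
#' trial-to-trial Fano factors of model and target counts (a deterministic
#' student has FF exactly 0 on every repeat).
#'
#' @param fit an `"activity_fit"` (or a bare network).
#' @param stimuli,targets held-out stimuli and `neurons x T x trials`
#'   rasters.
#' @param trials model rollouts per stimulus.
#' @param bin_width moving-average window (steps); default 5.
#' @param seed RNG seed.
#' @return list with `r` (per neuron), `mean_r` (over neurons with defined
#'   correlations), `model_ff`, `target_ff` (mean Fano factors), and the
#'   model rasters.
#' @export
rate_correlation <- function(fit, stimuli, targets, trials = 20,
                             bin_width = 5, seed = 1) {
  net <- if (inherits(fit, "activity_fit")) fit$net else as_net(fit)
  nL <- utils::tail(net$sizes, 1)
  L <- length(net$layers)
  model_rates <- NULL; target_rates <- NULL
  model_ff <- c(); target_ff <- c()
  rasters <- vector("list", length(stimuli))
  for (i in seq_along(stimuli)) {
    xs <- stimuli[[i]]
    X1 <- array(t(xs), dim = c(1, ncol(xs), nrow(xs)))
    X <- array(rep(X1, each = trials), dim = c(trials, ncol(xs), nrow(xs)))
    rec <- nsnn_forward(net, X, seed = derive_seed(seed, i))
    ras <- aperm(rec$layers[[L]]$o, c(2, 3, 1))   # neurons x T x trials
    rasters[[i]] <- ras
    model_rates <- cbind(model_rates, rate_curve(ras, bin_width))
    target_rates <- cbind(target_rates, rate_curve(targets[[i]], bin_width))
    mcnt <- apply(ras, c(3, 1), sum)      # trials x neurons
    tcnt <- apply(targets[[i]], c(3, 1), sum)
    model_ff <- c(model_ff, fano_factor_counts(mcnt))
    target_ff <- c(target_ff, fano_factor_counts(tcnt))
  }
  r <- vapply(seq_len(nL), function(m) {
    a <- model_rates[m, ]; b <- target_rates[m, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  list(r = r, mean_r = mean(r, na.rm = TRUE),
       model_ff = mean(model_ff, na.rm = TRUE),
       target_ff = mean(target_ff, na.rm = TRUE),
       rasters = rasters, bin_width = bin_width, trials = trials)
}

# mean Fano factor of a trials x neurons count matrix; NA if all silent.
fano_factor_counts <- function(cnt) {
  mu <- colMeans(cnt)
  va <- apply(cnt, 2, stats::var)
  if (!any(mu > 0)) return(NA_real_)
  mean(va[mu > 0] / mu[mu > 0])
}

#' Teacher-student activity-fitting experiment
#'
#' End-to-end harness: a noisy teacher network responds to smooth random
#' stimuli with trial-to-trial variability; a freshly initialized student of
#' the same architecture is fitted to the teacher's rasters with the
#' PSP-kernel MMD loss, and evaluated on held-out stimuli by firing-rate
#' correlation and Fano-factor recovery. `student = "dsnn"` fits a
#' deterministic student with the matched erf-like surrogate instead; its
#' repeats are identical, so its between-trial Fano factor is exactly 0.
#'
#' @param seed experiment seed (teacher, stimuli, fitting and evaluation
#'   seeds all derive from it).
#' @param student `"nsnn"` or `"dsnn"`.
#' @param n_in,n_neurons,T_ architecture and horizon of teacher and student.
#' @param n_stim,n_train stimuli generated / used for training (the rest are
#'   held out).
#' @param trials teacher trials per stimulus (and student evaluation trials).
#' @param epochs,lr,batch fitting settings (see [fit_activity()]).
#' @param sigma membrane-noise scale of teacher (and NSNN student).
#' @return list with `mean_r`, per-neuron `r`, `model_ff`, `target_ff`, the
#'   fitted `"activity_fit"` and the evaluation object.
#' @export
teacher_student_experiment <- function(seed = 1, student = c("nsnn", "dsnn"),
                                       n_in = 8, n_neurons = 6, T_ = 30,
                                       n_stim = 12, n_train = 8, trials = 15,
                                       epochs = 100, lr = 0.02, batch = 8,
                                       sigma = 0.2) {
  student <- match.arg(student)
  teacher <- nsnn_network(n_in, c(n_neurons), head = head_softmax(2),
                          noise = noise_model("gaussian", sigma),
                          init_gain = 2, init_bias = 0,
                          seed = derive_seed(seed, 1))
  stims <- gen_smooth_stimuli(n_stim, T_, n_in, seed = derive_seed(seed, 2))
  resp <- gen_teacher_responses(teacher, stims, trials,
                                seed = derive_seed(seed, 3))
  tr <- seq_len(n_train); te <- seq.int(n_train + 1, n_stim)
  noise <- if (student == "nsnn") noise_model("gaussian", sigma)
           else noise_model("none")
  sg <- if (student == "dsnn") surrogate_from_noise(noise_model("gaussian", sigma))
  stu <- nsnn_network(n_in, c(n_neurons), head = head_softmax(2),
                      noise = noise, init_bias = 0,
                      seed = derive_seed(seed, 4))
  fit <- fit_activity(stu, stims[tr], resp$rasters[tr], epochs = epochs,
                      lr = lr, batch = batch, sg = sg,
                      seed = derive_seed(seed, 5))
  ev <- rate_correlation(fit, stims[te], resp$rasters[te], trials = trials,
                         seed = derive_seed(seed, 6))
  list(mean_r = ev$mean_r, r = ev$r, model_ff = ev$model_ff,
       target_ff = ev$target_ff, fit = fit, evaluation = ev)
}
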