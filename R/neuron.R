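#' LIF neuron parameters
#'
#' Leak factor, firing threshold and reset potential of the discrete-time
#' leaky integrate-and-fire neuron
#' \deqn{u^t = \tau u^{t-1} + \mathrm{drive}^t,\qquad
#'       o^t = H(u^t - v_{th}),\qquad u^t \leftarrow u_{reset}\ \mathrm{if}\ o^t = 1.}
#'
#' @param tau leak factor in `[0, 1)`; default 0.5.
#' @param v_th firing threshold; default 1.
#' @param u_reset reset potential applied after a spike; default 0.
#' @return object of class `"neuron_params"`.
#' @export
neuron_params <- function(tau = 0.5, v_th = 1, u_reset = 0) {
  if (!is.numeric(tau) || tau < 0 || tau >= 1) stop("`tau` must lie in [0, 1)")
  check_finite(c(v_th, u_reset), "neuron parameters")
  structure(list(tau = tau, v_th = v_th, u_reset = u_reset),
            class = "neuron_params")
}

#' One step of (noisy) LIF dynamics
#'
#' Advances a population of LIF neurons one time step. The carried membrane
#' state is the noise-free accumulation `u' = tau * u + drive`; the membrane
#' noise is marginalized analytically, so firing is a Bernoulli draw with
#' probability `noise_cdf(u' - v_th, nm)` (escape-noise convention). Wherever
#' a spike is emitted the stored potential is hard-reset to `u_reset` within
#' the same step.
#'
#' Set `sample_noise = TRUE` to instead draw an explicit noise realization,
#' carry the noisy potential forward and fire by deterministic threshold
#' crossing; the per-step spike distribution is identical, but the carried
#' state differs. The explicit mode exists for stochastic-stability
#' demonstrations where the perturbed membrane itself is of interest.
#'
#' @param u numeric vector of membrane potentials (one per neuron).
#' @param drive numeric vector of synaptic drive, same length as `u`.
#' @param nm a [noise_model()].
#' @param params a [neuron_params()].
#' @param seed optional integer seed for the Bernoulli draws; `NULL` uses the
#'   current RNG stream.
#' @param xi optional uniform(0,1) draws (same length as `u`) to reuse instead
#'   of fresh randomness; spikes are `xi < p_fire`.
#' @param sample_noise logical; see Details.
#' @return list with `u` (stored post-reset potential), `p_fire`, and binary
#'   spikes `o`.
#' @examples
#' st <- lif_step(u = 0, drive = 1, nm = noise_model("gaussian", 0.3),
#'                params = neuron_params(), seed = 1)
#' st$p_fire  # 0.5: the accumulated potential sits exactly at threshold
#' @export
lif_step <- function(u, drive, nm, params = neuron_params(), seed = NULL,
                     xi = NULL, sample_noise = FALSE) {
  stopifnot(inherits(nm, "noise_model"), inherits(params, "neuron_params"))
  check_finite(drive, "drive")
  check_finite(u, "u")
  if (length(drive) != length(u)) stop("`drive` length must equal `u` length")
  u_acc <- params$tau * u + drive
  with_seed(seed, {
    if (sample_noise && nm$family != "none") {
      eps <- switch(nm$family,
        gaussian = stats::rnorm(length(u), sd = nm$scale),
        logistic = stats::rlogis(length(u), scale = nm$scale),
        uniform  = stats::runif(length(u), -nm$scale, nm$scale))
      u_acc <- u_acc + eps
      p <- as.numeric(u_acc > params$v_th)
      o <- p
    } else {
      p <- noise_cdf(u_acc - params$v_th, nm)
      if (is.null(xi)) xi <- stats::runif(length(u))
      o <- as.numeric(xi < p)
    }
    u_out <- ifelse(o == 1, params$u_reset, u_acc)
    list(u = u_out, p_fire = p, o = o)
  })
}
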