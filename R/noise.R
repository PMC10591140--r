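#' Membrane-noise model
#'
#' Specifies the distribution of the zero-mean membrane noise added to the
#' sub-threshold potential of a noisy leaky integrate-and-fire (LIF) neuron.
#' Under the escape-noise view, the noise enters the model only through its
#' cumulative distribution function \eqn{F_\epsilon} (the firing probability
#' at membrane distance \eqn{u - v_{th}} from threshold) and its density
#' \eqn{F'_\epsilon} (the post-synaptic factor of the noise-driven learning
#' rule).
#'
#' @param family one of `"gaussian"`, `"logistic"`, `"uniform"`, `"none"`.
#'   `"none"` is the deterministic (Heaviside) limit used by conventional
#'   deterministic SNNs.
#' @param scale positive scale of the noise: standard deviation for
#'   `"gaussian"`, the logistic scale parameter for `"logistic"`, the
#'   half-width for `"uniform"`. Ignored for `"none"`. Default 0.3, a moderate
#'   noise level at which learning is both informative and non-disruptive.
#'
#' @return An object of class `"noise_model"`.
#' @examples
#' nm <- noise_model("gaussian", 0.3)
#' noise_cdf(0, nm)    # 0.5 by symmetry
#' noise_pdf(0, nm)    # 1 / (0.3 * sqrt(2*pi))
#' @export
noise_model <- function(family = c("gaussian", "logistic", "uniform", "none"),
                        scale = 0.3) {
  family <- match.arg(family)
  if (family != "none") {
    if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
      stop("`scale` must be a single positive finite number")
    }
  }
  structure(list(family = family, scale = scale), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  if (x$family == "none") {
    cat("Membrane noise model: none (deterministic Heaviside firing)\n")
  } else {
    cat(sprintf("Membrane noise model: %s (scale = %g)\n", x$family, x$scale))
  }
  invisible(x)
}

#' Firing-probability function of a noise model
#'
#' The cumulative distribution function \eqn{F_\epsilon(x)} of the membrane
#' noise, evaluated at `x = u - v_th`. It is the probability that a noisy LIF
#' neuron at sub-threshold potential `u` fires in the current step. For the
#' deterministic family `"none"` it is the Heaviside step; a neuron exactly at
#' threshold (`x = 0`) does not fire, so the step is taken right-continuous
#' from below (`cdf(0) = 0`), fixing the measure-zero tie for reproducibility.
#'
#' @param x numeric vector, membrane distance(s) from threshold.
#' @param nm a [noise_model()].
#' @return probabilities in `[0, 1]`, same length as `x`.
#' @export
noise_cdf <- function(x, nm) {
  stopifnot(inherits(nm, "noise_model"))
  check_finite(x, "x")
  switch(nm$family,
    gaussian = stats::pnorm(x, sd = nm$scale),
    logistic = stats::plogis(x, scale = nm$scale),
    uniform  = stats::punif(x, min = -nm$scale, max = nm$scale),
    none     = as.numeric(x > 0)
  )
}

#' Noise density (post-synaptic learning factor)
#'
#' The probability density \eqn{F'_\epsilon(x)} of the membrane noise. In the
#' noise-driven learning rule this density, evaluated at `u - v_th`, replaces
#' the non-existent derivative of the spike function in the backward pass.
#' The deterministic family has no density: a purely deterministic neuron
#' carries no learning factor, which is exactly why the noisy model is needed
#' for gradient-based training.
#'
#' @inheritParams noise_cdf
#' @return nonnegative densities, same length as `x`.
#' @export
noise_pdf <- function(x, nm) {
  stopifnot(inherits(nm, "noise_model"))
  check_finite(x, "x")
  if (nm$family == "none") {
    stop("deterministic neuron (family = \"none\") has no learning factor; ",
         "use a surrogate_spec() instead")
  }
  switch(nm$family,
    gaussian = stats::dnorm(x, sd = nm$scale),
    logistic = stats::dlogis(x, scale = nm$scale),
    uniform  = stats::dunif(x, min = -nm$scale, max = nm$scale)
  )
}
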