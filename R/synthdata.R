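# Seeded generators for every synthetic input the package consumes: Poisson
# spike rasters, two-class firing-rate-pattern classification tasks,
# teacher-network responses with trial variability, and toy event streams.
# Every generator is a pure function of its parameters and seed.

#' Generate a Bernoulli/Poisson spike raster
#'
#' Independent per-step Bernoulli spiking. Rates are per-step firing
#' probabilities (not Hz), which avoids fixing a physical step duration.
#'
#' @param rates per-neuron firing probabilities in `[0, 1]`: a vector
#'   (constant in time) or a `neurons x time` matrix.
#' @param T_ number of steps (ignored when `rates` is a matrix).
#' @param trials number of independent trials.
#' @param seed RNG seed.
#' @return binary `neurons x time x trials` array of class `"spike_raster"`.
#' @export
gen_poisson_raster <- function(rates, T_ = NULL, trials = 1, seed = 1) {
  if (is.vector(rates)) {
    if (is.null(T_)) stop("`T_` is required when `rates` is a vector")
    rates <- matrix(rates, length(rates), T_)
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- nrow(rates); T_ <- ncol(rates)
  out <- with_seed(seed, {
    array((stats::runif(n * T_ * trials) <
             as.numeric(rates)) * 1, c(n, T_, trials))
  })
  structure(out, class = "spike_raster")
}

#' Generate a two-class (or k-class) firing-rate-pattern task
#'
#' Each class elevates the drive of its own block of input channels by
#' `contrast` above a shared baseline; independent Gaussian noise is added to
#' every channel and step. At `contrast = 0` the classes are statistically
#' identical (chance-level task); as `contrast` grows a linear readout of
#' the time-averaged inputs separates the classes perfectly.
#'
#' @param n_classes number of classes (default 2).
#' @param n_inputs input channels (default 20).
#' @param T_ steps per sequence (default 10).
#' @param n_samples total sequences, balanced over classes (default 400).
#' @param contrast class-specific drive elevation (default 0.5).
#' @param baseline shared drive level (default 0.2).
#' @param noise_sd per-step input noise (default 0.5).
#' @param seed RNG seed.
#' @return list of class `"rate_task"`: `x` (`(n_samples, n_inputs, T)`
#'   array), `y` (labels `1..n_classes`), `class_inputs` (list of each
#'   class's elevated channels), and the generating parameters.
#' @export
gen_rate_task <- function(n_classes = 2, n_inputs = 20, T_ = 10,
                          n_samples = 400, contrast = 0.5, baseline = 0.2,
                          noise_sd = 0.5, seed = 1) {
  stopifnot(contrast >= 0, n_inputs >= n_classes)
  blocks <- split(seq_len(n_inputs),
                  cut(seq_len(n_inputs), n_classes, labels = FALSE))
  y <- rep(seq_len(n_classes), length.out = n_samples)
  x <- with_seed(seed, {
    x <- array(stats::rnorm(n_samples * n_inputs * T_, mean = baseline,
                            sd = noise_sd),
               c(n_samples, n_inputs, T_))
    for (i in seq_len(n_samples)) {
      x[i, blocks[[y[i]]], ] <- x[i, blocks[[y[i]]], ] + contrast
    }
    x
  })
  structure(list(x = x, y = y, class_inputs = blocks,
                 params = list(n_classes = n_classes, n_inputs = n_inputs,
                               T_ = T_, n_samples = n_samples,
                               contrast = contrast, baseline = baseline,
                               noise_sd = noise_sd, seed = seed)),
            class = "rate_task")
}

#' Teacher-network spike responses with trial variability
#'
#' Rolls a (noisy) teacher network repeatedly over each stimulus and returns
#' the final spiking layer's rasters — a synthetic stand-in for recorded
#' sensory responses, with genuine trial-to-trial variability whenever the
#' teacher's noise scale is positive.
#'
#' @param teacher an [nsnn_network()].
#' @param stimuli list of `T x n_in` stimulus matrices.
#' @param trials repeats per stimulus.
#' @param seed RNG seed.
#' @return list with `rasters` (per stimulus: `neurons x T x trials`
#'   arrays) and `p_mean` (per stimulus: the trial-averaged firing
#'   probabilities, `neurons x T`).
#' @export
gen_teacher_responses <- function(teacher, stimuli, trials = 20, seed = 1) {
  L <- length(teacher$layers)
  rasters <- vector("list", length(stimuli))
  p_mean <- vector("list", length(stimuli))
  for (i in seq_along(stimuli)) {
    xs <- stimuli[[i]]
    if (is.vector(xs)) xs <- matrix(xs, ncol = teacher$n_in)
    X1 <- array(t(xs), dim = c(1, ncol(xs), nrow(xs)))
    X <- array(rep(X1, each = trials), dim = c(trials, ncol(xs), nrow(xs)))
    rec <- nsnn_forward(teacher, X, seed = derive_seed(seed, i))
    rasters[[i]] <- aperm(rec$layers[[L]]$o, c(2, 3, 1))
    # p is identical across trials only at step 1; later steps depend on the
    # sampled history, so the trial average is the relevant marginal.
    p_mean[[i]] <- apply(rec$layers[[L]]$p, c(2, 3), mean)
  }
  list(rasters = rasters, p_mean = p_mean)
}

#' Generate a toy event stream
#'
#' A stand-in for event-camera data: a fixed total budget of events is drawn
#' (one Bernoulli trial per pixel and step at probability `density`), and
#' each event lands either on a moving bar pattern (with probability
#' `pattern_frac`) or uniformly on the sensor. Output rows are sorted by
#' time.
#'
#' @param density per-pixel per-step event probability in `(0, 1]`.
#' @param sensor `c(width, height)` of the sensor.
#' @param T_ number of time steps.
#' @param pattern `"bar"` (a vertical bar sweeping horizontally) or
#'   `"none"` (uniform background only).
#' @param pattern_frac fraction of events placed on the pattern.
#' @param seed RNG seed.
#' @return `data.frame` with columns `t, x, y, polarity` (0-based `t`,
#'   coordinates in `[0, width)` x `[0, height)`), sorted by `t`; the sensor
#'   size is attached as attribute `"sensor"`.
#' @export
gen_event_stream <- function(density, sensor = c(32, 32), T_ = 50,
                             pattern = c("bar", "none"), pattern_frac = 0.5,
                             seed = 1) {
  pattern <- match.arg(pattern)
  stopifnot(density > 0, density <= 1)
  area <- sensor[1] * sensor[2]
  with_seed(seed, {
    n_events <- stats::rbinom(1, T_ * area, density)
    t_ <- sort(sample.int(T_, n_events, replace = TRUE) - 1L)
    on_pattern <- if (pattern == "bar") stats::runif(n_events) < pattern_frac
                  else rep(FALSE, n_events)
    x <- integer(n_events); yy <- integer(n_events); pol <- integer(n_events)
    bg <- !on_pattern
    x[bg] <- sample.int(sensor[1], sum(bg), replace = TRUE) - 1L
    yy[bg] <- sample.int(sensor[2], sum(bg), replace = TRUE) - 1L
    pol[bg] <- stats::rbinom(sum(bg), 1, 0.5)
    if (any(on_pattern)) {
      # bar at column position sweeping once across the sensor
      cx <- floor(sensor[1] * (t_[on_pattern] / max(T_ - 1, 1)))
      x[on_pattern] <- pmin(pmax(cx + sample(-1:1, sum(on_pattern),
                                             replace = TRUE), 0L),
                            sensor[1] - 1L)
      yy[on_pattern] <- sample.int(sensor[2], sum(on_pattern),
                                   replace = TRUE) - 1L
      pol[on_pattern] <- 1L
    }
    out <- data.frame(t = t_, x = x, y = yy, polarity = pol)
    attr(out, "sensor") <- sensor
    out
  })
}

#' Generate smooth sinusoidal stimulus sequences
#'
#' Dense real-valued input sequences in `[0, 1]`: each channel is a sinusoid
#' with random frequency and phase, a simple stand-in for slowly varying
#' sensory drive in the activity-fitting experiments.
#'
#' @param n_stim number of stimulus sequences.
#' @param T_ steps per sequence.
#' @param n_in input channels.
#' @param seed RNG seed.
#' @return list of `T x n_in` matrices.
#' @export
gen_smooth_stimuli <- function(n_stim, T_ = 30, n_in = 8, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_stim), function(k) {
      s <- matrix(0, T_, n_in)
      for (j in seq_len(n_in)) {
        s[, j] <- 0.5 + 0.5 * sin(2 * pi * seq_len(T_) / T_ *
                                    stats::runif(1, 0.5, 2) +
                                    stats::runif(1, 0, 2 * pi))
      }
      s
    })
  })
}
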