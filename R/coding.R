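# Trial-to-trial variability and reliability analytics. The neural code is
# the final spiking layer's output: spike counts per neuron over the
# simulation window, collected across repeated stochastic trials of one
# input; prediction vectors are the time-averaged softmax outputs.

#' Repeated stochastic trials of one input
#'
#' Rolls the network out `trials` times on the same input sequence (in one
#' vectorized batch) and collects the final layer's spike counts and the
#' per-trial prediction vectors.
#'
#' @param net an [nsnn_network()] or `"nsnn_fit"`.
#' @param x_seq `T x n_in` input matrix.
#' @param trials number of repeats (>= 2); default 20.
#' @param seed RNG seed.
#' @return object of class `"trial_ensemble"`: `counts` (trials x neurons),
#'   `predictions` (trials x classes, softmax heads only), and the final
#'   layer raster (`neurons x time x trials`).
#' @export
collect_trials <- function(net, x_seq, trials = 20, seed = 1) {
  net <- as_net(net)
  stopifnot(trials >= 2)
  if (is.vector(x_seq)) x_seq <- matrix(x_seq, ncol = net$n_in)
  X1 <- array(t(x_seq), dim = c(1, ncol(x_seq), nrow(x_seq)))
  X <- array(rep(X1, each = trials), dim = c(trials, dim(X1)[2], dim(X1)[3]))
  rec <- nsnn_forward(net, X, seed = seed)
  oL <- rec$layers[[length(net$layers)]]$o   # (trials, nL, T)
  counts <- apply(oL, c(1, 2), sum)
  preds <- if (net$head$type == "softmax") nsnn_predict(net, rec)$average
  raster <- aperm(oL, c(2, 3, 1))
  structure(list(counts = counts, predictions = preds, raster = raster),
            class = "trial_ensemble")
}

#' Fano factor of spike counts across trials
#'
#' The variance-to-mean ratio of each neuron's spike count over repeated
#' trials: 0 for perfectly repeatable (deterministic) responses,
#' approximately 1 for Poisson-like variability. The variance is the
#' unbiased sample variance (n - 1 denominator; recorded in the output so
#' results are interpretable). Neurons that never fire have an undefined
#' ratio; they are excluded from the mean and reported.
#'
#' @param x a `"trial_ensemble"` or a trials x neurons count matrix.
#' @return list with `ff` (per neuron; `NA` for excluded neurons),
#'   `mean_ff` (average over included neurons), `excluded` (indices of
#'   silent neurons), and `variance_convention`.
#' @export
fano_factor <- function(x) {
  counts <- if (inherits(x, "trial_ensemble")) x$counts else as.matrix(x)
  if (nrow(counts) < 2) stop("at least 2 trials are required")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  mu <- colMeans(counts)
  va <- apply(counts, 2, stats::var)
  ff <- ifelse(mu > 0, va / mu, NA_real_)
  excluded <- which(mu == 0)
  list(ff = ff, mean_ff = mean(ff[mu > 0]), excluded = excluded,
       variance_convention = "unbiased (n - 1)")
}

#' Mean pairwise cosine similarity of prediction vectors
#'
#' Prediction stability across trials: the average over all unordered trial
#' pairs of the cosine of the angle between the two prediction vectors. It
#' lies in `[-1, 1]` and equals 1 exactly when all vectors are positive
#' scalings of one another. Pairs involving an all-zero vector are excluded
#' and flagged.
#'
#' @param x a `"trial_ensemble"` or a trials x K matrix of vectors.
#' @return list with `similarity` (mean over pairs) and `n_excluded_pairs`.
#' @export
prediction_similarity <- function(x) {
  P <- if (inherits(x, "trial_ensemble")) x$predictions else as.matrix(x)
  if (is.null(P) || nrow(P) < 2) stop("at least 2 prediction vectors are required")
  nrm <- sqrt(rowSums(P^2))
  zero <- nrm == 0
  Pn <- P[!zero, , drop = FALSE] / nrm[!zero]
  n <- nrow(Pn)
  if (n < 2) stop("fewer than 2 nonzero prediction vectors")
  G <- tcrossprod(Pn)
  sims <- G[upper.tri(G)]
  n_tot <- nrow(P) * (nrow(P) - 1) / 2
  list(similarity = mean(sims), n_excluded_pairs = n_tot - length(sims))
}

#' Correlation between firing-rate variability and prediction stability
#'
#' Pearson correlation (with the two-sided t-test p value, reported but not
#' used for gating) between per-input mean Fano factors and per-input
#' prediction similarities. In networks that learn a rate-based code this
#' correlation is negative: inputs whose final-layer counts vary more across
#' trials yield less stable predictions.
#'
#' @param mean_ff,similarity numeric vectors, one entry per input (>= 3).
#' @return list with `r`, `p`, `n`.
#' @export
ff_similarity_correlation <- function(mean_ff, similarity) {
  stopifnot(length(mean_ff) == length(similarity))
  if (length(mean_ff) < 3) stop("at least 3 inputs are required")
  if (stats::sd(mean_ff) == 0 || stats::sd(similarity) == 0) {
    stop("zero variance in Fano factors or similarities; correlation undefined")
  }
  ct <- stats::cor.test(mean_ff, similarity, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mean_ff))
}

#' Per-input coding analysis of a model
#'
#' Runs [collect_trials()] for every input, computes the mean Fano factor of
#' the final-layer code and the prediction cosine similarity per input, and
#' their correlation across inputs (each input contributes one point).
#'
#' @param net an [nsnn_network()] or `"nsnn_fit"` with a softmax head.
#' @param x `(N, n_in, T)` array of inputs.
#' @param trials trials per input; default 20.
#' @param seed RNG seed.
#' @return list with `per_input` (`data.frame`: input, mean_ff, similarity)
#'   and `correlation` (as from [ff_similarity_correlation()]).
#' @export
coding_analysis <- function(net, x, trials = 20, seed = 1) {
  net <- as_net(net)
  N <- dim(x)[1]
  mean_ff <- numeric(N); sim <- numeric(N)
  for (i in seq_len(N)) {
    xs <- t(matrix(x[i, , ], dim(x)[2], dim(x)[3]))
    ens <- collect_trials(net, xs, trials, seed = derive_seed(seed, i))
    mean_ff[i] <- fano_factor(ens)$mean_ff
    sim[i] <- prediction_similarity(ens)$similarity
  }
  ok <- is.finite(mean_ff) & is.finite(sim)
  corr <- if (sum(ok) >= 3 && stats::sd(mean_ff[ok]) > 0 &&
              stats::sd(sim[ok]) > 0) {
    ff_similarity_correlation(mean_ff[ok], sim[ok])
  }
  list(per_input = data.frame(input = seq_len(N), mean_ff = mean_ff,
                              similarity = sim),
       correlation = corr)
}
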