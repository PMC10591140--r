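# Shared fixtures: tiny networks with probabilities well inside (0, 1) and
# custom loss heads used by the gradient-estimation oracles.

tiny_net <- function(sizes = c(2, 3, 2), n_in = 2, sigma = 0.3, seed = 1,
                     head = head_softmax(2)) {
  nsnn_network(n_in, sizes, head = head,
               noise = noise_model("gaussian", sigma), seed = seed)
}

tiny_input <- function(T_ = 2, n_in = 2) {
  matrix(seq(0.3, 0.9, length.out = T_ * n_in), nrow = T_, ncol = n_in)
}

# multilinear loss on a 3-neuron final layer: linear terms plus products of
# distinct variables (first-order spike-flip differences are exact for it)
multilinear_head <- function() {
  head_custom(
    f = function(O) 0.5 * O[, 1] + 1.5 * O[, 2] - O[, 1] * O[, 3] +
      2 * O[, 2] * O[, 3],
    grad = function(O) cbind(0.5 - O[, 3], 1.5 + 2 * O[, 3],
                             -O[, 1] + 2 * O[, 2]))
}

# max |a - b| in standard-error units, with a small absolute floor for
# entries whose Monte-Carlo variance is below resolution
max_z <- function(est, se, truth, floor_abs = 1e-6) {
  max(abs(est - truth) / pmax(se, floor_abs / 3))
}

report_z <- function(mc, truth, floor_abs = 1e-6) {
  zs <- c()
  for (l in seq_along(truth$layers)) {
    zs <- c(zs,
            max_z(mc$layers[[l]]$W, mc$se[[l]]$W, truth$layers[[l]]$W, floor_abs),
            max_z(mc$layers[[l]]$b, mc$se[[l]]$b, truth$layers[[l]]$b, floor_abs))
  }
  if (!is.null(truth$head) && !is.null(mc$head)) {
    zs <- c(zs,
            max_z(mc$head$W, mc$head_se$W, truth$head$W, floor_abs),
            max_z(mc$head$b, mc$head_se$b, truth$head$b, floor_abs))
  }
  max(zs)
}

flat_all <- function(rep_) {
  v <- numeric(0)
  for (g in rep_$layers) v <- c(v, as.numeric(g$W), g$b)
  if (!is.null(rep_$head)) v <- c(v, as.numeric(rep_$head$W), rep_$head$b)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
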