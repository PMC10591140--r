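---
title: "Noisy spiking networks: model, learning rule, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noisy spiking networks: model, learning rule, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsnn)
```

This vignette is the package's own account of the science it implements:
the probabilistic spiking neuron, the network model, the noise-driven
learning rule and the estimators that validate it, the stability analysis,
and — importantly — the synthetic study conditions under which all of the
package's tests run, with their limitations spelled out.

## The noisy LIF neuron

The discrete-time leaky integrate-and-fire neuron accumulates synaptic
drive into a leaky membrane, `u_t = tau * u_{t-1} + drive_t`, fires when
the membrane exceeds the threshold `v_th`, and hard-resets to `u_reset`.
Adding a zero-mean symmetric noise term to the membrane turns firing into a
Bernoulli event: the probability that `u_t + eps` exceeds `v_th` is
`F_eps(u_t - v_th)`, the noise cumulative distribution function (cdf)
evaluated at the distance from threshold. This *escape-noise* view is how
the package represents noise everywhere: the noise never needs to be
sampled, only its cdf (for firing) and its density (for learning) are used.

One representational choice deserves emphasis, because the membrane
recurrence makes it consequential: the noise can be written *inside* the
carried state or as a fresh perturbation at the threshold test. Per step the
two give the same firing distribution, but they differ in what is carried
forward. The package carries the **noise-free accumulation** and samples
firing as `Bernoulli(F_eps(u - v_th))` — the escape-noise convention, which
matches the Bernoulli formulation of the firing process and keeps the
carried state deterministic given the spike history. An explicit-noise mode
(`lif_step(..., sample_noise = TRUE)`) exists for demonstrations where the
perturbed membrane itself is of interest; it is not used in learning.

Two boundary conventions are fixed for reproducibility: the deterministic
family (`noise_model("none")`) fires only *strictly* above threshold, so its
"cdf" at 0 is 0 (a measure-zero tie, but tests need a fixed answer), and
the hard reset is applied after spike sampling within the same step.

Defaults, shared by everything in the package unless overridden:

| parameter | meaning                       | default | unit |
|-----------|-------------------------------|---------|------|
| `tau`     | membrane leak factor          | 0.5     | per step |
| `v_th`    | firing threshold              | 1       | dimensionless potential |
| `u_reset` | post-spike reset potential    | 0       | dimensionless potential |
| `scale`   | membrane-noise scale (sd)     | 0.3     | dimensionless potential |
| `tau_s`   | PSP filter time constant      | 2       | steps |

The noise scale 0.3 sits in the *moderate* regime: wide enough that the
density (the learning factor below) carries information near threshold,
narrow enough not to drown the drive. The package's noise-level study
(`scripts/acceptance.R`, part 7) reproduces the qualitative shape — good
accuracy at scale 0.3, degraded accuracy at 3.0 — on the synthetic task.

## Networks as Bayesian networks

`nsnn_network()` stacks affine transforms of spike vectors into layers of
noisy LIF neurons, with a softmax read-out head computing an instantaneous
cross-entropy loss at every step (averaged over the window by default;
`loss_mode = "last"` keeps only the final step). Within one time step,
layers are evaluated in order and layer `l` consumes the *same-step* spikes
of layer `l - 1`; the only unit delay is the membrane recurrence itself.
Because every spike is a Bernoulli variable conditioned on earlier
variables, the joint distribution of all spikes factorizes as a Bayesian
network — `joint_log_prob()` evaluates it — and that factorization is what
makes both the exact oracle and the unbiased estimator below possible.

Storage is 0-based in time on disk and 1-based in memory; rollout arrays
are indexed `[sample, neuron, time]`. Rollouts store the uniform draws that
realized each spike decision; this is deliberate and is what the estimator
below re-uses.

## Noise-driven learning and the surrogate correspondence

The gradient of the expected loss with respect to layer-`l` parameters is a
sum over all spike configurations — intractable in general. Conditioning on
one spike variable at a time (local marginalization) turns it into an
expectation of per-variable terms: the gradient of each variable's firing
probability times the difference in loss between the variable's two values.
Approximating that loss difference to first order in the flipped spike
gives the **noise-driven learning** rule implemented in `ndl_backward()`:
a backward pass through time in which the derivative of a spike with
respect to its membrane is replaced by the noise *density*
`F'_eps(u - v_th)`, so each parameter update is the product of three
factors — pre-synaptic (`∇_θ u`), post-synaptic (the density), and a global
learning signal (`∇_o f` propagated from the head).

Surrogate-gradient learning does exactly this with an arbitrary bell-shaped
function in place of the density. The correspondence is made literal:
`surrogate_from_noise()` maps each noise family to the surrogate that
reproduces NDL exactly (Gaussian → erf-like bell, logistic → sigmoid
derivative, uniform → rectangle, height = density peak), and
`noise_from_surrogate()` inverts the map up to a scalar absorbed into the
learning rate (the common erf surrogate `(1/pi) exp(-x^2)` is Gaussian
noise with sd `1/sqrt(2)` and multiplier `1/sqrt(pi)`). The test suite
asserts bit-level agreement of the two backward passes on shared rollouts.

Two scope decisions in the backward pass:

* **The reset path is detached.** A spike's effect on *later* membranes
  through the reset is not differentiated (the carried-state derivative is
  `tau * (1 - o_t)` with the spike treated as a constant). This matches
  standard practice for unrolled SNN training and keeps the temporal credit
  path confined to the leak term.
* **Per-step loss, averaged.** The instantaneous loss is computed every
  step; the trainer averages it over the window by default, with
  last-step-only as a config switch, since either convention is defensible
  for the global signal.

## The exact oracle and the unbiased estimator

On networks with at most 16 binary spike variables (`sum(sizes) * T <= 16`,
65,536 configurations), `enumerate_expected_loss()` computes the expected
loss exactly by a *vectorized teacher-forced sweep over all
configurations*, carrying membranes and resets along each configuration's
own spike history. `exact_gradient()` differentiates the sum analytically —
score terms through the noise cdf plus pathwise head terms — and can
cross-check every coordinate against central finite differences of the
enumerated expectation (step `1e-5`, relative agreement `1e-4`).

`local_marginal_estimate()` is the sampled counterpart. With
`exact_delta = TRUE` the loss difference for flipping spike `(l, m, t)` is
computed by **full downstream re-evaluation with common random numbers**:
the rollout's stored uniform draws are reused, the flipped value feeds the
same-step downstream layers and all subsequent membranes and resets, and
every downstream spike is re-drawn from its conditional via the same
uniforms. This construction is what makes the estimator's expectation equal
the enumeration gradient *for any loss* — flipping a spike changes the
conditional distribution of everything downstream, so re-evaluating the
loss at fixed downstream spikes would not be unbiased. The acceptance suite
verifies unbiasedness on a 2-3-2 network over two time steps at 200,000
samples, comparing every parameter within three Monte-Carlo standard
errors (with an absolute floor of `1e-6` for coordinates whose true value
and sample variance are both below numerical resolution). With
`exact_delta = FALSE` the first-order loss difference is used instead,
which reproduces the NDL gradient identically per record; its bias vanishes
when the loss is multilinear in the spikes (verified at 200,000 samples on
a single spiking stage), and for the cross-entropy head the residual bias
is *reported* by `bias_variance_report()`, not asserted small.

## Stochastic stability

The continuous-time counterpart of the membrane dynamic is a
drift–diffusion system `du = f(u, I) dt + g(u, I) dW` with linear drift
`f = a1 * u + B1 * I` (`a1 = -1/tau_m` for a leaky membrane) and diffusion
`g = a2 + b2 * f` (additive plus drift-proportional). Stability against a
small initial perturbation is quantified by the sample Lyapunov exponent of
the error between two trajectories driven by the *same* Wiener process,
with closed-form bounds

```
a1 - a2^2/2 - b2^2 - 2 a2 b2  <=  LE  <=  a1 - a2^2/2 + b2^2/2 + a2 b2
```

valid when the diffusion difference satisfies
`a2 ||eps|| <= ||dg|| <= (a2 + b2) ||eps||`.

A subtlety the package refuses to paper over: the literal layer system with
purely additive noise (`b2 = 0`) has `dg = 0` — shared noise cancels in the
subtraction, the error decays deterministically at rate `a1`, and the bound
assumption is *violated* (its lower envelope demands `||dg|| = a2 ||eps||`
exactly at `b2 = 0`). The bounds therefore describe an error equation whose
diffusion genuinely carries the `a2..a2+b2` envelope. `simulate_pair()`
exposes both readings: `coupling = "envelope"` (default) integrates the
error SDE `d eps = a1 eps dt + (a2 + theta * b2) eps dW`, which satisfies
the assumption by construction and reproduces the additive-case exponent
`a1 - a2^2/2`; `coupling = "literal"` subtracts two trajectories of the
literal system, checks the envelope assumption per step, and flags the
violation. The test suite exercises both — including the literal additive
case decaying at `a1`, as shared-noise cancellation predicts.

Numerics: Euler–Maruyama with `dt = 1e-3` (halving `dt` moves the estimate
by under 0.05); the `limsup` is replaced by the least-squares slope of
`log ||eps||` over the window after a 20% burn-in (lower variance than the
endpoint ratio); horizons and pair counts are always reported in the result
object. The bound-coverage check uses 40 pairs per coefficient triple so
that the slope estimator's standard error (~0.03) is small against the
±0.1 acceptance band — at `b2` near zero the true exponent sits exactly on
the collapsed bound, and an under-powered estimate would leave the band by
chance.

## Perturbations

Four operators, used to compare noisy and deterministic models under
matched training: FGSM (`x + gamma * sign(grad_x loss)`, exact max-norm
budget), a direct-optimization attack (zero-initialized perturbation
ascended for 30 iterations at step 0.002 with an adaptive-moment solver,
renormalized to the L2 sphere each iteration; plain ascent behind a flag),
per-event random dropping for event tables (uniform Bernoulli thinning —
the combined space/time random-drop strategy has exactly this marginal;
window- and region-targeted variants are provided since no mixing
proportion is canonical), and spike-state flips injected *into the
dynamics* during a rollout (`rollout(..., flip_prob = beta)`): each hidden
spike state flips with probability `beta` and downstream layers, membranes
and resets consume the flipped value. Flips default to all spiking layers
including the last (switchable), since restricting them to earlier layers
is the less conservative reading.

On the synthetic task the flip sweep `beta = 0.01..0.04` leaves both model
families essentially at ceiling — the toy task is far easier than natural
image benchmarks — so the suite asserts the ensemble ordering (noisy at
least as accurate as deterministic at the strongest sweep point) and the
acceptance script additionally reports accuracies at `beta = 0.3`, where
the degradation is visible.

## Coding analytics and spike-train fitting

The neural code is the final spiking layer's output. Across repeated trials
of one input, `fano_factor()` measures spike-count variability per neuron
(variance/mean; *unbiased* variance with `n - 1`, recorded in the output
since the convention changes small-sample values), excluding silent neurons
and then averaging — exclusion-before-averaging is stated in the output
because the alternative order changes the number. `prediction_similarity()`
measures decision stability as the mean pairwise cosine of prediction
vectors. In trained noisy networks the two anti-correlate across inputs
(each input is one point; 20 trials per input by default): inputs with more
variable codes yield less stable predictions, the signature of a rate-based
code. The degenerate deterministic case — similarity exactly 1, Fano factor
exactly 0 — is reproduced by the vanishing-noise limit.

For fitting spike trains, `mmd_psp_loss()` compares PSP-filtered prefixes:
`L = (1/T) sum_t sum_{tau<=t} ||PSP(yhat)_tau - PSP(y)_tau||^2` with the
first-order kernel `PSP_tau = (1 - 1/tau_s) PSP_{tau-1} + y_tau / tau_s`,
`tau_s = 2`. The double sum collapses to a single weighted pass (weight
`T - tau + 1` on prefix `tau`), evaluated in `O(T)` and verified against
the literal double loop to `1e-12`. The loss is a premetric on rasters —
nonnegative, symmetric, zero exactly on equality for `tau_s > 1`; no
triangle inequality is claimed. No per-neuron normalization is applied
inside the norm. `fit_activity()` trains a network against target rasters
with this loss: the gradient flows through the linear PSP filter into the
output spikes and then through the noise-density factor back in time.

## Synthetic study conditions — and what they do not show

All data is generated, seeded, by the `gen_*` functions; the conditions
below were fixed once, when the experiments were designed.

* **Rate task** (`gen_rate_task`): 2 classes, 20 input channels, 10 steps,
  400 sequences; each class elevates its own block of channels by a
  contrast of 0.5 over a 0.2 baseline with per-step Gaussian noise of sd
  0.5. The contrast/noise pair was calibrated so that the task is
  *informative about noise level*: a moderate-noise network (scale 0.3)
  learns it to ≥95% within the epoch budget while an over-corrupted one
  (scale 3.0) cannot, giving the noise-level study a visible optimum. A
  linear readout of the time-averaged inputs solves the task at high
  contrast, and the zero-contrast variant is exactly chance — both are
  tested.
* **Teacher–student fitting** (`teacher_student_experiment`): a one-layer
  noisy teacher (8 inputs, 6 neurons, noise sd 0.2, weight gain 2 — mean
  firing rates around 0.2–0.5) responds to smooth sinusoidal stimuli
  (12 stimuli, 30 steps, 15 trials; 8 train / 4 held out); a student of the
  same architecture is fitted for 100 epochs at learning rate 0.02 with
  8 rollouts per update. Evaluation smooths trial-averaged rates with a
  5-step moving window (the binning is a free choice; it is reported with
  the result). Teacher draws with very sparse neurons (rates of a few
  percent) are genuinely harder — their fitting gradient is small — and
  depress the held-out correlation for noisy and deterministic students
  alike; the multi-seed means reported by the tests and the acceptance
  script include such draws.
* **Event streams** (`gen_event_stream`): a binomial event budget
  (`density` per pixel-step) split between a moving-bar pattern and uniform
  background — enough structure for the dropping operators, nothing more.

What passing these tests does *not* show: the generators produce
stationary, low-dimensional, noise-free-labelled data with independent
Gaussian input noise; there is no refractoriness beyond the hard reset, no
temporally correlated (colored) membrane noise, no convolutional or
recurrent synaptic structure, and the scale is orders of magnitude below
natural-image or event-camera benchmarks. Results here validate the
*mechanisms* — firing law, estimator unbiasedness, the surrogate
correspondence, stability bounds, loss identities — not benchmark-level
performance claims.

## Numerical choices

* All randomness flows through explicit seeds; child seeds are derived
  arithmetically so that independent components of an experiment get
  decoupled streams. Identical seeds give bit-identical rollouts, curves
  and tables.
* Training is plain SGD (momentum optional) for auditability.
  `fit_activity()` clips each update's gradient to L2 norm 2: the MMD
  gradient can overshoot a unit into the far-subthreshold regime where the
  noise-density factor — and with it the gradient — vanishes, permanently
  silencing the unit; clipping guards the first updates without changing
  the estimator.
* The enumeration oracle is capped at 16 binary variables (65,536
  configurations), which keeps every oracle-based test in seconds.
* Monte-Carlo comparisons use 3-standard-error bands with an absolute
  floor of `1e-6` for coordinates whose sample variance is zero; multi-way
  marginal checks widen to 4 standard errors to keep the familywise error
  in check.
* Problem sizes throughout (2-3-2 oracle nets, 24-16 task networks,
  horizons of 10–50 steps, 2×10^5 estimator samples, 50 trajectory pairs)
  were chosen to make every statistical check well-powered while keeping
  the full suite and the acceptance script each within a few minutes on a
  single CPU.

## Known limitations

The local-marginalization estimator with exact loss differences re-runs the
downstream network once per spike variable and is therefore only practical
on oracle-scale networks (its purpose); the first-order variant is the
scalable rule. Convolutional transforms, batch-normalization variants and
online/local credit assignment are out of scope. The stability analysis
verifies the scalar/diagonal setting in which the bounds are instantiated;
general matrix couplings in the diffusion are not covered. The fitting
harness assumes aligned stimulus/response sampling and binary targets.
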