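---
title: "Valence-based spatial learning with opposing dopamine and serotonin plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valence-based spatial learning with opposing dopamine and serotonin plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`navplast` simulates goal-directed spatial learning in which two
neuromodulators gate the direction of synaptic plasticity: dopamine (DA)
converts spike-timing coincidences into long-term potentiation when an
agent reaches a reward, and serotonin (5-HT) converts them into
depression under aversive outcomes. This vignette is the package's
account of the model, the numerical choices behind the implementation,
and what the simulated experiments can and cannot show.

## The network

**Place cells.** Position is encoded by 121 Poisson place cells on an
11 x 11 grid with spacing and tuning width `sigma = 0.4` a.u. covering
the `[-2, 2]^2` arena. Cell `i` fires at
`rate_i(x) = 400 * exp(-||x - c_i||^2 / sigma^2)` Hz. Spikes are drawn
per 1-ms step by Bernoulli thinning with `p = rate * dt` (0.4 at the
field centre); the constructor rejects `rate * dt >= 1`.

**Action neurons.** Forty direction-coding neurons follow a zero-order
spike response model: the membrane potential is a weighted sum of
double-exponential EPSPs (`eps0 = 20` mV ms, `tau_m = 20` ms,
`tau_s = 5` ms) from place cells and from the other action neurons,
restricted to spikes arriving strictly after the neuron's own last
spike, plus a refractory after-potential `chi = -5` mV decaying with
`tau_m`. Spikes are emitted stochastically at the escape rate
`60 * exp((u - 16 mV) / delta_u)` Hz. The emission window `delta_u` has
no published value (it is inherited from earlier work on this
architecture); the package defaults to 2 mV and exposes it in
`membrane_params()`.

**Lateral ring and readout.** The action layer carries fixed
N-winner-takes-all connectivity: uniform inhibition `w- = -300`
(divided by N) plus ring excitation `w+ = 100` row-normalised over
`f(k, k') = (1 - delta_kk') * exp(20 * cos(theta_k - theta_k'))`, which
peaks at immediate neighbours. Preferred directions are
`theta_k = 2 pi k / 40` and only feed-forward weights are plastic. The
action is the population vector
`a(t) = (1/N) * sum_k rho_k(t) * a0 * (sin theta_k, cos theta_k)` with
`a0 = 0.08` and `rho_k` the spike train filtered by a unit-integral
double-exponential kernel (50 ms / 20 ms).

**Units of the readout.** The published description of this
architecture does not state whether `a(t)` is a displacement per step or a velocity. The
package reads `rho` in Hz and treats `a(t)` as a velocity (a.u./s),
applying `dx = a(t) * dt_move` every `dt_move = 10` ms. Under this
reading the agent traverses the arena within seconds, consistent with
the reported latency scales; the per-step reading is roughly twenty
times slower and produces no first rewards within an episode.

## The plasticity rules

Both rules share three ingredients:

* **STDP windows.** DA: symmetric, `W_DA(s) = A_DA * exp(-|s|/10 ms)`.
  5-HT: strictly causal and depressive, `A_5HT * exp(-s/10 ms)` for
  `s > 0`, half amplitude at `s = 0`, zero for `s < 0`. Windows are
  stored as magnitudes; the depressive sign is carried by the outcome
  variable.
* **Eligibility traces** (proto-weights): every pre/post pairing adds
  its window value to a per-synapse accumulator decaying with
  `tau_e = 2 s` (DA) or `5 s` (5-HT).
* **Clipping** of feed-forward weights to `[1, 3]` at every update
  point. Initial weights are uniform at 2, the midpoint of the clip
  range (initialisation is not specified in the source material; the
  midpoint leaves equal headroom for potentiation and depression).

**Sequential weight change (SWC)** resolves each episode with exactly
one modulator: a reward applies `+eta_DA * Gamma_DA`, read 300 ms after
the reward (consummatory delay; the trace keeps decaying through the
delay and place cells are deactivated at the outcome, so no new
pairings accrue); a failure applies `-eta_5HT * Gamma_5HT` at episode
end. Parameters: `A_DA = A_5HT = 1`, `eta = 0.01`. An online variant
accumulates the depressive candidate continuously at rate
`eta_5HT / T_max` and commits it only on failure.

**Competitive weight change (CWC)** integrates
`dw/dt = eta * (R_DA(t) * Gamma_DA - R_5HT(t) * Gamma_5HT)`
continuously: 5-HT responds tonically from episode start until the
outcome, DA phasically for `T_DA = 1 s` after a reward. Parameters:
`A_DA = 1`, `A_5HT = 0.01`, `eta = 1e-4`, `R_DA = R_5HT = 1`. A
rewarded episode can still depress synapses whose serotonergic integral
dominates — the sign predicate `cwc_sign_condition()` compares the two
episode integrals and is tested against independent quadrature.

**Time unit of the competitive rate.** The source material states
neither the unit of `dw/dt` nor the integration step. Read per-second,
`eta = 1e-4` moves a path synapse by about +0.03 per rewarded episode
against a clip window of width 2, and the rule never lifts performance
above chance. Read per-integration-step (1 ms, the natural simulation
step for `tau_s = 5` ms), the rule reproduces the published behaviour:
it learns, DA+5-HT outperforms DA-only, and DA-only saturates weights.
The package therefore treats the published `eta` as a per-millisecond
rate. Weight updates are applied (and clipped) every `dt_move` block
using the current proto-weights; since `tau_e >= 2 s`, the 10-ms
rectangle rule is accurate to well under a percent.

**Rate-based variants** replace spike pairing with its expectation:
the pairing rate of a synapse is `nu_pre * nu_post * int W(s) ds`
(`2 A tau` for the symmetric window, `A tau` for the causal one),
accumulated through the same eligibility traces and committed by the
same outcome logic. This is the package's resolution of a garbled
printed formula for the rate rule: the surrounding argument — plasticity
here depends on rates and the window integral, not on precise
timing — fixes the drift up to the stated constants. A postsynaptic
threshold term of the BCM form may exist in the original; it cannot be
recovered from the text and is deliberately not invented.

## Tasks

**Morris water maze.** Reward disc of radius 0.3 at (1.5, 1.5), start
at the origin, `T_max = 15 s`. Water is aversive: an unrewarded episode
is a serotonergic episode. Boundary crossings displace the agent by
`d0 = 0.01` along the inward wall normal (sum of normals at corners).

**Reversal learning (open field).** Reward at (1.5, 1.5) and punisher
at (-1.5, -1.5) for episodes 1-20; the centres swap for episodes 21-40.
Episodes end at either zone. Here the outcomes are mutually exclusive,
so both rules operate sequentially: reward commits the dopaminergic
update, punishment the serotonergic one, and an episode that reaches
neither zone commits nothing (no water, hence no tonic aversive cue —
this differs from the water maze on purpose). Under the competitive
rule the serotonergic commitment is the episode integral of
`R_5HT * Gamma_5HT`, gated by the punishment actually occurring.

**Optogenetic-style perturbations.** Inhibition sets the serotonergic
amplitude to zero (`A_5HT` for SWC, `R_5HT-Amp` for CWC); activation
doubles it. The published experiment perturbs three intervals of the
run but gives their positions only graphically; the package takes the
schedule as configuration. The packaged default used in the tests is
three seven-episode intervals — episodes 6-12, 20-26 and 34-40 — spread
over the run with the last covering the final episodes at which the
effect is scored.

**Probe test.** Spatial memory is probed by a fixed-duration episode
with learning frozen and the reward disabled (`run_probe()`); the
summary statistic is the median distance of the trajectory to the
platform centre. The published curves do not define this protocol; the
probe form here mirrors the behavioural convention, and "centre" is
taken as the platform centre rather than the arena centre.

## Episode engine

The per-millisecond loop is compiled (Rcpp). Three implementation
choices matter for exactness:

* EPSP, rate-filter and STDP traces use exact two-state exponential
  recursions; dropping presynaptic spikes at a postsynaptic spike
  (the strict `t > t_hat` rule) is implemented as a per-neuron reset of
  the accumulators.
* Eligibility accumulators are stored in lazily rescaled coordinates
  (`Gamma(t) = exp(-t/tau_e) * G(t)`), so pairings cost one add and no
  per-step decay of the 40 x 121 matrices is needed; over a 15-s
  episode the scale factor stays below `exp(8)`, far from overflow.
* Place cells further than `sigma * sqrt(log(peak/1e-3))` from the
  agent (rate below 1e-3 Hz) are treated as silent in the thinning
  loop; the expected number of spikes so discarded is below 2e-3 per
  episode.

Episode streams use a dedicated xoshiro256+ generator seeded per
episode from the simulation seed; simulation seeds are the first `M`
draws of `sample.int` under the master seed. Identical configurations
reproduce bit-identical results, and the tests assert it. The engine's
proto-weights are cross-checked against the R-level
window-sum/eligibility composition on recorded spike trains.

## What the simulations show — and what they cannot

All behavioural data are generated by the simulator itself; there is no
external data. The batch sizes used by the packaged checks are scaled
down from the published M = 1,000: M = 200 for the learning-curve and
perturbation comparisons, M = 500 for the first-reward divergence
(simulations stop at their first reward, which the statistic cannot
depend on), and M = 100 per serotonergic rate in the reversal sweep.
The first-reward divergence between the DA+5-HT and DA-only conditions
is the Jensen-Shannon divergence (base-2 logarithms) between empirical
first-reward distributions on a shared discrete support with an
overflow bin for never-rewarded simulations. Two statistics are
provided, because the published comparison does not define its support:
the *episode index* of the first reward (`first_reward_distribution()`)
and the *latency* of the first reward quantized to 1-s bins
(`first_reward_latency_distribution()`). They measure different things.
Serotonergic depression makes the agent avoid previously failed paths,
so it shortens the number of episodes to the first reward — the
episode-index divergence is therefore substantial (about 0.12-0.17 at
M = 500 under both rules). The within-episode exploration process
itself is unaltered by serotonin, so the latency divergence is small
(about 0.04-0.06), matching the published magnitudes and the published
conclusion that exploration is unchanged; the packaged divergence
checks accordingly use the quantized-latency statistic. Finite-sample
JSD estimates carry a positive bias that grows as M shrinks, which is
one reason the published values (0.075 and 0.063) should only be
expected within sampling error at reduced M.

The model is a mean-field behavioural account. It does not emulate
receptor-level diversity (5-HT2C vs 5-HT4, D1 vs D2), GABAergic
interactions, metaplasticity, conductance-based membrane dynamics,
plastic lateral connectivity or learned place fields — so agreement of
the packaged checks with the published curves supports the systemic
opponency hypothesis, not any particular receptor mechanism. Within
the model, conclusions are also conditional on the open choices
documented above (emission window, movement units, competitive-rate
unit, perturbation schedule), each fixed once and kept fixed.

## A worked example

```{r example}
library(navplast)

cfg_full <- nav_config("mwm", "swc", episodes = 40, n_sims = 50, seed = 1)
cfg_da <- nav_config("mwm", "swc", episodes = 40, n_sims = 50, seed = 1,
                     modulators = "da")
b_full <- run_batch(cfg_full)
b_da <- run_batch(cfg_da)
summary(b_full)
plot(b_full, b_da)
```
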