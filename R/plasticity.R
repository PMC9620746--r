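#' STDP learning window
#'
#' Two shapes are supported. The dopamine window is symmetric and
#' potentiating, `W(s) = A * exp(-|s|/tau)`. The serotonin window is
#' strictly causal and depressive: `W(s) = A * exp(-s/tau)` for `s > 0`,
#' `A/2` at `s = 0`, and 0 for `s < 0`. Windows are stored as magnitudes
#' (`A > 0`); the depressive sign of serotonin is carried by the outcome
#' signal `R` of the update rules.
#'
#' @param shape `"symmetric_da"` or `"causal_depressive_5ht"`.
#' @param amplitude Window amplitude `A` (dimensionless).
#' @param tau Window time constant (ms).
#' @return A list of class `stdp_window`.
#' @export
stdp_window <- function(shape = c("symmetric_da", "causal_depressive_5ht"),
                        amplitude = 1, tau = 10) {
  shape <- match.arg(shape)
  stopifnot(amplitude >= 0, tau > 0)
  structure(list(shape = shape, amplitude = amplitude, tau = tau),
            class = "stdp_window")
}

#' Evaluate an STDP window at pre-to-post lags
#'
#' @param s Lag `t_post - t_pre` (ms); vectorised.
#' @param w An [stdp_window()] object.
#' @return Window magnitude (dimensionless).
#' @export
window_value <- function(s, w) {
  if (w$shape == "symmetric_da") {
    w$amplitude * exp(-abs(s) / w$tau)
  } else {
    out <- ifelse(s > 0, w$amplitude * exp(-s / w$tau), 0)
    out[s == 0] <- w$amplitude / 2
    out
  }
}

#' Sum of window values over all pre/post spike pairs
#'
#' `sum over (t_pre, t_post) of W(t_post - t_pre)`; order-independent.
#'
#' @param pre_spikes,post_spikes Numeric spike-time vectors (ms).
#' @param w An [stdp_window()] object.
#' @return Scalar pairing sum (dimensionless).
#' @export
pairwise_stdp_sum <- function(pre_spikes, post_spikes, w) {
  if (!length(pre_spikes) || !length(post_spikes)) return(0)
  sum(window_value(outer(post_spikes, pre_spikes, `-`), w))
}

#' Eligibility trace
#'
#' Exponentially decaying per-synapse memory with kernel
#' `exp(-t/tau_e)` for `t >= 0`. `tau_e` defaults follow the modulators:
#' 2 s for dopamine, 5 s for serotonin.
#'
#' @param tau_e Decay time constant (s).
#' @param value Initial trace value.
#' @return A list of class `eligibility_trace`.
#' @export
eligibility_trace <- function(tau_e = 2, value = 0) {
  stopifnot(tau_e > 0)
  structure(list(tau_e = tau_e, value = value), class = "eligibility_trace")
}

#' Advance an eligibility trace
#'
#' Decays the trace by `exp(-dt/tau_e)` and then adds `increment`. Applied
#' at every STDP pairing event this reproduces the exact convolution of
#' the event train with the trace kernel.
#'
#' @param trace An [eligibility_trace()] object.
#' @param increment Pairing-sum increment added after the decay.
#' @param dt Elapsed time (ms).
#' @return The updated trace.
#' @export
update_trace <- function(trace, increment = 0, dt = 0) {
  stopifnot(dt >= 0)
  trace$value <- trace$value * exp(-dt / (1000 * trace$tau_e)) + increment
  trace
}

#' Plasticity parameters
#'
#' Bundles the learning rule with its constants. Defaults are the
#' published parameter rows of the two rules: sequential weight change
#' (SWC): `A_DA = A_5HT = 1`, `eta = 0.01`; competitive weight change
#' (CWC): `A_DA = 1`, `A_5HT = 0.01`, `eta = 1e-4`, modulator amplitudes
#' `R_DA = R_5HT = 1`, dopamine phasic duration 1 s. Both share the STDP
#' time constant 10 ms, eligibility decays 2 s (DA) / 5 s (5-HT) and clip
#' bounds [1, 3].
#'
#' @param rule One of `"swc"`, `"cwc"`, `"swc-online"`, `"rate-swc"`,
#'   `"rate-cwc"`.
#' @param ada,a5ht STDP window amplitudes for DA and 5-HT.
#' @param eta_da,eta_5ht Learning rates (for CWC the shared `eta`).
#' @param w_min,w_max Clip bounds for feed-forward weights.
#' @param rda_amp,r5ht_amp Modulator response amplitudes (CWC).
#' @param t_da Dopamine phasic duration after reward (s, CWC).
#' @param da_delay Delay of the DA update after reward (s, SWC).
#' @param tau_stdp STDP window time constant (ms).
#' @param tau_e_da,tau_e_5ht Eligibility-trace decays (s).
#' @param mod_5ht Multiplier on the serotonergic amplitude; 0 disables
#'   5-HT (DA-only condition), 2 models optogenetic activation.
#' @return A list of class `plasticity_params`.
#' @export
plasticity_params <- function(rule = c("swc", "cwc", "swc-online",
                                       "rate-swc", "rate-cwc"),
                              ada = NULL, a5ht = NULL,
                              eta_da = NULL, eta_5ht = NULL,
                              w_min = 1, w_max = 3,
                              rda_amp = 1, r5ht_amp = 1, t_da = 1,
                              da_delay = 0.3, tau_stdp = 10,
                              tau_e_da = 2, tau_e_5ht = 5, mod_5ht = 1) {
  rule <- match.arg(rule)
  cwc_like <- rule %in% c("cwc", "rate-cwc")
  if (is.null(ada)) ada <- 1
  if (is.null(a5ht)) a5ht <- if (cwc_like) 0.01 else 1
  if (is.null(eta_da)) eta_da <- if (cwc_like) 1e-4 else 0.01
  if (is.null(eta_5ht)) eta_5ht <- eta_da
  stopifnot(w_min < w_max, eta_da >= 0, eta_5ht >= 0, mod_5ht >= 0,
            tau_stdp > 0, tau_e_da > 0, tau_e_5ht > 0, t_da > 0)
  structure(
    list(rule = rule, ada = ada, a5ht = a5ht, eta_da = eta_da,
         eta_5ht = eta_5ht, w_min = w_min, w_max = w_max,
         rda_amp = rda_amp, r5ht_amp = r5ht_amp, t_da = t_da,
         da_delay = da_delay, tau_stdp = tau_stdp, tau_e_da = tau_e_da,
         tau_e_5ht = tau_e_5ht, mod_5ht = mod_5ht),
    class = "plasticity_params"
  )
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf(
    "Plasticity rule %s: A_DA = %g, A_5HT = %g, eta = (%g, %g), clip [%g, %g]\n",
    x$rule, x$ada, x$a5ht, x$eta_da, x$eta_5ht, x$w_min, x$w_max))
  invisible(x)
}

#' Sequential weight change at episode end
#'
#' Exactly one modulator resolves the episode: a rewarded episode applies
#' the dopamine proto-weight read `da_delay` after the reward
#' (`dw = eta_da * gamma_da`, potentiation); an unrewarded or punished
#' episode applies the serotonin proto-weight read at episode end
#' (`dw = -eta_5ht * gamma_5ht`, depression). The proto-weights passed in
#' must already be read at the rule's readout times.
#'
#' @param gamma_da,gamma_5ht Proto-weight matrices (pairing sums filtered
#'   by the eligibility traces), read at the readout time.
#' @param outcome `"reward"`, `"none"` or `"punishment"`.
#' @param p A [plasticity_params()] object.
#' @param neutral_updates Should a `"none"` outcome trigger the
#'   serotonergic update? `TRUE` for the water maze (water is aversive),
#'   `FALSE` for open-field reversal learning.
#' @return The weight-change matrix `dw` (before clipping).
#' @export
swc_apply <- function(gamma_da, gamma_5ht, outcome, p = plasticity_params("swc"),
                      neutral_updates = TRUE) {
  if (outcome == "reward") {
    p$eta_da * gamma_da
  } else if (outcome == "punishment" || neutral_updates) {
    -p$eta_5ht * gamma_5ht
  } else {
    gamma_5ht * 0
  }
}

#' Online serotonergic candidate update (SWC variant)
#'
#' The continuous form of the serotonergic arm of SWC: candidate
#' depressive updates accumulate at rate `eta_5ht / t_max` against the
#' running serotonin proto-weight, and are committed only if the episode
#' ends without reward (a reward discards them in favour of the dopamine
#' update).
#'
#' @param gamma_5ht Current serotonin proto-weight matrix.
#' @param dt Integration step (s).
#' @param t_max Maximum episode duration (s).
#' @param p A [plasticity_params()] object.
#' @return Incremental candidate weight change (non-positive).
#' @export
swc_online_apply <- function(gamma_5ht, dt, t_max = 15,
                             p = plasticity_params("swc-online")) {
  -(p$eta_5ht / t_max) * gamma_5ht * dt
}

#' Competitive weight change: one integration step
#'
#' `dw = eta * (R_DA(t) * gamma_da - R_5HT(t) * gamma_5ht) * dt`, where the
#' modulator responses are step functions: serotonin is active on
#' `[0, t_rew]` and dopamine on `(t_rew, t_rew + t_da]`. The rule's
#' canonical time unit is the millisecond integration step: the
#' published competitive learning rate (`eta = 1e-4`) is per
#' millisecond, and the simulation engine integrates it accordingly.
#' The sign of the integrated change is unit-independent.
#'
#' @param gamma_da,gamma_5ht Current proto-weight matrices.
#' @param t Current time (s).
#' @param t_rew Time of the outcome (reward time, or episode end when
#'   unrewarded; `Inf` while the episode is still running).
#' @param p A [plasticity_params()] object.
#' @param dt Integration step, in the same unit as `eta` is expressed
#'   per (milliseconds for the published rate).
#' @return Weight increment matrix for this step.
#' @export
cwc_step <- function(gamma_da, gamma_5ht, t, t_rew = Inf,
                     p = plasticity_params("cwc"), dt = 0.01) {
  rda <- if (t > t_rew && t <= t_rew + p$t_da) p$rda_amp else 0
  r5 <- if (t <= t_rew) p$r5ht_amp * p$mod_5ht else 0
  p$eta_da * (rda * gamma_da - r5 * gamma_5ht) * dt
}

#' Predicted sign of the competitive net change
#'
#' Compares the episode integrals `int R_DA(t) gamma_da(t) dt` and
#' `int R_5HT(t) gamma_5ht(t) dt`; potentiation is predicted where the
#' dopaminergic integral dominates. This is equivalent to integrating
#' [cwc_step()] over the episode and reading the sign.
#'
#' @param t Time grid (s).
#' @param gamma_da,gamma_5ht Proto-weight histories; matrices with
#'   `length(t)` rows (or vectors for a single synapse).
#' @param t_rew Outcome time (s).
#' @param p A [plasticity_params()] object.
#' @return Character vector per synapse: `"LTP"`, `"LTD"` or `"none"`.
#' @export
cwc_sign_condition <- function(t, gamma_da, gamma_5ht, t_rew,
                               p = plasticity_params("cwc")) {
  gamma_da <- as.matrix(gamma_da)
  gamma_5ht <- as.matrix(gamma_5ht)
  rda <- ifelse(t > t_rew & t <= t_rew + p$t_da, p$rda_amp, 0)
  r5 <- ifelse(t <= t_rew, p$r5ht_amp * p$mod_5ht, 0)
  ida <- trapz_cols(t, rda * gamma_da)
  i5 <- trapz_cols(t, r5 * gamma_5ht)
  ifelse(ida > i5, "LTP", ifelse(ida < i5, "LTD", "none"))
}

trapz_cols <- function(t, m) {
  m <- as.matrix(m)
  dt <- diff(t)
  colSums((m[-nrow(m), , drop = FALSE] + m[-1, , drop = FALSE]) / 2 * dt)
}

#' Clip synaptic weights to the stable range
#'
#' Elementwise clamp to `[w_min, w_max]` (defaults [1, 3]).
#'
#' @param w Weight matrix.
#' @param p A [plasticity_params()] object.
#' @return Clipped matrix.
#' @export
clip_weights <- function(w, p = plasticity_params()) {
  pmin(pmax(w, p$w_min), p$w_max)
}

#' Rate-based plasticity drift
#'
#' Timing-free counterpart of the spiking rules: the expected pairing
#' rate of a synapse is the product of pre- and postsynaptic rates with
#' the integral of its STDP window (`2 A tau` for the symmetric dopamine
#' window, `A tau` for the causal serotonin window), accumulated through
#' the eligibility trace and signed by the outcome variable `R`
#' (Hebbian for dopamine, anti-Hebbian for serotonin).
#'
#' @param nu_pre Presynaptic rate (Hz).
#' @param nu_post Postsynaptic rate (Hz).
#' @param w An [stdp_window()] object.
#' @param R Outcome sign: `+1` (dopamine) or `-1` (serotonin).
#' @param eta Learning rate.
#' @return Drift `eta * R * int(W) * nu_pre * nu_post` (per second;
#'   the window integral is taken in seconds).
#' @export
rate_based_update <- function(nu_pre, nu_post, w, R = 1, eta = 0.01) {
  stopifnot(R %in% c(-1, 1))
  wint <- window_integral(w) / 1000  # ms -> s
  eta * R * wint * nu_pre * nu_post
}

#' Integral of an STDP window
#'
#' `int W(s) ds` in dimensionless * ms: `2 A tau` for the symmetric
#' dopamine shape, `A tau` for the causal serotonin shape.
#'
#' @param w An [stdp_window()] object.
#' @return Scalar integral (ms).
#' @export
window_integral <- function(w) {
  if (w$shape == "symmetric_da") 2 * w$amplitude * w$tau
  else w$amplitude * w$tau
}
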