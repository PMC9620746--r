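#' Build a square grid of Gaussian place cells
#'
#' Place-cell centres are laid out on a regular grid with spacing `sigma`
#' covering a square arena of side `arena_side`, symmetric about the origin.
#' With the defaults (side 4 a.u., spacing 0.4 a.u.) this gives an 11 x 11
#' grid of 121 cells.
#'
#' @param arena_side Side length of the square arena (a.u.).
#' @param sigma Tuning width and grid spacing (a.u.); must divide
#'   `arena_side` evenly so that `arena_side / sigma + 1` is an integer
#'   number of centres per side.
#' @param peak_rate Maximal firing rate at the field centre (Hz).
#' @return An object of class `place_grid` with elements `centers`
#'   (n x 2 matrix), `sigma` and `peak_rate`.
#' @examples
#' g <- build_place_grid()
#' nrow(g$centers)  # 121
#' @export
build_place_grid <- function(arena_side = 4, sigma = 0.4, peak_rate = 400) {
  stopifnot(arena_side > 0, sigma > 0, peak_rate > 0)
  n_side <- arena_side / sigma + 1
  if (abs(n_side - round(n_side)) > 1e-8) {
    stop("arena_side must be an integer multiple of sigma", call. = FALSE)
  }
  n_side <- as.integer(round(n_side))
  half <- arena_side / 2
  ax <- seq(-half, half, length.out = n_side)
  centers <- as.matrix(expand.grid(x = ax, y = ax))
  dimnames(centers) <- NULL
  structure(
    list(centers = centers, sigma = sigma, peak_rate = peak_rate),
    class = "place_grid"
  )
}

#' @export
print.place_grid <- function(x, ...) {
  cat(sprintf(
    "Place-cell grid: %d cells (%d per side), sigma = %g a.u., peak rate = %g Hz\n",
    nrow(x$centers), as.integer(sqrt(nrow(x$centers))), x$sigma, x$peak_rate
  ))
  invisible(x)
}

#' Place-cell firing rates at a position
#'
#' Gaussian tuning: `rate_i = peak_rate * exp(-||x - c_i||^2 / sigma^2)`.
#'
#' @param x Numeric length-2 position (a.u.).
#' @param grid A [build_place_grid()] object.
#' @return Numeric vector of rates (Hz), one per cell.
#' @export
place_cell_rates <- function(x, grid) {
  stopifnot(length(x) == 2, all(is.finite(x)))
  d2 <- (grid$centers[, 1] - x[1])^2 + (grid$centers[, 2] - x[2])^2
  grid$peak_rate * exp(-d2 / grid$sigma^2)
}

#' Membrane parameters of the action neurons
#'
#' Defaults follow the spike-response-model constants used throughout:
#' membrane time constant 20 ms, EPSP rise time 5 ms, refractory scale
#' -5 mV, EPSP scale 20 mV ms, threshold 16 mV, emission window 2 mV and
#' maximal output rate 60 Hz. The resting potential is 0 mV.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_s EPSP rise time (ms).
#' @param chi Refractory scale factor (mV), non-positive.
#' @param eps0 EPSP scale (mV ms).
#' @param theta Spike threshold (mV).
#' @param delta_u Stochastic-emission voltage window (mV).
#' @param lambda0 Output rate at threshold (Hz).
#' @return A list of class `membrane_params`.
#' @export
membrane_params <- function(tau_m = 20, tau_s = 5, chi = -5, eps0 = 20,
                            theta = 16, delta_u = 2, lambda0 = 60) {
  stopifnot(tau_m > tau_s, tau_s > 0, lambda0 > 0, delta_u > 0, chi <= 0)
  structure(
    list(tau_m = tau_m, tau_s = tau_s, chi = chi, eps0 = eps0,
         theta = theta, delta_u = delta_u, lambda0 = lambda0),
    class = "membrane_params"
  )
}

#' EPSP kernel
#'
#' Double-exponential postsynaptic potential
#' `eps(t) = eps0/(tau_m - tau_s) * (exp(-t/tau_m) - exp(-t/tau_s))` for
#' `t >= 0` and 0 before the spike.
#'
#' @param t Time since the presynaptic spike (ms); vectorised.
#' @param p A [membrane_params()] object.
#' @return Potential contribution (mV).
#' @export
epsp_kernel <- function(t, p = membrane_params()) {
  if (p$tau_m == p$tau_s) stop("singular kernel: tau_m == tau_s", call. = FALSE)
  out <- p$eps0 / (p$tau_m - p$tau_s) *
    (exp(-t / p$tau_m) - exp(-t / p$tau_s))
  out[t < 0] <- 0
  out
}

#' Bernoulli thinning of an inhomogeneous Poisson process
#'
#' One time step of width `dt`: a spike is emitted with probability
#' `rate * dt` (the rate expressed per millisecond). `rate * dt >= 1` is
#' rejected as a discretisation error.
#'
#' @param rate Firing rate (Hz); vectorised.
#' @param dt Step width (ms).
#' @return Logical vector of spike indicators.
#' @export
sample_poisson <- function(rate, dt = 1) {
  stopifnot(all(rate >= 0), dt > 0)
  p <- rate * dt / 1000
  if (any(p >= 1)) {
    stop("rate * dt >= 1: time step too coarse for Bernoulli thinning",
         call. = FALSE)
  }
  stats::runif(length(p)) < p
}

#' Membrane potential of the action neurons (reference implementation)
#'
#' Sums feed-forward and lateral EPSPs arriving strictly after each
#' neuron's last spike, plus the refractory after-potential
#' `chi * exp((t_hat - t)/tau_m)`. This direct spike-sum form is the
#' reference against which the incremental engine is verified.
#'
#' @param state List with `place_spikes` (list of numeric spike-time
#'   vectors, ms, one per place cell), `action_spikes` (same, per action
#'   neuron) and `last_post_spike` (numeric per action neuron, `-Inf` if
#'   the neuron has not spiked).
#' @param w_feed Feed-forward weight matrix (n_action x n_place).
#' @param w_lat Lateral weight matrix (n_action x n_action).
#' @param t Evaluation time (ms).
#' @param p A [membrane_params()] object.
#' @return Numeric vector of membrane potentials (mV).
#' @export
membrane_potential <- function(state, w_feed, w_lat, t, p = membrane_params()) {
  n_act <- nrow(w_feed)
  u <- numeric(n_act)
  for (j in seq_len(n_act)) {
    t_hat <- state$last_post_spike[j]
    for (i in seq_len(ncol(w_feed))) {
      ts <- state$place_spikes[[i]]
      ts <- ts[ts > t_hat & ts <= t]
      if (length(ts)) u[j] <- u[j] + w_feed[j, i] * sum(epsp_kernel(t - ts, p))
    }
    for (k in seq_len(n_act)) {
      if (k == j) next
      ts <- state$action_spikes[[k]]
      ts <- ts[ts > t_hat & ts <= t]
      if (length(ts)) u[j] <- u[j] + w_lat[j, k] * sum(epsp_kernel(t - ts, p))
    }
    if (is.finite(t_hat) && t >= t_hat) {
      u[j] <- u[j] + p$chi * exp((t_hat - t) / p$tau_m)
    }
  }
  u
}

#' Instantaneous output rate of an action neuron
#'
#' Exponential escape rate `lambda0 * exp((u - theta)/delta_u)`.
#'
#' @param u Membrane potential (mV); vectorised.
#' @param p A [membrane_params()] object.
#' @return Rate (Hz).
#' @export
action_rate <- function(u, p = membrane_params()) {
  p$lambda0 * exp((u - p$theta) / p$delta_u)
}

#' Lateral ring connectivity of the action layer
#'
#' Fixed N-winner-takes-all coupling between direction-coding neurons:
#' uniform inhibition `w_minus / n` plus row-normalised excitation
#' `w_plus * f(k, k') / sum_k' f(k, k')` with
#' `f(k, k') = (1 - delta_kk') * exp(zeta * cos(theta_k - theta_k'))`.
#' Preferred directions are `theta_k = 2 pi k / n`, `k = 1..n`.
#'
#' @param n_action Number of action neurons.
#' @param w_minus Total inhibitory weight (negative).
#' @param w_plus Total excitatory weight per row.
#' @param zeta Angular sharpness of the excitatory profile.
#' @param a0 Magnitude of the preferred-direction action vectors
#'   (a.u. per second at unit rate); carried along for the readout.
#' @return A list of class `lateral_connectivity` with the weight matrix
#'   `w`, angles `theta`, action vectors `vectors` (n x 2) and the
#'   parameters.
#' @export
lateral_connectivity <- function(n_action = 40, w_minus = -300, w_plus = 100,
                                 zeta = 20, a0 = 0.08) {
  stopifnot(n_action >= 2)
  theta <- 2 * pi * seq_len(n_action) / n_action
  f <- exp(zeta * outer(theta, theta, function(a, b) cos(a - b)))
  diag(f) <- 0
  w <- w_minus / n_action + w_plus * f / rowSums(f)
  vectors <- a0 * cbind(sin(theta), cos(theta))
  structure(
    list(w = w, theta = theta, vectors = vectors, n_action = n_action,
         w_minus = w_minus, w_plus = w_plus, zeta = zeta, a0 = a0),
    class = "lateral_connectivity"
  )
}

#' Lateral weight matrix
#'
#' Convenience accessor returning only the fixed weight matrix of
#' [lateral_connectivity()].
#'
#' @inheritParams lateral_connectivity
#' @return An `n_action` x `n_action` numeric matrix.
#' @export
lateral_weights <- function(n_action = 40, w_minus = -300, w_plus = 100,
                            zeta = 20) {
  lateral_connectivity(n_action, w_minus, w_plus, zeta)$w
}

#' Causal rate filter for spike trains
#'
#' Kernel `gamma(t) = (exp(-t/tau_gamma) - exp(-t/nu_gamma)) /
#' (tau_gamma - nu_gamma)` for `t >= 0`; its integral is 1, so the
#' filtered train estimates the instantaneous rate.
#'
#' @param tau_gamma Decay time constant (ms).
#' @param nu_gamma Rise time constant (ms).
#' @return A list of class `rate_filter`.
#' @export
rate_filter <- function(tau_gamma = 50, nu_gamma = 20) {
  stopifnot(tau_gamma > nu_gamma, nu_gamma > 0)
  structure(list(tau_gamma = tau_gamma, nu_gamma = nu_gamma),
            class = "rate_filter")
}

#' Filtered instantaneous rate of a spike train
#'
#' Convolves a spike train with the [rate_filter()] kernel and evaluates
#' the result at the requested times. Rates are returned in Hz (the
#' kernel has unit integral over milliseconds; each spike therefore
#' contributes a transient whose time-integral is one spike).
#'
#' @param spike_times Numeric spike times (ms).
#' @param t Evaluation times (ms).
#' @param f A [rate_filter()] object.
#' @return Numeric vector of rates (Hz) at `t`.
#' @export
filtered_rate <- function(spike_times, t, f = rate_filter()) {
  vapply(t, function(tt) {
    s <- tt - spike_times
    s <- s[s >= 0]
    if (!length(s)) return(0)
    1000 * sum((exp(-s / f$tau_gamma) - exp(-s / f$nu_gamma)) /
                 (f$tau_gamma - f$nu_gamma))
  }, numeric(1))
}

#' Population-vector action readout
#'
#' The planar action (velocity, a.u./s) is the rate-weighted average of
#' the neurons' preferred-direction vectors:
#' `a = (1/N) * sum_k rho_k * a_k` with `a_k = a0 * (sin theta_k, cos
#' theta_k)` and `rho_k` in Hz.
#'
#' @param rho Numeric vector of filtered rates (Hz), one per action neuron.
#' @param conn A [lateral_connectivity()] object.
#' @return Numeric length-2 action vector.
#' @export
population_action <- function(rho, conn = lateral_connectivity()) {
  stopifnot(length(rho) == conn$n_action)
  drop(crossprod(conn$vectors, rho)) / conn$n_action
}
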