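# Deterministic synthetic instances with oracle-computed expectations.
# The oracles here are deliberately naive (explicit double loops, dense
# trapezoidal quadrature) and independent of the vectorised production
# code paths they are used to test.

oracle_window <- function(s, shape, amplitude, tau) {
  if (shape == "symmetric_da") return(amplitude * exp(-abs(s) / tau))
  if (s < 0) 0 else if (s == 0) amplitude / 2 else amplitude * exp(-s / tau)
}

oracle_pair_sum <- function(pre, post, shape, amplitude = 1, tau = 10) {
  total <- 0
  for (tp in pre) {
    for (tq in post) {
      total <- total + oracle_window(tq - tp, shape, amplitude, tau)
    }
  }
  total
}

# eligibility-filtered pairing sum read at time t_read: each pairing is
# registered at the later spike of its pair and decays with tau_e (s)
oracle_filtered_sum <- function(pre, post, shape, t_read,
                                amplitude = 1, tau = 10, tau_e = 2) {
  total <- 0
  for (tp in pre) {
    for (tq in post) {
      wv <- oracle_window(tq - tp, shape, amplitude, tau)
      t_evt <- max(tp, tq)
      if (t_evt <= t_read) {
        total <- total + wv * exp(-(t_read - t_evt) / (1000 * tau_e))
      }
    }
  }
  total
}

#' Deterministic spike-train scenarios with oracle expectations
#'
#' A small library of pre/post spike-train cases (empty trains, single
#' pairs at fixed lags, bursts, long trains spanning several eligibility
#' decays) whose pairwise STDP sums and eligibility-filtered readouts
#' are computed by an explicit brute-force oracle at generation time and
#' stored alongside.
#'
#' @param seed Seed for the randomised scenarios.
#' @return List of scenarios; each has `name`, `pre`, `post` (ms),
#'   `expected` (list with `da_sum`, `ht_sum`, `da_filtered_1s`,
#'   `ht_filtered_1s` read at 1000 ms).
#' @export
make_spike_scenarios <- function(seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- list(
    list(name = "empty", pre = numeric(0), post = numeric(0)),
    list(name = "pre_only", pre = c(10, 20), post = numeric(0)),
    list(name = "lag_minus20", pre = 100, post = 80),
    list(name = "lag_minus10", pre = 100, post = 90),
    list(name = "lag_zero", pre = 100, post = 100),
    list(name = "lag_plus10", pre = 100, post = 110),
    list(name = "lag_plus20", pre = 100, post = 120),
    list(name = "burst", pre = c(100, 102, 104, 106),
         post = c(101, 103, 105)),
    list(name = "long_train",
         pre = sort(stats::runif(40, 0, 8000)),
         post = sort(stats::runif(25, 0, 8000))),
    list(name = "sparse_long",
         pre = c(50, 2050, 4050, 6050), post = c(60, 2060, 4060, 6060))
  )
  lapply(base, function(sc) {
    sc$expected <- list(
      da_sum = oracle_pair_sum(sc$pre, sc$post, "symmetric_da"),
      ht_sum = oracle_pair_sum(sc$pre, sc$post, "causal_depressive_5ht"),
      da_filtered_1s = oracle_filtered_sum(sc$pre, sc$post, "symmetric_da",
                                           t_read = 1000, tau_e = 2),
      ht_filtered_1s = oracle_filtered_sum(sc$pre, sc$post,
                                           "causal_depressive_5ht",
                                           t_read = 1000, tau_e = 5)
    )
    sc
  })
}

oracle_kl_bits <- function(p, q) {
  total <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) total <- total + p[k] * log(p[k] / q[k], base = 2)
  }
  total
}

oracle_jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  0.5 * oracle_kl_bits(p, m) + 0.5 * oracle_kl_bits(q, m)
}

#' Distribution pairs with oracle Jensen-Shannon divergences
#'
#' Includes identical, disjoint and randomised pairs; expectations come
#' from a direct summation oracle in base-2 logarithms.
#'
#' @param seed Seed for the randomised pairs.
#' @param n_random Number of random pairs.
#' @return List of cases with `p`, `q`, `expected_jsd`, `expected_kl_pm`
#'   (KL of p against the mixture).
#' @export
make_distribution_pairs <- function(seed = 1, n_random = 20) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cases <- list(
    list(name = "identical", p = c(0.25, 0.25, 0.5), q = c(0.25, 0.25, 0.5)),
    list(name = "disjoint", p = c(1, 0), q = c(0, 1)),
    list(name = "point_vs_uniform", p = c(1, 0), q = c(0.5, 0.5))
  )
  for (r in seq_len(n_random)) {
    k <- sample(2:8, 1)
    p <- stats::rgamma(k, 1); p <- p / sum(p)
    q <- stats::rgamma(k, 1); q <- q / sum(q)
    cases[[length(cases) + 1]] <- list(name = sprintf("random_%02d", r),
                                       p = p, q = q)
  }
  lapply(cases, function(cs) {
    m <- (cs$p + cs$q) / 2
    cs$expected_jsd <- oracle_jsd_bits(cs$p, cs$q)
    cs$expected_kl_pm <- oracle_kl_bits(cs$p, m)
    cs
  })
}

#' Episode-shaped proto-weight histories with known net sign
#'
#' Generates random piecewise step/decay proto-weight histories for the
#' competitive rule, computes the dopaminergic and serotonergic episode
#' integrals by dense trapezoidal quadrature, and stores the implied
#' potentiation/depression label.
#'
#' @param seed Seed.
#' @param n Number of random cases (three constructed boundary cases are
#'   always included).
#' @return List of cases with `t` (s), `gamma_da`, `gamma_5ht`, `t_rew`,
#'   `params`, `expected_sign` (`"LTP"`, `"LTD"` or `"none"`) and the
#'   oracle integrals.
#' @export
make_cwc_integration_cases <- function(seed = 1, n = 100) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- plasticity_params("cwc")
  t <- seq(0, 15, by = 0.005)
  rand_history <- function() {
    # sum of a few decaying bumps placed at random times
    g <- numeric(length(t))
    for (b in seq_len(sample(1:4, 1))) {
      t0 <- stats::runif(1, 0, 12)
      amp <- stats::rgamma(1, 2)
      tau <- stats::runif(1, 0.5, 5)
      g <- g + ifelse(t >= t0, amp * exp(-(t - t0) / tau), 0)
    }
    g
  }
  oracle_case <- function(gda, g5, t_rew) {
    rda <- ifelse(t > t_rew & t <= t_rew + p$t_da, p$rda_amp, 0)
    r5 <- ifelse(t <= t_rew, p$r5ht_amp, 0)
    trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))
    ida <- trap(rda * gda)
    i5 <- trap(r5 * g5)
    list(ida = ida, i5 = i5,
         sign = if (ida > i5) "LTP" else if (ida < i5) "LTD" else "none")
  }
  cases <- list(
    list(name = "da_only", gamma_da = exp(-pmax(t - 5, 0)) * (t >= 5),
         gamma_5ht = numeric(length(t)), t_rew = 6),
    list(name = "ht_only", gamma_da = numeric(length(t)),
         gamma_5ht = exp(-pmax(t - 2, 0) / 3) * (t >= 2), t_rew = 10),
    # constructed equality: both modulator integrals are exactly zero
    list(name = "balanced_zero", gamma_da = numeric(length(t)),
         gamma_5ht = numeric(length(t)), t_rew = 10)
  )
  for (r in seq_len(n)) {
    cases[[length(cases) + 1]] <- list(
      name = sprintf("random_%03d", r),
      gamma_da = rand_history(), gamma_5ht = rand_history(),
      t_rew = stats::runif(1, 1, 14))
  }
  lapply(cases, function(cs) {
    o <- oracle_case(cs$gamma_da, cs$gamma_5ht, cs$t_rew)
    cs$t <- t
    cs$params <- p
    cs$expected_sign <- o$sign
    cs$oracle_integral_da <- o$ida
    cs$oracle_integral_5ht <- o$i5
    cs
  })
}

#' Serialise fixture libraries to JSON
#'
#' @param fixtures A fixture list from one of the `make_*` generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixtures_json <- function(fixtures, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to serialise fixtures", call. = FALSE)
  }
  jsonlite::write_json(fixtures, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
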