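test_that("place grid covers the arena with the expected cell counts", {
  g <- build_place_grid(4, 0.4, 400)
  expect_equal(nrow(g$centers), 121)
  expect_equal(sort(unique(g$centers[, 1])), seq(-2, 2, by = 0.4))
  expect_equal(sort(unique(g$centers[, 2])), seq(-2, 2, by = 0.4))

  corners <- build_place_grid(4, 4, 400)   # degenerate 2 x 2 grid
  expect_equal(nrow(corners$centers), 4)
  expect_setequal(corners$centers[, 1], c(-2, 2))

  expect_equal(nrow(build_place_grid(2, 0.5, 400)$centers), 25)
  expect_error(build_place_grid(4, 0.3), "multiple")
})

test_that("place-cell rates follow the Gaussian tuning curve", {
  g <- build_place_grid()
  r0 <- place_cell_rates(g$centers[61, ], g)
  expect_equal(max(r0), 400)            # at a centre the peak rate is attained
  expect_equal(which.max(r0), 61)

  # one tuning width away from a centre: peak * exp(-1)
  x <- g$centers[61, ] + c(g$sigma, 0)
  expect_equal(place_cell_rates(x, g)[61], 400 * exp(-1), tolerance = 1e-12)

  r <- place_cell_rates(c(0.13, -0.41), g)
  expect_true(all(r > 0 & r <= 400))
  # far outside every field the rate vanishes
  g2 <- build_place_grid(2, 1, 400)
  expect_lt(max(place_cell_rates(c(50, 50), g2)), 1e-300)
})

test_that("Bernoulli thinning matches Poisson statistics", {
  expect_false(any(sample_poisson(rep(0, 1000))))
  expect_error(sample_poisson(400, dt = 10), "too coarse")

  set.seed(1)
  n <- 1e5
  x <- sample_poisson(rep(400, n), dt = 1)
  p <- 0.4
  expect_lt(abs(mean(x) - p), 3 * sqrt(p * (1 - p) / n))
  # spike-count variance of the thinned process within 3 sigma of binomial
  counts <- colSums(matrix(x, nrow = 100))
  expect_lt(abs(var(counts) - 100 * p * (1 - p)),
            3 * sqrt(2 / (length(counts) - 1)) * 100 * p * (1 - p))
})

test_that("EPSP kernel is causal with the analytic peak", {
  p <- membrane_params()
  expect_equal(epsp_kernel(0, p), 0)
  expect_equal(epsp_kernel(c(-5, -0.001), p), c(0, 0))

  # peak location from the hand-derived stationarity condition
  t_star <- p$tau_m * p$tau_s / (p$tau_m - p$tau_s) * log(p$tau_m / p$tau_s)
  expect_equal(t_star, 9.2420, tolerance = 1e-4)
  opt <- optimize(function(t) epsp_kernel(t, p), c(0, 100), maximum = TRUE,
                  tol = 1e-10)
  expect_equal(opt$maximum, t_star, tolerance = 1e-6)
  expect_error(epsp_kernel(1, membrane_params(tau_m = 5, tau_s = 5 - 1e-12)),
               NA) # distinct taus fine
  pp <- membrane_params(); pp$tau_s <- pp$tau_m
  expect_error(epsp_kernel(1, pp), "singular")
})

test_that("membrane potential sums EPSPs after the last postsynaptic spike", {
  p <- membrane_params()
  w_feed <- matrix(0, 2, 3)
  w_lat <- matrix(0, 2, 2)
  empty <- list(place_spikes = rep(list(numeric(0)), 3),
                action_spikes = rep(list(numeric(0)), 2),
                last_post_spike = c(-Inf, -Inf))
  expect_equal(membrane_potential(empty, w_feed, w_lat, 50, p), c(0, 0))

  # single feed spike: u = w * eps(lag)
  st <- empty
  st$place_spikes[[2]] <- 10
  w_feed[1, 2] <- 1.7
  expect_equal(membrane_potential(st, w_feed, w_lat, 18, p)[1],
               1.7 * epsp_kernel(8, p))

  # immediately after a postsynaptic spike the refractory term dominates
  st$last_post_spike <- c(18, -Inf)
  u <- membrane_potential(st, w_feed, w_lat, 18, p)
  expect_equal(u[1], p$chi)  # spike at t_hat = t drops the feed EPSP (chi = -5)

  # with all weights zero only the refractory term remains
  u0 <- membrane_potential(st, w_feed * 0, w_lat, 25, p)
  expect_equal(u0[1], p$chi * exp((18 - 25) / p$tau_m))
})

test_that("escape rate is exponential in the membrane potential", {
  p <- membrane_params()
  expect_equal(action_rate(p$theta, p), 60)
  expect_equal(action_rate(p$theta + p$delta_u, p), 60 * exp(1))
  u <- seq(-40, 40, by = 0.5)
  expect_true(all(diff(action_rate(u, p)) > 0))
  expect_equal(action_rate(-1e6, p), 0)
})

test_that("lateral ring is fixed, symmetric and neighbour-exciting", {
  conn <- lateral_connectivity()
  w <- conn$w
  expect_equal(dim(w), c(40, 40))
  expect_equal(unname(diag(w)), rep(-300 / 40, 40))  # f(k,k) = 0
  expect_equal(w, t(w), tolerance = 1e-12)
  # excitatory part is maximal for immediate neighbours on the ring
  exc <- w - (-300 / 40)
  for (k in c(1, 7, 20)) {
    nb <- c(if (k == 1) 40 else k - 1, k %% 40 + 1)
    expect_equal(sort(order(exc[k, ], decreasing = TRUE)[1:2]), sort(nb))
  }
  # rows of the excitatory part are normalised to w_plus
  expect_equal(unname(rowSums(exc)), rep(100, 40), tolerance = 1e-9)
})

test_that("rate filter integrates to one and starts at zero", {
  f <- rate_filter()
  kern <- function(t) (exp(-t / f$tau_gamma) - exp(-t / f$nu_gamma)) /
    (f$tau_gamma - f$nu_gamma)
  expect_equal(integrate(kern, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  expect_equal(filtered_rate(numeric(0), c(0, 10, 100)), c(0, 0, 0))
  r <- filtered_rate(50, c(50, 60, 90, 400))
  expect_equal(r[1], 0)        # gamma(0) = 0
  expect_gt(r[2], 0)
  expect_gt(r[3], r[4])
})

test_that("population vector readout averages preferred directions", {
  conn <- lateral_connectivity()
  expect_equal(population_action(rep(0, 40), conn), c(0, 0))
  # single active neuron: a = rho * a_k / N; neuron 40 points along +y
  rho <- rep(0, 40); rho[40] <- 12
  a <- population_action(rho, conn)
  expect_equal(a, 12 * 0.08 / 40 * c(sin(2 * pi), cos(2 * pi)),
               tolerance = 1e-12)
  # uniform activity cancels by ring symmetry
  expect_equal(population_action(rep(7, 40), conn), c(0, 0),
               tolerance = 1e-12)
})
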