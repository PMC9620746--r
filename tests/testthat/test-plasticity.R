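test_that("STDP windows have the stated shapes and values", {
  da <- stdp_window("symmetric_da", 1, 10)
  ht <- stdp_window("causal_depressive_5ht", 1, 10)
  expect_equal(window_value(0, da), 1)
  expect_equal(window_value(c(-10, 10), da), rep(exp(-1), 2))
  expect_equal(window_value(c(-10, 10), da), window_value(c(10, -10), da))
  expect_equal(window_value(c(-5, -0.001), ht), c(0, 0))
  expect_equal(window_value(0, ht), 0.5)
  expect_equal(window_value(10, ht), exp(-1))
})

test_that("pairwise STDP sums are order-independent and causal for 5-HT", {
  da <- stdp_window("symmetric_da")
  ht <- stdp_window("causal_depressive_5ht")
  expect_equal(pairwise_stdp_sum(numeric(0), numeric(0), da), 0)
  expect_equal(pairwise_stdp_sum(0, 10, da), exp(-1))
  expect_equal(pairwise_stdp_sum(0, -10, da), exp(-1))
  expect_equal(pairwise_stdp_sum(0, -10, ht), 0)
  expect_equal(pairwise_stdp_sum(0, 10, ht), exp(-1))
  # additive over disjoint pre subsets (trace linearity)
  pre <- c(1, 5, 9, 30); post <- c(4, 8, 41)
  expect_equal(pairwise_stdp_sum(pre, post, da),
               pairwise_stdp_sum(pre[1:2], post, da) +
                 pairwise_stdp_sum(pre[3:4], post, da))
})

test_that("eligibility traces decay exponentially and superpose", {
  tr <- eligibility_trace(tau_e = 2, value = 1)
  expect_equal(update_trace(tr, 0, dt = 2000)$value, exp(-1))
  expect_equal(update_trace(eligibility_trace(2, 0), 0, 500)$value, 0)
  # two unit increments at 0 and tau_e: value exp(-1) + 1 at tau_e
  tr <- eligibility_trace(2, 0)
  tr <- update_trace(tr, 1, 0)
  tr <- update_trace(tr, 1, 2000)
  expect_equal(tr$value, exp(-1) + 1)
})

test_that("sequential rule applies exactly one modulator per episode", {
  p <- plasticity_params("swc")
  gda <- matrix(runif(12), 3, 4)
  g5 <- matrix(runif(12), 3, 4)
  expect_true(all(swc_apply(gda, g5, "reward", p) >= 0))
  expect_equal(swc_apply(gda, g5, "reward", p), p$eta_da * gda)
  expect_true(all(swc_apply(gda, g5, "none", p) <= 0))
  expect_equal(swc_apply(gda, g5, "punishment", p), -p$eta_5ht * g5)
  # open-field neutral episodes trigger no update
  expect_equal(swc_apply(gda, g5, "none", p, neutral_updates = FALSE),
               matrix(0, 3, 4))
  expect_equal(swc_apply(gda * 0, g5 * 0, "reward", p), matrix(0, 3, 4))
  # online candidate accumulates at eta/Tmax
  expect_equal(swc_online_apply(g5, dt = 1, t_max = 15),
               -0.01 / 15 * g5)
})

test_that("competitive step follows the modulator step functions", {
  p <- plasticity_params("cwc")
  gda <- matrix(1, 2, 2); g5 <- matrix(1, 2, 2)
  # before the outcome only serotonergic depression is active
  expect_true(all(cwc_step(gda, g5, t = 3, t_rew = 10, p) < 0))
  # in the phasic dopamine window only potentiation is active
  expect_true(all(cwc_step(gda, g5, t = 10.5, t_rew = 10, p) > 0))
  expect_equal(cwc_step(gda, g5, t = 11.5, t_rew = 10, p), matrix(0, 2, 2))
  # disabling the serotonergic response leaves pure LTP
  p0 <- plasticity_params("cwc", r5ht_amp = 0)
  expect_true(all(cwc_step(gda, g5, t = 3, t_rew = 10, p0) >= 0))
})

test_that("weights clip to the stable range", {
  p <- plasticity_params()
  expect_equal(clip_weights(matrix(c(3.7, 2, 0.2, 1), 2), p),
               matrix(c(3, 2, 1, 1), 2))
})

test_that("rate-based drift is bilinear and outcome-signed", {
  da <- stdp_window("symmetric_da")
  expect_equal(rate_based_update(0, 50, da), 0)
  expect_equal(rate_based_update(50, 0, da), 0)
  expect_lt(rate_based_update(50, 20, da, R = -1), 0)
  expect_equal(rate_based_update(50, 20, stdp_window("symmetric_da", 2)),
               2 * rate_based_update(50, 20, da))
  # window integrals: 2*A*tau symmetric, A*tau causal
  expect_equal(window_integral(stdp_window("symmetric_da", 1.5, 10)), 30)
  expect_equal(window_integral(stdp_window("causal_depressive_5ht", 1.5, 10)), 15)
})

test_that("engine proto-weights match the spike-sum + trace composition", {
  # record full spike trains, then recompute Gamma at episode end from
  # scratch with the R window/trace machinery (independent composition)
  cfg <- nav_config("mwm", "swc", t_max = 3)
  w <- matrix(2, 40, 121)
  da <- stdp_window("symmetric_da", cfg$params$ada, cfg$params$tau_stdp)
  ht <- stdp_window("causal_depressive_5ht", cfg$params$a5ht,
                    cfg$params$tau_stdp)
  for (seed in c(3, 99)) {
    rec <- run_episode(cfg, w, 1, seed = seed, record_spikes = TRUE)
    t_end <- rec$latency * 1000
    pre <- split(rec$place_spikes$t, factor(rec$place_spikes$cell, 1:121))
    post <- split(rec$action_spikes$t, factor(rec$action_spikes$neuron, 1:40))
    # a handful of synapses with activity, plus some silent ones
    busy <- order(rec$gamma_da, decreasing = TRUE)[c(1, 5, 50)]
    silent <- which(rec$gamma_da == 0)[1]
    for (idx in c(busy, silent)) {
      j <- (idx - 1) %% 40 + 1
      i <- (idx - 1) %/% 40 + 1
      oracle_gamma <- function(win, tau_e) {
        tot <- 0
        for (tp in pre[[i]]) for (tq in post[[j]]) {
          tot <- tot + window_value(tq - tp, win) *
            exp(-(t_end - max(tp, tq)) / (1000 * tau_e))
        }
        tot
      }
      expect_equal(rec$gamma_da[j, i], oracle_gamma(da, cfg$params$tau_e_da),
                   tolerance = 1e-8)
      expect_equal(rec$gamma_5ht[j, i], oracle_gamma(ht, cfg$params$tau_e_5ht),
                   tolerance = 1e-8)
    }
    # terminal update consistency: one modulator, correct readout time
    if (rec$outcome == "reward") {
      expect_equal(rec$dw_raw,
                   cfg$params$eta_da * exp(-300 / 2000) * rec$gamma_da,
                   tolerance = 1e-10)
    } else {
      expect_equal(rec$dw_raw, -cfg$params$eta_5ht * rec$gamma_5ht,
                   tolerance = 1e-10)
    }
  }
})

test_that("competitive episodes can mix potentiation and depression", {
  # unlike the sequential rule, a rewarded competitive episode may
  # depress synapses whose serotonergic integral dominates
  cfg <- nav_config("mwm", "cwc")
  w <- matrix(2, 40, 121)
  found_mixed <- FALSE
  for (s in 1:60) {
    rec <- run_episode(cfg, w, 1, seed = s)
    dw <- rec$w - w
    if (rec$outcome == "reward" && any(dw > 1e-12) && any(dw < -1e-12)) {
      found_mixed <- TRUE
      break
    }
  }
  expect_true(found_mixed)
})

test_that("serotonin restricts the weight growth dopamine alone produces", {
  # matched seeds, both rules: mean final weight under DA-only dominates
  for (rule in c("swc", "cwc")) {
    m_full <- m_da <- NULL
    for (mods in c("da+5ht", "da")) {
      cfg <- nav_config("mwm", rule, episodes = 12, n_sims = 6, seed = 5,
                        modulators = mods)
      b <- run_batch(cfg, keep_weights = TRUE)
      if (mods == "da") m_da <- mean(b$weights) else m_full <- mean(b$weights)
    }
    expect_gt(m_da, m_full)
  }
})
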