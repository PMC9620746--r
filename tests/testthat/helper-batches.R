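# Shared batch cache for the statistical acceptance checks. Batches are
# expensive, deterministic (fixed seeds) and reused across test blocks.
#
# Problem sizes used by the statistical checks (the methods vignette
# documents these choices):
ACC_M_LEARN <- 200L   # MWM learning-curve comparisons
ACC_M_JSD <- 500L     # first-reward JSD (first-reward only, early stop)
ACC_M_REV <- 100L     # reversal task, per serotonergic learning rate
ACC_SEED <- 20220413L

# three five-episode perturbation intervals, the last covering the final
# episodes at which the effect is scored
acc_opto_schedule <- function(mode) {
  data.frame(from = c(8L, 20L, 36L), to = c(12L, 24L, 40L), mode = mode)
}

.acc_cache <- new.env(parent = emptyenv())

# MWM batch under a named condition, memoised
acc_mwm_batch <- function(rule, condition = c("control", "da", "inhibit",
                                              "activate")) {
  condition <- match.arg(condition)
  key <- paste(rule, condition, sep = "/")
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  cfg <- nav_config(
    "mwm", rule, episodes = 40, n_sims = ACC_M_LEARN, seed = ACC_SEED,
    modulators = if (condition == "da") "da" else "da+5ht",
    opto = if (condition %in% c("inhibit", "activate"))
      acc_opto_schedule(condition) else NULL
  )
  .acc_cache[[key]] <- run_batch(cfg)
  .acc_cache[[key]]
}

# first-reward-only batch (episodes after the first reward do not enter
# the first-reward statistic, so simulations stop there)
acc_first_reward <- function(rule, modulators) {
  key <- paste("fr", rule, modulators, sep = "/")
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  seed <- ACC_SEED + 1L + (modulators == "da")
  cfg <- nav_config("mwm", rule, episodes = 40, n_sims = ACC_M_JSD,
                    seed = seed, modulators = modulators,
                    stop_after_first_reward = TRUE)
  b <- run_batch(cfg)
  .acc_cache[[key]] <- list(episode = b$first_reward,
                            latency = b$first_reward_latency)
  .acc_cache[[key]]
}

acc_reversal_batch <- function(eta_5ht) {
  key <- sprintf("rev/%g", eta_5ht)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  p <- plasticity_params("swc", eta_5ht = eta_5ht)
  cfg <- nav_config("reversal", "swc", episodes = 40, n_sims = ACC_M_REV,
                    seed = ACC_SEED + 2L, params = p)
  .acc_cache[[key]] <- run_batch(cfg)
  .acc_cache[[key]]
}

# one-sided test that success-at-final-episode is higher under a than b
final_success_greater <- function(batch_a, batch_b) {
  a <- batch_a$success[, ncol(batch_a$success)]
  b <- batch_b$success[, ncol(batch_b$success)]
  stats::prop.test(c(sum(a), sum(b)), c(length(a), length(b)),
                   alternative = "greater")$p.value
}
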