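rule_codes <- c("swc" = 0L, "cwc" = 1L, "swc-online" = 2L,
                "rate-swc" = 3L, "rate-cwc" = 4L)

#' Simulation run configuration
#'
#' Bundles the task protocol, learning rule, network constants and run
#' sizes into a single serialisable object. Two runs with identical
#' configurations (including `seed`) produce identical outputs.
#'
#' @param task `"mwm"` (Morris water maze) or `"reversal"`.
#' @param rule Plasticity rule; see [plasticity_params()].
#' @param episodes Episodes per trial (the reversal task swaps zones at
#'   `reversal_at`).
#' @param trials Consecutive trials (weights persist across episodes and
#'   trials).
#' @param n_sims Number of independent simulations `M` for [run_batch()].
#' @param seed Master seed.
#' @param modulators `"da+5ht"` (full model) or `"da"` (serotonin
#'   disabled).
#' @param opto Optional optogenetic schedule: a data frame with columns
#'   `from`, `to` (episode range, inclusive) and `mode` (`"inhibit"`
#'   zeroes the serotonergic amplitude, `"activate"` doubles it).
#' @param random_start Draw the start position uniformly per episode.
#' @param t_max Maximum episode duration (s).
#' @param dt Neural integration step (ms).
#' @param dt_move Movement/plasticity block step (ms).
#' @param reversal_at Episode after which reversal zones swap.
#' @param params A [plasticity_params()] object (defaults chosen by
#'   `rule`).
#' @param grid,conn,mem,filt,ar Network components; see
#'   [build_place_grid()], [lateral_connectivity()], [membrane_params()],
#'   [rate_filter()], [arena()].
#' @param w_init Initial feed-forward weight (uniform), default the
#'   midpoint of the clip range.
#' @param record_trajectories Keep position traces (needed for occupancy
#'   and distance metrics).
#' @param snapshot_episodes Episode indices at which to store weight
#'   snapshots.
#' @param stop_after_first_reward Stop a simulation once its first
#'   reward has been obtained (used for first-reward statistics, which
#'   do not depend on later episodes).
#' @return An object of class `nav_config`.
#' @export
nav_config <- function(task = c("mwm", "reversal"),
                       rule = c("swc", "cwc", "swc-online",
                                "rate-swc", "rate-cwc"),
                       episodes = 40, trials = 1, n_sims = 1, seed = 1,
                       modulators = c("da+5ht", "da"),
                       opto = NULL, random_start = FALSE,
                       t_max = 15, dt = 1, dt_move = 10, reversal_at = 20,
                       params = NULL,
                       grid = build_place_grid(),
                       conn = lateral_connectivity(),
                       mem = membrane_params(),
                       filt = rate_filter(),
                       ar = arena(),
                       w_init = NULL,
                       record_trajectories = FALSE,
                       snapshot_episodes = integer(0),
                       stop_after_first_reward = FALSE) {
  task <- match.arg(task)
  rule <- match.arg(rule)
  modulators <- match.arg(modulators)
  if (is.null(params)) params <- plasticity_params(rule)
  stopifnot(inherits(params, "plasticity_params"), identical(params$rule, rule))
  if (!is.null(opto)) {
    stopifnot(is.data.frame(opto),
              all(c("from", "to", "mode") %in% names(opto)),
              all(opto$mode %in% c("inhibit", "activate")))
  }
  if (is.null(w_init)) w_init <- (params$w_min + params$w_max) / 2
  stopifnot(episodes >= 0, trials >= 1, n_sims >= 1,
            dt > 0, dt_move >= dt, t_max > 0)
  protocol <- make_protocol(task, t_max = t_max,
                            start = if (random_start) "random" else c(0, 0),
                            episodes = episodes, trials = trials,
                            reversal_at = reversal_at, ar = ar)
  structure(
    list(task = task, rule = rule, episodes = episodes, trials = trials,
         n_sims = n_sims, seed = seed, modulators = modulators, opto = opto,
         random_start = random_start, t_max = t_max, dt = dt,
         dt_move = dt_move, reversal_at = reversal_at, params = params,
         grid = grid, conn = conn, mem = mem, filt = filt, arena = ar,
         protocol = protocol, w_init = w_init,
         record_trajectories = record_trajectories,
         snapshot_episodes = as.integer(snapshot_episodes),
         stop_after_first_reward = stop_after_first_reward),
    class = "nav_config"
  )
}

#' @export
print.nav_config <- function(x, ...) {
  cat(sprintf("navplast config: task %s, rule %s, %d episode(s) x %d trial(s), M = %d, seed = %d\n",
              x$task, x$rule, x$episodes, x$trials, x$n_sims, x$seed))
  cat(sprintf("  modulators: %s%s\n", x$modulators,
              if (!is.null(x$opto)) sprintf(", opto schedule (%d interval(s))",
                                            nrow(x$opto)) else ""))
  invisible(x)
}

# serotonergic multiplier in force at an episode (condition x opto)
episode_mod_5ht <- function(config, episode) {
  base <- if (config$modulators == "da") 0 else config$params$mod_5ht
  if (!is.null(config$opto)) {
    for (r in seq_len(nrow(config$opto))) {
      if (episode >= config$opto$from[r] && episode <= config$opto$to[r]) {
        base <- base * switch(config$opto$mode[r], inhibit = 0, activate = 2)
      }
    }
  }
  base
}

zones_matrix <- function(zones) {
  if (!length(zones)) return(matrix(numeric(0), 0, 4))
  do.call(rbind, lapply(zones, function(z) {
    c(z$center, z$radius, if (z$valence == "reward") 1 else -1)
  }))
}

#' Run a single episode
#'
#' Simulates neural dynamics and movement from the start position until
#' an outcome or `t_max`, applies the configured rule's weight update
#' and clipping, and returns the updated weights. Spike state, traces
#' and filtered rates are episode-local (activity is reset between
#' episodes); weights persist.
#'
#' @param config A [nav_config()] object.
#' @param weights Feed-forward weight matrix (action neurons x place
#'   cells), within the clip bounds.
#' @param episode_index Episode index within the run (determines zones
#'   and the optogenetic multiplier).
#' @param seed Integer seed for the episode's random stream.
#' @param learning Apply plasticity (disable for probe episodes).
#' @param zones Optional override of the zones in force (a list of
#'   [zone()] objects; an empty list runs a free-exploration probe).
#' @param start Optional override of the start position.
#' @param record Record the trajectory (at `dt_move` resolution).
#' @param record_spikes Record full spike trains (testing/diagnostics).
#' @return A list of class `episode_record`: `outcome`, `latency` (s),
#'   `w` (updated weights), `dw_raw` (terminal unclipped update for
#'   sequential rules), `gamma_da`/`gamma_5ht` (proto-weights at episode
#'   end), `final_pos`, optionally `trajectory` and spike tables.
#' @export
run_episode <- function(config, weights, episode_index = 1, seed = 1,
                        learning = TRUE, zones = NULL, start = NULL,
                        record = config$record_trajectories,
                        record_spikes = FALSE) {
  p <- config$params
  stopifnot(all(weights >= p$w_min - 1e-9), all(weights <= p$w_max + 1e-9))
  if (is.null(zones)) zones <- protocol_zones(config$protocol, episode_index)
  validate_zones(zones)
  if (is.null(start)) start <- draw_start(config$protocol, zones)
  plist <- unclass(p)
  plist$mod_5ht <- episode_mod_5ht(config, episode_index)
  res <- .engine_episode(
    weights, config$grid$centers, config$grid$sigma, config$grid$peak_rate,
    config$conn$w, config$conn$theta, config$conn$a0,
    unclass(config$mem), config$filt$tau_gamma, config$filt$nu_gamma,
    config$dt, config$dt_move, config$t_max * 1000,
    zones_matrix(zones), start, config$arena$half_side, config$arena$d0,
    rule_codes[[config$rule]], plist,
    config$task == "reversal", config$task == "mwm",
    learning, seed, record, record_spikes)
  res$outcome <- c("punishment", "none", "reward")[res$outcome + 2L]
  res$episode <- episode_index
  class(res) <- "episode_record"
  res
}

#' Run one simulation (a sequence of episodes with persistent weights)
#'
#' Executes `episodes x trials` episodes sequentially, starting from
#' uniform initial weights, applying the optogenetic schedule per
#' episode, and collecting per-episode outcomes, latencies and optional
#' snapshots.
#'
#' @param config A [nav_config()] object.
#' @param sim_seed Seed of this simulation's random stream (defaults to
#'   `config$seed`).
#' @return An object of class `nav_sim`: data frame `episodes` (episode,
#'   trial, outcome, latency, final position), `w_final`, `first_reward`
#'   (episode index of the first reward, `NA` if none), optional
#'   `snapshots` and `trajectories`.
#' @export
run_simulation <- function(config, sim_seed = config$seed) {
  n_ep_total <- config$episodes * config$trials
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sim_seed)
  eseeds <- sample.int(.Machine$integer.max - 1L, max(n_ep_total, 1L))
  w <- matrix(config$w_init, config$conn$n_action, nrow(config$grid$centers))
  out <- data.frame(episode = integer(0), trial = integer(0),
                    outcome = character(0), latency = numeric(0),
                    x = numeric(0), y = numeric(0))
  snapshots <- list()
  trajectories <- if (config$record_trajectories) vector("list", n_ep_total) else NULL
  first_reward <- NA_integer_
  first_reward_latency <- NA_real_
  ep_global <- 0L
  for (trial in seq_len(config$trials)) {
    for (ep in seq_len(config$episodes)) {
      ep_global <- ep_global + 1L
      rec <- run_episode(config, w, episode_index = ep,
                         seed = eseeds[ep_global])
      w <- rec$w
      out[ep_global, ] <- list(ep, trial, rec$outcome, rec$latency,
                               rec$final_pos[1], rec$final_pos[2])
      if (config$record_trajectories) trajectories[[ep_global]] <- rec$trajectory
      if (is.na(first_reward) && rec$outcome == "reward") {
        first_reward <- ep_global
        first_reward_latency <- rec$latency
      }
      if (ep %in% config$snapshot_episodes) {
        snapshots[[as.character(ep)]] <- w
      }
      if (config$stop_after_first_reward && !is.na(first_reward)) break
    }
    if (config$stop_after_first_reward && !is.na(first_reward)) break
  }
  structure(
    list(episodes = out, w_final = w, first_reward = first_reward,
         first_reward_latency = first_reward_latency,
         snapshots = snapshots, trajectories = trajectories,
         config = config, sim_seed = sim_seed),
    class = "nav_sim"
  )
}

#' @export
print.nav_sim <- function(x, ...) {
  n <- nrow(x$episodes)
  cat(sprintf("navplast simulation (%s, %s): %d episode(s) run\n",
              x$config$task, x$config$rule, n))
  cat(sprintf("  rewards: %d, punishments: %d, first reward at episode %s\n",
              sum(x$episodes$outcome == "reward"),
              sum(x$episodes$outcome == "punishment"),
              ifelse(is.na(x$first_reward), "never", x$first_reward)))
  invisible(x)
}

#' Run a batch of independent simulations
#'
#' Runs `n_sims` simulations with per-simulation seeds derived from the
#' master seed (the first `n_sims` draws of `sample.int` under
#' `set.seed(config$seed)`), and aggregates success fractions, latency
#' curves and first-reward statistics. Execution is sequential;
#' per-simulation streams are independent by construction.
#'
#' @param config A [nav_config()] object (`n_sims`, `seed` are taken
#'   from it).
#' @param keep_weights Retain each simulation's final weight matrix.
#' @param progress Print one progress line per simulation chunk.
#' @return An object of class `nav_batch` with matrices `success`,
#'   `latency` (simulations x episodes), `outcome` (character),
#'   `first_reward`, per-episode `success_fraction` (+ SEM), optional
#'   `weights` (3-d array) and `snapshots`.
#' @export
run_batch <- function(config, keep_weights = FALSE, progress = FALSE) {
  M <- config$n_sims
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, M)
  n_ep <- config$episodes * config$trials
  success <- matrix(NA, M, n_ep)
  latency <- matrix(NA_real_, M, n_ep)
  outcome <- matrix(NA_character_, M, n_ep)
  first_reward <- rep(NA_integer_, M)
  first_reward_latency <- rep(NA_real_, M)
  weights <- if (keep_weights)
    array(NA_real_, c(M, config$conn$n_action, nrow(config$grid$centers)))
  else NULL
  snapshots <- if (length(config$snapshot_episodes)) vector("list", M) else NULL
  trajectories <- if (config$record_trajectories) vector("list", M) else NULL
  for (m in seq_len(M)) {
    sim <- run_simulation(config, sim_seeds[m])
    k <- nrow(sim$episodes)
    success[m, seq_len(k)] <- sim$episodes$outcome == "reward"
    latency[m, seq_len(k)] <- sim$episodes$latency
    outcome[m, seq_len(k)] <- sim$episodes$outcome
    first_reward[m] <- sim$first_reward
    first_reward_latency[m] <- sim$first_reward_latency
    if (keep_weights) weights[m, , ] <- sim$w_final
    if (!is.null(snapshots)) snapshots[[m]] <- sim$snapshots
    if (!is.null(trajectories)) trajectories[[m]] <- sim$trajectories
    if (progress && (m %% 25 == 0 || m == M)) {
      message(sprintf("  simulation %d/%d", m, M))
    }
  }
  sf <- colMeans(success)
  sem <- apply(success, 2, function(v) stats::sd(v) / sqrt(sum(!is.na(v))))
  structure(
    list(success = success, latency = latency, outcome = outcome,
         first_reward = first_reward,
         first_reward_latency = first_reward_latency,
         success_fraction = sf,
         success_sem = sem, weights = weights, snapshots = snapshots,
         trajectories = trajectories, config = config,
         sim_seeds = sim_seeds),
    class = "nav_batch"
  )
}

#' @export
print.nav_batch <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("navplast batch: %s / %s / %s, M = %d, %d episode(s)\n",
              cfg$task, cfg$rule, cfg$modulators, cfg$n_sims,
              ncol(x$success)))
  sf <- x$success_fraction
  cat(sprintf("  success fraction: first episode %.3f, final episode %.3f\n",
              sf[1], sf[length(sf)]))
  invisible(x)
}

#' @export
summary.nav_batch <- function(object, ...) {
  sf <- object$success_fraction
  lat <- object$latency
  rew <- object$outcome == "reward"
  mean_lat <- vapply(seq_len(ncol(lat)), function(e) {
    v <- lat[rew[, e] %in% TRUE, e]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out <- list(
    task = object$config$task, rule = object$config$rule,
    modulators = object$config$modulators, n_sims = object$config$n_sims,
    success_fraction = sf, success_sem = object$success_sem,
    mean_latency_rewarded = mean_lat,
    first_reward = object$first_reward,
    final_success = sf[length(sf)]
  )
  class(out) <- "summary.nav_batch"
  out
}

#' @export
print.summary.nav_batch <- function(x, ...) {
  cat(sprintf("Batch summary (%s, %s, %s, M = %d):\n",
              x$task, x$rule, x$modulators, x$n_sims))
  cat(sprintf("  final-episode success fraction: %.3f (SEM %.3f)\n",
              x$final_success, x$success_sem[length(x$success_sem)]))
  fr <- x$first_reward
  cat(sprintf("  first reward: median episode %s (%d/%d simulations rewarded)\n",
              stats::median(fr, na.rm = TRUE), sum(!is.na(fr)), length(fr)))
  invisible(x)
}

#' Plot learning curves of one or more batches
#'
#' @param x A `nav_batch` object.
#' @param ... Further `nav_batch` objects to overlay.
#' @param labels Legend labels.
#' @export
plot.nav_batch <- function(x, ..., labels = NULL) {
  batches <- c(list(x), Filter(function(o) inherits(o, "nav_batch"), list(...)))
  n_ep <- max(vapply(batches, function(b) length(b$success_fraction), 1L))
  cols <- grDevices::hcl.colors(max(3, length(batches)), "Dark 2")
  graphics::plot(NULL, xlim = c(1, n_ep), ylim = c(0, 1),
                 xlab = "episode", ylab = "success fraction",
                 main = "Learning curve")
  for (b in seq_along(batches)) {
    sf <- batches[[b]]$success_fraction
    graphics::lines(seq_along(sf), sf, col = cols[b], lwd = 2)
  }
  if (is.null(labels)) {
    labels <- vapply(batches, function(b)
      paste(b$config$rule, b$config$modulators), character(1))
  }
  graphics::legend("topleft", legend = labels, col = cols[seq_along(batches)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Probe episode (spatial memory test)
#'
#' Runs a fixed-duration episode with learning frozen and the reward
#' zone disabled, recording the trajectory; used for distance-to-target
#' statistics after training.
#'
#' @param config A [nav_config()] object.
#' @param weights Trained feed-forward weights.
#' @param seed Episode seed.
#' @return An `episode_record` with a trajectory and no outcome.
#' @export
run_probe <- function(config, weights, seed = 1) {
  run_episode(config, weights, seed = seed, learning = FALSE,
              zones = list(), record = TRUE)
}

#' Coarse grid search over plasticity parameters
#'
#' Evaluates every grid point with a reduced batch and ranks them by the
#' success fraction over the final episode; ties are broken by the
#' lexicographic order of the parameter tuple (lower first). The same
#' master seed is used at every grid point.
#'
#' @param config Base [nav_config()] object.
#' @param param_grid Named list of parameter value vectors (names must
#'   be [plasticity_params()] fields, e.g. `eta_da`, `a5ht`).
#' @param m_small Batch size per grid point.
#' @return Data frame of grid points with `final_success`, ordered best
#'   first.
#' @export
grid_search <- function(config, param_grid, m_small = 20) {
  stopifnot(length(param_grid) > 0, all(nzchar(names(param_grid))))
  pts <- expand.grid(param_grid, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(pts)) stop("empty parameter grid", call. = FALSE)
  score <- numeric(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    cfg <- config
    for (nm in names(pts)) cfg$params[[nm]] <- pts[r, nm]
    cfg$n_sims <- m_small
    b <- run_batch(cfg)
    score[r] <- b$success_fraction[length(b$success_fraction)]
  }
  pts$final_success <- score
  ord <- do.call(order, c(list(-score), as.list(pts[names(param_grid)])))
  pts[ord, , drop = FALSE]
}
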