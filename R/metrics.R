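#' Discrete probability distribution on labelled bins
#'
#' @param prob Numeric vector of non-negative masses; normalised to sum
#'   to 1.
#' @param labels Optional bin labels.
#' @return A list of class `discrete_distribution`.
#' @export
discrete_distribution <- function(prob, labels = NULL) {
  stopifnot(all(prob >= 0), sum(prob) > 0)
  p <- prob / sum(prob)
  if (is.null(labels)) labels <- seq_along(p)
  stopifnot(length(labels) == length(p))
  structure(list(prob = p, labels = labels), class = "discrete_distribution")
}

as_prob <- function(x) {
  if (inherits(x, "discrete_distribution")) x$prob else {
    stopifnot(all(x >= 0))
    x / sum(x)
  }
}

#' Kullback-Leibler divergence (bits)
#'
#' `D_KL(P || Q) = sum_x P(x) log2(P(x)/Q(x))` with the convention
#' `0 * log(0/q) = 0`. `Q` must dominate `P` (`Q > 0` wherever `P > 0`),
#' which always holds when `Q` is the mixture `(P + Q)/2` used by the
#' Jensen-Shannon divergence.
#'
#' @param p,q Probability vectors or [discrete_distribution()] objects on
#'   the same bins.
#' @return Divergence in bits (non-negative).
#' @export
kl_divergence <- function(p, q) {
  p <- as_prob(p); q <- as_prob(q)
  stopifnot(length(p) == length(q))
  nz <- p > 0
  if (any(q[nz] == 0)) {
    stop("support violation: q must be positive wherever p is", call. = FALSE)
  }
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence (bits)
#'
#' `JSD(P || Q) = D_KL(P || M)/2 + D_KL(Q || M)/2` with
#' `M = (P + Q)/2`; symmetric and bounded in [0, 1] with base-2
#' logarithms.
#'
#' @inheritParams kl_divergence
#' @return Divergence in bits, in [0, 1].
#' @export
jsd <- function(p, q) {
  p <- as_prob(p); q <- as_prob(q)
  m <- (p + q) / 2
  kl_divergence(p, m) / 2 + kl_divergence(q, m) / 2
}

#' First-reward distribution across simulations
#'
#' The per-simulation statistic is the episode index of the first
#' rewarded episode, discretised with one bin per episode; simulations
#' that never obtain a reward are collected in a final overflow bin so
#' that distributions from different conditions share a common support.
#'
#' @param first_reward Integer vector, one entry per simulation: episode
#'   of the first reward, or `NA` if never rewarded.
#' @param n_episodes Number of episode bins.
#' @return A [discrete_distribution()] on bins `1..n_episodes` plus
#'   `"never"`.
#' @export
first_reward_distribution <- function(first_reward, n_episodes) {
  if (all(is.na(first_reward))) {
    stop("no simulation was ever rewarded: distribution undefined",
         call. = FALSE)
  }
  idx <- ifelse(is.na(first_reward), n_episodes + 1L, as.integer(first_reward))
  stopifnot(all(idx >= 1L), all(idx <= n_episodes + 1L))
  counts <- tabulate(idx, nbins = n_episodes + 1L)
  discrete_distribution(counts, labels = c(seq_len(n_episodes), "never"))
}

#' Latency-based first-reward distribution
#'
#' Alternative first-reward statistic: the latency (s) of the first
#' rewarded episode, discretised into fixed-width bins over
#' `[0, t_max]`, with the same `"never"` overflow bin for simulations
#' that are never rewarded.
#'
#' @param latency Numeric vector, one entry per simulation: latency of
#'   the first reward (s), or `NA` if never rewarded.
#' @param t_max Maximum episode duration (s).
#' @param bin_width Bin width (s).
#' @return A [discrete_distribution()].
#' @export
first_reward_latency_distribution <- function(latency, t_max = 15,
                                              bin_width = 1) {
  if (all(is.na(latency))) {
    stop("no simulation was ever rewarded: distribution undefined",
         call. = FALSE)
  }
  n_bins <- ceiling(t_max / bin_width)
  idx <- ifelse(is.na(latency), n_bins + 1L,
                pmin(floor(latency / bin_width) + 1L, n_bins))
  counts <- tabulate(idx, nbins = n_bins + 1L)
  discrete_distribution(counts, labels = c(seq_len(n_bins), "never"))
}

#' Coefficient of variation of per-place-cell synaptic weights
#'
#' For each place cell (column of the feed-forward weight matrix) the CV
#' is the sample standard deviation of its outgoing weights divided by
#' their mean. Weights are bounded below by `w_min > 0`, so the mean is
#' positive.
#'
#' @param w Feed-forward weight matrix (action neurons x place cells), or
#'   a 3-d array (simulations x action neurons x place cells), in which
#'   case per-cell CVs are averaged across simulations.
#' @return Numeric vector of CV values, one per place cell.
#' @export
coefficient_of_variation <- function(w) {
  cv1 <- function(m) {
    mu <- colMeans(m)
    if (any(mu <= 0)) stop("non-positive mean weight", call. = FALSE)
    apply(m, 2, stats::sd) / mu
  }
  if (length(dim(w)) == 3) {
    rowMeans(apply(w, 1, cv1))
  } else {
    cv1(as.matrix(w))
  }
}

#' Spatial occupancy map of trajectories
#'
#' Each trajectory (one episode) is binned on a `bins x bins` grid over
#' the arena and normalised to a per-episode probability map; maps are
#' then averaged across episodes/simulations and renormalised.
#'
#' @param trajectories A single n x 2 matrix or a list of such matrices.
#' @param bins Bins per side (default 50).
#' @param ar An [arena()] object.
#' @return A `bins x bins` matrix of visit probabilities summing to 1,
#'   with attributes `bins` and `half_side`; class `occupancy_map`.
#' @export
occupancy_map <- function(trajectories, bins = 50, ar = arena()) {
  if (is.matrix(trajectories)) trajectories <- list(trajectories)
  hs <- ar$half_side
  brk <- seq(-hs, hs, length.out = bins + 1)
  acc <- matrix(0, bins, bins)
  n_used <- 0
  for (tr in trajectories) {
    if (!nrow(tr)) next
    ix <- pmin(pmax(findInterval(tr[, 1], brk, rightmost.closed = TRUE), 1), bins)
    iy <- pmin(pmax(findInterval(tr[, 2], brk, rightmost.closed = TRUE), 1), bins)
    h <- matrix(0, bins, bins)
    for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
    acc <- acc + h / sum(h)
    n_used <- n_used + 1
  }
  stopifnot(n_used > 0)
  m <- acc / n_used
  structure(m, bins = bins, half_side = hs, class = c("occupancy_map", "matrix"))
}

#' Fold change between two occupancy maps
#'
#' Elementwise ratio of two maps on the same grid after adding one
#' visit-equivalent pseudocount (`1/bins^2`) to every bin of both maps,
#' so empty bins stay finite.
#'
#' @param map_a,map_b [occupancy_map()] objects on identical grids.
#' @return Matrix of ratios (`> 1` where condition A dwells more).
#' @export
fold_change_map <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b))) {
    stop("occupancy maps are on different grids", call. = FALSE)
  }
  pc <- 1 / length(map_a)
  (unclass(map_a) + pc) / (unclass(map_b) + pc)
}

#' Mean dwell time per arena quadrant
#'
#' The arena is partitioned into four equal quadrants at the origin with
#' a half-open convention (`x >= 0`, `y >= 0` belongs to the north-east
#' quadrant, etc.). Dwell time per quadrant is the number of trajectory
#' samples times the sampling interval, averaged across trajectories.
#'
#' @param trajectories A single n x 2 matrix or a list of such matrices.
#' @param dt_sample Sampling interval of the trajectories (s).
#' @param target Optional [zone()]; if given, the quadrant containing its
#'   centre is labelled `"target"` in the result's names.
#' @return Named numeric length-4 vector of mean dwell times (s), in the
#'   order NE, NW, SW, SE.
#' @export
quadrant_times <- function(trajectories, dt_sample = 0.01, target = NULL) {
  if (is.matrix(trajectories)) trajectories <- list(trajectories)
  quad <- function(x, y) {
    ifelse(x >= 0,
           ifelse(y >= 0, 1L, 4L),
           ifelse(y >= 0, 2L, 3L))
  }
  acc <- numeric(4)
  for (tr in trajectories) {
    q <- quad(tr[, 1], tr[, 2])
    acc <- acc + tabulate(q, 4) * dt_sample
  }
  out <- acc / length(trajectories)
  names(out) <- c("NE", "NW", "SW", "SE")
  if (!is.null(target)) {
    names(out)[quad(target$center[1], target$center[2])] <- "target"
  }
  out
}

#' Median distance of a trajectory to a reference point
#'
#' @param trajectory n x 2 position matrix.
#' @param reference Numeric length-2 reference point (e.g. the platform
#'   centre in a probe test).
#' @return Median Euclidean distance (a.u.).
#' @export
distance_stats <- function(trajectory, reference) {
  stopifnot(nrow(trajectory) > 0, length(reference) == 2)
  stats::median(sqrt((trajectory[, 1] - reference[1])^2 +
                       (trajectory[, 2] - reference[2])^2))
}

#' Two-sample comparison of condition summaries
#'
#' Mean difference and pooled-variance two-tailed t test between two
#' samples (thin wrapper over [stats::t.test()]).
#'
#' @param samples_a,samples_b Numeric vectors (at least 2 values each).
#' @return List with `diff` (mean a - mean b), `statistic`, `p_value`,
#'   `df`.
#' @export
compare_conditions <- function(samples_a, samples_b) {
  stopifnot(length(samples_a) >= 2, length(samples_b) >= 2)
  tt <- stats::t.test(samples_a, samples_b, var.equal = TRUE)
  list(diff = mean(samples_a) - mean(samples_b),
       statistic = unname(tt$statistic),
       p_value = tt$p.value,
       df = unname(tt$parameter))
}
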