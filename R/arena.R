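#' Square arena with bouncing boundary
#'
#' The arena is the square `[-half_side, half_side]^2`. When a proposed
#' move would leave the square, the agent is instead displaced by the
#' bouncing distance `d0` along the inward normal of the violated wall
#' (along the sum of inward normals at a corner).
#'
#' @param half_side Half side length (a.u.); the default gives
#'   `[-2, 2] x [-2, 2]`.
#' @param d0 Bouncing distance (a.u.).
#' @return A list of class `arena`.
#' @export
arena <- function(half_side = 2, d0 = 0.01) {
  stopifnot(half_side > 0, d0 > 0, d0 < half_side)
  structure(list(half_side = half_side, d0 = d0), class = "arena")
}

#' Circular reward or punishment zone
#'
#' @param center Numeric length-2 centre (a.u.).
#' @param radius Zone radius (a.u.).
#' @param valence `"reward"` or `"punishment"`.
#' @param ar An [arena()]; the zone must lie entirely inside it.
#' @return A list of class `zone`.
#' @export
zone <- function(center, radius = 0.3,
                 valence = c("reward", "punishment"), ar = arena()) {
  valence <- match.arg(valence)
  stopifnot(length(center) == 2, radius > 0)
  if (any(abs(center) + radius > ar$half_side)) {
    stop("zone extends outside the arena", call. = FALSE)
  }
  structure(list(center = as.numeric(center), radius = radius,
                 valence = valence), class = "zone")
}

validate_zones <- function(zones) {
  if (length(zones) < 2) return(invisible(zones))
  for (i in seq_len(length(zones) - 1)) {
    for (j in seq(i + 1, length(zones))) {
      d <- sqrt(sum((zones[[i]]$center - zones[[j]]$center)^2))
      if (d < zones[[i]]$radius + zones[[j]]$radius) {
        stop("overlapping zones are not allowed", call. = FALSE)
      }
    }
  }
  invisible(zones)
}

#' One kinematic step with boundary bouncing
#'
#' Applies the displacement `dx` if the result stays inside the arena;
#' otherwise displaces the agent by `d0` along the inward boundary
#' normal(s) of the wall(s) the proposed move would cross.
#'
#' @param x Current position (length-2, inside the arena).
#' @param dx Proposed displacement (length-2, a.u.).
#' @param ar An [arena()] object.
#' @return New position, always inside the arena.
#' @export
step_position <- function(x, dx, ar = arena()) {
  prop <- x + dx
  hs <- ar$half_side
  if (all(abs(prop) <= hs)) return(prop)
  normal <- c(
    if (prop[1] > hs) -1 else if (prop[1] < -hs) 1 else 0,
    if (prop[2] > hs) -1 else if (prop[2] < -hs) 1 else 0
  )
  out <- x + ar$d0 * normal
  pmin(pmax(out, -hs), hs)
}

#' Outcome of a position against a set of zones
#'
#' Zone membership uses the closed disc (boundary counts as inside).
#'
#' @param x Position (length-2).
#' @param zones List of [zone()] objects (possibly empty).
#' @return `"none"`, `"reward"` or `"punishment"` (first containing zone).
#' @export
check_outcome <- function(x, zones) {
  validate_zones(zones)
  for (z in zones) {
    if (sum((x - z$center)^2) <= z$radius^2) return(z$valence)
  }
  "none"
}

#' Task protocol: Morris water maze or reversal learning
#'
#' `"mwm"`: a single reward zone at (1.5, 1.5), radius 0.3, start at the
#' origin, maximum episode time 15 s. `"reversal"`: reward at (1.5, 1.5)
#' and punisher at (-1.5, -1.5) for episodes 1-20, centres swapped (radii
#' unchanged) for episodes 21-40.
#'
#' @param task `"mwm"` or `"reversal"`.
#' @param t_max Maximum episode duration (s).
#' @param start Start position (length-2) or `"random"` (drawn uniformly
#'   over the arena excluding the zones, per episode).
#' @param episodes Episodes per trial.
#' @param trials Number of consecutive trials.
#' @param reversal_at Last episode of the first phase (reversal task).
#' @param ar An [arena()] object.
#' @return A list of class `task_protocol`.
#' @export
make_protocol <- function(task = c("mwm", "reversal"), t_max = 15,
                          start = c(0, 0), episodes = 40, trials = 1,
                          reversal_at = 20, ar = arena()) {
  task <- match.arg(task)
  if (!identical(start, "random")) {
    stopifnot(length(start) == 2, all(abs(start) <= ar$half_side))
  }
  structure(
    list(task = task, t_max = t_max, start = start, episodes = episodes,
         trials = trials, reversal_at = reversal_at, arena = ar),
    class = "task_protocol"
  )
}

#' Zones in force at a given episode of a protocol
#'
#' @param protocol A [make_protocol()] object.
#' @param episode Episode index (1-based, within a trial).
#' @return List of [zone()] objects.
#' @export
protocol_zones <- function(protocol, episode = 1) {
  ar <- protocol$arena
  if (protocol$task == "mwm") {
    return(list(zone(c(1.5, 1.5), 0.3, "reward", ar)))
  }
  if (episode <= protocol$reversal_at) {
    list(zone(c(1.5, 1.5), 0.3, "reward", ar),
         zone(c(-1.5, -1.5), 0.3, "punishment", ar))
  } else {
    list(zone(c(-1.5, -1.5), 0.3, "reward", ar),
         zone(c(1.5, 1.5), 0.3, "punishment", ar))
  }
}

#' Draw a start position for an episode
#'
#' Fixed-start protocols return the configured position; random-start
#' protocols draw uniformly over the arena, rejecting points inside any
#' zone.
#'
#' @param protocol A [make_protocol()] object.
#' @param zones Zones in force (used to exclude starts inside them).
#' @return Numeric length-2 start position.
#' @export
draw_start <- function(protocol, zones = list()) {
  if (!identical(protocol$start, "random")) return(protocol$start)
  hs <- protocol$arena$half_side
  repeat {
    x <- stats::runif(2, -hs, hs)
    if (identical(check_outcome(x, zones), "none")) return(x)
  }
}

#' @export
print.task_protocol <- function(x, ...) {
  cat(sprintf("Task protocol: %s, %d episode(s) x %d trial(s), Tmax = %g s\n",
              x$task, x$episodes, x$trials, x$t_max))
  if (x$task == "reversal") {
    cat(sprintf("  zones swap after episode %d\n", x$reversal_at))
  }
  invisible(x)
}
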