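# Synthetic behavioral sessions: planned exploration bouts (and climbing
# episodes) embedded in a wandering trajectory, with the ground-truth
# exploration summary the scoring rules should reproduce.

#' Configuration of a synthetic behavioral session
#'
#' @param objects list of [object_spec()]s; all footprints must lie inside
#'   the arena.
#' @param bouts data.frame with columns `object` (label), `start_s`,
#'   `duration_s`, and optional `climbing` (logical); bouts must not
#'   overlap in time.
#' @param arena_cm square arena side (cm).
#' @param session_s session length (s).
#' @param sample_rate_hz sampling rate of the simulated video tracking.
#' @param latency_s optional latency to the first bout; if given, all bout
#'   starts are shifted so the earliest bout starts at this time.
#' @param seed integer seed.
#' @return `trajectory_config` object.
#' @export
trajectory_config <- function(objects, bouts, arena_cm = 33, session_s = 600,
                              sample_rate_hz = 25, latency_s = NULL,
                              seed = 1L) {
  labels <- vapply(objects, function(o) o$label, "")
  for (o in objects) {
    if (any(o$center - o$radius < 0) || any(o$center + o$radius > arena_cm)) {
      stop_invalid("trajectory_config(): object '%s' outside the arena", o$label)
    }
  }
  bouts <- as.data.frame(bouts)
  if (is.null(bouts$climbing)) bouts$climbing <- FALSE
  if (nrow(bouts)) {
    if (!all(bouts$object %in% labels)) {
      stop_invalid("trajectory_config(): bout references unknown object '%s'",
                   setdiff(bouts$object, labels)[1])
    }
    if (!is.null(latency_s)) {
      bouts$start_s <- bouts$start_s - min(bouts$start_s) + latency_s
    }
    o <- order(bouts$start_s)
    bouts <- bouts[o, , drop = FALSE]
    ends <- bouts$start_s + bouts$duration_s
    if (any(bouts$start_s[-1] < ends[-nrow(bouts)] - 1e-9)) {
      stop_invalid("trajectory_config(): bouts overlap in time")
    }
    if (any(ends > session_s + 1e-9)) {
      stop_invalid("trajectory_config(): bout extends beyond the session")
    }
  }
  structure(
    list(objects = objects, bouts = bouts, arena_cm = arena_cm,
         session_s = session_s, sample_rate_hz = sample_rate_hz,
         seed = as.integer(seed)),
    class = "trajectory_config"
  )
}

#' Generate a synthetic session trajectory with ground truth
#'
#' Builds a nose/body trajectory in which, during each planned non-climbing
#' bout, the nose sits inside the proximity band of the planned object and
#' heads toward it; during climbing bouts the nose is on the object and the
#' climbing flag is raised; outside bouts the animal wanders at a safe
#' distance from every object. The ground-truth summary applies the scoring
#' rules (chronological accumulation, 20-s criterion stop, climbing and
#' exclusion rules) to the bout plan on the sample grid.
#'
#' @param config a [trajectory_config()].
#' @param proximity_cm,heading_deg,criterion_s scoring parameters the truth
#'   is computed under (must match the scorer's).
#' @return list with `trajectory` (a [trajectory()]) and `truth` (an
#'   `exploration_summary`).
#' @export
generate_trajectory <- function(config, proximity_cm = 2, heading_deg = 45,
                                criterion_s = 20) {
  stopifnot(inherits(config, "trajectory_config"))
  dt <- 1 / config$sample_rate_hz
  t <- seq(0, config$session_s - dt, by = dt)
  n <- length(t)
  labels <- vapply(config$objects, function(o) o$label, "")
  centers <- t(vapply(config$objects, function(o) o$center, numeric(2)))
  radii <- vapply(config$objects, function(o) o$radius, numeric(1))
  arena <- config$arena_cm

  with_seed(config$seed, {
    # wandering baseline: smooth waypoint interpolation, pushed away from
    # object footprints so it can never satisfy the proximity rule
    n_way <- max(ceiling(config$session_s / 2), 2) + 1
    wx <- stats::runif(n_way, 4, arena - 4)
    wy <- stats::runif(n_way, 4, arena - 4)
    tw <- seq(0, config$session_s, length.out = n_way)
    nose_x <- stats::approx(tw, wx, t)$y
    nose_y <- stats::approx(tw, wy, t)$y
    safe <- proximity_cm + 1.5
    for (j in seq_along(labels)) {
      dx <- nose_x - centers[j, 1]
      dy <- nose_y - centers[j, 2]
      d <- sqrt(dx^2 + dy^2)
      too_close <- d < radii[j] + safe
      if (any(too_close)) {
        scale <- (radii[j] + safe) / pmax(d[too_close], 1e-6)
        nose_x[too_close] <- centers[j, 1] + dx[too_close] * scale
        nose_y[too_close] <- centers[j, 2] + dy[too_close] * scale
      }
    }
    nose_x <- pmin(pmax(nose_x, 0.5), arena - 0.5)
    nose_y <- pmin(pmax(nose_y, 0.5), arena - 0.5)
    # body trails the nose along the direction of travel
    vx <- c(diff(nose_x), 0); vy <- c(diff(nose_y), 0)
    vn <- sqrt(vx^2 + vy^2)
    ux <- ifelse(vn > 1e-6, vx / vn, 1)
    uy <- ifelse(vn > 1e-6, vy / vn, 0)
    body_x <- pmin(pmax(nose_x - 2 * ux, 0.5), arena - 0.5)
    body_y <- pmin(pmax(nose_y - 2 * uy, 0.5), arena - 0.5)
    climbing <- integer(n)

    planned <- integer(n)  # attributed object index per sample (0 = none)
    if (nrow(config$bouts)) {
      for (b in seq_len(nrow(config$bouts))) {
        bt <- config$bouts[b, ]
        j <- match(bt$object, labels)
        sel <- which(t >= bt$start_s - 1e-9 &
                       t < bt$start_s + bt$duration_s - 1e-9)
        if (!length(sel)) next
        if (isTRUE(bt$climbing)) {
          jit <- stats::runif(2, -0.2, 0.2)
          nose_x[sel] <- centers[j, 1] + jit[1]
          nose_y[sel] <- centers[j, 2] + jit[2]
          body_x[sel] <- centers[j, 1] - 1
          body_y[sel] <- centers[j, 2]
          climbing[sel] <- 1L
        } else {
          phi <- stats::runif(1, 0, 2 * pi)
          wob <- 0.3 * sin(seq_along(sel) / 8) +
            stats::rnorm(length(sel), sd = 0.05)
          dist_b <- pmin(pmax(1 + wob, 0.3), proximity_cm - 0.2)
          ang <- phi + 0.15 * sin(seq_along(sel) / 11)
          nx <- centers[j, 1] + (radii[j] + dist_b) * cos(ang)
          ny <- centers[j, 2] + (radii[j] + dist_b) * sin(ang)
          nx <- pmin(pmax(nx, 0.5), arena - 0.5)
          ny <- pmin(pmax(ny, 0.5), arena - 0.5)
          # body placed so the heading vector points at the object center,
          # with a small angular jitter well inside the heading cone
          hx <- centers[j, 1] - nx
          hy <- centers[j, 2] - ny
          hn <- sqrt(hx^2 + hy^2)
          jang <- stats::runif(length(sel), -1, 1) *
            (heading_deg * pi / 180) * 0.4
          ca <- cos(jang); sa <- sin(jang)
          bx <- nx - 2 * (ca * hx - sa * hy) / hn
          by <- ny - 2 * (sa * hx + ca * hy) / hn
          nose_x[sel] <- nx; nose_y[sel] <- ny
          body_x[sel] <- pmin(pmax(bx, 0), arena)
          body_y[sel] <- pmin(pmax(by, 0), arena)
          planned[sel] <- j
        }
      }
    }

    traj <- trajectory(t, cbind(nose_x, nose_y), cbind(body_x, body_y),
                       climbing, config$sample_rate_hz, arena)
    truth <- accumulate_exploration(planned, t, rep(dt, n), labels,
                                    criterion_s, config$session_s)
    list(trajectory = traj, truth = truth)
  })
}
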