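# Rule-based scoring of novel-object-recognition (NOR) and novel-object
# location (NOL) sessions: exploration counts when the nose is within the
# proximity band of an object and heading toward it; climbing is never
# counted; scoring stops at a 20-second total criterion; animals that do
# not reach the criterion are excluded.

#' Arena object specification
#'
#' @param label object label.
#' @param center numeric (x, y) position in cm.
#' @param radius footprint radius in cm (> 0).
#' @param role `"familiar"`, `"novel"` or `"moved"`.
#' @return `object_spec` object.
#' @export
object_spec <- function(label, center, radius, role = "familiar") {
  if (radius <= 0) stop_invalid("object_spec(): radius must be > 0")
  structure(list(label = label, center = as.numeric(center), radius = radius,
                 role = match.arg(role, c("familiar", "novel", "moved"))),
            class = "object_spec")
}

#' Construct a trajectory object
#'
#' @param time_s strictly increasing sample times, s.
#' @param nose,body n x 2 matrices of (x, y) positions in cm.
#' @param climbing logical/0-1 vector: all four paws on an object.
#' @param sample_rate_hz nominal sampling rate.
#' @param arena_cm square arena side, cm.
#' @return `trajectory` object (a data.frame with attributes).
#' @export
trajectory <- function(time_s, nose, body, climbing, sample_rate_hz,
                       arena_cm = 33) {
  if (any(diff(time_s) <= 0)) stop_invalid("trajectory(): time must strictly increase")
  df <- data.frame(time_s = time_s,
                   nose_x_cm = nose[, 1], nose_y_cm = nose[, 2],
                   body_x_cm = body[, 1], body_y_cm = body[, 2],
                   climbing = as.integer(climbing))
  attr(df, "sample_rate_hz") <- sample_rate_hz
  attr(df, "arena_cm") <- arena_cm
  class(df) <- c("trajectory", "data.frame")
  df
}

# Shared accumulation rule: given per-sample attributed object index (0 =
# none), apply the stop-at-criterion cap, latency and exclusion rules.
accumulate_exploration <- function(obj_idx, time_s, dt, labels,
                                   criterion_s, session_s) {
  keep <- time_s < session_s
  obj_idx <- obj_idx[keep]
  time_s <- time_s[keep]
  dt <- dt[keep]
  per <- stats::setNames(numeric(length(labels)), labels)
  total <- 0
  latency <- NA_real_
  for (i in seq_along(obj_idx)) {
    k <- obj_idx[i]
    if (k == 0L) next
    if (is.na(latency)) latency <- time_s[i]
    per[k] <- per[k] + dt[i]
    total <- total + dt[i]
    if (total >= criterion_s) break
  }
  reached <- total >= criterion_s
  structure(
    list(per_object_s = per, total_s = total, latency_s = latency,
         reached_criterion = reached, excluded = !reached),
    class = "exploration_summary"
  )
}

#' @export
print.exploration_summary <- function(x, ...) {
  cat(sprintf("exploration: total %.2f s (%s), latency %.2f s%s\n",
              x$total_s,
              paste(sprintf("%s: %.2f", names(x$per_object_s),
                            x$per_object_s), collapse = ", "),
              if (is.na(x$latency_s)) NA else x$latency_s,
              if (x$excluded) " [excluded: criterion not reached]" else ""))
  invisible(x)
}

#' Score an object-exploration session
#'
#' A sample counts toward an object when the nose is within
#' `proximity_cm` of the object's footprint boundary, the nose-heading
#' vector (nose minus body) points within `heading_deg` of the object
#' center, and the climbing flag is off. Counted time accumulates in
#' chronological order and scoring stops once the total reaches
#' `criterion_s`; an animal that does not reach the criterion within
#' `session_s` is flagged excluded. Note the proximity rule implements
#' "nose within 2 cm of the object", the standard reading of the scoring
#' protocol.
#'
#' @param traj a [trajectory()].
#' @param objects list of [object_spec()]s.
#' @param proximity_cm proximity band from the footprint boundary (cm).
#' @param heading_deg heading cone half-angle (degrees).
#' @param criterion_s total-exploration criterion (s).
#' @param session_s scored session length (s).
#' @return `exploration_summary`: per-object seconds, total, latency to
#'   first exploration, `reached_criterion`, `excluded`.
#' @export
score_exploration <- function(traj, objects, proximity_cm = 2,
                              heading_deg = 45, criterion_s = 20,
                              session_s = 600) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(objects)) stop_invalid("score_exploration(): no objects")
  if (nrow(traj) < 2L || diff(range(traj$time_s)) < 1) {
    stop_invalid("score_exploration(): trajectory shorter than 1 s")
  }
  labels <- vapply(objects, function(o) o$label, "")
  n <- nrow(traj)
  hx <- traj$nose_x_cm - traj$body_x_cm
  hy <- traj$nose_y_cm - traj$body_y_cm
  hnorm <- sqrt(hx^2 + hy^2)
  cosmax <- cos(heading_deg * pi / 180)
  bdist <- matrix(Inf, n, length(objects))
  ok <- matrix(FALSE, n, length(objects))
  for (j in seq_along(objects)) {
    o <- objects[[j]]
    dx <- o$center[1] - traj$nose_x_cm
    dy <- o$center[2] - traj$nose_y_cm
    dc <- sqrt(dx^2 + dy^2)
    bdist[, j] <- dc - o$radius
    facing <- (hx * dx + hy * dy) / pmax(hnorm * pmax(dc, 1e-9), 1e-9) >= cosmax
    ok[, j] <- bdist[, j] <= proximity_cm & facing & traj$climbing == 0L
  }
  obj_idx <- integer(n)
  any_ok <- rowSums(ok) > 0
  if (any(any_ok)) {
    bd <- bdist
    bd[!ok] <- Inf
    obj_idx[any_ok] <- apply(bd[any_ok, , drop = FALSE], 1, which.min)
  }
  dt <- c(diff(traj$time_s), 1 / (attr(traj, "sample_rate_hz") %||%
                                    (1 / mean(diff(traj$time_s)))))
  accumulate_exploration(obj_idx, traj$time_s, dt, labels,
                         criterion_s, session_s)
}

#' Split explored seconds into novel and familiar
#'
#' @param summary an [score_exploration()] result (must not be excluded).
#' @param novel_label label of the novel (or moved) object.
#' @return named numeric `c(novel_s, familiar_s)` where `familiar_s` sums
#'   the remaining objects.
#' @export
object_preference <- function(summary, novel_label) {
  stopifnot(inherits(summary, "exploration_summary"))
  if (summary$excluded) {
    stop_invalid("object_preference(): summary is excluded (criterion not reached)")
  }
  per <- summary$per_object_s
  if (!novel_label %in% names(per)) {
    stop_invalid("object_preference(): unknown object label '%s'", novel_label)
  }
  c(novel_s = unname(per[novel_label]),
    familiar_s = sum(per[setdiff(names(per), novel_label)]))
}

#' Latency ratio between two sessions
#'
#' Ratio of the latency to first exploration at Day 14 over Day 0; values
#' below 1 indicate improved spatial orientation in the now-familiar
#' environment.
#'
#' @param day14_latency,day0_latency latencies in seconds (`day0 > 0`).
#' @return the ratio.
#' @export
latency_ratio <- function(day14_latency, day0_latency) {
  if (!is.finite(day0_latency) || day0_latency <= 0) {
    stop_invalid("latency_ratio(): Day-0 latency must be positive")
  }
  day14_latency / day0_latency
}

#' Sucrose preference in percent
#'
#' `100 * sucrose / (sucrose + water)` by consumed mass.
#'
#' @param sucrose_g,water_g consumed grams (>= 0, not both zero).
#' @return percent preference.
#' @examples
#' sucrose_preference(3, 1)  # 75
#' @export
sucrose_preference <- function(sucrose_g, water_g) {
  if (sucrose_g < 0 || water_g < 0) {
    stop_invalid("sucrose_preference(): negative consumption")
  }
  if (sucrose_g + water_g <= 0) {
    stop_invalid("sucrose_preference(): total consumption is zero")
  }
  100 * sucrose_g / (sucrose_g + water_g)
}
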