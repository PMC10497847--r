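# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a global seed and a stage label
#'
#' Deterministic, stage-order independent, and kept inside the 32-bit
#' integer range so it is always a valid `set.seed()` argument.
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) %% 1000003 * 2654435 + h) %% 2147483399 + 1)
}

#' Arc length of a polyline given as an n x 2 matrix
#' @noRd
polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Cumulative arc length at each vertex of a polyline
#' @noRd
polyline_cumlen <- function(pts) {
  pts <- as.matrix(pts)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

#' Point and unit tangent at arc position s along a polyline
#' @noRd
polyline_point_at <- function(pts, s) {
  pts <- as.matrix(pts)
  cl <- polyline_cumlen(pts)
  s <- min(max(s, 0), cl[length(cl)])
  i <- max(which(cl <= s + 1e-12))
  if (i >= nrow(pts)) i <- nrow(pts) - 1L
  seg <- pts[i + 1L, ] - pts[i, ]
  len <- sqrt(sum(seg^2))
  tang <- if (len > 0) seg / len else c(1, 0)
  list(point = pts[i, ] + tang * (s - cl[i]), tangent = tang)
}

#' Resample a polyline at n equally spaced arc positions (vectorized)
#' @noRd
polyline_resample <- function(pts, n) {
  pts <- as.matrix(pts)
  cl <- polyline_cumlen(pts)
  total <- cl[length(cl)]
  if (total <= 0) return(matrix(rep(pts[1, ], n), ncol = 2, byrow = TRUE))
  s <- seq(0, total, length.out = n)
  i <- pmin(findInterval(s, cl, rightmost.closed = TRUE), nrow(pts) - 1L)
  seg <- pts[i + 1L, , drop = FALSE] - pts[i, , drop = FALSE]
  seglen <- pmax(sqrt(rowSums(seg^2)), 1e-12)
  frac <- (s - cl[i]) / seglen
  pts[i, , drop = FALSE] + seg * frac
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
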