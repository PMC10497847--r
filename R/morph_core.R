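# Dendrite-core tracing and region-fluorescence quantification.

# Bilinear interpolation of an intensity matrix at (x, y) um coordinates.
# Pixel centers sit at (index - 0.5) * pixel_size; coordinates are clamped
# to the image.
interp_intensity <- function(intensity, pixel_size, pts) {
  pts <- matrix(pts, ncol = 2)
  nr <- nrow(intensity); nc <- ncol(intensity)
  cx <- pmin(pmax(pts[, 1] / pixel_size + 0.5, 1), nc)
  cy <- pmin(pmax(pts[, 2] / pixel_size + 0.5, 1), nr)
  x0 <- pmin(floor(cx), nc - 1L); y0 <- pmin(floor(cy), nr - 1L)
  fx <- cx - x0; fy <- cy - y0
  i00 <- intensity[cbind(y0, x0)]
  i01 <- intensity[cbind(y0, x0 + 1)]
  i10 <- intensity[cbind(y0 + 1, x0)]
  i11 <- intensity[cbind(y0 + 1, x0 + 1)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

smooth_image <- function(intensity, sigma_px = 1.5) {
  if (sigma_px <= 0) return(intensity)
  as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(intensity), sigma = sigma_px)))
}

# 8-connected shortest bright-ridge path between two pixels, Dijkstra on
# inverted intensity.
ridge_path <- function(sm, from_rc, to_rc, margin = 25L) {
  nr <- nrow(sm); nc <- ncol(sm)
  r0 <- max(min(from_rc[1], to_rc[1]) - margin, 1L)
  r1 <- min(max(from_rc[1], to_rc[1]) + margin, nr)
  c0 <- max(min(from_rc[2], to_rc[2]) - margin, 1L)
  c1 <- min(max(from_rc[2], to_rc[2]) + margin, nc)
  sub <- sm[r0:r1, c0:c1]
  h <- nrow(sub); w <- ncol(sub)
  rng <- range(sub)
  cost <- (rng[2] - sub) / max(rng[2] - rng[1], 1e-9) + 0.02
  idx <- function(r, c) (c - 1L) * h + r
  edges <- list(); wts <- list(); k <- 1L
  steps <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (s in seq_len(nrow(steps))) {
    dr <- steps[s, 1]; dc <- steps[s, 2]; len <- steps[s, 3]
    rs <- seq_len(h); cs <- seq_len(w)
    rA <- rs[rs + dr >= 1 & rs + dr <= h]
    cA <- cs[cs + dc >= 1 & cs + dc <= w]
    if (!length(rA) || !length(cA)) next
    A <- as.matrix(expand.grid(r = rA, c = cA))
    B <- cbind(A[, 1] + dr, A[, 2] + dc)
    edges[[k]] <- rbind(idx(A[, 1], A[, 2]), idx(B[, 1], B[, 2]))
    wts[[k]] <- len * (cost[A] + cost[B]) / 2
    k <- k + 1L
  }
  g <- igraph::make_empty_graph(n = h * w, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  igraph::E(g)$weight <- unlist(wts)
  v0 <- idx(from_rc[1] - r0 + 1L, from_rc[2] - c0 + 1L)
  v1 <- idx(to_rc[1] - r0 + 1L, to_rc[2] - c0 + 1L)
  sp <- igraph::shortest_paths(g, from = v0, to = v1, output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  cbind(row = (vp - 1L) %% h + 1L + r0 - 1L,
        col = (vp - 1L) %/% h + 1L + c0 - 1L)
}

#' Trace the dendrite core between rough anchor points
#'
#' Finds the bright ridge of the dendrite tube between user-supplied
#' anchors (maximal-intensity path on a smoothed copy of the image), then
#' refines each path point to the sub-pixel intensity centroid of its
#' perpendicular profile, smooths the centerline with cubic smoothing
#' splines, and reports the arc length in um.
#'
#' @param image a [fluorescence_image()].
#' @param anchor_points n x 2 matrix (n >= 2) of rough (x, y) um points on
#'   the dendrite.
#' @param smooth_sigma_px Gaussian smoothing (pixels) applied before the
#'   ridge search.
#' @return `dendrite_core` object: `polyline` (m x 2 um points), `length`
#'   (um), `radius` (um, half the FWHM of the central perpendicular
#'   profile).
#' @export
define_dendrite_core <- function(image, anchor_points, smooth_sigma_px = 2) {
  stopifnot(inherits(image, "fluorescence_image"))
  anchor_points <- matrix(as.numeric(anchor_points), ncol = 2)
  if (nrow(anchor_points) < 2L) {
    stop_invalid("define_dendrite_core(): need at least 2 anchor points")
  }
  if (any(duplicated(round(anchor_points / image$pixel_size)))) {
    stop_invalid("define_dendrite_core(): anchor points must be distinct")
  }
  px <- image$pixel_size
  sm <- smooth_image(image$intensity, smooth_sigma_px)
  rng <- range(sm)
  thr <- rng[1] + EBImage::otsu(
    EBImage::Image((sm - rng[1]) / max(rng[2] - rng[1], 1e-9)),
    range = c(0, 1)) * (rng[2] - rng[1])
  local_int <- interp_intensity(sm, px, anchor_points)
  if (any(local_int < thr)) {
    stop_invalid("define_dendrite_core(): anchor %d lies on background",
                 which(local_int < thr)[1])
  }
  to_rc <- function(p) c(max(min(round(p[2] / px + 0.5), nrow(sm)), 1L),
                         max(min(round(p[1] / px + 0.5), ncol(sm)), 1L))
  path_rc <- NULL
  for (i in seq_len(nrow(anchor_points) - 1L)) {
    seg <- ridge_path(sm, to_rc(anchor_points[i, ]),
                      to_rc(anchor_points[i + 1L, ]))
    if (i > 1L) seg <- seg[-1L, , drop = FALSE]
    path_rc <- rbind(path_rc, seg)
  }
  pts <- cbind((path_rc[, "col"] - 0.5) * px, (path_rc[, "row"] - 0.5) * px)

  bg <- stats::median(image$intensity)
  radius <- estimate_tube_radius(sm, px, pts, bg)
  pts <- refine_centerline(sm, px, pts, half_window = max(2.5 * radius, 3 * px),
                           bg = bg)
  pts <- smooth_polyline(pts)
  structure(list(polyline = pts, length = polyline_length(pts),
                 radius = radius),
            class = "dendrite_core")
}

#' @export
print.dendrite_core <- function(x, ...) {
  cat(sprintf("dendrite core: %.2f um (%d points, radius ~ %.2f um)\n",
              x$length, nrow(x$polyline), x$radius))
  invisible(x)
}

# Half the FWHM of the perpendicular profile at the path midpoint.
estimate_tube_radius <- function(sm, px, pts, bg) {
  mid <- nrow(pts) %/% 2L
  lo <- max(mid - 3L, 1L); hi <- min(mid + 3L, nrow(pts))
  tang <- pts[hi, ] - pts[lo, ]
  tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
  nrm <- c(-tang[2], tang[1])
  tt <- seq(-2, 2, by = px / 4)
  prof <- interp_intensity(sm, px, cbind(pts[mid, 1] + tt * nrm[1],
                                         pts[mid, 2] + tt * nrm[2]))
  w <- fwhm_of_profile(tt, prof, bg)
  if (is.na(w)) 0.4 else w / 2
}

# Full width at half maximum (above bg) of a unimodal profile; NA if the
# peak does not rise above background.
fwhm_of_profile <- function(tt, prof, bg) {
  pk <- which.max(prof)
  if (prof[pk] <= bg) return(NA_real_)
  half <- bg + (prof[pk] - bg) / 2
  li <- pk
  while (li > 1L && prof[li] >= half) li <- li - 1L
  if (prof[li] >= half) return(NA_real_)
  tl <- tt[li] + (tt[li + 1L] - tt[li]) *
    (half - prof[li]) / (prof[li + 1L] - prof[li])
  ri <- pk
  while (ri < length(prof) && prof[ri] >= half) ri <- ri + 1L
  if (prof[ri] >= half) return(NA_real_)
  tr <- tt[ri - 1L] + (tt[ri] - tt[ri - 1L]) *
    (prof[ri - 1L] - half) / (prof[ri - 1L] - prof[ri])
  tr - tl
}

# Move each path point to the intensity centroid of its perpendicular
# profile (sub-pixel centerline refinement).
refine_centerline <- function(sm, px, pts, half_window, bg) {
  n <- nrow(pts)
  out <- pts
  tt <- seq(-half_window, half_window, by = px / 3)
  for (i in seq_len(n)) {
    lo <- max(i - 3L, 1L); hi <- min(i + 3L, n)
    tang <- pts[hi, ] - pts[lo, ]
    len <- sqrt(sum(tang^2))
    if (len < 1e-9) next
    tang <- tang / len
    nrm <- c(-tang[2], tang[1])
    prof <- interp_intensity(sm, px, cbind(pts[i, 1] + tt * nrm[1],
                                           pts[i, 2] + tt * nrm[2]))
    wgt <- pmax(prof - bg, 0)
    if (sum(wgt) <= 0) next
    tc <- sum(tt * wgt) / sum(wgt)
    out[i, ] <- pts[i, ] + tc * nrm
  }
  out
}

# Smooth a traced polyline with smoothing splines in arc-length parameter
# and resample it uniformly.
smooth_polyline <- function(pts, n_out = 200L) {
  if (nrow(pts) < 8L) return(pts)
  s <- polyline_cumlen(pts)
  keep <- c(TRUE, diff(s) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  dfree <- max(4, min(12, nrow(pts) %/% 6))
  fx <- stats::smooth.spline(s, pts[, 1], df = dfree)
  fy <- stats::smooth.spline(s, pts[, 2], df = dfree)
  ss <- seq(min(s), max(s), length.out = n_out)
  cbind(stats::predict(fx, ss)$y, stats::predict(fy, ss)$y)
}

#' Background-corrected mean fluorescence of a region
#'
#' Mean of the in-region pixel values inside a threshold window
#' (over/under mode: only values in `[low_threshold, high_threshold]`
#' count), minus the mean value of the background regions. The default
#' window 640-4095 matches 12-bit acquisition with an autofluorescence
#' floor.
#'
#' @param image a [fluorescence_image()].
#' @param region_mask logical matrix selecting the region.
#' @param low_threshold,high_threshold inclusive window applied to region
#'   pixels.
#' @param background_regions list of logical matrices (or a single one)
#'   whose raw mean is subtracted.
#' @return corrected mean intensity; negative values are allowed and
#'   carry attribute `flagged_negative = TRUE`.
#' @export
quantify_region_fluorescence <- function(image, region_mask,
                                         low_threshold = 640,
                                         high_threshold = 4095,
                                         background_regions = list()) {
  stopifnot(inherits(image, "fluorescence_image"))
  if (low_threshold >= high_threshold) {
    stop_invalid("quantify_region_fluorescence(): low threshold must be below high")
  }
  if (!any(region_mask)) stop_invalid("quantify_region_fluorescence(): empty mask")
  vals <- image$intensity[region_mask]
  vals <- vals[vals >= low_threshold & vals <= high_threshold]
  if (length(vals) == 0L) {
    stop_invalid("quantify_region_fluorescence(): no pixels inside the threshold window")
  }
  bgv <- 0
  if (length(background_regions)) {
    if (is.matrix(background_regions)) background_regions <- list(background_regions)
    bgv <- mean(unlist(lapply(background_regions,
                              function(m) image$intensity[m])))
  }
  out <- mean(vals) - bgv
  if (out < 0) attr(out, "flagged_negative") <- TRUE
  out
}

#' Normalize group means to a reference group
#'
#' @param group_means named numeric vector of corrected mean intensities.
#' @param reference name of the reference group (normalizes to 1).
#' @return named vector of normalized values.
#' @export
normalize_to_reference <- function(group_means, reference) {
  if (!reference %in% names(group_means)) {
    stop_invalid("normalize_to_reference(): unknown reference group '%s'", reference)
  }
  ref <- group_means[[reference]]
  if (ref == 0) stop_invalid("normalize_to_reference(): reference mean is zero")
  group_means / ref
}

#' Concordance between immunofluorescence and proteomic abundance ratios
#'
#' Pearson correlation between matched vectors of between-group IF
#' intensity ratios and TPA concentration ratios.
#'
#' @param if_ratios,tpa_ratios numeric vectors of equal length >= 3.
#' @return Pearson correlation coefficient.
#' @export
if_tpa_concordance <- function(if_ratios, tpa_ratios) {
  if (length(if_ratios) != length(tpa_ratios) || length(if_ratios) < 3L) {
    stop_invalid("if_tpa_concordance(): need equal-length vectors of size >= 3")
  }
  if (stats::sd(if_ratios) == 0 || stats::sd(tpa_ratios) == 0) {
    stop_invalid("if_tpa_concordance(): zero variance in a ratio vector")
  }
  stats::cor(if_ratios, tpa_ratios)
}
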