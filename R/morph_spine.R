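# Per-spine morphometry: skeleton fit by fluorescence maximization,
# curvilinear length, head width excluding the basal third, shape ratio
# and linear density.

roi_pixel_um <- function(roi, pixel_size) {
  cbind((roi$pixels[, 2] - 0.5) * pixel_size,
        (roi$pixels[, 1] - 0.5) * pixel_size)
}

# Geodesic distances (um) from the ROI pixel nearest the base point to all
# ROI pixels, 8-connected; keeps the graph for path extraction.
roi_geodesic <- function(roi, pixel_size, base_point) {
  pix <- roi$pixels
  n <- nrow(pix)
  key <- paste(pix[, 1], pix[, 2])
  lut <- seq_len(n)
  names(lut) <- key
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (st in list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))) {
    nb <- paste(pix[, 1] + st[1], pix[, 2] + st[2])
    hit <- !is.na(lut[nb])
    from <- c(from, lut[key[hit]])
    to <- c(to, lut[nb[hit]])
    wt <- c(wt, rep(st[3] * pixel_size, sum(hit)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  um <- roi_pixel_um(roi, pixel_size)
  d0 <- sqrt((um[, 1] - base_point[1])^2 + (um[, 2] - base_point[2])^2)
  v0 <- which.min(d0)
  list(dist = as.numeric(igraph::distances(g, v = v0)[1, ]),
       graph = g, from_vertex = v0)
}

# Candidate tip pixels: the ROI pixels most geodesically distant from the
# base, thinned so candidates are spatially separated.
candidate_tips <- function(um, gd, pixel_size, k = 3L, min_sep_px = 4) {
  ord <- order(gd, decreasing = TRUE)
  picked <- integer(0)
  for (i in ord) {
    if (!is.finite(gd[i])) next
    if (length(picked) &&
        any(sqrt((um[picked, 1] - um[i, 1])^2 +
                 (um[picked, 2] - um[i, 2])^2) < min_sep_px * pixel_size)) next
    picked <- c(picked, i)
    if (length(picked) >= k) break
  }
  picked
}

resample_polyline_n <- function(pts, n) polyline_resample(pts, n)

# Mean interpolated intensity along the curve minus a curvature penalty
# (sum of squared turning angles, scaled by the ROI peak intensity).
skeleton_objective <- function(ctrl, sm, pixel_size, lambda, scale_int,
                               n_samp = 40L) {
  cur <- resample_polyline_n(ctrl, n_samp)
  ints <- interp_intensity(sm, pixel_size, cur)
  v1 <- diff(cur)
  ang <- atan2(v1[, 2], v1[, 1])
  turn <- diff(ang)
  turn <- atan2(sin(turn), cos(turn))
  mean(ints) - lambda * scale_int * sum(turn^2)
}

#' Fit the virtual skeleton of a spine
#'
#' Finds, within a spine ROI, the curve from the base point into the spine
#' along which sampled fluorescence is maximal (mean intensity along the
#' curve, with a curvature penalty so the "virtual skeleton" stays smooth).
#' The search is a deterministic multi-start: candidate tips are the ROI
#' pixels most geodesically distant from the base; for each candidate, the
#' interior control points of a fixed-size polyline are optimized by
#' Nelder-Mead; the best objective wins, ties broken by the shorter curve.
#' The distal endpoint is then refined to the arc position where the
#' axial intensity profile falls to half of the head plateau above
#' background, which makes the curvilinear length robust to how far the
#' mask extends into the PSF skirt.
#'
#' @param image a [fluorescence_image()].
#' @param roi a [spine_roi()] with at least 4 pixels.
#' @param lambda curvature penalty weight (dimensionless; scaled by the
#'   ROI peak intensity).
#' @param n_control number of polyline control points (base + interior +
#'   tip).
#' @param smooth_sigma_px image smoothing before sampling.
#' @return `spine_skeleton`: `points` (m x 2 um from base to tip),
#'   `length` (um), `integrated_fluorescence` (counts summed along the
#'   curve), `base_point`.
#' @export
fit_spine_skeleton <- function(image, roi, lambda = 0.05, n_control = 5L,
                               smooth_sigma_px = 1) {
  stopifnot(inherits(image, "fluorescence_image"), inherits(roi, "spine_roi"))
  if (nrow(roi$pixels) < 4L) stop_invalid("fit_spine_skeleton(): ROI too small")
  px <- image$pixel_size
  sm <- smooth_image(image$intensity, smooth_sigma_px)
  um <- roi_pixel_um(roi, px)
  geo <- roi_geodesic(roi, px, roi$base_point)
  gd <- geo$dist
  tips <- candidate_tips(um, gd, px)
  if (!length(tips)) stop_invalid("fit_spine_skeleton(): no reachable tip candidates")
  scale_int <- max(interp_intensity(sm, px, um))
  base <- roi$base_point

  best <- NULL
  for (ti in tips) {
    tip <- um[ti, ]
    # initialize along the within-ROI geodesic path so strongly curved
    # spines start near their true skeleton
    vp <- tryCatch(as.integer(igraph::shortest_paths(
      geo$graph, from = geo$from_vertex, to = ti,
      output = "vpath")$vpath[[1]]), error = function(e) integer(0))
    init <- if (length(vp) >= 2L) {
      polyline_resample(rbind(base, um[vp, , drop = FALSE], tip), n_control)
    } else {
      cbind(seq(base[1], tip[1], length.out = n_control),
            seq(base[2], tip[2], length.out = n_control))
    }
    init[1, ] <- base; init[n_control, ] <- tip
    free0 <- as.vector(init[2:(n_control - 1L), , drop = FALSE])
    obj <- function(par) {
      ctrl <- rbind(base,
                    matrix(par, ncol = 2),
                    tip)
      -skeleton_objective(ctrl, sm, px, lambda, scale_int)
    }
    fit <- stats::optim(free0, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-7))
    ctrl <- rbind(base, matrix(fit$par, ncol = 2), tip)
    val <- -fit$value
    len <- polyline_length(ctrl)
    if (is.null(best) || val > best$val + 1e-9 ||
        (abs(val - best$val) <= 1e-9 && len < best$len)) {
      best <- list(ctrl = ctrl, val = val, len = len)
    }
  }

  refined <- refine_skeleton_tip(best$ctrl, sm, px)
  pts <- refined$points
  L <- refined$length
  samp <- resample_polyline_n(pts, max(20L, ceiling(L / (px / 2))))
  ds <- L / (nrow(samp) - 1L)
  integ <- sum(interp_intensity(image$intensity, px, samp)) * ds
  structure(list(points = pts, length = L,
                 integrated_fluorescence = integ, base_point = base),
            class = "spine_skeleton")
}

#' @export
print.spine_skeleton <- function(x, ...) {
  cat(sprintf("spine skeleton: L = %.3f um (%d points)\n",
              x$length, nrow(x$points)))
  invisible(x)
}

# Trim or extend the distal end of the fitted curve to the half-plateau
# crossing of the axial intensity profile.
refine_skeleton_tip <- function(ctrl, sm, px) {
  L0 <- polyline_length(ctrl)
  n <- max(40L, ceiling(L0 / (px / 4)))
  cur <- resample_polyline_n(ctrl, n)
  # extend beyond the mask tip along the final direction
  tang <- cur[n, ] - cur[n - 1L, ]
  tang <- tang / max(sqrt(sum(tang^2)), 1e-12)
  ext_len <- max(0.5, 6 * px)
  n_ext <- ceiling(ext_len / (L0 / (n - 1L)))
  ds <- L0 / (n - 1L)
  ext <- t(vapply(seq_len(n_ext), function(j) cur[n, ] + tang * j * ds,
                  numeric(2)))
  all_pts <- rbind(cur, ext)
  s_all <- seq(0, by = ds, length.out = nrow(all_pts))
  prof <- interp_intensity(sm, px, all_pts)
  bg <- stats::median(sm)
  head_idx <- which(s_all >= 0.6 * L0 & s_all <= 0.95 * L0)
  plateau <- max(prof[head_idx])
  if (plateau <= bg) {
    return(list(points = cur, length = L0))
  }
  half <- bg + (plateau - bg) / 2
  # last arc position (searching outward from the plateau) still >= half
  pk <- head_idx[which.max(prof[head_idx])]
  j <- pk
  while (j < length(prof) && prof[j + 1L] >= half) j <- j + 1L
  if (j >= length(prof)) {
    L <- s_all[length(s_all)]
  } else {
    frac <- (prof[j] - half) / max(prof[j] - prof[j + 1L], 1e-12)
    L <- s_all[j] + frac * ds
  }
  L <- max(L, 2 * px)
  keep <- s_all <= L
  pts <- all_pts[keep, , drop = FALSE]
  end <- polyline_point_at(all_pts, L)$point
  pts <- rbind(pts, end)
  list(points = pts, length = L)
}

#' Measure the spine head width
#'
#' Scans arc positions along the distal two-thirds of the fitted skeleton
#' (the basal third adjacent to the dendrite is excluded) and measures the
#' full width at half maximum, above background, of the intensity profile
#' perpendicular to the skeleton. The head width is the maximum such
#' width.
#'
#' @param image a [fluorescence_image()].
#' @param skeleton a [fit_spine_skeleton()] result.
#' @param roi the spine's [spine_roi()] (bounds the profile window).
#' @param smooth_sigma_px image smoothing before profile sampling.
#' @return head width in um.
#' @export
measure_head_width <- function(image, skeleton, roi, smooth_sigma_px = 1) {
  stopifnot(inherits(image, "fluorescence_image"),
            inherits(skeleton, "spine_skeleton"))
  px <- image$pixel_size
  if (skeleton$length <= 0) stop_invalid("measure_head_width(): zero-length skeleton")
  sm <- smooth_image(image$intensity, smooth_sigma_px)
  bg <- stats::median(sm)
  um <- roi_pixel_um(roi, px)
  t_max <- min(max(dist_point_polyline(um, skeleton$points)) + 3 * px, 2.5)
  tt <- seq(-t_max, t_max, by = px / 4)
  L <- skeleton$length
  s_grid <- seq(L / 3 + px / 2, L, by = px / 2)
  widths <- rep(NA_real_, length(s_grid))
  for (i in seq_along(s_grid)) {
    pa <- polyline_point_at(skeleton$points, s_grid[i])
    nrm <- c(-pa$tangent[2], pa$tangent[1])
    prof <- interp_intensity(sm, px, cbind(pa$point[1] + tt * nrm[1],
                                           pa$point[2] + tt * nrm[2]))
    widths[i] <- fwhm_of_profile(tt, prof, bg)
  }
  if (all(is.na(widths))) {
    stop_invalid("measure_head_width(): no measurable head (all profiles below background)")
  }
  max(widths, na.rm = TRUE)
}

#' Length-to-width shape ratio with class assignment
#'
#' @param length curvilinear spine length, um (> 0).
#' @param head_width maximal head diameter, um (> 0).
#' @return list with `ratio` and `class_label` (ratio bin, see
#'   [spine_class_bins()]); ratios below 2 are the mature compartment,
#'   above 2 the immature one.
#' @examples
#' compute_shape_ratio(2.0, 0.5)  # ratio 4, filopodia
#' @export
compute_shape_ratio <- function(length, head_width) {
  if (!is.finite(length) || length <= 0 || !is.finite(head_width) ||
      head_width <= 0) {
    stop_invalid("compute_shape_ratio(): length and head_width must be positive")
  }
  r <- length / head_width
  list(ratio = r, class_label = classify_ratio(r))
}

#' Linear spine density
#'
#' @param spine_count number of spines counted (>= 0).
#' @param dendrite_length analyzed dendrite core length, um (> 0).
#' @return spines per um.
#' @examples
#' compute_linear_density(27, 25)  # 1.08
#' @export
compute_linear_density <- function(spine_count, dendrite_length) {
  if (!is.finite(dendrite_length) || dendrite_length <= 0) {
    stop_invalid("compute_linear_density(): dendrite_length must be > 0")
  }
  if (spine_count < 0) stop_invalid("compute_linear_density(): negative count")
  spine_count / dendrite_length
}

#' Measure all spines of an image
#'
#' Runs [fit_spine_skeleton()] and [measure_head_width()] over a list of
#' ROIs and tabulates length, head width, ratio and class per spine. ROIs
#' that fail to yield a measurable head are reported with NA and kept in
#' the table.
#'
#' @param image a [fluorescence_image()].
#' @param rois list of [spine_roi()] objects.
#' @param ... forwarded to [fit_spine_skeleton()].
#' @return data.frame: `roi_id`, `length_um`, `head_width_um`, `ratio`,
#'   `class`.
#' @export
measure_spines <- function(image, rois, ...) {
  rows <- lapply(rois, function(roi) {
    res <- tryCatch({
      sk <- fit_spine_skeleton(image, roi, ...)
      w <- measure_head_width(image, sk, roi)
      sr <- compute_shape_ratio(sk$length, w)
      data.frame(roi_id = roi$id, length_um = sk$length, head_width_um = w,
                 ratio = sr$ratio, class = sr$class_label)
    }, error = function(e) {
      data.frame(roi_id = roi$id, length_um = NA_real_,
                 head_width_um = NA_real_, ratio = NA_real_,
                 class = NA_character_)
    })
    res
  })
  do.call(rbind, rows)
}

#' Summarize a per-group spine sample
#'
#' @param group group name.
#' @param measurements data.frame as returned by [measure_spines()].
#' @param dendrite_length_um total dendrite core length analyzed, um.
#' @return `spine_group_sample`: measurements plus `spine_count`,
#'   `dendrite_length_um` and `density` (spines/um).
#' @export
spine_group_sample <- function(group, measurements, dendrite_length_um) {
  n <- nrow(measurements)
  structure(
    list(group = group, measurements = measurements,
         spine_count = n, dendrite_length_um = dendrite_length_um,
         density = compute_linear_density(n, dendrite_length_um)),
    class = "spine_group_sample"
  )
}

#' @export
print.spine_group_sample <- function(x, ...) {
  cat(sprintf("group %s: %d spines over %.1f um (density %.3f /um)\n",
              x$group, x$spine_count, x$dendrite_length_um, x$density))
  invisible(x)
}
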