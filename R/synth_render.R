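# Rendering of synthetic DiI-like fluorescence scenes: a dendrite tube plus
# spines of known geometry, Gaussian PSF blur, Poisson photon noise and
# Gaussian read noise, with exact per-spine ground truth.

#' Construct a fluorescence image object
#'
#' @param intensity numeric matrix of non-negative counts (rows = y,
#'   columns = x; pixel centers at (index - 0.5) * pixel_size um).
#' @param pixel_size um per pixel (> 0).
#' @return `fluorescence_image` object.
#' @export
fluorescence_image <- function(intensity, pixel_size) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop_invalid("fluorescence_image(): pixel_size must be a positive scalar")
  }
  if (any(intensity < 0)) {
    stop_invalid("fluorescence_image(): intensities must be non-negative")
  }
  structure(list(intensity = intensity, pixel_size = pixel_size),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("fluorescence image %d x %d px, %.3f um/px (%.1f x %.1f um)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              nrow(x$intensity) * x$pixel_size,
              ncol(x$intensity) * x$pixel_size))
  invisible(x)
}

#' Spine region of interest
#'
#' @param pixels integer matrix (n x 2) of (row, col) pixel coordinates of
#'   the mask (connected, nonempty).
#' @param base_point numeric (x, y) in um: the point where the spine meets
#'   the dendrite tube surface.
#' @param id region identifier.
#' @return `spine_roi` object.
#' @export
spine_roi <- function(pixels, base_point, id = 1L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop_invalid("spine_roi(): empty mask")
  structure(list(pixels = pixels, base_point = as.numeric(base_point),
                 id = id),
            class = "spine_roi")
}

# Perpendicular distances from points P (n x 2) to segment a-b, plus the
# clamped projection parameter (0..seglen).
dist_point_segment <- function(P, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) {
    return(list(dist = sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2), t = 0))
  }
  t <- ((P[, 1] - a[1]) * d[1] + (P[, 2] - a[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- a[1] + t * d[1]
  py <- a[2] + t * d[2]
  list(dist = sqrt((P[, 1] - px)^2 + (P[, 2] - py)^2), t = t)
}

# Minimum distance from points P to a polyline.
dist_point_polyline <- function(P, pts) {
  pts <- as.matrix(pts)
  best <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(pts) - 1L)) {
    di <- dist_point_segment(P, pts[i, ], pts[i + 1L, ])$dist
    best <- pmin(best, di)
  }
  best
}

# Skeleton of a spine spec anchored at base point p0 with unit direction u:
# straight line or circular arc of the given curvature. Returns sampled
# points at arc positions s.
spine_skeleton_points <- function(p0, u, L, curvature, s) {
  if (abs(curvature) < 1e-9) {
    cbind(p0[1] + s * u[1], p0[2] + s * u[2])
  } else {
    R <- 1 / curvature
    nrm <- c(-u[2], u[1])
    cx <- p0[1] + R * nrm[1]
    cy <- p0[2] + R * nrm[2]
    ang <- s / R
    cbind(cx + R * (-nrm[1] * cos(ang) + u[1] * sin(ang)),
          cy + R * (-nrm[2] * cos(ang) + u[2] * sin(ang)))
  }
}

#' Assign attachment positions and orientations to sampled spines
#'
#' Places spines at evenly spaced arc positions along the dendrite core,
#' alternating sides, leaving a margin at both ends. For a straight
#' horizontal core this yields spines pointing alternately up and down.
#'
#' @param specs list of [spine_shape_spec()] objects.
#' @param core_length dendrite core arc length (um).
#' @param margin um kept free at each end of the core.
#' @return the spec list with `attachment` and `orientation` filled in.
#' @export
place_spines <- function(specs, core_length, margin = 1.5) {
  n <- length(specs)
  if (n == 0L) return(specs)
  usable <- core_length - 2 * margin
  if (usable <= 0) stop_invalid("place_spines(): core too short for margin")
  at <- margin + usable * (seq_len(n) - 0.5) / n
  for (i in seq_len(n)) {
    specs[[i]]$attachment <- at[i]
    specs[[i]]$side <- if (i %% 2L == 0L) 1 else -1
  }
  specs
}

#' Scene configuration for synthetic spine image rendering
#'
#' Defaults mirror the acquisition geometry of confocal DiI imaging:
#' 0.07 um pixels and a 1024 x 1024 frame.
#'
#' @param spines list of placed [spine_shape_spec()] objects (each with a
#'   non-NA `attachment`).
#' @param pixel_size um per pixel.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param dendrite_path n x 2 matrix of (x, y) um vertices of the dendrite
#'   core; default a horizontal line across the image center.
#' @param dendrite_radius dendrite tube radius, um.
#' @param psf_sigma Gaussian PSF standard deviation, um (>= 0).
#' @param photon_scale expected photon counts at structure peak.
#' @param background_level additive background counts.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param poisson_noise apply Poisson photon noise?
#' @param seed integer seed for the noise draws.
#' @return `scene_config` object.
#' @export
scene_config <- function(spines = list(), pixel_size = 0.07,
                         image_shape = c(1024L, 1024L),
                         dendrite_path = NULL, dendrite_radius = 0.4,
                         psf_sigma = 0.1, photon_scale = 500,
                         background_level = 10, read_noise_sd = 2,
                         poisson_noise = TRUE, seed = 1L) {
  if (pixel_size <= 0) stop_invalid("scene_config(): pixel_size must be > 0")
  if (psf_sigma < 0) stop_invalid("scene_config(): psf_sigma must be >= 0")
  height_um <- image_shape[1] * pixel_size
  width_um <- image_shape[2] * pixel_size
  if (is.null(dendrite_path)) {
    dendrite_path <- rbind(c(0.02 * width_um, height_um / 2),
                           c(0.98 * width_um, height_um / 2))
  }
  dendrite_path <- as.matrix(dendrite_path)
  core_len <- polyline_length(dendrite_path)
  for (i in seq_along(spines)) {
    sp <- spines[[i]]
    if (!inherits(sp, "spine_shape_spec")) {
      stop_invalid("scene_config(): spines[[%d]] is not a spine_shape_spec", i)
    }
    if (is.na(sp$attachment) || sp$attachment < 0 || sp$attachment > core_len) {
      stop_invalid("scene_config(): spine %d attachment not on the dendrite path", i)
    }
  }
  structure(
    list(spines = spines, pixel_size = pixel_size,
         image_shape = as.integer(image_shape),
         dendrite_path = dendrite_path, dendrite_radius = dendrite_radius,
         psf_sigma = psf_sigma, photon_scale = photon_scale,
         background_level = background_level, read_noise_sd = read_noise_sd,
         poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Geometry of one placed spine in scene coordinates.
spine_geometry <- function(spec, dendrite_path, dendrite_radius) {
  at <- polyline_point_at(dendrite_path, spec$attachment)
  nrm <- c(-at$tangent[2], at$tangent[1]) * (spec$side %||% 1)
  # orientation is relative to the outward normal: the default pi/2 means
  # perpendicular to the dendrite; other values tilt the spine by
  # (orientation - pi/2) radians within the image plane.
  tilt <- (spec$orientation %||% (pi / 2)) - pi / 2
  ct <- cos(tilt); st <- sin(tilt)
  u <- c(ct * nrm[1] - st * nrm[2], st * nrm[1] + ct * nrm[2])
  base <- at$point + dendrite_radius * u
  L <- spec$length
  W <- spec$head_width
  sc <- max(L - W / 2, 0)
  head_center <- drop(spine_skeleton_points(base, u, L, spec$curvature %||% 0, sc))
  tip <- drop(spine_skeleton_points(base, u, L, spec$curvature %||% 0, L))
  list(base = base, dir = u, head_center = head_center, tip = tip,
       sc = sc, L = L, W = W, nw = spec$neck_width,
       curvature = spec$curvature %||% 0)
}

#' Render a synthetic fluorescence scene with ground truth
#'
#' Renders the dendrite tube and every spine (tapered neck from the neck
#' width up to the head width, plus a circular head of the head-width
#' diameter whose far edge is the spine tip), blurs with a Gaussian PSF,
#' and adds Poisson photon noise, a constant background and Gaussian read
#' noise. Identical configuration and seed give a bit-identical image.
#'
#' @param config a [scene_config()].
#' @return list with `image` (a [fluorescence_image()]), and `truth`: a
#'   list holding `spines` (data.frame of true length, head width, ratio,
#'   class, base/tip coordinates), `rois` (list of [spine_roi()] masks from
#'   the noise-free geometry), `label_mask` (integer matrix of spine ids),
#'   `core` (dendrite polyline) and `core_length` (um).
#' @examples
#' sp <- place_spines(sample_spine_shapes(c(mushroom = 1), 2, seed = 3),
#'                    core_length = 14)
#' cfg <- scene_config(sp, image_shape = c(120L, 220L), seed = 5)
#' sc <- render_scene(cfg)
#' sc$truth$spines$ratio
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  px <- config$pixel_size
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  width_um <- nc * px; height_um <- nr * px

  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px

  support <- matrix(FALSE, nr, nc)
  label <- matrix(0L, nr, nc)

  # dendrite tube: band of pixels within dendrite_radius of the core,
  # computed per segment on a cropped bounding box
  core <- config$dendrite_path
  pad <- config$dendrite_radius + 3 * config$psf_sigma + 2 * px
  bb <- c(max(min(core[, 1]) - pad, 0), min(max(core[, 1]) + pad, width_um),
          max(min(core[, 2]) - pad, 0), min(max(core[, 2]) + pad, height_um))
  ci <- which(xs >= bb[1] & xs <= bb[2])
  ri <- which(ys >= bb[3] & ys <= bb[4])
  if (length(ci) && length(ri)) {
    P <- cbind(rep(xs[ci], each = length(ri)), rep(ys[ri], times = length(ci)))
    dd <- dist_point_polyline(P, core)
    m <- matrix(dd <= config$dendrite_radius, nrow = length(ri))
    support[ri, ci] <- support[ri, ci] | m
  }
  dendrite_mask <- support

  truth_rows <- list()
  rois <- list()
  for (i in seq_along(config$spines)) {
    sp <- config$spines[[i]]
    g <- spine_geometry(sp, core, config$dendrite_radius)
    if (g$tip[1] < 0 || g$tip[1] > width_um || g$tip[2] < 0 ||
        g$tip[2] > height_um ||
        g$head_center[1] - g$W / 2 < 0 || g$head_center[1] + g$W / 2 > width_um ||
        g$head_center[2] - g$W / 2 < 0 || g$head_center[2] + g$W / 2 > height_um) {
      stop_invalid("render_scene(): spine %d extends outside the image", i)
    }
    ds <- min(px / 3, 0.02)
    s_grid <- seq(0, g$L, by = ds)
    skel <- spine_skeleton_points(g$base, g$dir, g$L, g$curvature, s_grid)
    # neck half-width: linear taper from neck radius at the base to the
    # head radius at the head center
    w_neck <- if (g$sc > 0) {
      g$nw / 2 + (g$W / 2 - g$nw / 2) * pmin(s_grid / g$sc, 1)
    } else rep(g$W / 2, length(s_grid))

    pad_s <- g$W / 2 + 3 * config$psf_sigma + 2 * px
    bbx <- range(skel[, 1]); bby <- range(skel[, 2])
    ci2 <- which(xs >= bbx[1] - pad_s & xs <= bbx[2] + pad_s)
    ri2 <- which(ys >= bby[1] - pad_s & ys <= bby[2] + pad_s)
    P2 <- cbind(rep(xs[ci2], each = length(ri2)),
                rep(ys[ri2], times = length(ci2)))
    # nearest skeleton sample per pixel
    best_d <- rep(Inf, nrow(P2)); best_j <- rep(1L, nrow(P2))
    for (j in seq_along(s_grid)) {
      dj <- (P2[, 1] - skel[j, 1])^2 + (P2[, 2] - skel[j, 2])^2
      upd <- dj < best_d
      best_d[upd] <- dj[upd]; best_j[upd] <- j
    }
    best_d <- sqrt(best_d)
    in_neck <- s_grid[best_j] <= g$sc + ds & best_d <= w_neck[best_j]
    dh <- sqrt((P2[, 1] - g$head_center[1])^2 + (P2[, 2] - g$head_center[2])^2)
    in_head <- dh <= g$W / 2
    m2 <- matrix(in_neck | in_head, nrow = length(ri2))
    sup_before <- support[ri2, ci2]
    support[ri2, ci2] <- sup_before | m2
    spine_only <- m2 & !dendrite_mask[ri2, ci2]
    lab_block <- label[ri2, ci2]
    lab_block[spine_only] <- i
    label[ri2, ci2] <- lab_block

    pix <- which(label == i, arr.ind = TRUE)
    rois[[i]] <- spine_roi(pix, base_point = g$base, id = i)
    truth_rows[[i]] <- data.frame(
      id = i, class = sp$class_label, length = g$L, head_width = g$W,
      ratio = g$L / g$W, attachment = sp$attachment,
      base_x = g$base[1], base_y = g$base[2],
      tip_x = g$tip[1], tip_y = g$tip[2]
    )
  }

  img <- matrix(0, nr, nc)
  img[support] <- config$photon_scale
  if (config$psf_sigma > 0) {
    sigma_px <- config$psf_sigma / px
    img <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = sigma_px)))
    img[img < 0] <- 0
  }
  signal <- img + config$background_level
  out <- with_seed(config$seed, {
    v <- if (config$poisson_noise) {
      stats::rpois(length(signal), lambda = as.vector(signal))
    } else as.vector(signal)
    if (config$read_noise_sd > 0) {
      v <- v + stats::rnorm(length(v), sd = config$read_noise_sd)
    }
    v
  })
  out <- matrix(pmax(out, 0), nr, nc)

  spines_df <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(id = integer(), class = character(), length = numeric(),
               head_width = numeric(), ratio = numeric(),
               attachment = numeric(), base_x = numeric(), base_y = numeric(),
               tip_x = numeric(), tip_y = numeric())

  list(
    image = fluorescence_image(out, px),
    truth = list(spines = spines_df, rois = rois, label_mask = label,
                 core = core, core_length = polyline_length(core))
  )
}

#' Render a single spine in a minimal scene
#'
#' Convenience wrapper building a small image just large enough for one
#' spine on a short horizontal dendrite; used for per-spine measurement
#' benchmarks.
#'
#' @param spec a [spine_shape_spec()].
#' @param pixel_size,psf_sigma,photon_scale,background_level,read_noise_sd,poisson_noise,seed
#'   forwarded to [scene_config()].
#' @return as [render_scene()].
#' @export
single_spine_scene <- function(spec, pixel_size = 0.07, psf_sigma = 0.1,
                               photon_scale = 500, background_level = 10,
                               read_noise_sd = 2, poisson_noise = TRUE,
                               seed = 1L) {
  reach <- spec$length + spec$head_width / 2 + 1
  width_um <- max(2 * spec$head_width + 3, 4)
  height_um <- reach + 1.5
  nr <- ceiling(height_um / pixel_size)
  nc <- ceiling(width_um / pixel_size)
  dend_y <- height_um - 0.8
  path <- rbind(c(0.2, dend_y), c(width_um - 0.2, dend_y))
  spec$attachment <- polyline_length(path) / 2
  spec$side <- -1  # outward normal pointing up (towards smaller y)
  cfg <- scene_config(list(spec), pixel_size = pixel_size,
                      image_shape = c(nr, nc), dendrite_path = path,
                      dendrite_radius = 0.4, psf_sigma = psf_sigma,
                      photon_scale = photon_scale,
                      background_level = background_level,
                      read_noise_sd = read_noise_sd,
                      poisson_noise = poisson_noise, seed = seed)
  render_scene(cfg)
}

#' @describeIn fluorescence_image display the image in grey scale with the
#'   origin at the top left.
#' @param x a `fluorescence_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.fluorescence_image <- function(x, ...) {
  m <- t(x$intensity)[, rev(seq_len(nrow(x$intensity))), drop = FALSE]
  graphics::image(m, col = grDevices::grey.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(x$intensity) / ncol(x$intensity), ...)
  invisible(x)
}
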