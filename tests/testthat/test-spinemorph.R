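# Morphometry: dendrite core, skeleton fit, head width, ratio, density,
# region fluorescence.

test_that("dendrite core length recovers straight and curved tubes within 2%", {
  sc <- tube_scene(rbind(c(1.5, 2.1), c(11.5, 2.1)), c(60L, 200L))
  core <- define_dendrite_core(sc$image, rbind(c(1.5, 2.1), c(11.5, 2.1)))
  expect_lt(abs(core$length - 10) / 10, 0.02)

  theta <- seq(0, pi / 2, length.out = 60)
  path <- cbind(1.5 + 5 * sin(theta), 6.5 - 5 * cos(theta))
  sc2 <- tube_scene(path, c(110L, 110L))
  core2 <- define_dendrite_core(sc2$image,
                                rbind(path[1, ], path[30, ], path[60, ]))
  expect_lt(abs(core2$length - pi / 2 * 5) / (pi / 2 * 5), 0.02)
})

test_that("dendrite core rejects degenerate or background anchors", {
  sc <- tube_scene(rbind(c(1.5, 2.1), c(11.5, 2.1)), c(60L, 200L))
  expect_error(define_dendrite_core(sc$image, rbind(c(2, 2.1), c(2, 2.1))),
               "distinct")
  expect_error(define_dendrite_core(sc$image, rbind(c(1.5, 0.3), c(11.5, 2.1))),
               "background")
})

test_that("skeleton length recovers straight spines and follows curvature", {
  spec <- spine_shape_spec("thin", 1.5, 0.6)
  sc <- single_spine_scene(spec, poisson_noise = FALSE, read_noise_sd = 0)
  sk <- fit_spine_skeleton(sc$image, sc$truth$rois[[1]])
  expect_lt(abs(sk$length - 1.5) / 1.5, 0.10)
  expect_equal(sk$points[1, ], sk$base_point)

  # curved spine, arc 2.2 um vs chord 1.8 um: measured length must be
  # curvilinear, i.e. closer to the arc
  x <- uniroot(function(x) sin(x) / x - 1.8 / 2.2, c(0.1, 3))$root
  curv <- 2 * x / 2.2
  spec_c <- spine_shape_spec("thin", 2.2, 0.75, neck_width = 0.5,
                             curvature = curv)
  sc_c <- single_spine_scene(spec_c, poisson_noise = FALSE, read_noise_sd = 0)
  sk_c <- fit_spine_skeleton(sc_c$image, sc_c$truth$rois[[1]])
  expect_lt(abs(sk_c$length - 2.2), abs(sk_c$length - 1.8))
})

test_that("skeleton fit is deterministic and rejects tiny ROIs", {
  spec <- spine_shape_spec("mushroom", 1.2, 0.8)
  sc <- single_spine_scene(spec, seed = 5)
  s1 <- fit_spine_skeleton(sc$image, sc$truth$rois[[1]])
  s2 <- fit_spine_skeleton(sc$image, sc$truth$rois[[1]])
  expect_identical(s1$length, s2$length)
  expect_identical(s1$points, s2$points)
  tiny <- spine_roi(matrix(c(5, 5, 5, 6, 6, 5), ncol = 2, byrow = TRUE),
                    c(0.3, 0.3))
  expect_error(fit_spine_skeleton(sc$image, tiny), "ROI too small")
})

test_that("measured lengths preserve ordering of true lengths (noise-free)", {
  l_short <- {
    s <- single_spine_scene(spine_shape_spec("thin", 1.5, 0.6),
                            poisson_noise = FALSE, read_noise_sd = 0)
    fit_spine_skeleton(s$image, s$truth$rois[[1]])$length
  }
  l_long <- {
    s <- single_spine_scene(spine_shape_spec("thin", 1.8, 0.7),
                            poisson_noise = FALSE, read_noise_sd = 0)
    fit_spine_skeleton(s$image, s$truth$rois[[1]])$length
  }
  expect_lt(l_short, l_long)
})

test_that("head width recovers the planted diameter within 15%", {
  spec <- spine_shape_spec("mushroom", 1.1, 0.6, neck_width = 0.3)
  sc <- single_spine_scene(spec, poisson_noise = FALSE, read_noise_sd = 0)
  sk <- fit_spine_skeleton(sc$image, sc$truth$rois[[1]])
  w <- measure_head_width(sc$image, sk, sc$truth$rois[[1]])
  expect_lt(abs(w - 0.6) / 0.6, 0.15)
})

test_that("a disk head without PSF is measured within one pixel", {
  px <- 0.07
  spec <- spine_shape_spec("mushroom", 1.3, 0.7, neck_width = 0.35)
  sc <- single_spine_scene(spec, pixel_size = px, psf_sigma = 0,
                           poisson_noise = FALSE, read_noise_sd = 0)
  sk <- fit_spine_skeleton(sc$image, sc$truth$rois[[1]])
  w <- measure_head_width(sc$image, sk, sc$truth$rois[[1]])
  expect_lt(abs(w - 0.7), px * 1.5)
})

test_that("widest section in the basal third is excluded from head width", {
  # hand-built image: vertical spine with a wide basal blob (within the
  # basal third) and a narrower distal head
  px <- 0.07
  nr <- 80L; nc <- 60L
  img <- matrix(0, nr, nc)
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  cx <- 2.1
  base_y <- 4.6; tip_y <- 1.6   # length 3 um upward
  # narrow stalk
  stalk <- abs(outer(ys, xs, function(y, x) x - cx)) <= 0.12 &
    outer(ys, xs, function(y, x) y) <= base_y &
    outer(ys, xs, function(y, x) y) >= tip_y
  # wide blob at 0.25 um above base (basal third), diameter 1.0
  blob <- outer(ys, xs, function(y, x) sqrt((x - cx)^2 + (y - (base_y - 0.35))^2)) <= 0.5
  # distal head at 2.5 um above base, diameter 0.6
  head <- outer(ys, xs, function(y, x) sqrt((x - cx)^2 + (y - (tip_y + 0.3))^2)) <= 0.3
  img[stalk | blob | head] <- 500
  im <- fluorescence_image(img, px)
  pix <- which(stalk | blob | head, arr.ind = TRUE)
  roi <- spine_roi(pix, base_point = c(cx, base_y))
  sk <- fit_spine_skeleton(im, roi)
  w <- measure_head_width(im, sk, roi)
  expect_lt(w, 0.8)   # the 1.0-um basal blob must not be reported
  expect_lt(abs(w - 0.6) / 0.6, 0.25)
})

test_that("shape ratio arithmetic, classification and compartment split", {
  r1 <- compute_shape_ratio(2.0, 0.5)
  expect_equal(r1$ratio, 4.0)
  expect_identical(r1$class_label, "filopodia")
  r2 <- compute_shape_ratio(1.0, 1.0)
  expect_equal(r2$ratio, 1.0)
  expect_identical(r2$class_label, "mushroom")
  # mature/immature split at 2
  expect_lt(compute_shape_ratio(1.9, 1.0)$ratio, 2)
  expect_gt(compute_shape_ratio(2.1, 1.0)$ratio, 2)
  expect_error(compute_shape_ratio(0, 1), "positive")
})

test_that("linear density is exact arithmetic", {
  expect_equal(compute_linear_density(10, 10), 1.0)
  expect_equal(compute_linear_density(0, 50), 0.0)
  expect_identical(compute_linear_density(27, 25), 1.08)
  expect_error(compute_linear_density(5, 0), "> 0")
})

test_that("region fluorescence applies the threshold window and background", {
  img <- fluorescence_image(matrix(c(rep(1000, 50), rep(200, 50)), 10, 10),
                            pixel_size = 1)
  region <- matrix(FALSE, 10, 10); region[, 1:5] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[, 6:10] <- TRUE
  v <- quantify_region_fluorescence(img, region, 640, 4095, list(bg))
  expect_equal(as.numeric(v), 800)

  # sub-window values are excluded from the region mean
  img2 <- fluorescence_image(matrix(c(500, 1000, 1000, 500), 2, 2), 1)
  v2 <- quantify_region_fluorescence(img2, matrix(TRUE, 2, 2), 640, 4095)
  expect_equal(as.numeric(v2), 1000)
  expect_error(
    quantify_region_fluorescence(img2, matrix(TRUE, 2, 2), 2000, 4095),
    "threshold window")

  means <- c("Y-CTR" = 2.0, "Y-BAY" = 1.5, "O-CTR" = 1.0, "O-BAY" = 1.8)
  norm <- normalize_to_reference(means, "Y-CTR")
  expect_equal(unname(norm["Y-CTR"]), 1.0)
  expect_equal(unname(norm["O-CTR"]), 0.5)
})

test_that("IF/TPA concordance is a Pearson correlation with guards", {
  x <- c(0.5, 1.0, 1.5, 2.0)
  expect_equal(if_tpa_concordance(x, x), 1.0)
  expect_equal(if_tpa_concordance(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_error(if_tpa_concordance(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(if_tpa_concordance(c(1, 2), c(1, 2)), ">= 3")
  set.seed(21)
  tpa <- runif(12, 0.5, 2)
  ifr <- tpa * (1 + rnorm(12, sd = 0.05))
  expect_gt(if_tpa_concordance(ifr, tpa), 0.9)
})

test_that("measured ratios are near scale-free across pixel sizes", {
  spec <- spine_shape_spec("mushroom", 1.3, 0.7)
  r1 <- {
    s <- single_spine_scene(spec, pixel_size = 0.07, seed = 4)
    measure_spines(s$image, s$truth$rois)$ratio
  }
  r2 <- {
    s <- single_spine_scene(spec, pixel_size = 0.035, seed = 4)
    measure_spines(s$image, s$truth$rois)$ratio
  }
  expect_lt(abs(r1 - r2) / r1, 0.05)
})
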