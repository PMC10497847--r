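# Synthetic generators: spine populations, rendered scenes, trajectories,
# protein tables.

test_that("spine sampling honors the class mixture and the ratio bins", {
  sp <- sample_spine_shapes(c(stubby = 1), n = 3, seed = 1)
  expect_length(sp, 3)
  expect_true(all(vapply(sp, function(s) s$ratio, 0) < 1))

  expect_identical(sample_spine_shapes(c(mushroom = 1), 0), list())
  expect_error(sample_spine_shapes(c(stubby = 0, thin = 0), 5), "sum")
  expect_error(sample_spine_shapes(c(blob = 1), 5), "class")

  # 50/50 mixture frequency inside the exact binomial 99% CI at n = 1000
  sp2 <- sample_spine_shapes(c(mushroom = 1, filopodia = 1), 1000, seed = 7)
  k <- sum(vapply(sp2, function(s) s$class_label, "") == "mushroom")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  # every sampled spine sits in its class bin
  for (s in sp2) expect_identical(classify_ratio(s$ratio), s$class_label)
  # seeded determinism
  sp3 <- sample_spine_shapes(c(mushroom = 1, filopodia = 1), 1000, seed = 7)
  expect_identical(sp2, sp3)
})

test_that("spec constructor enforces the geometric invariants", {
  expect_error(spine_shape_spec("mushroom", 3, 0.5), "bin")
  expect_error(spine_shape_spec("thin", 1.5, 0.6, neck_width = 0.9), "neck")
  expect_error(spine_shape_spec("thin", -1, 0.5), "positive")
  s <- spine_shape_spec("filopodia", 2.0, 0.45)
  expect_equal(s$ratio, 2 / 0.45)
})

test_that("noise-free rendering is a binary-scaled tube with exact truth", {
  sc <- tube_scene(rbind(c(1, 2), c(9, 2)), c(60L, 150L), psf_sigma = 0,
                   background = 0)
  img <- sc$image$intensity
  expect_setequal(unique(as.vector(img)), c(0, 500))
  expect_equal(max(img), 500)
  expect_equal(sc$truth$core_length, 8)

  spec <- spine_shape_spec("filopodia", 2.0, 0.5)
  one <- single_spine_scene(spec, seed = 1)
  expect_equal(one$truth$spines$ratio, 4.0)
})

test_that("rendered disk diameter matches the spec within one pixel", {
  # stubby-free check of the mask geometry: a head of diameter d renders
  # as a mask whose widest row is within 1 px of d / pixel_size
  px <- 0.07
  spec <- spine_shape_spec("mushroom", 1.2, 0.8)
  sc <- single_spine_scene(spec, pixel_size = px, psf_sigma = 0,
                           poisson_noise = FALSE, read_noise_sd = 0)
  roi <- sc$truth$rois[[1]]
  widths <- table(roi$pixels[, 1])
  expect_lt(abs(max(widths) - 0.8 / px), 1.5)
})

test_that("rendering is deterministic per seed and seeds differ", {
  spec <- spine_shape_spec("thin", 1.5, 0.6)
  a1 <- single_spine_scene(spec, seed = 1)$image$intensity
  a2 <- single_spine_scene(spec, seed = 1)$image$intensity
  b <- single_spine_scene(spec, seed = 2)$image$intensity
  expect_identical(a1, a2)
  expect_false(identical(a1, b))
})

test_that("rendering refuses spines extending outside the image", {
  spec <- spine_shape_spec("filopodia", 3.0, 0.5)
  path <- rbind(c(0.5, 1.0), c(6.5, 1.0))
  spec$attachment <- 3; spec$side <- -1  # points up, image too short
  expect_error(
    render_scene(scene_config(list(spec), image_shape = c(30L, 100L),
                              dendrite_path = path)),
    "spine 1")
})

test_that("ground-truth ratio is length/head_width to machine precision", {
  sp <- place_spines(sample_spine_shapes(spine_mixture_preset("young"),
                                         6, seed = 9), core_length = 22)
  cfg <- scene_config(sp, image_shape = c(140L, 360L), seed = 2)
  sc <- render_scene(cfg)
  expect_equal(sc$truth$spines$ratio,
               sc$truth$spines$length / sc$truth$spines$head_width,
               tolerance = 1e-15)
  expect_equal(nrow(sc$truth$spines), 6)
})

test_that("trajectory truth applies cap, climbing and exclusion rules", {
  objs <- nor_objects()
  # one 5 s bout at A
  g <- generate_trajectory(trajectory_config(
    objs, data.frame(object = "A", start_s = 50, duration_s = 5), seed = 1))
  expect_equal(unname(g$truth$per_object_s["A"]), 5, tolerance = 0.05)
  expect_equal(unname(g$truth$per_object_s["B"]), 0)
  expect_true(g$truth$excluded)  # 5 s < 20 s criterion

  # 12 s at A then 12 s at B -> capped at 20 (A 12, B 8)
  g2 <- generate_trajectory(trajectory_config(
    objs, data.frame(object = c("A", "B"), start_s = c(30, 60),
                     duration_s = c(12, 12)), seed = 2))
  expect_equal(unname(g2$truth$per_object_s["A"]), 12, tolerance = 0.05)
  expect_equal(unname(g2$truth$per_object_s["B"]), 8, tolerance = 0.05)
  expect_false(g2$truth$excluded)

  # climbing only: nothing counted, excluded flag raised
  g3 <- generate_trajectory(trajectory_config(
    objs, data.frame(object = "A", start_s = 20, duration_s = 30,
                     climbing = TRUE), seed = 3))
  expect_equal(g3$truth$total_s, 0)
  expect_true(g3$truth$excluded)

  expect_error(trajectory_config(
    objs, data.frame(object = "C", start_s = 1, duration_s = 5)),
    "unknown object")
  expect_error(trajectory_config(
    objs, data.frame(object = c("A", "A"), start_s = c(10, 12),
                     duration_s = c(5, 5))),
    "overlap")
})

test_that("protein table generator plants exact effects with seeded determinism", {
  cfg0 <- protein_table_config(n_proteins = 200, fraction_dap = 0, seed = 4)
  g0 <- generate_protein_table(cfg0)
  expect_equal(nrow(g0$truth), 0)

  cfg1 <- protein_table_config(n_proteins = 1000, fraction_dap = 0.1, seed = 4)
  g1 <- generate_protein_table(cfg1)
  expect_equal(nrow(g1$truth), 100)
  g1b <- generate_protein_table(cfg1)
  expect_identical(g1$table$intensities, g1b$table$intensities)

  expect_error(protein_table_config(groups = c(A = 1L, B = 5L)), ">= 2")
})

test_that("group-structured missingness lands inside the binomial 99% CI", {
  cfg <- protein_table_config(
    n_proteins = 1000, fraction_dap = 0,
    missing_rate = c("Y-CTR" = 0.5, "Y-BAY" = 0, "O-CTR" = 0, "O-BAY" = 0),
    seed = 6)
  g <- generate_protein_table(cfg)
  cols <- names(g$table$groups)[g$table$groups == "Y-CTR"]
  n_cells <- 1000 * length(cols)
  miss <- sum(is.na(g$table$intensities[, cols]))
  ci <- qbinom(c(0.005, 0.995), n_cells, 0.5)
  expect_gte(miss, ci[1]); expect_lte(miss, ci[2])
  other <- setdiff(colnames(g$table$intensities), cols)
  expect_equal(sum(is.na(g$table$intensities[, other])), 0)
})

test_that("planted fold equals the group mean concentration ratio as noise vanishes", {
  cfg <- protein_table_config(n_proteins = 300, fraction_dap = 0.2,
                              fold_range = c(1.5, 1.5), sample_cv = 1e-8,
                              missing_rate = 0, effect_group = "O-BAY",
                              seed = 8)
  g <- generate_protein_table(cfg)
  tpa <- compute_tpa(g$table)
  up <- g$truth$protein_id[g$truth$direction == "up"]
  ratios <- group_ratio_matrix(tpa, list(c("O-BAY", "O-CTR")), up)
  # ratio = fold / (total-intensity shift), identical for all planted-up
  # proteins; fold recovered after normalizing out the shared shift
  null_ids <- setdiff(rownames(tpa$concentrations), g$truth$protein_id)
  base <- group_ratio_matrix(tpa, list(c("O-BAY", "O-CTR")), null_ids)
  expect_equal(unname(ratios[, 1] / stats::median(base[, 1])),
               rep(1.5, length(up)), tolerance = 1e-6)
})
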