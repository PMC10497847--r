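# End-to-end synthetic study: four groups (Y-CTR, Y-BAY, O-CTR, O-BAY)
# through image morphometry, behavior scoring and TPA proteomics, with a
# reproducible report bundle.

#' Configuration of a synthetic four-group study
#'
#' Per-group defaults encode the study conditions: young controls carry a
#' young-like (immature-rich) spine mixture and aged controls an aged-like
#' one; treated young animals shift toward mature shapes with a halved
#' spine density; treated old animals keep density but gain filopodia-like
#' spines. Group densities default to 1.02, 0.54, 1.05 and 1.08 spines/um.
#'
#' @param seed global seed; per-stage seeds are derived deterministically
#'   from it (stage label hashed into the seed), so stages can be rerun
#'   independently.
#' @param groups group names.
#' @param spine_mixtures named list of class-weight vectors per group.
#' @param densities named numeric: planted linear spine density per group
#'   (spines/um of dendrite core).
#' @param spines_per_group spines rendered and measured per group.
#' @param comparisons list of group pairs for KS/stratified-KS and
#'   differential abundance.
#' @param n_animals animals per group for the behavioral stage.
#' @param latency_day0_s mean Day-0 latency; `latency_factors` multiply it
#'   at Day 14 per group (< 1 improves orientation).
#' @param novel_bias fraction of planned exploration on the novel object
#'   per group.
#' @param proteome_config a [protein_table_config()]; its seed is
#'   overridden by the derived stage seed.
#' @param stratify_threshold ratio threshold for compartment-stratified KS.
#' @param fc_threshold,alpha differential-abundance cutoffs.
#' @param image_pixel_size um/pixel of the rendered scenes.
#' @return `study_config` object.
#' @export
study_config <- function(seed = 1L,
                         groups = c("Y-CTR", "Y-BAY", "O-CTR", "O-BAY"),
                         spine_mixtures = NULL,
                         densities = c("Y-CTR" = 1.02, "Y-BAY" = 0.54,
                                       "O-CTR" = 1.05, "O-BAY" = 1.08),
                         spines_per_group = 60L,
                         comparisons = list(c("O-BAY", "O-CTR"),
                                            c("O-CTR", "Y-CTR"),
                                            c("O-BAY", "Y-CTR"),
                                            c("Y-BAY", "Y-CTR")),
                         n_animals = 9L,
                         latency_day0_s = 30,
                         latency_factors = c("Y-CTR" = 0.5, "Y-BAY" = 1.1,
                                             "O-CTR" = 1.2, "O-BAY" = 0.5),
                         novel_bias = c("Y-CTR" = 0.65, "Y-BAY" = 0.62,
                                        "O-CTR" = 0.52, "O-BAY" = 0.62),
                         proteome_config = NULL,
                         stratify_threshold = 2,
                         fc_threshold = 1.2, alpha = 0.05,
                         image_pixel_size = 0.07) {
  if (anyDuplicated(groups)) stop_invalid("study_config(): duplicate group names")
  for (cp in comparisons) {
    if (!all(cp %in% groups)) {
      stop_invalid("study_config(): comparison references undefined group '%s'",
                   setdiff(cp, groups)[1])
    }
  }
  if (is.null(spine_mixtures)) {
    young <- spine_mixture_preset("young")
    aged <- spine_mixture_preset("aged")
    spine_mixtures <- list(
      "Y-CTR" = young,
      # treated young: shorter/thicker (mature-shifted)
      "Y-BAY" = c(stubby = 0.20, mushroom = 0.35, thin = 0.25,
                  long_thin = 0.12, filopodia = 0.08),
      "O-CTR" = aged,
      # treated old: immature compartment more filopodia-like
      "O-BAY" = c(stubby = 0.24, mushroom = 0.38, thin = 0.12,
                  long_thin = 0.12, filopodia = 0.14)
    )
    spine_mixtures <- spine_mixtures[groups[groups %in% names(spine_mixtures)]]
  }
  structure(
    list(seed = as.integer(seed), groups = groups,
         spine_mixtures = spine_mixtures, densities = densities,
         spines_per_group = as.integer(spines_per_group),
         comparisons = comparisons, n_animals = as.integer(n_animals),
         latency_day0_s = latency_day0_s, latency_factors = latency_factors,
         novel_bias = novel_bias,
         proteome_config = proteome_config,
         stratify_threshold = stratify_threshold,
         fc_threshold = fc_threshold, alpha = alpha,
         image_pixel_size = image_pixel_size),
    class = "study_config"
  )
}

# Morphometry stage for one group: render scenes holding the planted
# density, measure every spine, return measurements + density per scene.
run_group_morphometry <- function(group, config, stage_seed) {
  mix <- config$spine_mixtures[[group]]
  density <- config$densities[[group]]
  n <- config$spines_per_group
  # at least three scenes per group so per-scene densities support a t-test
  per_scene <- max(2L, min(10L, ceiling(n / 3)))
  n_scenes <- ceiling(n / per_scene)
  meas <- list(); dens <- numeric(0); core_um <- numeric(0)
  made <- 0L
  for (sc in seq_len(n_scenes)) {
    n_here <- min(per_scene, n - made)
    made <- made + n_here
    # dendrite segment lengths vary between cells; jitter the core length
    # so per-scene densities scatter around the planted group density
    core_len <- (n_here / density) *
      with_seed(derive_seed(stage_seed, paste0("core", sc)),
                stats::rlnorm(1, 0, 0.08))
    specs <- sample_spine_shapes(mix, n_here,
                                 seed = derive_seed(stage_seed,
                                                    paste0("shapes", sc)))
    margin <- 2
    width_um <- core_len + 2 * margin + 1
    height_um <- 2 * (max(vapply(specs, function(s) s$length +
                                   s$head_width / 2, 0)) + 1.6)
    px <- config$image_pixel_size
    path <- rbind(c(margin / 2, height_um / 2),
                  c(margin / 2 + core_len + margin, height_um / 2))
    specs <- place_spines(specs, polyline_length(path), margin = margin / 2)
    cfg <- scene_config(specs, pixel_size = px,
                        image_shape = c(ceiling(height_um / px),
                                        ceiling(width_um / px)),
                        dendrite_path = path,
                        seed = derive_seed(stage_seed, paste0("scene", sc)))
    scn <- render_scene(cfg)
    m <- measure_spines(scn$image, scn$truth$rois)
    m$group <- group; m$scene <- sc
    m$true_ratio <- scn$truth$spines$ratio
    meas[[sc]] <- m
    dens <- c(dens, compute_linear_density(n_here, core_len))
    core_um <- c(core_um, core_len)
  }
  list(measurements = do.call(rbind, meas), scene_density = dens,
       dendrite_um = sum(core_um))
}

# Behavior stage for one group: Day-0 and Day-14 sessions per animal.
run_group_behavior <- function(group, config, stage_seed) {
  objs <- list(object_spec("A", c(10, 10), 2.5, role = "familiar"),
               object_spec("B", c(23, 23), 2.5, role = "novel"))
  rows <- list()
  for (animal in seq_len(config$n_animals)) {
    for (day in c(0L, 14L)) {
      sseed <- derive_seed(stage_seed, sprintf("a%d_d%d", animal, day))
      lat <- with_seed(derive_seed(sseed, "latency"), {
        base <- stats::rlnorm(1, log(config$latency_day0_s), 0.25)
        if (day == 14L) base * config$latency_factors[[group]] else base
      })
      bias <- config$novel_bias[[group]]
      total_plan <- 24
      plan <- data.frame(
        object = c("B", "A", "B", "A"),
        start_s = NA_real_,
        duration_s = c(total_plan * bias * 0.6, total_plan * (1 - bias) * 0.6,
                       total_plan * bias * 0.4, total_plan * (1 - bias) * 0.4),
        climbing = FALSE
      )
      gaps <- with_seed(derive_seed(sseed, "gaps"), stats::runif(3, 15, 40))
      starts <- lat + cumsum(c(0, plan$duration_s[-4] + gaps))
      plan$start_s <- starts
      cfg <- trajectory_config(objs, plan, session_s = 600,
                               sample_rate_hz = 25, seed = sseed)
      gen <- generate_trajectory(cfg)
      sc <- score_exploration(gen$trajectory, objs)
      pref <- if (!sc$excluded) object_preference(sc, "B") else
        c(novel_s = NA_real_, familiar_s = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        group = group, animal = animal, day = day,
        novel_s = pref[["novel_s"]], familiar_s = pref[["familiar_s"]],
        latency_s = sc$latency_s, total_s = sc$total_s,
        excluded = sc$excluded)
    }
  }
  do.call(rbind, rows)
}

#' Run the end-to-end synthetic study
#'
#' Generates the four-group data, runs morphometry, behavior scoring and
#' the proteomic pipeline, computes the group statistics (full and
#' compartment-stratified KS on shape ratios, density t-tests, latency
#' ratios, differential abundance, mean-ratio matrix, DAP overlaps) and
#' writes a versioned report bundle: CSV tables, an `overlaps.json`, a
#' `manifest.json` with per-file MD5 checksums and all seeds/parameters,
#' and a `run.log`. The data files and manifest are bit-reproducible per
#' seed; wall-clock timings go only to the log, which is excluded from
#' the manifest for that reason.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `report` (named file paths), `checksums` (MD5 of
#'   each data file), and the in-memory stage results.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("study seed=%d groups=%s\n", config$seed,
              paste(config$groups, collapse = ",")), file = log_path)
  log_stage <- function(stage, t0, params) {
    cat(sprintf("stage=%s params={%s} elapsed_s=%.2f\n", stage, params,
                as.numeric(proc.time()[3] - t0)),
        file = log_path, append = TRUE)
  }

  # --- morphometry ---
  t0 <- proc.time()[3]
  morph <- lapply(config$groups, function(g) {
    run_group_morphometry(g, config, derive_seed(config$seed,
                                                 paste0("morph:", g)))
  })
  names(morph) <- config$groups
  spines_df <- do.call(rbind, lapply(morph, `[[`, "measurements"))
  density_df <- do.call(rbind, lapply(config$groups, function(g) {
    data.frame(group = g, scene = seq_along(morph[[g]]$scene_density),
               density = morph[[g]]$scene_density,
               dendrite_um = morph[[g]]$dendrite_um)
  }))
  log_stage("morphometry", t0,
            sprintf("spines_per_group=%d", config$spines_per_group))

  # --- shape-ratio statistics ---
  t0 <- proc.time()[3]
  ks_rows <- list()
  for (cp in config$comparisons) {
    a <- spines_df$ratio[spines_df$group == cp[1] & !is.na(spines_df$ratio)]
    b <- spines_df$ratio[spines_df$group == cp[2] & !is.na(spines_df$ratio)]
    full <- ks_two_sample(a, b)
    add <- function(res, stratum) {
      data.frame(comparison = paste(cp, collapse = " vs "),
                 stratum = stratum, D = res$D, ks = res$ks_scaled,
                 p = res$p, n1 = res$n1, n2 = res$n2)
    }
    ks_rows[[length(ks_rows) + 1L]] <- add(full, "all")
    for (side in c("below", "above")) {
      res <- tryCatch(
        stratified_ks(a, b, threshold = config$stratify_threshold,
                      side = side),
        error = function(e) NULL)
      if (!is.null(res)) {
        ks_rows[[length(ks_rows) + 1L]] <- add(res, side)
      }
    }
  }
  ks_df <- do.call(rbind, ks_rows)
  dens_tests <- do.call(rbind, lapply(config$comparisons, function(cp) {
    a <- density_df$density[density_df$group == cp[1]]
    b <- density_df$density[density_df$group == cp[2]]
    tt <- tryCatch(t_test_two_sample(a, b), error = function(e) NULL)
    data.frame(comparison = paste(cp, collapse = " vs "),
               mean_a = mean(a), mean_b = mean(b),
               t = if (is.null(tt)) NA_real_ else tt$t,
               p = if (is.null(tt)) NA_real_ else tt$p)
  }))
  log_stage("spine_stats", t0,
            sprintf("threshold=%g", config$stratify_threshold))

  # --- behavior ---
  t0 <- proc.time()[3]
  behav <- do.call(rbind, lapply(config$groups, function(g) {
    run_group_behavior(g, config, derive_seed(config$seed,
                                              paste0("behavior:", g)))
  }))
  lat_rows <- do.call(rbind, lapply(config$groups, function(g) {
    sub <- behav[behav$group == g, ]
    d0 <- sub$latency_s[sub$day == 0]
    d14 <- sub$latency_s[sub$day == 14]
    ok <- is.finite(d0) & is.finite(d14) & d0 > 0
    data.frame(group = g,
               median_latency_ratio = stats::median(
                 mapply(latency_ratio, d14[ok], d0[ok])))
  }))
  behav_tests <- do.call(rbind, lapply(config$groups, function(g) {
    sub <- behav[behav$group == g & behav$day == 14 & !behav$excluded, ]
    tt <- tryCatch(t_test_two_sample(sub$novel_s, sub$familiar_s),
                   error = function(e) NULL)
    data.frame(group = g,
               novel_mean_s = mean(sub$novel_s),
               familiar_mean_s = mean(sub$familiar_s),
               p = if (is.null(tt)) NA_real_ else tt$p)
  }))
  log_stage("behavior", t0, sprintf("n_animals=%d", config$n_animals))

  # --- proteome ---
  t0 <- proc.time()[3]
  pcfg <- config$proteome_config %||%
    protein_table_config(effect_group = "O-BAY")
  pcfg$seed <- derive_seed(config$seed, "proteome")
  gen <- generate_protein_table(pcfg)
  tab <- filter_group_presence(filter_min_unique_peptides(gen$table))
  tpa <- compute_tpa(tab)
  daps <- lapply(config$comparisons, function(cp) {
    differential_abundance(tpa, cp, fc_threshold = config$fc_threshold,
                           alpha = config$alpha)
  })
  names(daps) <- vapply(config$comparisons,
                        function(cp) paste(cp, collapse = "_vs_"), "")
  dap_sets <- lapply(daps, function(d) d$protein_id[d$direction != "ns"])
  overlap <- if (length(dap_sets) >= 2) {
    overlap_sets(dap_sets[seq_len(min(3L, length(dap_sets)))])
  } else NULL
  top_ids <- unique(unlist(lapply(daps, function(d) {
    utils::head(d$protein_id[order(d$q)][d$direction[order(d$q)] != "ns"], 10)
  })))
  ratio_mat <- if (length(top_ids)) {
    group_ratio_matrix(tpa, config$comparisons, top_ids)
  } else NULL
  log_stage("proteome", t0, sprintf("n_proteins=%d", pcfg$n_proteins))

  # --- report bundle ---
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  report <- c(
    spines = wr(spines_df, "spine_measurements.csv"),
    density = wr(density_df, "spine_density.csv"),
    ks = wr(ks_df, "spine_ks.csv"),
    density_tests = wr(dens_tests, "density_tests.csv"),
    behavior = wr(behav, "behavior_scores.csv"),
    latency = wr(lat_rows, "latency_ratios.csv"),
    behavior_tests = wr(behav_tests, "behavior_tests.csv")
  )
  for (nm in names(daps)) {
    report[paste0("dap_", nm)] <- wr(as.data.frame(daps[[nm]]),
                                     paste0("dap_", nm, ".csv"))
  }
  if (!is.null(overlap)) {
    p <- file.path(out_dir, "dap_overlaps.json")
    jsonlite::write_json(as.list(overlap), p, auto_unbox = TRUE)
    report["overlaps"] <- p
  }
  if (!is.null(ratio_mat)) {
    report["ratio_matrix"] <- wr(data.frame(protein_id = rownames(ratio_mat),
                                            ratio_mat, check.names = FALSE),
                                 "ratio_matrix.csv")
  }
  checksums <- tools::md5sum(unname(report))
  manifest <- list(
    seed = config$seed,
    groups = as.list(stats::setNames(config$densities, config$groups)),
    spines_per_group = config$spines_per_group,
    n_animals = config$n_animals,
    files = as.list(stats::setNames(unname(checksums), basename(names(checksums))))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  report["manifest"] <- mp
  log_stage("report", t0, sprintf("files=%d", length(report)))

  list(report = report, checksums = checksums,
       spines = spines_df, density = density_df, ks = ks_df,
       behavior = behav, latency_ratios = lat_rows, daps = daps,
       overlap = overlap, ratio_matrix = ratio_mat)
}
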