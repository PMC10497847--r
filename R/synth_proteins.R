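# Synthetic MaxQuant-like protein intensity tables: log-normal raw
# intensities, planted fold-change effects in a designated group,
# group-structured missingness and unique-peptide counts, with the planted
# truth labels.

#' Configuration of a synthetic protein intensity table
#'
#' Defaults mirror the study design: four groups of five biological
#' replicates each.
#'
#' @param n_proteins number of proteins.
#' @param groups named integer vector: samples per group (each >= 2).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-protein baseline raw intensity (natural log).
#' @param mw_meanlog,mw_sdlog log-normal parameters of the molecular
#'   weight (kDa).
#' @param fraction_dap fraction of proteins with a planted group effect
#'   (exact count `round(fraction_dap * n_proteins)`).
#' @param fold_range planted fold-change range (uniform; lower bound must
#'   be >= 1.2, the differential-abundance cutoff).
#' @param frac_up fraction of planted effects that are up (rest are down).
#' @param effect_group group receiving the planted effects; default the
#'   first group.
#' @param missing_rate probability an intensity is missing; scalar or a
#'   named per-group vector.
#' @param sample_cv within-protein between-sample coefficient of variation
#'   (fraction, e.g. 0.2 for 20%).
#' @param single_peptide_frac fraction of proteins with a single unique
#'   peptide (the rest get 2 or more).
#' @param seed integer seed.
#' @return `protein_table_config` object.
#' @export
protein_table_config <- function(n_proteins = 2000L,
                                 groups = c("Y-CTR" = 5L, "Y-BAY" = 5L,
                                            "O-CTR" = 5L, "O-BAY" = 5L),
                                 baseline_log_mean = log(1e7),
                                 baseline_log_sd = 1.5,
                                 mw_meanlog = log(50), mw_sdlog = 0.5,
                                 fraction_dap = 0.1,
                                 fold_range = c(1.2, 2),
                                 frac_up = 0.5,
                                 effect_group = names(groups)[1],
                                 missing_rate = 0.05,
                                 sample_cv = 0.2,
                                 single_peptide_frac = 0.1,
                                 seed = 1L) {
  if (any(groups < 2L)) {
    stop_invalid("protein_table_config(): every group needs >= 2 samples")
  }
  if (fraction_dap < 0 || fraction_dap > 1) {
    stop_invalid("protein_table_config(): fraction_dap must be in [0, 1]")
  }
  if (fold_range[1] < 1) {
    stop_invalid("protein_table_config(): planted fold changes must be >= 1")
  }
  if (!effect_group %in% names(groups)) {
    stop_invalid("protein_table_config(): unknown effect group '%s'", effect_group)
  }
  if (is.null(names(missing_rate))) {
    missing_rate <- stats::setNames(rep(missing_rate[1], length(groups)),
                                    names(groups))
  }
  structure(
    list(n_proteins = as.integer(n_proteins), groups = groups,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         mw_meanlog = mw_meanlog, mw_sdlog = mw_sdlog,
         fraction_dap = fraction_dap, fold_range = fold_range,
         frac_up = frac_up, effect_group = effect_group,
         missing_rate = missing_rate, sample_cv = sample_cv,
         single_peptide_frac = single_peptide_frac, seed = as.integer(seed)),
    class = "protein_table_config"
  )
}

#' Generate a synthetic protein table with planted truth
#'
#' Raw intensities are log-normal around a per-protein baseline with a
#' between-sample noise matching `sample_cv`; planted proteins are scaled
#' by their fold change (up) or its inverse (down) in the effect group;
#' missing entries are `NA`; unique-peptide counts and molecular weights
#' are drawn per protein. Deterministic for a fixed seed.
#'
#' @param config a [protein_table_config()].
#' @return list with `table` (a [protein_table()]) and `truth`
#'   (data.frame `protein_id`, `fold`, `direction` of the planted
#'   effects; empty when `fraction_dap = 0`).
#' @export
generate_protein_table <- function(config) {
  stopifnot(inherits(config, "protein_table_config"))
  n <- config$n_proteins
  gnames <- names(config$groups)
  sample_names <- unlist(lapply(gnames, function(g) {
    paste0(g, "_", seq_len(config$groups[[g]]))
  }))
  groups <- stats::setNames(rep(gnames, times = config$groups), sample_names)
  n_s <- length(sample_names)
  sdlog_noise <- sqrt(log(1 + config$sample_cv^2))

  with_seed(config$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    mw <- stats::rlnorm(n, config$mw_meanlog, config$mw_sdlog)
    up1 <- stats::runif(n) < config$single_peptide_frac
    upep <- ifelse(up1, 1L, 2L + stats::rpois(n, 4))
    base_log <- stats::rnorm(n, config$baseline_log_mean,
                             config$baseline_log_sd)
    n_dap <- round(config$fraction_dap * n)
    dap_idx <- if (n_dap > 0) sample.int(n, n_dap) else integer(0)
    folds <- stats::runif(n_dap, config$fold_range[1], config$fold_range[2])
    dirs <- ifelse(stats::runif(n_dap) < config$frac_up, "up", "down")

    log_int <- matrix(stats::rnorm(n * n_s, 0, sdlog_noise), n, n_s) + base_log
    eff_cols <- which(groups == config$effect_group)
    if (n_dap > 0) {
      shift <- log(folds) * ifelse(dirs == "up", 1, -1)
      log_int[dap_idx, eff_cols] <- log_int[dap_idx, eff_cols] + shift
    }
    intens <- exp(log_int)
    colnames(intens) <- sample_names

    for (g in gnames) {
      rate <- config$missing_rate[[g]]
      if (rate > 0) {
        cols <- which(groups == g)
        drop <- matrix(stats::runif(n * length(cols)) < rate, n)
        intens[, cols][drop] <- NA_real_
      }
    }

    proteins <- data.frame(protein_id = ids, mw_kda = mw,
                           unique_peptides = upep,
                           stringsAsFactors = FALSE)
    truth <- data.frame(protein_id = ids[dap_idx],
                        fold = folds, direction = dirs,
                        stringsAsFactors = FALSE)
    list(table = protein_table(proteins, intens, groups), truth = truth)
  })
}
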