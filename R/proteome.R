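# Total Protein Approach quantification and differential abundance:
# unique-peptide and group-presence filters, TPA concentrations
# (intensity / (MW * total sample intensity)), fold-change + FDR calls,
# group mean-ratio matrices and DAP set overlaps.

#' Construct a protein intensity table
#'
#' @param proteins data.frame with columns `protein_id`, `mw_kda` (> 0)
#'   and `unique_peptides`.
#' @param intensities numeric matrix (proteins x samples) of raw
#'   intensities; missing values are `NA` (never zero-as-missing).
#' @param groups named character vector mapping sample (column) names to
#'   group names.
#' @return `protein_table` object.
#' @export
protein_table <- function(proteins, intensities, groups) {
  intensities <- as.matrix(intensities)
  if (nrow(proteins) != nrow(intensities)) {
    stop_invalid("protein_table(): proteins and intensity rows differ")
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- names(groups)
  }
  if (!setequal(colnames(intensities), names(groups))) {
    stop_invalid("protein_table(): every sample needs a group")
  }
  groups <- groups[colnames(intensities)]
  if (any(intensities < 0, na.rm = TRUE)) {
    stop_invalid("protein_table(): negative intensities")
  }
  if (any(proteins$mw_kda <= 0)) {
    stop_invalid("protein_table(): molecular weights must be positive")
  }
  rownames(intensities) <- proteins$protein_id
  structure(list(proteins = proteins, intensities = intensities,
                 groups = groups),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("protein table: %d proteins x %d samples (%d groups)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$groups))))
  invisible(x)
}

#' Filter proteins by minimum unique-peptide count
#'
#' @param table a [protein_table()].
#' @param k minimum unique peptides (default 2); proteins below are
#'   removed, order preserved.
#' @return filtered `protein_table`.
#' @export
filter_min_unique_peptides <- function(table, k = 2) {
  stopifnot(inherits(table, "protein_table"))
  if (k < 1) stop_invalid("filter_min_unique_peptides(): k must be >= 1")
  keep <- table$proteins$unique_peptides >= k
  protein_table(table$proteins[keep, , drop = FALSE],
                table$intensities[keep, , drop = FALSE], table$groups)
}

#' Filter proteins by within-group presence
#'
#' A protein is retained when its present-sample fraction reaches
#' `min_frac` in at least one group (`mode = "any"`, the default,
#' preserving group-specific proteins) or in every group
#' (`mode = "every"`). The comparison is `>=` on counts, so 3 of 5
#' samples meets a 60% requirement.
#'
#' @param table a [protein_table()].
#' @param min_frac required fraction in (0, 1].
#' @param mode `"any"` or `"every"`.
#' @return filtered `protein_table`.
#' @export
filter_group_presence <- function(table, min_frac = 0.6,
                                  mode = c("any", "every")) {
  stopifnot(inherits(table, "protein_table"))
  mode <- match.arg(mode)
  if (min_frac <= 0 || min_frac > 1) {
    stop_invalid("filter_group_presence(): min_frac must be in (0, 1]")
  }
  gset <- unique(table$groups)
  frac <- sapply(gset, function(g) {
    cols <- names(table$groups)[table$groups == g]
    rowMeans(!is.na(table$intensities[, cols, drop = FALSE]))
  })
  frac <- matrix(frac, nrow = nrow(table$intensities))
  hit <- frac >= min_frac - 1e-12
  keep <- if (mode == "any") rowSums(hit) > 0 else rowSums(hit) == length(gset)
  protein_table(table$proteins[keep, , drop = FALSE],
                table$intensities[keep, , drop = FALSE], table$groups)
}

#' Total Protein Approach concentrations
#'
#' Converts raw intensities to protein concentrations:
#' `conc(i, s) = intensity(i, s) / (MW_i * sum_j intensity(j, s))`,
#' i.e. mol per gram of total protein (MW in kDa gives mol/g up to the
#' kDa unit). Missing intensities stay missing, and by construction
#' `sum_i conc(i, s) * MW_i = 1` over the proteins present in each
#' sample.
#'
#' @param table a [protein_table()].
#' @return `tpa_matrix`: `concentrations` (proteins x samples), `mw_kda`,
#'   `groups`.
#' @export
compute_tpa <- function(table) {
  stopifnot(inherits(table, "protein_table"))
  if (nrow(table$intensities) == 0L) stop_invalid("compute_tpa(): empty table")
  totals <- colSums(table$intensities, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop_invalid("compute_tpa(): sample '%s' has no measured intensities",
                 colnames(table$intensities)[which(totals <= 0)[1]])
  }
  conc <- sweep(table$intensities, 2, totals, "/") / table$proteins$mw_kda
  structure(list(concentrations = conc, mw_kda = table$proteins$mw_kda,
                 groups = table$groups),
            class = "tpa_matrix")
}

#' @export
print.tpa_matrix <- function(x, ...) {
  cat(sprintf("TPA concentrations: %d proteins x %d samples\n",
              nrow(x$concentrations), ncol(x$concentrations)))
  invisible(x)
}

group_columns <- function(groups, g) names(groups)[groups == g]

#' Differential protein abundance between two groups
#'
#' Per protein (with at least `min_present` present samples in each
#' group): fold change as the ratio of group mean concentrations
#' (A over B), a two-sided pooled t-test on log concentrations (missing
#' values excluded, no imputation), Benjamini-Hochberg FDR across tested
#' proteins, and a direction call: `up` when fold >= `fc_threshold` and
#' q <= `alpha`, `down` when fold <= 1/`fc_threshold` and q <= `alpha`,
#' otherwise `ns`.
#'
#' @param tpa a [compute_tpa()] result.
#' @param comparison character pair `c(groupA, groupB)`.
#' @param fc_threshold fold-change cutoff (default 1.2).
#' @param alpha FDR level (default 0.05).
#' @param min_present minimum present samples per group per protein.
#' @return data.frame `dap_records`: `protein_id`, `fold`, `p`, `q`,
#'   `direction`.
#' @export
differential_abundance <- function(tpa, comparison, fc_threshold = 1.2,
                                   alpha = 0.05, min_present = 2L) {
  stopifnot(inherits(tpa, "tpa_matrix"))
  if (length(comparison) != 2L || !all(comparison %in% tpa$groups)) {
    stop_invalid("differential_abundance(): comparison groups not in the table")
  }
  ca <- group_columns(tpa$groups, comparison[1])
  cb <- group_columns(tpa$groups, comparison[2])
  A <- tpa$concentrations[, ca, drop = FALSE]
  B <- tpa$concentrations[, cb, drop = FALSE]
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  testable <- nA >= min_present & nB >= min_present
  ids <- rownames(tpa$concentrations)
  res <- data.frame(protein_id = ids[testable],
                    fold = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- which(testable)
  for (r in seq_along(idx)) {
    i <- idx[r]
    a <- A[i, !is.na(A[i, ])]
    b <- B[i, !is.na(B[i, ])]
    res$fold[r] <- mean(a) / mean(b)
    res$p[r] <- tryCatch(t_test_two_sample(log(a), log(b))$p,
                         error = function(e) 1)
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$direction <- "ns"
  res$direction[res$fold >= fc_threshold & res$q <= alpha] <- "up"
  res$direction[res$fold <= 1 / fc_threshold & res$q <= alpha] <- "down"
  attr(res, "comparison") <- comparison
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "alpha") <- alpha
  class(res) <- c("dap_records", "data.frame")
  res
}

#' Matrix of group mean-abundance ratios
#'
#' Entry (protein, comparison) is the mean concentration in the first
#' group of the comparison divided by the mean in the second, the form
#' used for abundance-change heatmaps across comparisons.
#'
#' @param tpa a [compute_tpa()] result.
#' @param comparisons list of `c(groupA, groupB)` pairs.
#' @param protein_subset protein ids (rows) to report; default all.
#' @return numeric matrix proteins x comparisons (named
#'   `"A_vs_B"`).
#' @export
group_ratio_matrix <- function(tpa, comparisons,
                               protein_subset = rownames(tpa$concentrations)) {
  stopifnot(inherits(tpa, "tpa_matrix"))
  missing_ids <- setdiff(protein_subset, rownames(tpa$concentrations))
  if (length(missing_ids)) {
    stop_invalid("group_ratio_matrix(): unknown protein '%s'", missing_ids[1])
  }
  out <- matrix(NA_real_, length(protein_subset), length(comparisons),
                dimnames = list(protein_subset,
                                vapply(comparisons,
                                       function(cp) paste(cp, collapse = "_vs_"),
                                       "")))
  for (k in seq_along(comparisons)) {
    cp <- comparisons[[k]]
    A <- tpa$concentrations[protein_subset,
                            group_columns(tpa$groups, cp[1]), drop = FALSE]
    B <- tpa$concentrations[protein_subset,
                            group_columns(tpa$groups, cp[2]), drop = FALSE]
    mb <- rowMeans(B, na.rm = TRUE)
    if (any(!is.finite(mb)) || any(mb == 0, na.rm = TRUE)) {
      stop_invalid("group_ratio_matrix(): zero or undefined denominator mean")
    }
    out[, k] <- rowMeans(A, na.rm = TRUE) / mb
  }
  out
}

#' Exclusive overlap counts between DAP sets
#'
#' Partitions the union of two or more named protein-id sets into the
#' exclusive Venn regions and counts each region; region names join the
#' member set names with `&`.
#'
#' @param dap_lists named list (length >= 2) of protein-id vectors.
#' @return named integer vector of exclusive region counts (regions sum
#'   to the union size).
#' @examples
#' overlap_sets(list(A = c("p1", "p2"), B = c("p2", "p3")))
#' @export
overlap_sets <- function(dap_lists) {
  if (length(dap_lists) < 2L || is.null(names(dap_lists))) {
    stop_invalid("overlap_sets(): need >= 2 named lists")
  }
  ids <- unique(unlist(dap_lists))
  member <- vapply(dap_lists, function(s) ids %in% s,
                   logical(length(ids)))
  member <- matrix(member, nrow = length(ids),
                   dimnames = list(ids, names(dap_lists)))
  nm <- names(dap_lists)
  regions <- character(0)
  counts <- integer(0)
  for (mask in seq_len(2^length(nm) - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(nm) - 1L)))
    key <- paste(nm[inset], collapse = "&")
    cnt <- sum(apply(member, 1, function(row) all(row == inset)))
    regions <- c(regions, key)
    counts <- c(counts, cnt)
  }
  stats::setNames(counts, regions)
}
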