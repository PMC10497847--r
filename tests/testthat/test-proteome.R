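# TPA quantification, filters, differential abundance, ratios, overlaps.

tiny_table <- function(intens, mw = NULL, upep = NULL,
                       groups = c(s1 = "G1", s2 = "G1", s3 = "G2", s4 = "G2")) {
  n <- nrow(intens)
  colnames(intens) <- names(groups)
  protein_table(
    data.frame(protein_id = paste0("p", seq_len(n)),
               mw_kda = mw %||% rep(50, n),
               unique_peptides = upep %||% rep(3L, n)),
    intens, groups)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("unique-peptide filter keeps counts >= k in order", {
  tab <- tiny_table(matrix(1, 3, 4), upep = c(1L, 2L, 5L))
  f <- filter_min_unique_peptides(tab, 2)
  expect_identical(f$proteins$protein_id, c("p2", "p3"))
  expect_identical(filter_min_unique_peptides(tab, 1)$proteins$protein_id,
                   tab$proteins$protein_id)

  # synthetic table with exactly 10% single-peptide proteins
  cfg <- protein_table_config(n_proteins = 1000, single_peptide_frac = 0.1,
                              fraction_dap = 0, seed = 12)
  g <- generate_protein_table(cfg)
  n1 <- sum(g$table$proteins$unique_peptides == 1)
  expect_equal(nrow(filter_min_unique_peptides(g$table)$intensities),
               1000 - n1)
})

test_that("group-presence filter implements >= 60% in at least one group", {
  groups <- stats::setNames(rep(c("G1", "G2"), each = 5),
                            paste0("s", 1:10))
  m <- matrix(1, 3, 10)
  m[1, c(4, 5, 6:10)] <- NA     # 3/5 in G1, 0/5 in G2 -> retained
  m[2, c(3, 4, 5, 8, 9, 10)] <- NA  # 2/5 in both -> removed
  tab <- tiny_table(m, groups = groups)
  f <- filter_group_presence(tab, 0.6)
  expect_identical(f$proteins$protein_id, c("p1", "p3"))
  # "every" mode removes the group-specific protein too
  fe <- filter_group_presence(tab, 0.6, mode = "every")
  expect_identical(fe$proteins$protein_id, "p3")
})

test_that("presence filter matches a brute-force recount on planted missingness", {
  cfg <- protein_table_config(n_proteins = 400, fraction_dap = 0,
                              missing_rate = 0.35, seed = 31)
  g <- generate_protein_table(cfg)
  f <- filter_group_presence(g$table, 0.6)
  # independent recount, protein by protein
  keep <- logical(400)
  for (i in 1:400) {
    ok <- FALSE
    for (grp in unique(g$table$groups)) {
      cols <- names(g$table$groups)[g$table$groups == grp]
      pres <- sum(!is.na(g$table$intensities[i, cols]))
      if (pres / length(cols) >= 0.6) ok <- TRUE
    }
    keep[i] <- ok
  }
  expect_equal(nrow(f$intensities), sum(keep))
  expect_identical(f$proteins$protein_id, g$table$proteins$protein_id[keep])
})

test_that("peptide and presence filters commute", {
  cfg <- protein_table_config(n_proteins = 300, fraction_dap = 0,
                              missing_rate = 0.3, single_peptide_frac = 0.2,
                              seed = 9)
  g <- generate_protein_table(cfg)
  ab <- filter_group_presence(filter_min_unique_peptides(g$table))
  ba <- filter_min_unique_peptides(filter_group_presence(g$table))
  expect_identical(ab$proteins, ba$proteins)
  expect_identical(ab$intensities, ba$intensities)
})

test_that("TPA normalization conserves total protein mass", {
  # single protein: concentration forced to 1/MW
  tab1 <- tiny_table(matrix(7, 1, 4), mw = 50)
  tpa1 <- compute_tpa(tab1)
  expect_equal(unname(tpa1$concentrations[1, ]), rep(1 / 50, 4))

  # equal intensities, MW 25 vs 50 -> concentration ratio 2:1
  tab2 <- tiny_table(matrix(3, 2, 4), mw = c(25, 50))
  tpa2 <- compute_tpa(tab2)
  expect_equal(unname(tpa2$concentrations[1, ] / tpa2$concentrations[2, ]),
               rep(2, 4))

  # conservation identity on random tables with missingness
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(rlnorm(200, 10, 1.5), 50, 4)
    m[sample(200, 20)] <- NA
    tab <- tiny_table(m, mw = rlnorm(50, log(50), 0.4))
    tpa <- compute_tpa(tab)
    mass <- colSums(tpa$concentrations * tpa$mw_kda, na.rm = TRUE)
    expect_equal(unname(mass), rep(1, 4), tolerance = 1e-12)
  }

  # all-absent sample errors with its name
  m <- matrix(1, 2, 4); m[, 2] <- NA
  expect_error(compute_tpa(tiny_table(m)), "s2")
})

test_that("differential abundance recovers strong planted effects and partitions calls", {
  cfg <- protein_table_config(n_proteins = 600, fraction_dap = 0.1,
                              fold_range = c(2, 2), sample_cv = 0.2,
                              missing_rate = 0, effect_group = "O-BAY",
                              seed = 17)
  g <- generate_protein_table(cfg)
  tpa <- compute_tpa(g$table)
  da <- differential_abundance(tpa, c("O-BAY", "O-CTR"))
  expect_setequal(unique(da$direction), c("up", "down", "ns"))
  called <- da$protein_id[da$direction != "ns"]
  expect_gt(mean(g$truth$protein_id %in% called), 0.6)
  # direction respects the fold/q invariant
  up <- da[da$direction == "up", ]
  expect_true(all(up$fold >= 1.2 & up$q <= 0.05))
  dn <- da[da$direction == "down", ]
  expect_true(all(dn$fold <= 1 / 1.2 & dn$q <= 0.05))
  expect_error(differential_abundance(tpa, c("O-BAY", "nope")), "groups")
})

test_that("proteins with identical group values are called ns", {
  m <- matrix(rep(c(1, 2, 4, 8), each = 6), 4, 6, byrow = TRUE)
  groups <- stats::setNames(rep(c("G1", "G2"), each = 3), paste0("s", 1:6))
  tab <- tiny_table(m * matrix(exp(rnorm(24, 0, 1e-6)), 4), groups = groups)
  tpa <- compute_tpa(tab)
  da <- differential_abundance(tpa, c("G1", "G2"), min_present = 3)
  expect_true(all(da$direction == "ns"))
})

test_that("group ratio matrix returns planted mean ratios", {
  m <- matrix(10, 3, 4)
  m[, 1:2] <- m[, 1:2] * 1.3   # group G1 scaled x1.3 uniformly
  tab <- tiny_table(m)
  tpa <- compute_tpa(tab)
  # uniform scaling cancels under TPA (total scales too) -> ratios 1
  r <- group_ratio_matrix(tpa, list(c("G1", "G2")))
  expect_equal(unname(r[, 1]), rep(1, 3), tolerance = 1e-12)

  # identical groups -> all ratios exactly 1
  tab2 <- tiny_table(matrix(c(5, 7, 9), 3, 4))
  r2 <- group_ratio_matrix(compute_tpa(tab2), list(c("G1", "G2")))
  expect_equal(unname(r2[, 1]), rep(1, 3))
  expect_error(group_ratio_matrix(compute_tpa(tab2), list(c("G1", "G2")),
                                  "missing_protein"), "unknown")
})

test_that("overlap counts partition the union into exclusive regions", {
  ov <- overlap_sets(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(unname(ov["A"]), 1)
  expect_equal(unname(ov["B"]), 1)
  expect_equal(unname(ov["A&B"]), 1)
  expect_equal(sum(ov), 3)

  ov2 <- overlap_sets(list(A = c("x", "y"), B = c("u", "v")))
  expect_equal(unname(ov2["A&B"]), 0)

  # three planted sets against brute-force set algebra
  A <- paste0("p", 1:40); B <- paste0("p", 25:60); C <- paste0("p", c(1:10, 50:70))
  ov3 <- overlap_sets(list(A = A, B = B, C = C))
  expect_equal(unname(ov3["A"]), length(setdiff(setdiff(A, B), C)))
  expect_equal(unname(ov3["A&B"]), length(setdiff(intersect(A, B), C)))
  expect_equal(unname(ov3["A&B&C"]), length(intersect(intersect(A, B), C)))
  expect_equal(unname(ov3["B&C"]), length(setdiff(intersect(B, C), A)))
  expect_equal(sum(ov3), length(union(union(A, B), C)))
})
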