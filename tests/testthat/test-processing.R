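test_that("feature QC removes decoys, contaminants and low-quality PSMs", {
  vals <- matrix(1:20 + 0.0, 10, 2, dimnames = list(paste0("f", 1:10), c("c1", "c2")))
  ds <- make_raw_dataset(vals,
    protein = rep("P1", 10),
    decoy = c(TRUE, rep(FALSE, 9)),
    contaminant = rep(FALSE, 10),
    sample_to_carrier = c(NA, 0.04, rep(0.2, 8)),
    purity = rep(0.9, 10),
    identification_fdr = rep(0.001, 10)
  )
  out <- filter_features(ds, feature_qc_rules(drop_decoys = TRUE))
  expect_equal(n_features(out), 9L)

  # sample-to-carrier 0.04 under the 5% threshold is removed
  out2 <- filter_features(ds, feature_qc_rules(
    drop_decoys = TRUE, min_sample_to_carrier_ratio = 0.05
  ))
  expect_false("f2" %in% out2$features$feature_id)
  expect_equal(n_features(out2), 8L)

  # inactive rules leave the data untouched
  out3 <- filter_features(ds, feature_qc_rules())
  expect_equal(n_features(out3), 10L)

  # an active rule without its column is a configuration error
  ds_nocol <- make_raw_dataset(vals)
  expect_error(
    filter_features(ds_nocol, feature_qc_rules(drop_decoys = TRUE)),
    "decoy"
  )
})

test_that("feature QC is idempotent", {
  vals <- matrix(1:10 + 0.0, 5, 2, dimnames = list(paste0("f", 1:5), c("c1", "c2")))
  ds <- make_raw_dataset(vals, purity = c(0.5, 0.7, 0.9, 0.55, 0.99))
  rules <- feature_qc_rules(min_spectral_purity = 0.6)
  once <- filter_features(ds, rules)
  twice <- filter_features(once, rules)
  expect_identical(twice$intensities, once$intensities)
})

test_that("median CV within proteins matches hand computation", {
  # pep2's relative intensity in c1 is 6/2 = 3, pep1's is 1 -> CV of (1, 3)
  # is sd/mean = sqrt(2)/2
  vals <- mat(
    c(
      2, 2, 2, 2,
      6, 2 / 3, 2 / 3, 2 / 3
    ),
    c("pep1", "pep2"), paste0("c", 1:4)
  )
  ds <- make_raw_dataset(vals, protein = c("P1", "P1"))
  cv <- compute_cell_median_cv(ds, min_peptides_per_protein = 2)
  expect_equal(cv$median_cv[1], sqrt(2) / 2, tolerance = 1e-12)

  # identical relative intensities give CV exactly 0
  vals_eq <- mat(
    c(
      2, 4,
      3, 6
    ),
    c("pep1", "pep2"), c("c1", "c2")
  )
  ds_eq <- make_raw_dataset(vals_eq, protein = c("P1", "P1"))
  cv_eq <- compute_cell_median_cv(ds_eq, min_peptides_per_protein = 2)
  expect_equal(cv_eq$median_cv, c(0, 0), tolerance = 1e-12)

  # no protein reaches the peptide minimum -> missing CV
  cv_na <- compute_cell_median_cv(ds, min_peptides_per_protein = 3)
  expect_true(all(is.na(cv_na$median_cv)))

  # CV is defined on raw intensities only
  expect_error(
    compute_cell_median_cv(log_transform(ds)),
    "log"
  )
})

test_that("cell QC applies count, median-log window and CV rules", {
  set.seed(42)
  n_pep <- 30
  good <- 2^runif(n_pep, 6.5, 7.5) # median log2 inside (6, 8)
  dim_names <- list(paste0("p", 1:n_pep), c("ok", "sparse", "dim"))
  vals <- cbind(good, c(good[1:5], rep(NA, n_pep - 5)), 2^runif(n_pep, 2, 4))
  dimnames(vals) <- dim_names
  ds <- make_raw_dataset(vals, protein = rep("P1", n_pep))
  out <- filter_cells(ds, cell_qc_rules(min_peptides_per_cell = 10))
  expect_equal(out$cells$cell_id, c("ok", "dim"))
  out2 <- filter_cells(ds, cell_qc_rules(
    min_peptides_per_cell = 10,
    median_log_intensity_range = c(6, 8)
  ))
  expect_equal(out2$cells$cell_id, "ok")
  # empty rules are the identity
  out3 <- filter_cells(ds, cell_qc_rules())
  expect_identical(out3$intensities, ds$intensities)
})

test_that("aggregation to peptides medians children and resolves proteins", {
  vals <- mat(
    c(
      2, 1,
      4, 2,
      NA, 10,
      7, NA
    ),
    paste0("psm", 1:4), c("c1", "c2")
  )
  ds <- make_raw_dataset(vals,
    peptide = c("AAA", "AAA", "AAA", "BBB"),
    protein = c("P1", "P1", "P1", "P2")
  )
  out <- aggregate_to_peptides(ds)
  expect_equal(out$level, "peptide")
  expect_equal(unname(out$intensities["AAA", "c1"]), 3) # median(2, 4)
  expect_equal(unname(out$intensities["AAA", "c2"]), 2) # median(1, 2, 10)
  expect_equal(unname(out$intensities["BBB", "c1"]), 7) # single child
  expect_true(is.na(out$intensities["BBB", "c2"]))
  # a peptide is observed in a cell iff at least one child is observed
  expect_equal(
    !is.na(out$intensities["AAA", ]),
    c(c1 = TRUE, c2 = TRUE)
  )
})

test_that("peptides mapping to several proteins error, drop or keep-first", {
  vals <- mat(c(1, 2, 3, 4), c("psm1", "psm2"), c("c1", "c2"))
  ds <- make_raw_dataset(vals,
    peptide = c("AAA", "AAA"), protein = c("P1", "P2")
  )
  expect_error(aggregate_to_peptides(ds), "AAA")
  dropped <- aggregate_to_peptides(ds, ambiguous = "drop")
  expect_equal(n_features(dropped), 0L)
  kept <- aggregate_to_peptides(ds, ambiguous = "keep_first")
  expect_equal(kept$features$protein, "P1")
  expect_equal(unname(kept$intensities["AAA", "c1"]), 2) # median(1, 3)
})

test_that("log transform is exact and invertible", {
  vals <- mat(c(8, NA, 1, 4), c("p1", "p2"), c("c1", "c2"))
  ds <- make_raw_dataset(vals)
  out <- log_transform(ds, base = 2)
  expect_equal(unname(out$intensities["p1", "c1"]), 3)
  expect_equal(unname(out$intensities["p2", "c1"]), 0)
  expect_true(out$log_transformed)
  expect_error(log_transform(out), "already")

  back <- 2^out$intensities
  expect_equal(back, ds$intensities, tolerance = 1e-12)

  ds_neg <- make_raw_dataset(mat(c(-1, 2), c("p1", "p2"), "c1"))
  expect_error(log_transform(ds_neg), "p1")
})

test_that("the pipeline applies feature QC, cell QC, aggregation, log in order", {
  vals <- mat(
    c(
      2, 4, 8,
      4, 8, NA,
      1, NA, NA
    ),
    paste0("psm", 1:3), c("c1", "c2", "c3")
  )
  ds <- make_raw_dataset(vals,
    peptide = c("AAA", "AAA", "BBB"),
    protein = c("P1", "P1", "P2"),
    decoy = c(FALSE, FALSE, FALSE)
  )
  out <- process_dataset(
    ds,
    feature_rules = feature_qc_rules(drop_decoys = TRUE),
    cell_rules = cell_qc_rules(min_peptides_per_cell = 2),
    aggregate_key = "peptide", log_base = 2
  )
  expect_equal(
    out$history$step,
    c("filter_features", "filter_cells", "aggregate_to_peptides", "log_transform")
  )
  # cell c3 lost (1 observed PSM); AAA in c1 = log2(median(2, 4)) = log2(3)
  expect_equal(out$cells$cell_id, c("c1", "c2"))
  expect_equal(unname(out$intensities["AAA", "c1"]), log2(3))
})
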