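cells6 <- tibble::tibble(
  cell_id = paste0("c", 1:6),
  group = c("A", "A", "B", "B", "C", "C"),
  dose = c(1, 2, 3, 1, 2, 3)
)

test_that("sum-contrast encoding: a-1 columns, last level -1, centered numerics", {
  design <- build_design(cells6, model_spec(group = "biological"))
  expect_equal(ncol(design$X), 3L) # intercept + 2
  expect_equal(unname(design$X[1, ]), c(1, 1, 0)) # level A
  expect_equal(unname(design$X[3, ]), c(1, 0, 1)) # level B
  expect_equal(unname(design$X[5, ]), c(1, -1, -1)) # last level C
  expect_equal(design$var_index$group, 2:3)

  d2 <- build_design(
    tibble::tibble(cell_id = paste0("c", 1:3), x = c(1, 2, 3)),
    model_spec(x = "technical")
  )
  expect_equal(unname(d2$X[, "x"]), c(-1, 0, 1))
  expect_equal(mean(d2$X[, "x"]), 0)

  expect_error(
    build_design(
      tibble::tibble(cell_id = "c1", g = "A"),
      model_spec(g = "biological")
    ),
    "single level"
  )
})

test_that("per-peptide subsetting drops constant parameters, keeps the intercept", {
  design <- build_design(cells6, model_spec(group = "biological"))
  # observed only in group A: both contrast columns constant -> intercept only
  expect_equal(subset_model(design, 1:2), 1L)
  # all cells observed: full design retained
  expect_equal(subset_model(design, 1:6), 1:3)
  # a single observed cell keeps only the intercept
  expect_equal(subset_model(design, 3L), 1L)
  # A and B observed: the two indicators sum to the intercept, so the
  # jointly collinear trailing column is pruned and only A-vs-B remains
  expect_equal(subset_model(design, 1:4), c(1L, 2L))
})

test_that("ridge closed form: intercept-only shrinkage and null data", {
  cells4 <- tibble::tibble(
    cell_id = paste0("c", 1:4),
    run = c("r1", "r1", "r2", "r2")
  )
  # peptide observed twice within one run -> intercept-only model;
  # with lambda = 1, beta0 = sum(y) / (n + lambda) = 2 / 3
  vals <- mat(c(1, 1, NA, NA), "pep1", paste0("c", 1:4))
  ds <- make_peptide_dataset(vals, cells4)
  fit <- fit_model(ds, model_spec(run = "technical", lambda = 1))
  expect_equal(unname(fit$fits$coefficients[[1]]), 2 / 3, tolerance = 1e-12)

  # all-zero data give zero coefficients and zero SSE
  vals0 <- mat(rep(0, 4), "pep1", paste0("c", 1:4))
  ds0 <- make_peptide_dataset(vals0, cells4)
  fit0 <- fit_model(ds0, model_spec(run = "technical", lambda = 1e-3))
  expect_equal(unname(fit0$fits$coefficients[[1]]), c(0, 0))
  expect_equal(fit0$fits$sse[[1]], 0)
})

test_that("at lambda = 0 the fit matches a least-squares oracle", {
  set.seed(7)
  n <- 12
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:n),
    g = rep(c("A", "B"), each = n / 2),
    x = rnorm(n)
  )
  y <- rnorm(n)
  ds <- make_peptide_dataset(
    matrix(y, 1, n, dimnames = list("pep1", cells$cell_id)), cells
  )
  fit <- fit_model(ds, model_spec(g = "biological", x = "technical", lambda = 0))
  X <- fit$design$X
  oracle <- lm.fit(X, y)
  expect_equal(unname(fit$fits$coefficients[[1]]),
    unname(oracle$coefficients),
    tolerance = 1e-10
  )
  expect_equal(fit$fits$sse[[1]], sum(oracle$residuals^2), tolerance = 1e-10)
  expect_equal(fit$fits$df[[1]], n - 3L)
})

test_that("n/p filtering skips inestimable peptides with the strict bound", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:8),
    run = rep(c("r1", "r2"), each = 4)
  )
  vals <- mat(
    c(
      1, 2, 3, 1, 2, 3, 1, 2, # complete: n/p = 8/2 = 4
      1, 2, NA, NA, NA, NA, NA, NA, # one run: n/p = 2/1 = 2
      1, NA, NA, NA, 2, NA, NA, NA, # both runs, n = p = 2 -> skipped
      NA, NA, NA, NA, NA, NA, NA, 4 # single obs: n/p = 1 -> skipped
    ),
    paste0("pep", 1:4), cells$cell_id
  )
  ds <- make_peptide_dataset(vals, cells)
  fit <- fit_model(ds, model_spec(run = "technical"))
  expect_setequal(fit$fits$feature_id, c("pep1", "pep2"))
  expect_setequal(fit$skipped$feature_id, c("pep3", "pep4"))
  expect_equal(fit$fits$np[fit$fits$feature_id == "pep1"], 4)
  # run-restricted peptide retains only the intercept
  expect_equal(fit$fits$params[[which(fit$fits$feature_id == "pep2")]], 1L)
  # a stricter threshold removes the n/p = 2 peptide too
  fit3 <- fit_model(ds, model_spec(run = "technical"), np_threshold = 3)
  expect_setequal(fit3$fits$feature_id, "pep1")
})

test_that("coefficient norm is monotone non-increasing in lambda", {
  set.seed(11)
  n <- 10
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:n), g = rep(c("A", "B"), each = n / 2)
  )
  y <- rnorm(n, sd = 2)
  ds <- make_peptide_dataset(
    matrix(y, 1, n, dimnames = list("pep1", cells$cell_id)), cells
  )
  norms <- vapply(c(0, 1e-3, 0.1, 1, 10), function(l) {
    f <- fit_model(ds, model_spec(g = "biological", lambda = l))
    sqrt(sum(f$fits$coefficients[[1]]^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("permuting cell order leaves coefficients unchanged", {
  set.seed(3)
  sim <- simulate_scp(
    n_cells = 30, n_peptides = 10, n_proteins = 5, n_runs = 2,
    n_labels = 2, seed = 5
  )
  ds <- sim$dataset
  perm <- sample(n_cells(ds))
  ds_perm <- ds
  ds_perm$intensities <- ds$intensities[, perm]
  ds_perm$cells <- ds$cells[perm, ]
  spec <- model_spec(
    run = "technical", label = "technical", cell_type = "biological"
  )
  f1 <- fit_model(ds, spec)
  f2 <- fit_model(ds_perm, spec)
  common <- intersect(f1$fits$feature_id, f2$fits$feature_id)
  expect_true(length(common) > 0)
  for (id in common) {
    expect_equal(
      f1$fits$coefficients[[which(f1$fits$feature_id == id)]],
      f2$fits$coefficients[[which(f2$fits$feature_id == id)]],
      tolerance = 1e-10
    )
  }
})

test_that("effects plus intercept plus residuals reconstruct the data", {
  sim <- simulate_scp(
    n_cells = 40, n_peptides = 20, n_proteins = 8, seed = 2
  )
  ds <- sim$dataset
  fit <- fit_model(ds, model_spec(
    size_factor = "normalization", run = "technical",
    label = "technical", cell_type = "biological"
  ))
  recon <- effect_matrix(fit, "intercept") + effect_matrix(fit, "residuals")
  for (v in c("size_factor", "run", "label", "cell_type")) {
    recon <- recon + effect_matrix(fit, v)
  }
  Y <- ds$intensities[fit$fits$feature_id, , drop = FALSE]
  expect_equal(recon[!is.na(recon)], Y[!is.na(recon)], tolerance = 1e-9)
  expect_identical(is.na(recon), is.na(Y))
  expect_error(effect_matrix(fit, "nope"), "Unknown")
})

test_that("balanced binary design at small lambda recovers group-mean deviations", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:6), g = rep(c("A", "B"), each = 3)
  )
  y <- c(5, 6, 7, 1, 2, 3) # means 6 and 2
  ds <- make_peptide_dataset(
    matrix(y, 1, 6, dimnames = list("pep1", cells$cell_id)), cells
  )
  fit <- fit_model(ds, model_spec(g = "biological", lambda = 0))
  eff <- effect_matrix(fit, "g")
  expect_equal(unname(eff[1, ]), c(2, 2, 2, -2, -2, -2), tolerance = 1e-10)
  expect_equal(
    unname(effect_matrix(fit, "intercept")[1, ]), rep(4, 6),
    tolerance = 1e-10
  )
})

test_that("batch-corrected reconstruction keeps what it is told to keep", {
  sim <- simulate_scp(n_cells = 40, n_peptides = 25, seed = 9)
  ds <- sim$dataset
  fit <- fit_model(ds, model_spec(
    run = "technical", label = "technical", cell_type = "biological"
  ))
  all_vars <- c("run", "label", "cell_type")
  full <- batch_corrected(fit, keep = all_vars)
  Y <- ds$intensities[fit$fits$feature_id, , drop = FALSE]
  expect_equal(full[!is.na(full)], Y[!is.na(full)], tolerance = 1e-9)
  base_only <- batch_corrected(fit, keep = character())
  expect_equal(
    base_only,
    effect_matrix(fit, "intercept") + effect_matrix(fit, "residuals"),
    tolerance = 1e-12
  )
  expect_error(batch_corrected(fit, keep = "typo"), "typo")
})
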