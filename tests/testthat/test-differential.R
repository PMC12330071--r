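cells_ab <- tibble::tibble(
  cell_id = paste0("c", 1:12), g = rep(c("A", "B"), each = 6)
)

test_that("contrast rows follow the sum-contrast encoding arithmetic", {
  d2 <- build_design(cells_ab, model_spec(g = "biological"))
  L2 <- build_contrast(d2, "g", "A", "B")
  expect_equal(unname(L2[1, ]), c(0, 2)) # (+1) - (-1)

  cells3 <- tibble::tibble(
    cell_id = paste0("c", 1:6), g = c("A", "A", "B", "B", "C", "C")
  )
  d3 <- build_design(cells3, model_spec(g = "biological"))
  LAC <- build_contrast(d3, "g", "A", "C")
  expect_equal(unname(LAC[1, ]), c(0, 2, 1)) # (1,0) - (-1,-1)
  # self-contrast is the zero row
  LAA <- build_contrast(d3, "g", "A", "A")
  expect_equal(unname(LAA[1, ]), c(0, 0, 0))
  expect_error(build_contrast(d3, "g", "A", "Z"), "level")
})

test_that("ridge variance-covariance reduces to OLS at lambda = 0 and is symmetric", {
  set.seed(13)
  X <- cbind(1, rnorm(9), rnorm(9))
  s2 <- 1.7
  V0 <- vcov_ridge(X, s2, lambda = 0)
  expect_equal(V0, s2 * solve(crossprod(X)), tolerance = 1e-10)
  V1 <- vcov_ridge(X, s2, lambda = 0.5)
  expect_equal(V1, t(V1), tolerance = 1e-12)
  expect_true(all(eigen(V1, only.values = TRUE)$values > -1e-12))
  # intercept-only: variance = sigma2 * n / (n + lambda)^2
  ones <- matrix(1, 5, 1)
  expect_equal(
    drop(vcov_ridge(ones, s2, lambda = 2)),
    s2 * 5 / (5 + 2)^2,
    tolerance = 1e-12
  )
})

test_that("with complete data and lambda -> 0 the contrast t equals the pooled t-test", {
  set.seed(17)
  y <- c(rnorm(6, 10), rnorm(6, 9))
  ds <- make_peptide_dataset(
    matrix(y, 1, 12, dimnames = list("pep1", cells_ab$cell_id)), cells_ab
  )
  fit <- fit_model(ds, model_spec(g = "biological", lambda = 0))
  L <- build_contrast(fit$design, "g", "A", "B")
  inf <- test_contrasts(fit, L)
  oracle <- t.test(y[1:6], y[7:12], var.equal = TRUE)
  expect_equal(inf$t, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(inf$p_value, oracle$p.value, tolerance = 1e-9)
  expect_equal(inf$estimate, mean(y[1:6]) - mean(y[7:12]), tolerance = 1e-9)
  expect_equal(inf$df, 10L)
})

test_that("a peptide observed in a single group is reported non-estimable", {
  y <- c(rnorm(6, 10), rep(NA, 6))
  ds <- make_peptide_dataset(
    matrix(y, 1, 12, dimnames = list("pep1", cells_ab$cell_id)), cells_ab
  )
  fit <- fit_model(ds, model_spec(g = "biological"))
  inf <- test_contrasts(fit, build_contrast(fit$design, "g", "A", "B"))
  expect_false(inf$estimable)
  expect_true(is.na(inf$p_value))
  expect_true(is.na(inf$estimate))
})

test_that("swapping contrast groups negates estimates and keeps p-values", {
  sim <- simulate_scp(n_cells = 60, n_peptides = 20, seed = 23)
  fit <- fit_model(sim$dataset, model_spec(
    run = "technical", label = "technical", cell_type = "biological"
  ))
  types <- sort(unique(sim$dataset$cells$cell_type))
  inf_ab <- test_contrasts(
    fit, build_contrast(fit$design, "cell_type", types[1], types[2])
  )
  inf_ba <- test_contrasts(
    fit, build_contrast(fit$design, "cell_type", types[2], types[1])
  )
  expect_equal(inf_ab$estimate, -inf_ba$estimate, tolerance = 1e-10)
  expect_equal(inf_ab$p_value, inf_ba$p_value, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand-stepped procedure", {
  inf <- tibble::tibble(
    feature_id = paste0("p", 1:4), contrast = "g:A-B",
    estimate = 1, se = 1, t = 1, df = 5,
    p_value = c(0.01, 0.02, 0.03, 0.04),
    baseline = 8, estimable = TRUE
  )
  adj <- adjust_pvalues(inf, method = "bh")
  expect_equal(adj$adj_p_value, rep(0.04, 4))
  # single test: adjusted equals raw
  adj1 <- adjust_pvalues(inf[1, ], method = "bh")
  expect_equal(adj1$adj_p_value, 0.01)
  # adjusted p is never below raw p
  expect_true(all(adj$adj_p_value >= adj$p_value))
})

test_that("binned IHW falls back to BH when small and respects the weight budget", {
  inf_small <- tibble::tibble(
    feature_id = paste0("p", 1:8), contrast = "g:A-B",
    estimate = 1, se = 1, t = 1, df = 5,
    p_value = seq(0.01, 0.08, by = 0.01),
    baseline = rnorm(8, 8), estimable = TRUE
  )
  adj <- adjust_pvalues(inf_small, method = "ihw", n_bins = 5)
  expect_equal(adj$adj_p_value, p.adjust(inf_small$p_value, "BH"))

  set.seed(41)
  n <- 600
  inf_big <- tibble::tibble(
    feature_id = paste0("p", 1:n), contrast = "g:A-B",
    estimate = 1, se = 1, t = 1, df = 5,
    p_value = c(runif(n / 2)^3, runif(n / 2)), # informative baseline
    baseline = c(rnorm(n / 2, 10), rnorm(n / 2, 6)),
    estimable = TRUE
  )
  adj_big <- adjust_pvalues(inf_big, method = "ihw", n_bins = 5, seed = 7)
  expect_equal(mean(adj_big$weight), 1, tolerance = 1e-12)
  expect_true(all(adj_big$adj_p_value >= 0 & adj_big$adj_p_value <= 1))
  # weighting should not lose power relative to BH on this informative setup
  n_bh <- sum(p.adjust(inf_big$p_value, "BH") <= 0.05)
  n_ihw <- sum(adj_big$adj_p_value <= 0.05)
  expect_gte(n_ihw, 0.8 * n_bh)
})

test_that("p-value combination matches hand-computed oracles", {
  expect_equal(combine_pvalues(c(0.5, 0.5), "fisher"),
    pchisq(-2 * log(0.25), df = 4, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_equal(combine_pvalues(c(0.5, 0.5), "fisher"), 0.5966, tolerance = 1e-4)
  expect_equal(combine_pvalues(c(0.01, 0.04), "simes"), 0.02, tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.01, 0.04), "berger"), 0.04, tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.2, 0.6), "wilkinson"),
    1 - 0.8^2,
    tolerance = 1e-12
  )
  expect_equal(combine_pvalues(c(0.01, 0.04), "holm_min"), 0.02, tolerance = 1e-12)
  expect_equal(
    combine_pvalues(c(0.1, 0.2), "stouffer"),
    pnorm((qnorm(0.9) + qnorm(0.8)) / sqrt(2), lower.tail = FALSE),
    tolerance = 1e-12
  )
  # pearson on a single p returns that p (consistency anchor)
  expect_equal(combine_pvalues(0.3, "pearson"), 0.3, tolerance = 1e-12)
})

test_that("single-peptide proteins inherit the peptide p for every method", {
  methods <- c(
    "fisher", "simes", "berger", "pearson", "holm_min", "stouffer",
    "wilkinson"
  )
  inf <- tibble::tibble(
    feature_id = "pep1", contrast = "g:A-B", estimate = 1.5, se = 0.5,
    t = 3, df = 8, p_value = 0.0171, baseline = 9, estimable = TRUE
  )
  map <- tibble::tibble(feature_id = "pep1", protein = "Q1")
  for (m in methods) {
    prot <- combine_to_protein(inf, map, method = m)
    expect_equal(prot$p_value, 0.0171, tolerance = 1e-10)
    expect_equal(prot$representative, "pep1")
    expect_equal(prot$logfc, 1.5)
  }
})

test_that("protein aggregation picks the representative by method convention", {
  inf <- tibble::tibble(
    feature_id = c("pepA", "pepB", "pepC"),
    contrast = "g:A-B",
    estimate = c(2, -1, 0.5),
    se = 1, t = 1, df = 5,
    p_value = c(0.001, 0.5, 0.04),
    baseline = 8, estimable = TRUE
  )
  map <- tibble::tibble(
    feature_id = c("pepA", "pepB", "pepC"), protein = "Q1"
  )
  simes <- combine_to_protein(inf, map, method = "simes")
  expect_equal(simes$representative, "pepA")
  expect_equal(simes$logfc, 2)
  berger <- combine_to_protein(inf, map, method = "berger")
  expect_equal(berger$representative, "pepB")
  expect_equal(berger$logfc, -1)
  expect_equal(berger$p_value, 0.5)

  # proteins without estimable peptides are reported as skipped
  inf2 <- dplyr::bind_rows(inf, tibble::tibble(
    feature_id = "pepD", contrast = "g:A-B", estimate = NA_real_,
    se = NA_real_, t = NA_real_, df = 5, p_value = NA_real_,
    baseline = 7, estimable = FALSE
  ))
  map2 <- dplyr::bind_rows(map, tibble::tibble(
    feature_id = "pepD", protein = "Q2"
  ))
  out <- combine_to_protein(inf2, map2, method = "simes")
  expect_equal(attr(out, "skipped")$protein, "Q2")
  expect_false("Q2" %in% out$protein)
})
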