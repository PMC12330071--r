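#' Simulate an SCP peptide-by-cell data set with known ground truth
#'
#' Generates log2-scale peptide intensities under the same additive model
#' the package fits: per-peptide baseline, per-cell size factor, MS-run
#' batch effects, label-channel effects, cell-type effects and Gaussian
#' residual noise. Each categorical effect family is drawn centered
#' Gaussian per peptide and re-centered to sum to zero across levels, so
#' the truth aligns exactly with the sum-contrast design encoding and "true
#' log fold change" between two groups is well-defined. Missingness is
#' completely at random (MCAR) plus structural run dropout: a peptide can
#' be absent from an entire acquisition run, the pattern that forces
#' per-peptide model adaptation.
#'
#' The defaults emulate a batch-dominated multiplexed experiment: run
#' effects (scale 1 log2 unit) dominate the cell-type signal (scale 0.5),
#' labels contribute a small share, and about a fifth of the entries are
#' missing.
#'
#' @param n_cells,n_peptides,n_proteins Dimensions of the simulated
#'   experiment; peptides are spread evenly over proteins.
#' @param n_runs Number of MS acquisition runs; cells are assigned to runs
#'   in contiguous blocks, as acquired.
#' @param n_labels Number of label channels, cycling within run (0 for a
#'   label-free design).
#' @param n_cell_types Number of biological cell types, randomized across
#'   runs.
#' @param celltype_scale,run_scale,label_scale Standard deviations (log2
#'   units) of the per-peptide effect draws for each family.
#' @param baseline_mean,baseline_scale Mean and sd of per-peptide baseline
#'   log2 intensities.
#' @param residual_sd Residual noise sd (log2 units).
#' @param size_factor_sd Sd of the per-cell additive size factor.
#' @param mcar_rate Probability that any entry is missing at random.
#' @param run_dropout_rate Probability that a peptide is entirely absent
#'   from a given run.
#' @param seed Integer seed; the simulation is deterministic given the
#'   seed and leaves the global random state untouched.
#' @return A list with `dataset` (a log2 peptide-level [scp_dataset()] with
#'   cell annotations `run`, `label`, `cell_type`, `size_factor`) and
#'   `truth` (list: `coefficients` tibble aligned to the sum-contrast
#'   encoding, `residual_sd`, `cells`, `dropout`, `config`).
#' @export
simulate_scp <- function(n_cells = 200, n_peptides = 300, n_proteins = 100,
                         n_runs = 4, n_labels = 4, n_cell_types = 2,
                         celltype_scale = 0.5, run_scale = 1,
                         label_scale = 0.3,
                         baseline_mean = 8, baseline_scale = 1.5,
                         residual_sd = 0.5, size_factor_sd = 0.3,
                         mcar_rate = 0.2, run_dropout_rate = 0.05,
                         seed = 1L) {
  stopifnot(
    n_cells >= 1, n_peptides >= 1, n_proteins >= 1, n_runs >= 1,
    n_cell_types >= 1, mcar_rate >= 0, mcar_rate < 1,
    run_dropout_rate >= 0, run_dropout_rate < 1
  )
  with_local_seed(seed, {
    pad <- function(prefix, i, n) {
      sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
    }
    cell_ids <- pad("cell", seq_len(n_cells), n_cells)
    pep_ids <- pad("pep", seq_len(n_peptides), n_peptides)
    run <- pad("run", rep(seq_len(n_runs), each = ceiling(n_cells / n_runs))[
      seq_len(n_cells)
    ], n_runs)
    label <- if (n_labels >= 2) {
      pad("label", rep_len(seq_len(n_labels), n_cells), n_labels)
    } else {
      NULL
    }
    cell_type <- pad("type", sample(seq_len(n_cell_types), n_cells, TRUE),
      n_cell_types
    )
    size_factor <- rnorm(n_cells, 0, size_factor_sd)

    baseline <- rnorm(n_peptides, baseline_mean, baseline_scale)
    draw_effects <- function(n_levels, scale) {
      if (n_levels < 2 || scale == 0) {
        return(matrix(0, n_peptides, max(n_levels, 1)))
      }
      e <- matrix(rnorm(n_peptides * n_levels, 0, scale), n_peptides)
      e - rowMeans(e) # sum-to-zero across levels
    }
    run_eff <- draw_effects(n_runs, run_scale)
    label_eff <- draw_effects(n_labels, label_scale)
    type_eff <- draw_effects(n_cell_types, celltype_scale)

    run_i <- as.integer(factor(run, levels = sort(unique(run))))
    type_i <- as.integer(factor(cell_type, levels = sort(unique(cell_type))))
    label_i <- if (is.null(label)) {
      rep(1L, n_cells)
    } else {
      as.integer(factor(label, levels = sort(unique(label))))
    }
    Y <- matrix(baseline, n_peptides, n_cells) +
      matrix(size_factor, n_peptides, n_cells, byrow = TRUE) +
      run_eff[, run_i, drop = FALSE] +
      label_eff[, label_i, drop = FALSE] +
      type_eff[, type_i, drop = FALSE] +
      matrix(rnorm(n_peptides * n_cells, 0, residual_sd), n_peptides)
    dimnames(Y) <- list(pep_ids, cell_ids)

    miss <- matrix(runif(n_peptides * n_cells) < mcar_rate, n_peptides)
    dropout <- which(
      matrix(runif(n_peptides * n_runs) < run_dropout_rate, n_peptides),
      arr.ind = TRUE
    )
    for (d in seq_len(nrow(dropout))) {
      miss[dropout[d, 1], run_i == dropout[d, 2]] <- TRUE
    }
    if (all(miss)) abort("Simulation settings left every entry missing.")
    Y[miss] <- NA_real_

    protein <- pad(
      "prot", ceiling(seq_len(n_peptides) * n_proteins / n_peptides),
      n_proteins
    )
    cells <- tibble::tibble(
      cell_id = cell_ids, run = run, cell_type = cell_type,
      size_factor = size_factor
    )
    if (!is.null(label)) cells$label <- label
    ds <- scp_dataset(
      Y,
      tibble::tibble(feature_id = pep_ids, peptide = pep_ids, protein = protein),
      cells,
      level = "peptide", log_transformed = TRUE, log_base = 2
    )

    # truth aligned to the sum-contrast encoding: intercept absorbs the
    # mean size factor, levels 1..a-1 carry the centered effects
    truth_terms <- function(name, eff, lev) {
      if (ncol(eff) < 2) {
        return(NULL)
      }
      purrr::map_dfr(seq_len(ncol(eff) - 1), function(i) {
        tibble::tibble(
          feature_id = pep_ids,
          term = paste0(name, "=", lev[i]),
          value = eff[, i]
        )
      })
    }
    coef_truth <- dplyr::bind_rows(
      tibble::tibble(
        feature_id = pep_ids, term = "(Intercept)",
        value = baseline + mean(size_factor)
      ),
      tibble::tibble(
        feature_id = pep_ids, term = "size_factor", value = 1
      ),
      truth_terms("run", run_eff, sort(unique(run))),
      if (!is.null(label)) {
        truth_terms("label", label_eff, sort(unique(label)))
      },
      truth_terms("cell_type", type_eff, sort(unique(cell_type)))
    )
    list(
      dataset = ds,
      truth = list(
        coefficients = coef_truth,
        residual_sd = residual_sd,
        cells = cells,
        dropout = tibble::tibble(
          feature_id = pep_ids[dropout[, 1]],
          run = sort(unique(run))[dropout[, 2]]
        ),
        config = list(
          n_cells = n_cells, n_peptides = n_peptides,
          n_proteins = n_proteins, n_runs = n_runs, n_labels = n_labels,
          n_cell_types = n_cell_types, celltype_scale = celltype_scale,
          run_scale = run_scale, label_scale = label_scale,
          baseline_mean = baseline_mean, baseline_scale = baseline_scale,
          residual_sd = residual_sd, size_factor_sd = size_factor_sd,
          mcar_rate = mcar_rate, run_dropout_rate = run_dropout_rate,
          seed = seed
        )
      )
    )
  })
}

# evaluate an expression under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(
    if (!is.null(old)) {
      assign(".Random.seed", old, .GlobalEnv)
    } else if (exists(".Random.seed", .GlobalEnv)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  )
  set.seed(seed)
  expr
}

#' Parameter-recovery report against simulation truth
#'
#' Compares fitted coefficients to the generator's true coefficients,
#' family by family: mean error (bias), root mean squared error, and the
#' coverage of t-based confidence intervals built from the ridge
#' variance-covariance matrix.
#'
#' @param truth The `truth` element returned by [simulate_scp()].
#' @param fit An `scplm_fit` obtained on the simulated data with a matching
#'   formula (same descriptor names).
#' @param level Confidence level for the intervals (default 0.95).
#' @return A tibble with one row per effect family: `family`, `n`
#'   (coefficients compared), `bias`, `rmse`, `coverage`.
#' @export
evaluate_recovery <- function(truth, fit, level = 0.95) {
  stopifnot(inherits(fit, "scplm_fit"))
  est <- fitted_coefficients_se(fit)
  tab <- dplyr::inner_join(
    est, truth$coefficients,
    by = c("feature_id", "term"), suffix = c("", "_true")
  )
  if (!nrow(tab)) {
    abort("No common (feature, term) pairs: do the formulas match the generator's descriptors?")
  }
  alpha <- 1 - level
  tab |>
    dplyr::mutate(
      family = sub("=.*$", "", .data$term),
      err = .data$estimate - .data$value,
      covered = abs(.data$err) <= qt(1 - alpha / 2, .data$df) * .data$se
    ) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias = mean(.data$err),
      rmse = sqrt(mean(.data$err^2)),
      coverage = mean(.data$covered),
      .by = "family"
    )
}

# tidy coefficients with ridge standard errors
fitted_coefficients_se <- function(fit) {
  X <- fit$design$X
  purrr::map_dfr(seq_len(nrow(fit$fits)), function(j) {
    params <- fit$fits$params[[j]]
    V <- vcov_ridge(
      X[fit$fits$observed[[j]], params, drop = FALSE],
      fit$fits$sigma2[[j]], fit$lambda
    )
    beta <- fit$fits$coefficients[[j]]
    tibble::tibble(
      feature_id = fit$fits$feature_id[[j]],
      term = names(beta),
      estimate = unname(beta),
      se = if (is.null(V)) NA_real_ else sqrt(diag(V)),
      df = fit$fits$df[[j]]
    )
  })
}
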