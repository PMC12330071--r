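#' Run the full analysis pipeline from a single configuration
#'
#' Chains the stages simulate/read -> process -> model -> variance ->
#' differential -> components -> benchmark, driven by one flat
#' configuration (an R list or a YAML file). Every stage is optional:
#' omitted sections are skipped. All result tables are written to the
#' output directory as delimited text together with a machine-readable
#' `manifest.json` recording the configuration, seed, processing history
#' and package version, which suffices to re-execute the identical
#' analysis.
#'
#' Configuration sections (see the vignette for a worked example):
#' \describe{
#'   \item{input}{either `simulate:` with [simulate_scp()] arguments, or
#'     `matrix`/`feature_annotations`/`cell_annotations` paths (plus
#'     `level`, `log_transformed`), or `long_table`/`column_map`/`level`.}
#'   \item{processing}{`feature_rules`, `cell_rules` (argument lists for
#'     [feature_qc_rules()] / [cell_qc_rules()]), `aggregate_key`,
#'     `log_base`, `ambiguous`.}
#'   \item{model}{`variables:` named role map, `lambda`, `np_threshold`.}
#'   \item{contrasts}{list of `{variable, group_a, group_b}` entries.}
#'   \item{adjust}{`method` ("bh"/"ihw"), `n_bins`, `alpha`.}
#'   \item{protein}{`method` for [combine_to_protein()].}
#'   \item{components}{`variables:` list, `k`.}
#'   \item{benchmark}{`keep:` variables to retain, `bio_label`,
#'     `tech_label`, `n_pcs`, `k`.}
#'   \item{seed, output_dir}{reproducibility seed and output location.}
#' }
#'
#' @param config A named list or path to a YAML file.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the in-memory results (`dataset`, `fit`,
#'   `variance`, `inference`, `proteins`, `components`, `benchmark`,
#'   `manifest`) and the output directory path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) abort("`output_dir` is required.")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  results <- list()
  tables <- list()

  # --- input -----------------------------------------------------------
  inp <- config$input %||% abort("`input` section is required.")
  if (!is.null(inp$simulate)) {
    say("Simulating data set")
    sim_args <- inp$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim <- do.call(simulate_scp, sim_args)
    ds <- sim$dataset
    results$truth <- sim$truth
    tables$simulation_truth <- sim$truth$coefficients
  } else if (!is.null(inp$matrix)) {
    say("Reading matrix %s", inp$matrix)
    ds <- read_matrix(inp$matrix, inp$feature_annotations,
      inp$cell_annotations,
      level = inp$level %||% "peptide",
      log_transformed = isTRUE(inp$log_transformed),
      log_base = inp$log_base %||% 2
    )
  } else if (!is.null(inp$long_table)) {
    say("Reading long table %s", inp$long_table)
    ds <- read_long_table(inp$long_table, inp$column_map,
      level = inp$level %||% "psm"
    )
  } else {
    abort("`input` must provide `simulate`, `matrix` or `long_table`.")
  }

  # --- processing ------------------------------------------------------
  proc <- config$processing
  if (!is.null(proc)) {
    say("Processing (%d features, %d cells)", n_features(ds), n_cells(ds))
    ds <- process_dataset(
      ds,
      feature_rules = if (!is.null(proc$feature_rules)) {
        do.call(feature_qc_rules, proc$feature_rules)
      },
      cell_rules = if (!is.null(proc$cell_rules)) {
        do.call(cell_qc_rules, proc$cell_rules)
      },
      aggregate_key = proc$aggregate_key,
      log_base = proc$log_base,
      ambiguous = proc$ambiguous %||% "error"
    )
  }
  results$dataset <- ds
  write_matrix(ds, file.path(out_dir, "processed_matrix.tsv"))
  tables$processing_log <- ds$history

  # --- model -----------------------------------------------------------
  mod <- config$model
  fit <- NULL
  if (!is.null(mod)) {
    vars <- mod$variables %||%
      abort("`model$variables` must map descriptor names to roles.")
    unknown <- setdiff(
      names(vars),
      c(names(ds$cells), "median_intensity")
    )
    if (length(unknown)) {
      abort(sprintf(
        "Model stage: descriptor(s) not in the cell annotations: %s.",
        paste(unknown, collapse = ", ")
      ))
    }
    spec <- do.call(model_spec, c(vars, list(lambda = mod$lambda %||% 1e-3)))
    say("Fitting %d peptides", n_features(ds))
    fit <- fit_model(ds, spec, np_threshold = mod$np_threshold %||% 1)
    results$fit <- fit
    tables$coefficients <- tidy(fit)
    tables$model_summary <- glance(fit)
    tables$skipped_peptides <- fit$skipped
  }

  # --- variance --------------------------------------------------------
  if (!is.null(fit) && !isFALSE(config$variance)) {
    say("Analysis of variance")
    vt <- variance_analysis(fit)
    results$variance <- vt
    tables$variance_peptide <- vt
    tables$variance_global <- global_variance(vt)
    if ("protein" %in% names(ds$features)) {
      tables$variance_protein <- protein_variance(vt, ds$features)
    }
  }

  # --- differential ----------------------------------------------------
  if (!is.null(fit) && length(config$contrasts)) {
    say("Differential abundance analysis")
    L <- do.call(rbind, lapply(config$contrasts, function(co) {
      build_contrast(fit$design, co$variable, co$group_a, co$group_b)
    }))
    inf <- test_contrasts(fit, L)
    adj <- config$adjust %||% list()
    inf <- adjust_pvalues(inf,
      method = adj$method %||% "bh",
      n_bins = adj$n_bins %||% 5,
      alpha = adj$alpha %||% 0.05, seed = seed
    )
    results$inference <- inf
    tables$peptide_inference <- inf
    if ("protein" %in% names(ds$features)) {
      prot <- combine_to_protein(
        inf, ds$features,
        method = (config$protein %||% list())$method %||% "simes"
      )
      results$proteins <- prot
      tables$protein_inference <- prot
    }
  }

  # --- components ------------------------------------------------------
  comp_cfg <- config$components
  if (!is.null(fit) && !is.null(comp_cfg)) {
    for (v in comp_cfg$variables %||% list()) {
      say("Component analysis: %s", v)
      cr <- apca(fit, v, k = comp_cfg$k %||% 20)
      results$components[[v]] <- cr
      tables[[paste0("scores_", v)]] <- tidy(cr)
      tables[[paste0("eigenvalues_", v)]] <- tibble::tibble(
        component = seq_along(cr$eigenvalues),
        eigenvalue = cr$eigenvalues,
        percent_variance = cr$percent_variance
      )
    }
  }

  # --- benchmark -------------------------------------------------------
  bm <- config$benchmark
  if (!is.null(fit) && !is.null(bm)) {
    say("Benchmarking batch correction")
    corrected <- batch_corrected(fit, keep = unlist(bm$keep %||% list()))
    cells <- fit$cells[match(colnames(corrected), fit$cells$cell_id), ]
    rep <- benchmark_correction(
      corrected,
      bio_labels = cells[[bm$bio_label]],
      tech_labels = cells[[bm$tech_label]],
      n_pcs = bm$n_pcs %||% 20,
      k = bm$k %||% length(unique(cells[[bm$bio_label]])),
      seed = seed
    )
    results$benchmark <- rep
    tables$benchmark_metrics <- rep$metrics
  }

  # --- outputs ---------------------------------------------------------
  paths <- write_results(tables, out_dir)
  manifest <- list(
    package = "scplm",
    version = as.character(utils::packageVersion("scplm")),
    seed = seed,
    config = config,
    history = as.list(ds$history),
    outputs = as.list(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  results$manifest <- manifest
  results$output_dir <- out_dir
  say("Done: %s", out_dir)
  invisible(results)
}
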