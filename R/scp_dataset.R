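#' SCP data set container
#'
#' An `scp_dataset` bundles a features-by-cells intensity matrix (missing
#' entries stored as `NA`), a feature annotation table, a cell annotation
#' table and a processing history. It is the substrate consumed by every
#' processing, modeling and exploration function in the package.
#'
#' Zero is never used as a missingness sentinel: raw zero intensities are
#' converted to `NA` on ingestion so that raw-scale and log-scale data share
#' one contract.
#'
#' @param intensities Numeric matrix, features in rows, cells in columns.
#'   Missing values are `NA`. Row and column names are the feature and cell
#'   identifiers.
#' @param features Data frame of feature annotations with a `feature_id`
#'   column matching the matrix row names. Typical columns: `peptide`,
#'   `protein`, PSM-level QC columns.
#' @param cells Data frame of cell annotations with a `cell_id` column
#'   matching the matrix column names.
#' @param level Quantification level, one of `"psm"`, `"precursor"`,
#'   `"peptide"`.
#' @param log_transformed Logical; whether intensities are on a log scale.
#' @param log_base Base of the log transform if `log_transformed`.
#'
#' @return An object of class `scp_dataset`.
#' @export
scp_dataset <- function(intensities, features, cells,
                        level = c("psm", "precursor", "peptide"),
                        log_transformed = FALSE, log_base = NA_real_) {
  level <- match.arg(level)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  features <- tibble::as_tibble(features)
  cells <- tibble::as_tibble(cells)
  if (!"feature_id" %in% names(features)) {
    abort("`features` must contain a `feature_id` column.")
  }
  if (!"cell_id" %in% names(cells)) {
    abort("`cells` must contain a `cell_id` column.")
  }
  features$feature_id <- as.character(features$feature_id)
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(features$feature_id)) {
    abort("Feature ids must be unique.")
  }
  if (anyDuplicated(cells$cell_id)) {
    abort("Cell ids must be unique.")
  }
  if (nrow(intensities) != nrow(features)) {
    abort(sprintf(
      "Matrix has %d rows but %d feature annotations.",
      nrow(intensities), nrow(features)
    ))
  }
  if (ncol(intensities) != nrow(cells)) {
    abort(sprintf(
      "Matrix has %d columns but %d cell annotations.",
      ncol(intensities), nrow(cells)
    ))
  }
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- cells$cell_id
  if (!log_transformed && any(intensities == 0, na.rm = TRUE)) {
    abort("Zero intensities must be stored as missing (NA), never as 0.")
  }
  structure(
    list(
      intensities = intensities,
      features = features,
      cells = cells,
      level = level,
      log_transformed = log_transformed,
      log_base = if (log_transformed) log_base else NA_real_,
      history = empty_history()
    ),
    class = "scp_dataset"
  )
}

empty_history <- function() {
  tibble::tibble(
    step = character(),
    parameters = character(),
    features_before = integer(),
    features_after = integer(),
    cells_before = integer(),
    cells_after = integer()
  )
}

#' @export
print.scp_dataset <- function(x, ...) {
  n_obs <- sum(!is.na(x$intensities))
  n_tot <- length(x$intensities)
  cat(sprintf(
    "<scp_dataset> %d features x %d cells (%s level, %s scale)\n",
    nrow(x$intensities), ncol(x$intensities), x$level,
    if (x$log_transformed) sprintf("log%g", x$log_base) else "raw"
  ))
  if (n_tot > 0) {
    cat(sprintf(
      "  observed: %d/%d entries (%.1f%% missing)\n",
      n_obs, n_tot, 100 * (1 - n_obs / n_tot)
    ))
  }
  if (nrow(x$history)) {
    cat("  history:", paste(x$history$step, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.scp_dataset <- function(x) dim(x$intensities)

#' Number of features / cells in a data set
#' @param ds An `scp_dataset`.
#' @return Integer count.
#' @export
n_features <- function(ds) nrow(ds$intensities)

#' @rdname n_features
#' @export
n_cells <- function(ds) ncol(ds$intensities)

# Append one processing record; every processing verb goes through here so
# the history grows by exactly one row per applied step.
record_step <- function(ds, step, parameters, before_dim) {
  rec <- tibble::tibble(
    step = step,
    parameters = paste(
      names(parameters), vapply(parameters, format_param, character(1)),
      sep = "=", collapse = "; "
    ),
    features_before = before_dim[[1]],
    features_after = nrow(ds$intensities),
    cells_before = before_dim[[2]],
    cells_after = ncol(ds$intensities)
  )
  ds$history <- dplyr::bind_rows(ds$history, rec)
  ds
}

format_param <- function(x) {
  if (is.null(x)) "NULL" else paste(format(x), collapse = ",")
}

# Subset keeping annotations aligned; internal, id-based callers only.
subset_dataset <- function(ds, feature_keep = NULL, cell_keep = NULL) {
  if (!is.null(feature_keep)) {
    ds$intensities <- ds$intensities[feature_keep, , drop = FALSE]
    ds$features <- ds$features[feature_keep, , drop = FALSE]
  }
  if (!is.null(cell_keep)) {
    ds$intensities <- ds$intensities[, cell_keep, drop = FALSE]
    ds$cells <- ds$cells[cell_keep, , drop = FALSE]
  }
  ds
}

#' Tidy an SCP data set into a long tibble
#'
#' Returns one row per observed (feature, cell) intensity, joined with the
#' feature and cell annotations, ready for dplyr/ggplot2 pipelines.
#'
#' @param x An `scp_dataset`.
#' @param keep_missing Keep rows for missing entries (`intensity = NA`)?
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `cell_id`, `intensity` and
#'   all annotation columns.
#' @method tidy scp_dataset
#' @export
tidy.scp_dataset <- function(x, keep_missing = FALSE, ...) {
  long <- tibble::tibble(
    feature_id = rep(rownames(x$intensities), times = ncol(x$intensities)),
    cell_id = rep(colnames(x$intensities), each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  if (!keep_missing) long <- long[!is.na(long$intensity), , drop = FALSE]
  long |>
    dplyr::left_join(x$features, by = "feature_id") |>
    dplyr::left_join(x$cells, by = "cell_id")
}

#' @method glance scp_dataset
#' @export
glance.scp_dataset <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$intensities),
    n_cells = ncol(x$intensities),
    level = x$level,
    log_transformed = x$log_transformed,
    prop_missing = if (length(x$intensities)) {
      mean(is.na(x$intensities))
    } else {
      NA_real_
    },
    n_steps = nrow(x$history)
  )
}

assert_scp_dataset <- function(ds) {
  if (!inherits(ds, "scp_dataset")) {
    abort("Expected an `scp_dataset` object.")
  }
  invisible(ds)
}
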