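#' Read a long-format PSM/precursor quantification table
#'
#' Ingests the long table layout emitted by search engines after
#' quantification: one row per (feature, cell) measurement. Zero intensities
#' are treated as missing and duplicate (feature, cell) pairs are collapsed
#' by their median.
#'
#' @param path Path to a delimited text file (`.csv` comma, otherwise tab).
#' @param column_map Named list mapping semantic roles to column names.
#'   Mandatory roles: `feature`, `cell`, `intensity`. Optional roles:
#'   `peptide`, `protein`, and any QC role (e.g. `decoy`, `contaminant`,
#'   `sample_to_carrier`, `purity`, `identification_fdr`) whose column is
#'   carried into the feature annotations under the role name.
#' @param level Quantification level of the rows (`"psm"` or `"precursor"`).
#' @return An [scp_dataset()].
#' @export
read_long_table <- function(path, column_map, level = c("psm", "precursor")) {
  level <- match.arg(level)
  tab <- read_delim_auto(path)
  for (role in c("feature", "cell", "intensity")) {
    if (is.null(column_map[[role]])) {
      abort(sprintf("`column_map` must name a column for role '%s'.", role))
    }
  }
  if (nrow(tab) == 0 && ncol(tab) == 0) { # empty file
    return(scp_dataset(
      matrix(numeric(), 0, 0),
      tibble::tibble(feature_id = character()),
      tibble::tibble(cell_id = character()),
      level = level
    ))
  }
  missing_cols <- setdiff(unlist(column_map), names(tab))
  if (length(missing_cols)) {
    abort(sprintf(
      "Column(s) not found in %s: %s", path,
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(tab) == 0) {
    return(scp_dataset(
      matrix(numeric(), 0, 0),
      tibble::tibble(feature_id = character()),
      tibble::tibble(cell_id = character()),
      level = level
    ))
  }
  ints <- tab[[column_map$intensity]]
  if (!is.numeric(ints)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ints))) & !is.na(ints))
    abort(sprintf(
      "Non-numeric intensity value(s), first at row %d.",
      if (length(bad)) bad[1] else 1L
    ))
  }
  long <- tibble::tibble(
    feature_id = as.character(tab[[column_map$feature]]),
    cell_id = as.character(tab[[column_map$cell]]),
    intensity = as.numeric(ints)
  )
  # zeros are missed measurements, not true zero abundance
  long$intensity[long$intensity == 0] <- NA_real_

  feature_ids <- unique(long$feature_id)
  cell_ids <- unique(long$cell_id)

  collapsed <- long |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::summarise(
      intensity = median(.data$intensity),
      .by = c("feature_id", "cell_id")
    )
  mat <- matrix(NA_real_, length(feature_ids), length(cell_ids),
    dimnames = list(feature_ids, cell_ids)
  )
  mat[cbind(collapsed$feature_id, collapsed$cell_id)] <- collapsed$intensity

  annot_roles <- setdiff(names(column_map), c("cell", "intensity"))
  feat <- tab[!duplicated(as.character(tab[[column_map$feature]])), , drop = FALSE]
  features <- tibble::tibble(feature_id = feature_ids)
  for (role in setdiff(annot_roles, "feature")) {
    features[[role]] <- feat[[column_map[[role]]]][
      match(feature_ids, as.character(feat[[column_map$feature]]))
    ]
  }
  scp_dataset(mat, features, tibble::tibble(cell_id = cell_ids), level = level)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble::tibble())
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE
  )
}

#' Read a features-by-cells intensity matrix with sidecar annotations
#'
#' @param path Matrix file: first column feature ids, remaining column names
#'   are cell ids. Empty fields are missing values.
#' @param feature_annotation_path,cell_annotation_path Delimited tables keyed
#'   by `feature_id` / `cell_id` covering exactly the matrix ids.
#' @param level,log_transformed,log_base Passed to [scp_dataset()].
#' @return An [scp_dataset()].
#' @export
read_matrix <- function(path, feature_annotation_path, cell_annotation_path,
                        level = "peptide", log_transformed = FALSE,
                        log_base = NA_real_) {
  tab <- read_delim_auto(path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1]])
  features <- read_delim_auto(feature_annotation_path)
  cells <- read_delim_auto(cell_annotation_path)
  check_ids(rownames(mat), as.character(features$feature_id), "feature")
  check_ids(colnames(mat), as.character(cells$cell_id), "cell")
  features <- features[match(rownames(mat), features$feature_id), , drop = FALSE]
  cells <- cells[match(colnames(mat), cells$cell_id), , drop = FALSE]
  scp_dataset(mat, features, cells,
    level = level,
    log_transformed = log_transformed, log_base = log_base
  )
}

check_ids <- function(matrix_ids, annot_ids, what) {
  missing <- setdiff(matrix_ids, annot_ids)
  extra <- setdiff(annot_ids, matrix_ids)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "%s ids do not match annotations.%s%s", what,
      if (length(missing)) {
        sprintf(" Missing annotation for: %s.", paste(missing, collapse = ", "))
      } else {
        ""
      },
      if (length(extra)) {
        sprintf(" Annotated but absent from matrix: %s.", paste(extra, collapse = ", "))
      } else {
        ""
      }
    ))
  }
}

#' Write an SCP data set to a matrix file plus annotation sidecars
#'
#' The matrix round-trips bit-exactly through [read_matrix()]: values are
#' written with full precision and missing entries as empty fields.
#'
#' @param ds An `scp_dataset`.
#' @param path Matrix output path (`.tsv` or `.csv`).
#' @param feature_annotation_path,cell_annotation_path Sidecar output paths;
#'   defaults derive from `path`.
#' @return Invisibly, the three paths written.
#' @export
write_matrix <- function(ds, path,
                         feature_annotation_path = sub("(\\.[^.]+)$", "_features\\1", path),
                         cell_annotation_path = sub("(\\.[^.]+)$", "_cells\\1", path)) {
  assert_scp_dataset(ds)
  tab <- tibble::as_tibble(ds$intensities)
  tab <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(ds$intensities)), tab)
  write_delim_auto(tab, path)
  write_delim_auto(ds$features, feature_annotation_path)
  write_delim_auto(ds$cells, cell_annotation_path)
  invisible(c(path, feature_annotation_path, cell_annotation_path))
}

write_delim_auto <- function(tab, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tab, path, delim = delim, na = "")
}

#' Write a named list of result tables to a directory
#'
#' One delimited file per table, deterministic column order (as given).
#'
#' @param tables Named list of data frames.
#' @param directory Output directory, created if needed.
#' @param delim_ext File extension (`"tsv"` or `"csv"`).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_results <- function(tables, directory, delim_ext = "tsv") {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a fully named list.")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(directory, paste0(nm, ".", delim_ext))
    write_delim_auto(tibble::as_tibble(tables[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}
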