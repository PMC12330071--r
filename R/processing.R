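#' Feature quality-control rules
#'
#' Rules applied to PSM/precursor-level feature annotations. Any rule left
#' `NULL` is inactive. Features with a missing value in an active rule's
#' column are retained (no evidence against them).
#'
#' @param drop_decoys Drop features flagged in the `decoy` column?
#' @param drop_contaminants Drop features flagged in the `contaminant`
#'   column?
#' @param max_identification_fdr Keep features with identification FDR at or
#'   below this fraction (column `identification_fdr`).
#' @param min_sample_to_carrier_ratio Keep features whose single-cell signal
#'   relative to the carrier channel is at least this fraction (column
#'   `sample_to_carrier`).
#' @param min_spectral_purity Keep features with isolation-window purity at
#'   least this fraction (column `purity`).
#' @return A `feature_qc_rules` list.
#' @export
feature_qc_rules <- function(drop_decoys = NULL, drop_contaminants = NULL,
                             max_identification_fdr = NULL,
                             min_sample_to_carrier_ratio = NULL,
                             min_spectral_purity = NULL) {
  for (thr in c(
    max_identification_fdr, min_sample_to_carrier_ratio,
    min_spectral_purity
  )) {
    if (!is.null(thr) && (thr < 0 || thr > 1)) {
      abort("QC thresholds are fractions and must lie in [0, 1].")
    }
  }
  structure(
    list(
      drop_decoys = drop_decoys, drop_contaminants = drop_contaminants,
      max_identification_fdr = max_identification_fdr,
      min_sample_to_carrier_ratio = min_sample_to_carrier_ratio,
      min_spectral_purity = min_spectral_purity
    ),
    class = "feature_qc_rules"
  )
}

#' Cell quality-control rules
#'
#' @param min_peptides_per_cell Minimum number of quantified features per
#'   cell.
#' @param median_log_intensity_range Length-2 numeric `(low, high)`: cells
#'   whose median log2 intensity falls outside this open interval are
#'   removed. Computed on a provisional log2 of the observed raw values.
#' @param max_median_cv Maximum allowed median coefficient of variation
#'   within proteins (fraction, e.g. 0.6).
#' @param min_peptides_per_protein_for_cv Minimum observed peptides a
#'   protein needs in a cell to contribute a CV value.
#' @return A `cell_qc_rules` list.
#' @export
cell_qc_rules <- function(min_peptides_per_cell = NULL,
                          median_log_intensity_range = NULL,
                          max_median_cv = NULL,
                          min_peptides_per_protein_for_cv = 3L) {
  if (!is.null(median_log_intensity_range)) {
    if (length(median_log_intensity_range) != 2 ||
      median_log_intensity_range[1] >= median_log_intensity_range[2]) {
      abort("`median_log_intensity_range` must be (low, high) with low < high.")
    }
  }
  if (!is.null(max_median_cv) && max_median_cv <= 0) {
    abort("`max_median_cv` must be positive.")
  }
  structure(
    list(
      min_peptides_per_cell = min_peptides_per_cell,
      median_log_intensity_range = median_log_intensity_range,
      max_median_cv = max_median_cv,
      min_peptides_per_protein_for_cv = min_peptides_per_protein_for_cv
    ),
    class = "cell_qc_rules"
  )
}

#' Filter features on PSM-level quality control
#'
#' @param ds An `scp_dataset` at PSM or precursor level.
#' @param rules A [feature_qc_rules()] object.
#' @return The filtered `scp_dataset` with a processing record appended.
#' @export
filter_features <- function(ds, rules) {
  assert_scp_dataset(ds)
  before <- dim(ds$intensities)
  keep <- rep(TRUE, nrow(ds$features))
  need_col <- function(col, rule) {
    if (!col %in% names(ds$features)) {
      abort(sprintf(
        "Rule '%s' is active but column '%s' is absent from the feature annotations.",
        rule, col
      ))
    }
    ds$features[[col]]
  }
  pass <- function(x) !is.na(x) & x # flagged -> drop
  if (isTRUE(rules$drop_decoys)) {
    keep <- keep & !pass(as.logical(need_col("decoy", "drop_decoys")))
  }
  if (isTRUE(rules$drop_contaminants)) {
    keep <- keep & !pass(as.logical(need_col("contaminant", "drop_contaminants")))
  }
  if (!is.null(rules$max_identification_fdr)) {
    x <- need_col("identification_fdr", "max_identification_fdr")
    keep <- keep & (is.na(x) | x <= rules$max_identification_fdr)
  }
  if (!is.null(rules$min_sample_to_carrier_ratio)) {
    x <- need_col("sample_to_carrier", "min_sample_to_carrier_ratio")
    keep <- keep & (is.na(x) | x >= rules$min_sample_to_carrier_ratio)
  }
  if (!is.null(rules$min_spectral_purity)) {
    x <- need_col("purity", "min_spectral_purity")
    keep <- keep & (is.na(x) | x >= rules$min_spectral_purity)
  }
  ds <- subset_dataset(ds, feature_keep = which(keep))
  record_step(ds, "filter_features", rules[!vapply(rules, is.null, logical(1))],
    before_dim = before
  )
}

#' Per-cell median coefficient of variation within proteins
#'
#' For each cell, every protein with at least `min_peptides_per_protein`
#' observed peptides contributes a CV: each peptide's intensity is first
#' divided by that peptide's mean across cells (relative intensity), then
#' CV = sd/mean over the protein's peptides in the cell. The cell's value is
#' the median over proteins; cells with no qualifying protein get `NA`.
#'
#' @param ds Raw-scale `scp_dataset` with a `protein` feature annotation.
#' @param min_peptides_per_protein Minimum observed peptides per protein.
#' @return A tibble with columns `cell_id`, `median_cv`.
#' @export
compute_cell_median_cv <- function(ds, min_peptides_per_protein = 3L) {
  assert_scp_dataset(ds)
  if (ds$log_transformed) {
    abort("CV is defined on raw intensities; the data set is log-transformed.")
  }
  if (!"protein" %in% names(ds$features)) {
    abort("Feature annotations must contain a `protein` column.")
  }
  rel <- ds$intensities / rowMeans(ds$intensities, na.rm = TRUE)
  protein <- ds$features$protein
  cvs <- vapply(seq_len(ncol(rel)), function(i) {
    x <- rel[, i]
    obs <- !is.na(x)
    if (!any(obs)) {
      return(NA_real_)
    }
    by_prot <- split(x[obs], protein[obs])
    by_prot <- by_prot[lengths(by_prot) >= min_peptides_per_protein]
    if (!length(by_prot)) {
      return(NA_real_)
    }
    median(vapply(by_prot, function(v) sd(v) / mean(v), numeric(1)))
  }, numeric(1))
  tibble::tibble(cell_id = colnames(ds$intensities), median_cv = cvs)
}

#' Filter cells on quality control
#'
#' @param ds A raw-scale `scp_dataset`.
#' @param rules A [cell_qc_rules()] object.
#' @return The filtered `scp_dataset` with a processing record appended.
#' @export
filter_cells <- function(ds, rules) {
  assert_scp_dataset(ds)
  before <- dim(ds$intensities)
  keep <- rep(TRUE, ncol(ds$intensities))
  if (!is.null(rules$min_peptides_per_cell)) {
    n_obs <- colSums(!is.na(ds$intensities))
    keep <- keep & n_obs >= rules$min_peptides_per_cell
  }
  if (!is.null(rules$median_log_intensity_range)) {
    med <- apply(ds$intensities, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_real_ else median(log2(x))
    })
    rng <- rules$median_log_intensity_range
    keep <- keep & !is.na(med) & med > rng[1] & med < rng[2]
  }
  if (!is.null(rules$max_median_cv)) {
    cv <- compute_cell_median_cv(
      ds, rules$min_peptides_per_protein_for_cv %||% 3L
    )$median_cv
    keep <- keep & (is.na(cv) | cv <= rules$max_median_cv)
  }
  ds <- subset_dataset(ds, cell_keep = which(keep))
  record_step(ds, "filter_cells", rules[!vapply(rules, is.null, logical(1))],
    before_dim = before
  )
}

#' Aggregate PSM/precursor rows to peptides
#'
#' One output row per distinct value of `key`; the value for a peptide in a
#' cell is the median over its observed child features, missing when no
#' child is observed there.
#'
#' @param ds An `scp_dataset` at PSM or precursor level.
#' @param key Feature annotation column defining the peptide identity
#'   (default `"peptide"`).
#' @param ambiguous How to treat a peptide mapping to more than one protein:
#'   `"error"` (default), `"drop"` the peptide, or `"keep_first"` keep the
#'   alphabetically first protein.
#' @return A peptide-level `scp_dataset`.
#' @export
aggregate_to_peptides <- function(ds, key = "peptide",
                                  ambiguous = c("error", "drop", "keep_first")) {
  assert_scp_dataset(ds)
  ambiguous <- match.arg(ambiguous)
  if (!ds$level %in% c("psm", "precursor")) {
    abort("Aggregation expects a PSM- or precursor-level data set.")
  }
  if (!key %in% names(ds$features)) {
    abort(sprintf("Key column '%s' is absent from the feature annotations.", key))
  }
  before <- dim(ds$intensities)
  keys <- as.character(ds$features[[key]])
  has_protein <- "protein" %in% names(ds$features)
  if (has_protein) {
    prot_map <- ds$features |>
      dplyr::distinct(.data[[key]], .data$protein) |>
      dplyr::add_count(.data[[key]])
    amb <- unique(prot_map[[key]][prot_map$n > 1])
    if (length(amb)) {
      if (ambiguous == "error") {
        abort(sprintf(
          "Peptide(s) mapping to multiple proteins: %s. Set `ambiguous` to 'drop' or 'keep_first'.",
          paste(head(amb, 10), collapse = ", ")
        ))
      } else if (ambiguous == "drop") {
        keep <- !keys %in% amb
        ds <- subset_dataset(ds, feature_keep = which(keep))
        keys <- keys[keep]
      }
    }
  }
  key_levels <- unique(keys)
  agg <- rowsum_median(ds$intensities, keys, key_levels)
  features <- tibble::tibble(feature_id = key_levels, peptide = key_levels)
  if (has_protein) {
    if (length(key_levels)) {
      prot <- ds$features |>
        dplyr::summarise(
          protein = sort(as.character(.data$protein))[1],
          .by = dplyr::all_of(key)
        )
      features$protein <- prot$protein[match(key_levels, prot[[key]])]
    } else {
      features$protein <- character(0)
    }
  }
  out <- scp_dataset(agg, features, ds$cells, level = "peptide")
  out$history <- ds$history
  record_step(out, "aggregate_to_peptides",
    list(key = key, summary = "median", ambiguous = ambiguous),
    before_dim = before
  )
}

# median aggregation of rows by group, NA-aware
rowsum_median <- function(mat, groups, levels) {
  out <- matrix(NA_real_, length(levels), ncol(mat),
    dimnames = list(levels, colnames(mat))
  )
  idx <- split(seq_along(groups), factor(groups, levels = levels))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- mat[rows, ]
    } else {
      out[g, ] <- apply(mat[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Log-transform intensities
#'
#' @param ds A raw-scale `scp_dataset`; all observed values must be
#'   positive.
#' @param base Log base (default 2, the field's convention for fold
#'   changes).
#' @return The log-scale `scp_dataset`.
#' @export
log_transform <- function(ds, base = 2) {
  assert_scp_dataset(ds)
  if (ds$log_transformed) abort("Data set is already log-transformed.")
  bad <- which(ds$intensities <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-positive observed intensity at feature '%s', cell '%s'.",
      rownames(ds$intensities)[bad[1, 1]], colnames(ds$intensities)[bad[1, 2]]
    ))
  }
  before <- dim(ds$intensities)
  ds$intensities <- log(ds$intensities, base = base)
  ds$log_transformed <- TRUE
  ds$log_base <- base
  record_step(ds, "log_transform", list(base = base), before_dim = before)
}

#' Minimal processing pipeline
#'
#' Applies the four processing steps in the fixed order feature QC, cell QC,
#' aggregation to peptides, log transform. Normalization, imputation and
#' batch correction are deliberately absent: they are handled by the model.
#'
#' @param ds A PSM/precursor-level `scp_dataset`.
#' @param feature_rules A [feature_qc_rules()] object (or `NULL` to skip).
#' @param cell_rules A [cell_qc_rules()] object (or `NULL` to skip).
#' @param aggregate_key Feature column naming the peptide (or `NULL` to
#'   skip aggregation, e.g. for already-peptide-level input).
#' @param log_base Log base (or `NULL` to skip the transform).
#' @param ambiguous Passed to [aggregate_to_peptides()].
#' @return A processed `scp_dataset`.
#' @export
process_dataset <- function(ds, feature_rules = NULL, cell_rules = NULL,
                            aggregate_key = "peptide", log_base = 2,
                            ambiguous = "error") {
  if (!is.null(feature_rules)) ds <- filter_features(ds, feature_rules)
  if (!is.null(cell_rules)) ds <- filter_cells(ds, cell_rules)
  if (!is.null(aggregate_key)) {
    ds <- aggregate_to_peptides(ds, key = aggregate_key, ambiguous = ambiguous)
  }
  if (!is.null(log_base)) ds <- log_transform(ds, base = log_base)
  ds
}
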