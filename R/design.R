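#' Specify the linear model over cell descriptors
#'
#' Each argument in `...` names a cell descriptor and gives its role in the
#' experiment: `"normalization"` (e.g. the per-cell median intensity),
#' `"technical"` (e.g. MS acquisition run, label channel) or
#' `"biological"` (e.g. cell type). The descriptor's kind (categorical or
#' numeric) is inferred from the annotation column when the design is built.
#'
#' The special descriptor name `median_intensity` is computed on demand by
#' [fit_model()] as the median of each cell's observed log2 intensities, so
#' it need not be present in the cell annotations.
#'
#' @param ... Named role strings, e.g.
#'   `model_spec(median_intensity = "normalization", run = "technical",
#'   cell_type = "biological")`. Order is kept and determines column order
#'   in the design.
#' @param lambda Ridge penalty, a small non-negative constant that
#'   stabilizes estimation when a peptide's n/p ratio is close to 1
#'   (default `1e-3`).
#' @return A `model_spec` object.
#' @export
model_spec <- function(..., lambda = 1e-3) {
  roles <- list(...)
  if (!length(roles)) abort("A model needs at least one descriptor.")
  if (is.null(names(roles)) || any(names(roles) == "")) {
    abort("Every descriptor must be named, e.g. `run = \"technical\"`.")
  }
  roles <- vapply(roles, as.character, character(1))
  bad <- setdiff(roles, c("normalization", "technical", "biological"))
  if (length(bad)) {
    abort(sprintf(
      "Unknown role(s): %s. Use 'normalization', 'technical' or 'biological'.",
      paste(bad, collapse = ", ")
    ))
  }
  if (lambda < 0) abort("`lambda` must be non-negative.")
  structure(
    list(variables = names(roles), roles = roles, lambda = lambda),
    class = "model_spec"
  )
}

#' Build the encoded design matrix
#'
#' Encodes the cell descriptors named in the model specification into a
#' design matrix with an imposed intercept. Categorical descriptors use
#' sum-to-zero contrasts over lexicographically ordered levels: a
#' descriptor with `a` levels contributes `a - 1` columns, level `i < a`
#' maps to indicator column `i` and the last level to `-1` in every column
#' of the descriptor. Numeric descriptors are centered on their mean over
#' all cells.
#'
#' @param cells Cell annotation data frame (must include every descriptor
#'   in `spec` as a column).
#' @param spec A [model_spec()].
#' @return An `scplm_design`: list with the matrix `X` (cells x
#'   parameters), `var_index` (named list mapping each descriptor to its
#'   parameter column indices), `intercept_index`, and encoding metadata
#'   (`levels`, `centers`, `roles`).
#' @export
build_design <- function(cells, spec) {
  cells <- tibble::as_tibble(cells)
  missing <- setdiff(spec$variables, names(cells))
  if (length(missing)) {
    abort(sprintf(
      "Descriptor(s) absent from the cell annotations: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  n <- nrow(cells)
  cols <- list(`(Intercept)` = rep(1, n))
  var_index <- list()
  levels_meta <- list()
  centers <- list()
  for (v in spec$variables) {
    x <- cells[[v]]
    if (is.numeric(x)) {
      if (any(!is.finite(x))) {
        abort(sprintf("Numeric descriptor '%s' has non-finite values.", v))
      }
      centers[[v]] <- mean(x)
      cols[[v]] <- x - centers[[v]]
      var_index[[v]] <- length(cols) - 1L
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2) {
        abort(sprintf(
          "Categorical descriptor '%s' has a single level ('%s') and cannot be modeled.",
          v, lev
        ))
      }
      levels_meta[[v]] <- lev
      a <- length(lev)
      start <- length(cols)
      for (i in seq_len(a - 1)) {
        enc <- as.numeric(as.character(x) == lev[i])
        enc[as.character(x) == lev[a]] <- -1
        cols[[paste0(v, "=", lev[i])]] <- enc
      }
      var_index[[v]] <- seq(start + 1L, start + a - 1L) - 1L
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- if ("cell_id" %in% names(cells)) cells$cell_id else NULL
  # exact duplicate (collinear) columns are tolerated: per-peptide
  # subsetting may still drop them, but the user should know
  dup <- duplicated(t(X))
  if (any(dup[-1])) {
    warn(sprintf(
      "Design contains duplicated column(s): %s.",
      paste(colnames(X)[dup], collapse = ", ")
    ))
  }
  structure(
    list(
      X = X,
      var_index = lapply(var_index, function(i) i + 1L),
      intercept_index = 1L,
      levels = levels_meta,
      centers = centers,
      roles = setNames(spec$roles, spec$variables),
      lambda = spec$lambda
    ),
    class = "scplm_design"
  )
}

#' @export
print.scplm_design <- function(x, ...) {
  cat(sprintf(
    "<scplm_design> %d cells x %d parameters (intercept + %s)\n",
    nrow(x$X), ncol(x$X),
    paste(sprintf("%s[%d]", names(x$var_index), lengths(x$var_index)),
      collapse = " + "
    )
  ))
  invisible(x)
}

# variance threshold below which a design column counts as constant on the
# observed cells; absolute, guards against floating-point false positives
CONSTANT_VAR_TOL <- 1e-12

#' Retained parameters for a peptide's observation pattern
#'
#' Missing values can make design columns constant on the cells where a
#' peptide is observed (e.g. a peptide seen in a single MS run). Such
#' parameters are inestimable and dropped; the intercept is always kept.
#' Columns that individually vary but are jointly collinear on the
#' observed cells (a peptide seen in two of three runs makes the two run
#' indicators sum to the intercept) are also pruned, keeping the earliest
#' columns, so that every retained parameter is identifiable and effect
#' matrices are not contaminated by minimum-norm coefficient splitting.
#'
#' @param design An `scplm_design`.
#' @param observed Integer or logical index of observed cells (rows of the
#'   design).
#' @return Sorted integer vector of retained parameter column indices.
#' @export
subset_model <- function(design, observed) {
  Xo <- design$X[observed, , drop = FALSE]
  if (nrow(Xo) < 1) abort("`observed` selects no cells.")
  keep <- which(apply(Xo, 2, var) > CONSTANT_VAR_TOL)
  keep <- sort(unique(c(design$intercept_index, keep)))
  qrX <- qr(Xo[, keep, drop = FALSE])
  if (qrX$rank < length(keep)) {
    keep <- sort(keep[qrX$pivot[seq_len(qrX$rank)]])
  }
  keep
}
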