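#' Fit the adaptive ridge model to every peptide
#'
#' For each peptide the model is restricted to the cells where it is
#' observed (`O_j`) and to the design parameters that are not constant on
#' those cells (`S_j`, intercept always kept). Coefficients are estimated by
#' ridge-penalized least squares with the closed form
#' `(X'X + lambda I)^-1 X'y`; the small penalty stabilizes estimation when
#' the peptide's n/p ratio (observations over retained parameters) is close
#' to 1. Peptides whose n/p falls below the threshold, or at or below 1, are
#' skipped rather than imputed.
#'
#' @param ds A peptide-level, log-transformed `scp_dataset`.
#' @param spec A [model_spec()].
#' @param np_threshold Minimum n/p ratio required to fit a peptide
#'   (default 1, i.e. only the estimability bound; some analyses prefer a
#'   stricter 3). Peptides with `n/p < np_threshold` or `n/p <= 1` are
#'   skipped.
#' @return An `scplm_fit` object with elements `design`, `fits` (one row
#'   per fitted peptide with list-columns for coefficients and residuals),
#'   `skipped` (feature id and reason), plus the data needed for
#'   reconstruction.
#' @export
fit_model <- function(ds, spec, np_threshold = 1) {
  assert_scp_dataset(ds)
  if (!ds$log_transformed) {
    abort("Modeling expects log-transformed intensities; call `log_transform()` first.")
  }
  cells <- ds$cells
  if ("median_intensity" %in% spec$variables &&
    !"median_intensity" %in% names(cells)) {
    cells$median_intensity <- cell_median_intensity(ds)
  }
  design <- build_design(cells, spec)
  Y <- t(ds$intensities) # cells x peptides
  m <- ncol(Y)
  fit_rows <- vector("list", m)
  skip_rows <- vector("list", m)
  for (j in seq_len(m)) {
    fid <- colnames(Y)[j]
    y_all <- Y[, j]
    observed <- which(!is.na(y_all))
    if (!length(observed)) {
      skip_rows[[j]] <- tibble::tibble(
        feature_id = fid, reason = "no observations", np = 0
      )
      next
    }
    params <- subset_model(design, observed)
    np <- length(observed) / length(params)
    if (np <= 1 || np < np_threshold) {
      skip_rows[[j]] <- tibble::tibble(
        feature_id = fid,
        reason = sprintf("n/p = %.3g below threshold", np), np = np
      )
      next
    }
    fit <- fit_peptide(
      y_all[observed], design$X[observed, params, drop = FALSE], spec$lambda
    )
    if (is.null(fit)) {
      skip_rows[[j]] <- tibble::tibble(
        feature_id = fid, reason = "singular system", np = np
      )
      next
    }
    fit_rows[[j]] <- tibble::tibble(
      feature_id = fid,
      n_obs = length(observed),
      n_par = length(params),
      np = np,
      df = fit$df,
      sse = fit$sse,
      sigma2 = fit$sigma2,
      observed = list(observed),
      params = list(params),
      coefficients = list(fit$beta),
      residuals = list(fit$residuals)
    )
  }
  structure(
    list(
      design = design,
      fits = dplyr::bind_rows(fit_rows),
      skipped = dplyr::bind_rows(skip_rows),
      Y = Y,
      features = ds$features,
      cells = cells,
      lambda = spec$lambda,
      np_threshold = np_threshold
    ),
    class = "scplm_fit"
  )
}

#' Ridge-penalized least squares for a single peptide
#'
#' Solves `argmin ||y - X beta||^2 + lambda ||beta||^2` through the closed
#' form `(X'X + lambda I)^-1 X'y` and derives residuals, SSE, residual
#' degrees of freedom `nrow(X) - ncol(X)` and the residual variance
#' `SSE / df`. At `lambda = 0` on a full-rank system this is ordinary
#' least squares.
#'
#' @param y Observed intensities (no missing values; subset upstream).
#' @param X Design matrix rows matching `y` (observed cells x retained
#'   parameters).
#' @param lambda Non-negative ridge penalty.
#' @return A list with `beta`, `residuals`, `sse`, `df`, `sigma2`, or
#'   `NULL` when the penalized system is numerically singular.
#' @export
fit_peptide <- function(y, X, lambda = 1e-3) {
  p <- ncol(X)
  XtX <- crossprod(X)
  beta <- tryCatch(
    solve(XtX + diag(lambda, p), crossprod(X, y))[, 1],
    error = function(e) NULL
  )
  if (is.null(beta) || any(!is.finite(beta))) {
    return(NULL)
  }
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  sse <- sum(res^2)
  df <- length(y) - p
  list(
    beta = beta, residuals = res, sse = sse, df = df,
    sigma2 = if (df >= 1) sse / df else NA_real_
  )
}

# per-cell median of observed (log-scale) intensities, used as the
# normalization descriptor; cells without observations get the average of
# the others so their centered value is neutral
cell_median_intensity <- function(ds) {
  med <- apply(ds$intensities, 2, function(x) median(x, na.rm = TRUE))
  if (anyNA(med)) {
    warn("Some cells have no observed intensities; their normalization factor is set to the mean of the others.")
    med[is.na(med)] <- mean(med, na.rm = TRUE)
  }
  med
}

#' @export
print.scplm_fit <- function(x, ...) {
  cat(sprintf(
    "<scplm_fit> %d peptides fitted, %d skipped; %d cells, %d parameters (lambda = %g)\n",
    nrow(x$fits), nrow(x$skipped), nrow(x$design$X), ncol(x$design$X),
    x$lambda
  ))
  invisible(x)
}

#' Effect matrix of one model variable
#'
#' Returns the features-by-cells matrix of the model contribution of a
#' single variable: entry (j, i) is `sum_k X[i, k] beta[k]` over the
#' variable's retained parameters, for cells where peptide j is observed,
#' and missing elsewhere. Variables entirely dropped for a peptide give a
#' zero row on the observed cells. `"intercept"` and `"residuals"` are also
#' accepted.
#'
#' @param fit An `scplm_fit`.
#' @param variable A modeled descriptor name, `"intercept"`, or
#'   `"residuals"`.
#' @return Numeric matrix, features x cells, `NA` where unobserved.
#' @export
effect_matrix <- function(fit, variable) {
  stopifnot(inherits(fit, "scplm_fit"))
  known <- c(names(fit$design$var_index), "intercept", "residuals")
  if (!variable %in% known) {
    abort(sprintf(
      "Unknown variable '%s'. Available: %s.", variable,
      paste(known, collapse = ", ")
    ))
  }
  X <- fit$design$X
  out <- matrix(NA_real_, nrow(fit$fits), nrow(X),
    dimnames = list(fit$fits$feature_id, rownames(X))
  )
  for (j in seq_len(nrow(fit$fits))) {
    obs <- fit$fits$observed[[j]]
    if (variable == "residuals") {
      out[j, obs] <- fit$fits$residuals[[j]]
      next
    }
    params <- fit$fits$params[[j]]
    beta <- fit$fits$coefficients[[j]]
    k_f <- if (variable == "intercept") {
      fit$design$intercept_index
    } else {
      fit$design$var_index[[variable]]
    }
    active <- which(params %in% k_f)
    if (!length(active)) {
      out[j, obs] <- 0
    } else {
      out[j, obs] <- drop(
        X[obs, params[active], drop = FALSE] %*% beta[active]
      )
    }
  }
  out
}

#' Batch-corrected data reconstruction
#'
#' Rebuilds the intensity matrix from the intercept (baseline) effect, the
#' effect matrices of the variables to retain (typically the biological
#' ones), and the residuals. Technical effects are thereby removed while
#' the missingness pattern is preserved. Keeping every modeled variable
#' reproduces the observed data exactly.
#'
#' @param fit An `scplm_fit`.
#' @param keep Character vector of modeled variables whose effects are
#'   retained (may be empty for intercept + residuals only).
#' @return Numeric matrix, features x cells, `NA` where unobserved.
#' @export
batch_corrected <- function(fit, keep = character()) {
  stopifnot(inherits(fit, "scplm_fit"))
  unknown <- setdiff(keep, names(fit$design$var_index))
  if (length(unknown)) {
    abort(sprintf(
      "Unknown variable(s) in `keep`: %s.", paste(unknown, collapse = ", ")
    ))
  }
  out <- effect_matrix(fit, "intercept") + effect_matrix(fit, "residuals")
  for (v in keep) out <- out + effect_matrix(fit, v)
  out
}

#' Tidy peptide-level coefficients
#'
#' @param x An `scplm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (peptide, retained parameter):
#'   `feature_id`, `term`, `estimate`, plus `n_obs`, `np`, `df`.
#' @method tidy scplm_fit
#' @export
tidy.scplm_fit <- function(x, ...) {
  purrr::map2_dfr(
    x$fits$feature_id, x$fits$coefficients,
    function(fid, beta) {
      tibble::tibble(
        feature_id = fid, term = names(beta), estimate = unname(beta)
      )
    }
  ) |>
    dplyr::left_join(
      dplyr::select(
        x$fits, "feature_id", "n_obs", "n_par", "np", "df", "sigma2"
      ),
      by = "feature_id"
    )
}

#' @method glance scplm_fit
#' @export
glance.scplm_fit <- function(x, ...) {
  tibble::tibble(
    n_fitted = nrow(x$fits),
    n_skipped = nrow(x$skipped),
    n_cells = nrow(x$design$X),
    n_parameters = ncol(x$design$X),
    lambda = x$lambda,
    np_threshold = x$np_threshold,
    median_np = if (nrow(x$fits)) median(x$fits$np) else NA_real_,
    mean_sigma2 = if (nrow(x$fits)) mean(x$fits$sigma2) else NA_real_
  )
}
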