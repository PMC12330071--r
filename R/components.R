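#' NIPALS principal component analysis with missing values
#'
#' Extracts principal components one at a time by alternating regressions
#' on the observed entries only, which makes the decomposition tolerant of
#' missing values without imputation. Each accepted component is deflated
#' from the observed entries before the next is extracted. On complete data
#' the result coincides with the singular value decomposition (scores
#' `t = u d`, loadings `v`, eigenvalue `d^2`).
#'
#' The input is used as given (no centering); see [apca()] for the
#' feature-centered front end. Loadings are unit-norm; the eigenvalue of a
#' component is the sum of its squared scores. A deterministic sign
#' convention makes the largest-magnitude loading element positive.
#'
#' When entries are missing, the one-component-at-a-time fixed point is
#' not the best joint rank-k fit of the observed entries; by default the
#' extracted components therefore seed an alternating-least-squares
#' refinement of the whole k-component model on the observed entries,
#' after which the factors are re-orthogonalized. On complete data the
#' refinement converges to the same truncated SVD the sequential
#' algorithm targets and merely polishes it to higher accuracy.
#'
#' @param A Numeric matrix (rows = observations/cells, columns =
#'   features), `NA` for missing entries; every row and column needs at
#'   least one observed entry.
#' @param k Number of components to extract; silently truncated to the
#'   achievable number when deflation exhausts the matrix.
#' @param tol Convergence tolerance on the change of the loading vector.
#' @param max_iter Maximum iterations per component.
#' @param refine_iter Maximum joint refinement sweeps (0 disables
#'   refinement and returns the plain sequential NIPALS solution).
#' @return List with `scores` (rows x k), `loadings` (columns x k),
#'   `eigenvalues` (length k, non-increasing) and `converged` (logical per
#'   component).
#' @export
nipals <- function(A, k, tol = 1e-9, max_iter = 500, refine_iter = 100) {
  A <- as.matrix(A)
  if (any(rowSums(!is.na(A)) == 0)) {
    abort("Every row must have at least one observed entry.")
  }
  if (any(colSums(!is.na(A)) == 0)) {
    abort("Every column must have at least one observed entry.")
  }
  n <- nrow(A)
  m <- ncol(A)
  k <- min(k, n, m)
  obs <- !is.na(A)
  R <- A
  scores <- matrix(0, n, 0)
  loadings <- matrix(0, m, 0)
  eig <- numeric(0)
  converged <- logical(0)
  for (comp in seq_len(k)) {
    col_var <- apply(R, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) 0 else var(x)
    })
    if (all(col_var <= .Machine$double.eps) &&
      sum(R^2, na.rm = TRUE) < 1e-24) {
      break # matrix fully deflated; rank reached
    }
    t_vec <- R[, which.max(col_var)]
    t_vec[is.na(t_vec)] <- 0
    p_old <- rep(0, m)
    ok <- FALSE
    w <- obs * 1 # numeric copy for the observed-entry denominators
    R0 <- R
    R0[!obs] <- 0
    for (iter in seq_len(max_iter)) {
      # loadings: regress each column of R on the scores (observed only)
      denom_p <- drop(crossprod(w, t_vec^2))
      p_vec <- ifelse(denom_p > 0, drop(crossprod(R0, t_vec)) / denom_p, 0)
      nrm <- sqrt(sum(p_vec^2))
      if (nrm == 0) break
      p_vec <- p_vec / nrm
      # scores: regress each row of R on the loadings (observed only)
      denom_t <- drop(w %*% p_vec^2)
      t_vec <- ifelse(denom_t > 0, drop(R0 %*% p_vec) / denom_t, 0)
      if (sqrt(sum((p_vec - p_old)^2)) < tol) {
        ok <- TRUE
        break
      }
      p_old <- p_vec
    }
    if (sum(t_vec^2) == 0) break
    # sign convention: largest-magnitude loading element positive
    s <- sign(p_vec[which.max(abs(p_vec))])
    if (s < 0) {
      p_vec <- -p_vec
      t_vec <- -t_vec
    }
    R[obs] <- R[obs] - (tcrossprod(t_vec, p_vec))[obs]
    scores <- cbind(scores, t_vec)
    loadings <- cbind(loadings, p_vec)
    eig <- c(eig, sum(t_vec^2))
    converged <- c(converged, ok)
  }
  if (ncol(scores) && refine_iter > 0) {
    ref <- nipals_refine(A, obs, scores, loadings, tol, refine_iter)
    scores <- ref$scores
    loadings <- ref$loadings
    eig <- ref$eigenvalues
  }
  if (ncol(scores)) {
    # sign convention: largest-magnitude loading element positive
    for (c in seq_len(ncol(scores))) {
      s <- sign(loadings[which.max(abs(loadings[, c])), c])
      if (s < 0) {
        loadings[, c] <- -loadings[, c]
        scores[, c] <- -scores[, c]
      }
    }
    colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncol(scores)))
    rownames(scores) <- rownames(A)
    rownames(loadings) <- colnames(A)
  }
  list(
    scores = scores, loadings = loadings, eigenvalues = eig,
    converged = converged
  )
}

# joint alternating-least-squares refinement of a rank-k fit on the
# observed entries, seeded by the sequential NIPALS factors; factors are
# re-orthogonalized into score/loading/eigenvalue form afterwards
nipals_refine <- function(A, obs, scores, loadings, tol, refine_iter) {
  n <- nrow(A)
  m <- ncol(A)
  k <- ncol(scores)
  S <- scores
  V <- loadings
  A0 <- A
  A0[!obs] <- 0
  sse <- function(S, V) {
    fit <- tcrossprod(S, V)
    sum((A0 - fit * obs)^2)
  }
  best <- list(S = S, V = V, sse = sse(S, V))
  eps <- 1e-10
  for (sweep in seq_len(refine_iter)) {
    for (i in seq_len(n)) {
      o <- obs[i, ]
      Vo <- V[o, , drop = FALSE]
      S[i, ] <- solve(
        crossprod(Vo) + diag(eps, k), crossprod(Vo, A[i, o])
      )
    }
    for (j in seq_len(m)) {
      o <- obs[, j]
      So <- S[o, , drop = FALSE]
      V[j, ] <- solve(
        crossprod(So) + diag(eps, k), crossprod(So, A[o, j])
      )
    }
    cur <- sse(S, V)
    improvement <- best$sse - cur
    if (cur < best$sse) best <- list(S = S, V = V, sse = cur)
    if (improvement >= 0 && improvement < tol * max(best$sse, 1)) break
  }
  # rotate the factor pair into orthonormal loadings and orthogonal scores
  qs <- qr(best$S)
  core <- svd(qr.R(qs) %*% t(best$V))
  scores_new <- qr.Q(qs) %*% core$u %*% diag(core$d, k, k)
  list(
    scores = scores_new,
    loadings = core$v,
    eigenvalues = colSums(scores_new^2)
  )
}

#' APCA+ component analysis of one model variable
#'
#' ANOVA-PCA extended to linear models: the effect matrix of the chosen
#' variable is augmented with the model residuals, features are centered on
#' their observed entries, and the result is decomposed by [nipals()]. The
#' scores place the cells in the subspace dominated by the chosen effect
#' (plus residual heterogeneity); the loadings weigh the peptides.
#'
#' Besides the modeled variables, `variable` may be `"residual"` (PCA of
#' the residual matrix alone, to hunt for unmodeled structure) or
#' `"unmodelled"` (PCA of the processed data themselves, the pre-modeling
#' view).
#'
#' @param fit An `scplm_fit`.
#' @param variable Modeled descriptor name, `"residual"` or
#'   `"unmodelled"`.
#' @param k Number of components (default 20).
#' @param tol,max_iter Passed to [nipals()].
#' @return An `scplm_components` object: `scores` (cells x k), `loadings`
#'   (features x k), `eigenvalues`, `percent_variance`, `centering`
#'   (feature means removed), `variable`.
#' @export
apca <- function(fit, variable, k = 20, tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(fit, "scplm_fit"))
  known <- c(names(fit$design$var_index), "residual", "unmodelled")
  if (!variable %in% known) {
    abort(sprintf(
      "Unknown variable '%s'. Available: %s.", variable,
      paste(known, collapse = ", ")
    ))
  }
  if (k < 1) abort("`k` must be at least 1.")
  A <- if (variable == "unmodelled") {
    fit$Y[, fit$fits$feature_id, drop = FALSE] # cells x features
  } else if (variable == "residual") {
    t(effect_matrix(fit, "residuals"))
  } else {
    t(effect_matrix(fit, variable) + effect_matrix(fit, "residuals"))
  }
  keep_cells <- rowSums(!is.na(A)) > 0
  A <- A[keep_cells, , drop = FALSE]
  centering <- colMeans(A, na.rm = TRUE)
  Ac <- sweep(A, 2, centering)
  res <- nipals(Ac, k = k, tol = tol, max_iter = max_iter)
  achieved <- length(res$eigenvalues)
  if (achieved < k) {
    warn(sprintf(
      "Only %d component(s) achievable (requested %d).", achieved, k
    ))
  }
  total_var <- sum(Ac^2, na.rm = TRUE)
  structure(
    list(
      scores = res$scores,
      loadings = res$loadings,
      eigenvalues = res$eigenvalues,
      percent_variance = if (total_var > 0) {
        100 * res$eigenvalues / total_var
      } else {
        rep(0, achieved)
      },
      converged = res$converged,
      centering = centering,
      variable = variable,
      cells = fit$cells[keep_cells, , drop = FALSE]
    ),
    class = "scplm_components"
  )
}

#' @export
print.scplm_components <- function(x, ...) {
  cat(sprintf(
    "<scplm_components> variable '%s': %d component(s), %.1f%% variance\n",
    x$variable, length(x$eigenvalues), sum(x$percent_variance)
  ))
  invisible(x)
}

#' Tidy component scores
#'
#' @param x An `scplm_components` object.
#' @param ... Unused.
#' @return A tibble of cell scores joined with the cell annotations.
#' @method tidy scplm_components
#' @export
tidy.scplm_components <- function(x, ...) {
  dplyr::bind_cols(x$cells, tibble::as_tibble(x$scores))
}

#' Protein-level loadings
#'
#' Aggregates peptide loadings to proteins as the per-component median over
#' each protein's peptides. Useful for exploring effects at the protein
#' level, but note the aggregated loadings are no longer orthogonal.
#'
#' @param components An `scplm_components` object.
#' @param protein_map Data frame with columns `feature_id` and `protein`
#'   covering all peptides in the loadings.
#' @return A tibble: `protein`, `n_peptides`, one column per component.
#' @export
protein_loadings <- function(components, protein_map) {
  load_tab <- tibble::as_tibble(components$loadings)
  load_tab$feature_id <- rownames(components$loadings)
  unmapped <- setdiff(load_tab$feature_id, protein_map$feature_id)
  if (length(unmapped)) {
    abort(sprintf(
      "Peptide(s) without a protein mapping: %s.",
      paste(head(unmapped, 10), collapse = ", ")
    ))
  }
  load_tab |>
    dplyr::left_join(
      dplyr::select(protein_map, "feature_id", "protein"),
      by = "feature_id"
    ) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      dplyr::across(dplyr::starts_with("PC"), median),
      .by = "protein"
    )
}

#' Scatter plot of two component scores
#'
#' @param components An `scplm_components` object.
#' @param dims Length-2 integer: which components to plot.
#' @param color Cell annotation column to color by (optional).
#' @return A ggplot object.
#' @export
plot_components <- function(components, dims = c(1, 2), color = NULL) {
  tab <- tidy(components)
  xc <- paste0("PC", dims[1])
  yc <- paste0("PC", dims[2])
  gg <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .data[[xc]], y = .data[[yc]]
  ))
  gg <- if (is.null(color)) {
    gg + ggplot2::geom_point(alpha = 0.7)
  } else {
    gg + ggplot2::geom_point(
      ggplot2::aes(color = .data[[color]]),
      alpha = 0.7
    )
  }
  gg +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xc, components$percent_variance[dims[1]]),
      y = sprintf("%s (%.1f%%)", yc, components$percent_variance[dims[2]])
    ) +
    ggplot2::theme_minimal()
}
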