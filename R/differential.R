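#' Build a group-difference contrast
#'
#' Constructs the contrast row estimating the model-implied mean difference
#' `group_a - group_b` for a categorical descriptor under its sum-to-zero
#' encoding: the row is `encoding(group_a) - encoding(group_b)` on the
#' descriptor's parameter columns and zero elsewhere (including the
#' intercept).
#'
#' @param design An `scplm_design`.
#' @param variable Categorical descriptor name.
#' @param group_a,group_b Levels to compare; a positive estimate means
#'   higher abundance in `group_a`.
#' @param name Contrast name; defaults to `"variable:group_a-group_b"`.
#' @return A one-row contrast matrix (class `scplm_contrast`) with columns
#'   aligned to the design parameters. Rows of several calls can be stacked
#'   with `rbind()`.
#' @export
build_contrast <- function(design, variable, group_a, group_b,
                           name = paste0(variable, ":", group_a, "-", group_b)) {
  stopifnot(inherits(design, "scplm_design"))
  lev <- design$levels[[variable]]
  if (is.null(lev)) {
    abort(sprintf("'%s' is not a categorical descriptor of this design.", variable))
  }
  for (g in c(group_a, group_b)) {
    if (!g %in% lev) {
      abort(sprintf(
        "'%s' is not a level of '%s' (levels: %s).", g, variable,
        paste(lev, collapse = ", ")
      ))
    }
  }
  enc <- function(g) {
    i <- match(g, lev)
    a <- length(lev)
    if (i < a) as.numeric(seq_len(a - 1) == i) else rep(-1, a - 1)
  }
  L <- matrix(0, 1, ncol(design$X), dimnames = list(name, colnames(design$X)))
  L[1, design$var_index[[variable]]] <- enc(group_a) - enc(group_b)
  class(L) <- c("scplm_contrast", class(L))
  L
}

#' Variance-covariance matrix of ridge coefficients
#'
#' Sandwich form for linear ridge regression:
#' `(X'X + lambda I)^-1 X'X (X'X + lambda I)^-1 * sigma2`. At `lambda = 0`
#' this reduces to the ordinary least-squares `sigma2 (X'X)^-1`.
#'
#' @param X Design matrix restricted to the peptide's observed cells and
#'   retained parameters.
#' @param sigma2 Residual variance estimate.
#' @param lambda Ridge penalty.
#' @return Symmetric positive semi-definite matrix, or `NULL` when the
#'   system is singular.
#' @export
vcov_ridge <- function(X, sigma2, lambda = 0) {
  XtX <- crossprod(X)
  A <- tryCatch(solve(XtX + diag(lambda, ncol(X))), error = function(e) NULL)
  if (is.null(A)) {
    return(NULL)
  }
  V <- A %*% XtX %*% A * sigma2
  (V + t(V)) / 2
}

#' Peptide-level differential abundance tests
#'
#' For every fitted peptide and every contrast row, computes the estimate
#' `L beta`, its standard error from the ridge variance-covariance matrix,
#' the t statistic `T = L beta / sqrt(L V L')` and a two-sided p-value from
#' the t distribution with the peptide's residual degrees of freedom. A
#' contrast needing a parameter that was dropped for a peptide (e.g. a
#' group the peptide was never observed in) is reported as non-estimable
#' with missing statistics, never silently dropped.
#'
#' @param fit An `scplm_fit`.
#' @param contrasts A contrast matrix from [build_contrast()] (rows may be
#'   stacked with `rbind()`).
#' @return A tibble with one row per (peptide, contrast): `feature_id`,
#'   `contrast`, `estimate` (log fold change), `se`, `t`, `df`, `p_value`,
#'   `baseline` (intercept estimate) and `estimable`.
#' @export
test_contrasts <- function(fit, contrasts) {
  stopifnot(inherits(fit, "scplm_fit"))
  L <- unclass(contrasts)
  if (ncol(L) != ncol(fit$design$X)) {
    abort("Contrast matrix does not match the design's parameter count.")
  }
  X <- fit$design$X
  out <- purrr::map_dfr(seq_len(nrow(fit$fits)), function(j) {
    params <- fit$fits$params[[j]]
    obs <- fit$fits$observed[[j]]
    beta <- fit$fits$coefficients[[j]]
    df <- fit$fits$df[[j]]
    V <- vcov_ridge(
      X[obs, params, drop = FALSE], fit$fits$sigma2[[j]], fit$lambda
    )
    baseline <- beta[[1]]
    purrr::map_dfr(seq_len(nrow(L)), function(ci) {
      l <- L[ci, ]
      needed <- which(l != 0)
      if (!all(needed %in% params) || is.null(V)) {
        return(tibble::tibble(
          feature_id = fit$fits$feature_id[[j]],
          contrast = rownames(L)[ci],
          estimate = NA_real_, se = NA_real_, t = NA_real_,
          df = df, p_value = NA_real_, baseline = baseline,
          estimable = FALSE
        ))
      }
      l_sub <- l[params]
      est <- sum(l_sub * beta)
      se <- sqrt(drop(t(l_sub) %*% V %*% l_sub))
      tval <- if (se > 0) est / se else NA_real_
      tibble::tibble(
        feature_id = fit$fits$feature_id[[j]],
        contrast = rownames(L)[ci],
        estimate = est, se = se, t = tval, df = df,
        p_value = if (is.na(tval)) NA_real_ else 2 * pt(-abs(tval), df),
        baseline = baseline, estimable = TRUE
      )
    })
  })
  out
}

#' Multiple-testing adjustment
#'
#' Adjusts the peptide-level p-values per contrast, either by plain
#' Benjamini-Hochberg or by a binned, cross-weighted variant of independent
#' hypothesis weighting (IHW): peptides are stratified into quantile bins
#' of their baseline (intercept) intensity; in two folds, per-bin weights
#' are learned on the complementary fold to maximize the number of weighted
#' BH discoveries at `alpha` subject to a mean weight of one, and applied
#' as `p / weight` in a weighted BH step. High-baseline peptides are less
#' noisy and typically earn larger weights, increasing power. With fewer
#' than `10 * n_bins` estimable tests the method falls back to plain BH.
#'
#' @param inferences Output of [test_contrasts()].
#' @param method `"bh"` or `"ihw"`.
#' @param n_bins Number of baseline-intensity bins for `"ihw"`.
#' @param alpha Target FDR level used when learning weights.
#' @param seed Integer seed for the fold assignment (local RNG; the global
#'   random state is untouched).
#' @return `inferences` with columns `adj_p_value` and `weight` added.
#' @export
adjust_pvalues <- function(inferences, method = c("bh", "ihw"), n_bins = 5,
                           alpha = 0.05, seed = 1L) {
  method <- match.arg(method)
  if (!any(!is.na(inferences$p_value))) {
    inferences$adj_p_value <- NA_real_
    inferences$weight <- NA_real_
    return(inferences)
  }
  inferences |>
    dplyr::group_by(.data$contrast) |>
    dplyr::group_modify(~ adjust_one_contrast(.x, method, n_bins, alpha, seed)) |>
    dplyr::ungroup() |>
    dplyr::relocate("contrast", .after = "feature_id")
}

adjust_one_contrast <- function(tab, method, n_bins, alpha, seed) {
  ok <- which(!is.na(tab$p_value))
  tab$adj_p_value <- NA_real_
  tab$weight <- NA_real_
  if (!length(ok)) {
    return(tab)
  }
  p <- tab$p_value[ok]
  if (method == "bh" || length(ok) < 10 * n_bins) {
    tab$adj_p_value[ok] <- p.adjust(p, "BH")
    tab$weight[ok] <- 1
    return(tab)
  }
  baseline <- tab$baseline[ok]
  bins <- cut(rank(baseline, ties.method = "first"),
    breaks = n_bins, labels = FALSE
  )
  folds <- local_seed_sample(seed, rep_len(1:2, length(ok)))
  w <- numeric(length(ok))
  for (f in 1:2) {
    learn <- folds != f
    w_bins <- learn_bin_weights(p[learn], bins[learn], n_bins, alpha)
    w[folds == f] <- w_bins[bins[folds == f]]
  }
  w <- w / mean(w) # enforce the unit weight budget exactly
  tab$adj_p_value[ok] <- pmin(1, p.adjust(pmin(1, p / w), "BH"))
  tab$weight[ok] <- w
  tab
}

# draws a permutation-free fold labeling under a local RNG state
local_seed_sample <- function(seed, x) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample(x)
}

# coordinate ascent over per-bin multiplicative weights, maximizing weighted
# BH discoveries at `alpha` with the mean weight constrained to 1
learn_bin_weights <- function(p, bins, n_bins, alpha) {
  n_disc <- function(w_bins) {
    w <- w_bins[bins]
    w <- w / mean(w)
    sum(p.adjust(pmin(1, p / w), "BH") <= alpha)
  }
  w <- rep(1, n_bins)
  grid <- c(1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)
  for (sweep in 1:3) {
    for (b in seq_len(n_bins)) {
      cand <- vapply(grid, function(g) {
        wb <- w
        wb[b] <- g
        n_disc(wb)
      }, numeric(1))
      w[b] <- grid[which.max(cand)]
    }
  }
  w / mean(w[bins])
}

#' Combine peptide-level inference to the protein level
#'
#' Combines the p-values of each protein's estimable peptides by grouped
#' hypothesis testing and reports a representative peptide whose log fold
#' change becomes the protein log fold change. Fisher's, Pearson's and
#' Stouffer's methods test whether all peptide nulls hold jointly; Simes',
#' Wilkinson's (order 1) and the Holm-minimum approach are sensitive to the
#' best peptide; Berger's intersection-union test requires every peptide to
#' be significant. The representative is the maximum-p peptide for Berger
#' and the minimum-p peptide otherwise (ties: larger absolute estimate,
#' then lexicographic id). Protein p-values are BH-adjusted per contrast.
#'
#' @param inferences Output of [test_contrasts()] (adjusted columns are
#'   ignored; combination acts on raw p-values).
#' @param protein_map Data frame with columns `feature_id` and `protein`.
#' @param method One of `"fisher"`, `"simes"`, `"berger"`, `"pearson"`,
#'   `"holm_min"`, `"stouffer"`, `"wilkinson"`.
#' @return A tibble with one row per (protein, contrast): `protein`,
#'   `contrast`, `p_value`, `adj_p_value`, `representative`, `logfc`,
#'   `n_peptides`, `method`. Proteins with no estimable peptide are
#'   reported in the `skipped` attribute.
#' @export
combine_to_protein <- function(inferences, protein_map,
                               method = c(
                                 "fisher", "simes", "berger", "pearson",
                                 "holm_min", "stouffer", "wilkinson"
                               )) {
  method <- match.arg(method)
  unmapped <- setdiff(unique(inferences$feature_id), protein_map$feature_id)
  if (length(unmapped)) {
    abort(sprintf(
      "Peptide(s) without a protein mapping: %s.",
      paste(head(unmapped, 10), collapse = ", ")
    ))
  }
  tab <- inferences |>
    dplyr::left_join(
      dplyr::select(protein_map, "feature_id", "protein"),
      by = "feature_id"
    )
  skipped <- tab |>
    dplyr::summarise(
      n_estimable = sum(!is.na(.data$p_value)),
      .by = c("protein", "contrast")
    ) |>
    dplyr::filter(.data$n_estimable == 0) |>
    dplyr::mutate(reason = "no estimable peptide")
  out <- tab |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$protein, .data$contrast) |>
    dplyr::group_modify(function(g, key) {
      comb <- combine_pvalues(g$p_value, method)
      rep_i <- representative_peptide(g, method)
      tibble::tibble(
        p_value = comb,
        representative = g$feature_id[rep_i],
        logfc = g$estimate[rep_i],
        n_peptides = nrow(g)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(method = method)
  out <- out |>
    dplyr::mutate(
      adj_p_value = p.adjust(.data$p_value, "BH"),
      .by = "contrast"
    )
  attr(out, "skipped") <- skipped
  out
}

#' Combine a vector of p-values
#'
#' @param p Numeric vector of p-values (no missing values).
#' @param method See [combine_to_protein()].
#' @return A single combined p-value.
#' @export
combine_pvalues <- function(p, method) {
  k <- length(p)
  if (!k) abort("No p-values to combine.")
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  switch(method,
    fisher = pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE),
    pearson = pchisq(-2 * sum(log1p(-p)), df = 2 * k, lower.tail = TRUE),
    simes = min(pmin(1, k * sort(p) / seq_len(k))),
    berger = max(p),
    holm_min = min(pmin(1, cummax((k - seq_len(k) + 1) * sort(p)))),
    stouffer = pnorm(sum(qnorm(p, lower.tail = FALSE)) / sqrt(k),
      lower.tail = FALSE
    ),
    wilkinson = 1 - (1 - min(p))^k,
    abort(sprintf("Unknown combination method '%s'.", method))
  )
}

representative_peptide <- function(g, method) {
  ord <- order(
    if (method == "berger") -g$p_value else g$p_value,
    -abs(g$estimate),
    g$feature_id
  )
  ord[1]
}

#' Volcano plot of peptide-level differential abundance
#'
#' @param inferences Output of [adjust_pvalues()] (or [test_contrasts()],
#'   in which case raw p-values are shown).
#' @param alpha Significance threshold drawn as a horizontal line.
#' @return A ggplot object, faceted by contrast.
#' @export
plot_volcano <- function(inferences, alpha = 0.05) {
  pcol <- if ("adj_p_value" %in% names(inferences)) "adj_p_value" else "p_value"
  inferences |>
    dplyr::filter(!is.na(.data[[pcol]])) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$estimate, y = -log10(.data[[pcol]])
    )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(
      x = "log2 fold change",
      y = sprintf("-log10 %s", if (pcol == "adj_p_value") "adjusted p" else "p")
    ) +
    ggplot2::theme_minimal()
}
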