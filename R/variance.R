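#' Analysis of variance across model variables
#'
#' Decomposes each fitted peptide's variation into the contribution of each
#' model variable and the residuals. For variable `f` with retained
#' parameters `K_f`, the regression sum of squares is
#' `SSR(f) = || X[O_j, K_f] beta[K_f] ||^2` and the residual sum of squares
#' is `SSE = || residuals ||^2`; the percentage of variance explained is
#' `100 * SSR(f) / (SSE + sum_l SSR(l))`. The intercept is a baseline, not
#' a variance source, and does not appear. Variables entirely dropped for a
#' peptide are reported with zero percent so the table stays rectangular.
#'
#' @param fit An `scplm_fit`.
#' @return A tibble with columns `feature_id`, `component` (variable name
#'   or `"residual"`), `ss` (sum of squares) and `percent_variance`;
#'   percentages sum to 100 within each peptide.
#' @export
variance_analysis <- function(fit) {
  stopifnot(inherits(fit, "scplm_fit"))
  vars <- names(fit$design$var_index)
  X <- fit$design$X
  rows <- purrr::map_dfr(seq_len(nrow(fit$fits)), function(j) {
    obs <- fit$fits$observed[[j]]
    params <- fit$fits$params[[j]]
    beta <- fit$fits$coefficients[[j]]
    ssr <- vapply(vars, function(v) {
      active <- which(params %in% fit$design$var_index[[v]])
      if (!length(active)) {
        return(0)
      }
      sum(drop(X[obs, params[active], drop = FALSE] %*% beta[active])^2)
    }, numeric(1))
    ssr <- unname(ssr)
    sse <- fit$fits$sse[[j]]
    total <- sse + sum(ssr)
    tibble::tibble(
      feature_id = fit$fits$feature_id[[j]],
      component = c(vars, "residual"),
      ss = c(ssr, sse),
      # degenerate all-zero peptide: attribute everything to the residual
      percent_variance = if (total > 0) {
        100 * c(ssr, sse) / total
      } else {
        c(rep(0, length(vars)), 100)
      }
    )
  })
  rows
}

#' Global variance decomposition
#'
#' Averages the per-peptide percentages of variance explained across all
#' peptides, component by component; the averages again sum to 100.
#'
#' @param variance_table Output of [variance_analysis()].
#' @return A tibble with columns `component` and `percent_variance`.
#' @export
global_variance <- function(variance_table) {
  if (!nrow(variance_table)) abort("Empty variance table.")
  variance_table |>
    dplyr::summarise(
      percent_variance = mean(.data$percent_variance),
      .by = "component"
    )
}

#' Protein-level variance decomposition
#'
#' Averages the percentage of variance explained over the peptides of each
#' protein.
#'
#' @param variance_table Output of [variance_analysis()].
#' @param protein_map Data frame with columns `feature_id` and `protein`
#'   covering every peptide in the table.
#' @return A tibble with columns `protein`, `component`,
#'   `percent_variance` and `n_peptides`.
#' @export
protein_variance <- function(variance_table, protein_map) {
  unmapped <- setdiff(
    unique(variance_table$feature_id),
    protein_map$feature_id
  )
  if (length(unmapped)) {
    abort(sprintf(
      "Peptide(s) without a protein mapping: %s.",
      paste(head(unmapped, 10), collapse = ", ")
    ))
  }
  variance_table |>
    dplyr::left_join(
      dplyr::select(protein_map, "feature_id", "protein"),
      by = "feature_id"
    ) |>
    dplyr::summarise(
      percent_variance = mean(.data$percent_variance),
      n_peptides = dplyr::n_distinct(.data$feature_id),
      .by = c("protein", "component")
    )
}

#' Stacked-bar plot of a variance decomposition
#'
#' @param variance_table Output of [variance_analysis()],
#'   [protein_variance()] (set `id` to `"protein"`) or a global table.
#' @param id Column identifying the bar unit (`"feature_id"` by default);
#'   `NULL` plots a single global bar.
#' @param top Keep the `top` units with the lowest residual percentage.
#' @return A ggplot object.
#' @export
plot_variance <- function(variance_table, id = "feature_id", top = 30) {
  if (is.null(id)) {
    variance_table$unit <- "global"
  } else {
    variance_table$unit <- variance_table[[id]]
  }
  keep <- variance_table |>
    dplyr::filter(.data$component == "residual") |>
    dplyr::arrange(.data$percent_variance) |>
    dplyr::pull(.data$unit) |>
    head(top)
  variance_table |>
    dplyr::filter(.data$unit %in% keep) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$unit, y = .data$percent_variance, fill = .data$component
    )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% variance explained", fill = "Component") +
    ggplot2::theme_minimal()
}
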