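#' Clustering agreement and partition quality metrics
#'
#' Standard definitions: `ari()` is the pair-counting Rand index corrected
#' for chance; `nmi()` is mutual information normalized by the arithmetic
#' mean of the two entropies; `purity()` assigns each cluster its dominant
#' truth label and reports the fraction of correctly covered points (not
#' symmetric in its arguments); `asw()` is the average silhouette width,
#' the mean over points of `(b - a) / max(a, b)` with `a` the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster (singleton clusters contribute 0).
#'
#' @param a,b,clusters,truth,labels Label vectors of equal length.
#' @param points Numeric matrix of coordinates (rows = points) for `asw()`;
#'   Euclidean distances are used.
#' @return A single number: ARI in `[-0.5, 1]`, NMI and purity in
#'   `[0, 1]`, ASW in `[-1, 1]`.
#' @name cluster_metrics
NULL

#' @rdname cluster_metrics
#' @export
ari <- function(a, b) {
  check_lengths(a, b)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n_pairs
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    return(1)
  } # both partitions trivial and identical in structure
  (sum_ij - expected) / denom
}

#' @rdname cluster_metrics
#' @export
nmi <- function(a, b) {
  check_lengths(a, b)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (tab[i, j] > 0) {
        mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
      }
    }
  }
  denom <- (h(pa) + h(pb)) / 2
  if (denom == 0) {
    return(1)
  }
  unname(mi / denom)
}

#' @rdname cluster_metrics
#' @export
purity <- function(clusters, truth) {
  check_lengths(clusters, truth)
  tab <- table(clusters, truth)
  sum(apply(tab, 1, max)) / length(clusters)
}

#' @rdname cluster_metrics
#' @export
asw <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels)) {
    abort("`points` and `labels` must have matching lengths.")
  }
  if (length(unique(labels)) < 2) {
    abort("ASW needs at least two distinct labels.")
  }
  d <- as.matrix(stats::dist(points))
  labels <- as.character(labels)
  s <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      return(0)
    } # singleton convention
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(l) mean(d[i, labels == l]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

check_lengths <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Label vectors must have equal lengths.")
  }
  if (!length(a)) abort("Empty label vectors.")
}

#' Benchmark batch-correction quality
#'
#' Scores a (possibly batch-corrected) intensity matrix by the protocol:
#' NIPALS PCA on the feature-centered matrix, k-means clustering of the PC
#' scores, then ARI/NMI/purity of the clustering against the biological
#' labels (separation, higher is better) and against the technical labels
#' (reported as `1 - metric`, so higher means better batch mixing). The
#' average silhouette width is computed on the PC scores directly with the
#' known labels.
#'
#' @param corrected Features-by-cells numeric matrix, `NA` for missing
#'   entries (e.g. output of [batch_corrected()]).
#' @param bio_labels,tech_labels Per-cell label vectors (e.g. cell type and
#'   MS run).
#' @param n_pcs Number of principal components to keep (default 20).
#' @param k Number of k-means clusters (default: number of distinct
#'   biological labels).
#' @param seed Seed for the k-means restarts (local RNG).
#' @param nstart k-means restarts; the best inertia wins.
#' @return An `scplm_benchmark`: list with `metrics` (tibble: `metric`,
#'   `biological`, `one_minus_technical`), `clusters`, `scores`, `n_pcs`,
#'   `k`.
#' @export
benchmark_correction <- function(corrected, bio_labels, tech_labels,
                                 n_pcs = 20, k = length(unique(bio_labels)),
                                 seed = 1L, nstart = 10) {
  corrected <- as.matrix(corrected)
  if (ncol(corrected) != length(bio_labels) ||
    ncol(corrected) != length(tech_labels)) {
    abort("Labels must cover every cell (column) of the matrix.")
  }
  if (k < 2) abort("`k` must be at least 2.")
  if (ncol(corrected) < k) abort("Fewer cells than clusters requested.")
  A <- t(corrected) # cells x features
  keep_feat <- colSums(!is.na(A)) > 0
  keep_cell <- rowSums(!is.na(A)) > 0
  A <- A[keep_cell, keep_feat, drop = FALSE]
  bio <- as.character(bio_labels)[keep_cell]
  tech <- as.character(tech_labels)[keep_cell]
  Ac <- sweep(A, 2, colMeans(A, na.rm = TRUE))
  pca <- nipals(Ac, k = n_pcs)
  scores <- pca$scores
  km <- with_local_seed(
    seed, kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
  )
  clusters <- km$cluster
  metrics <- tibble::tibble(
    metric = c("ARI", "NMI", "PS", "ASW"),
    biological = c(
      ari(clusters, bio), nmi(clusters, bio), purity(clusters, bio),
      asw(scores, bio)
    ),
    one_minus_technical = 1 - c(
      ari(clusters, tech), nmi(clusters, tech), purity(clusters, tech),
      asw(scores, tech)
    )
  )
  structure(
    list(
      metrics = metrics, clusters = clusters, scores = scores,
      n_pcs = ncol(scores), k = k,
      nmi_normalization = "arithmetic mean of entropies"
    ),
    class = "scplm_benchmark"
  )
}

#' @export
print.scplm_benchmark <- function(x, ...) {
  cat(sprintf(
    "<scplm_benchmark> %d PCs, k-means k = %d\n", x$n_pcs, x$k
  ))
  print(x$metrics)
  invisible(x)
}

#' @method tidy scplm_benchmark
#' @export
tidy.scplm_benchmark <- function(x, ...) x$metrics
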