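# Small programmatic fixtures shared across the test files.

# raw PSM-level data set: `values` is a features x cells matrix (NA = missing)
make_raw_dataset <- function(values, peptide = rownames(values),
                             protein = NULL, level = "psm", ...) {
  features <- tibble::tibble(
    feature_id = rownames(values), peptide = peptide
  )
  if (!is.null(protein)) features$protein <- protein
  extra <- list(...)
  for (nm in names(extra)) features[[nm]] <- extra[[nm]]
  scp_dataset(
    values, features,
    tibble::tibble(cell_id = colnames(values)),
    level = level
  )
}

mat <- function(values, features, cells) {
  matrix(values,
    nrow = length(features), byrow = TRUE,
    dimnames = list(features, cells)
  )
}

# log-scale peptide-level data set with arbitrary cell annotations
make_peptide_dataset <- function(values, cells_tab, protein = NULL) {
  features <- tibble::tibble(
    feature_id = rownames(values), peptide = rownames(values)
  )
  if (!is.null(protein)) features$protein <- protein
  scp_dataset(values, features, cells_tab,
    level = "peptide",
    log_transformed = TRUE, log_base = 2
  )
}

# brute-force pair-counting adjusted Rand index, independent of ari()
oracle_ari <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      if (sa && !sb) s10 <- s10 + 1
      if (!sa && sb) s01 <- s01 + 1
      if (!sa && !sb) s00 <- s00 + 1
    }
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# entropy-based NMI (arithmetic-mean normalization), independent of nmi()
oracle_nmi <- function(a, b) {
  n <- length(a)
  ent <- function(x) {
    p <- as.numeric(table(x)) / n
    -sum(p * log(p))
  }
  joint <- table(a, b) / n
  hx <- ent(a)
  hy <- ent(b)
  hxy <- -sum(joint[joint > 0] * log(joint[joint > 0]))
  mi <- hx + hy - hxy
  if (hx + hy == 0) 1 else mi / ((hx + hy) / 2)
}

oracle_purity <- function(clusters, truth) {
  total <- 0
  for (cl in unique(clusters)) {
    members <- truth[clusters == cl]
    total <- total + max(table(members))
  }
  total / length(clusters)
}
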