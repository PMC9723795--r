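# fixtures and independent oracles used across test files

# random count table: f features, s samples, sparse Poisson counts
random_table <- function(f, s, lambda = 2, sparsity = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(f * s, lambda) * rbinom(f * s, 1, 1 - sparsity), f, s)
  rownames(m) <- sprintf("f%03d", seq_len(f))
  colnames(m) <- sprintf("s%03d", seq_len(s))
  # keep every sample nonzero so compositional ops are defined
  zero <- colSums(m) == 0
  m[1, zero] <- 1L
  abundance_table(tibble::as_tibble(cbind(
    tibble::tibble(feature_id = rownames(m)),
    tibble::as_tibble(m)
  )))
}

table_from_matrix <- function(m, prefix_f = "f", prefix_s = "s") {
  if (is.null(rownames(m))) rownames(m) <- paste0(prefix_f, seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0(prefix_s, seq_len(ncol(m)))
  abundance_table(dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(m)),
    tibble::as_tibble(m)
  ))
}

tbl_matrix <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl$feature_id
  m
}

# independent czm oracle: per-column loop written against the definition,
# structured differently from the implementation
czm_oracle <- function(m) {
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    n <- sum(col)
    p <- col / n
    smallest <- min(p[col > 0])
    cap <- 0.65 * smallest / (1 + 0.65 * smallest * sum(col == 0))
    imputed <- min(0.5 / n, cap)
    nz_shrink <- 1 - imputed * sum(col == 0)
    for (i in seq_along(col)) {
      out[i, j] <- if (col[i] == 0) imputed else p[i] * nz_shrink
    }
  }
  out
}

# ARI without depending on mclust in unit tests (contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# wide node x sample matrix -> long profile tibble
toy_profiles <- function(mat) {
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(cag_id = rownames(mat)), tibble::as_tibble(mat)),
    -"cag_id",
    names_to = "sample_id", values_to = "value"
  )
}

# monthly metadata stub aligned with generator sample ids
monthly_dates <- function(n) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    date = seq(as.Date("2012-01-15"), by = "month", length.out = n)
  )
}

# recovered-vs-planted ARI for a CAG membership tibble; unassigned genes
# become singleton clusters
recovery_ari <- function(truth_genes, cags) {
  m <- dplyr::left_join(truth_genes, cags, by = "gene_id",
    suffix = c("_true", "_hat"))
  lab <- ifelse(is.na(m$cag_id_hat), paste0("unbinned_", m$gene_id), m$cag_id_hat)
  ari(m$cag_id_true, lab)
}
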