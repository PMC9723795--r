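#' Bray-Curtis dissimilarity between samples
#'
#' `BC(a, b) = sum_i |x_ai - x_bi| / sum_i (x_ai + x_bi)`: 0 for
#' identical samples, 1 for disjoint supports, invariant to a common
#' rescaling of a sample's counts.
#'
#' @param table An abundance table (tibble, `feature_id` + samples).
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
braycurtis_matrix <- function(table) {
  validate_abundance(table)
  m <- abund_matrix(table)
  if (ncol(m) < 2L) abort("need at least 2 samples")
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0(
      "sample(s) with zero total: ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Mean community similarity as a function of sampling lag
#'
#' For every whole-month lag `L`, the mean of `1 - BC` over all sample
#' pairs collected exactly `L` calendar months apart.  In a seasonal
#' community the curve peaks at multiples of 12 months and dips at
#' half-period lags.
#'
#' @param dissim Square dissimilarity matrix with sample-id dimnames
#'   (e.g. from [braycurtis_matrix()]).
#' @param dates Either a `Date` vector aligned with the matrix rows or a
#'   metadata tibble with `sample_id` and `date` columns.
#' @return A tibble `lag_months`, `mean_similarity`, `n_pairs`; lags
#'   with no pairs are omitted.
#' @export
lag_similarity <- function(dissim, dates) {
  if (is.data.frame(dates)) {
    dates <- as.Date(dates$date[match(rownames(dissim), dates$sample_id)])
  }
  if (anyNA(dates) || length(dates) != nrow(dissim)) {
    abort("dates must cover every sample in the matrix")
  }
  mo <- as.integer(format(dates, "%Y")) * 12L + as.integer(format(dates, "%m"))
  pairs <- which(upper.tri(dissim), arr.ind = TRUE)
  tibble(
    lag_months = abs(mo[pairs[, 1L]] - mo[pairs[, 2L]]),
    similarity = 1 - dissim[pairs]
  ) %>%
    dplyr::filter(.data$lag_months >= 1L) %>%
    dplyr::group_by(.data$lag_months) %>%
    dplyr::summarise(
      mean_similarity = mean(.data$similarity),
      n_pairs = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::arrange(.data$lag_months)
}

#' ANOSIM permutation test between groups of samples
#'
#' Rank-based analysis of similarities:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)`
#' with `M` the number of sample pairs, ranks taken over all
#' off-diagonal dissimilarities with average-rank ties; the p-value is
#' `(1 + #(permuted R >= observed)) / (1 + n_perm)` under random
#' relabelling.  Computed by `vegan::anosim()`; the seed fixes the
#' permutation stream.
#'
#' @param dissim Square dissimilarity matrix (or `dist`).
#' @param groups Group label per sample (>= 2 groups of >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An `anosim_result` list: `statistic` (R), `p_value`,
#'   `n_perm`, `permuted` (the permuted R values).
#' @export
anosim_test <- function(dissim, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(table(groups) < 2L)) abort("every group needs at least 2 samples")
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(dissim), groups, permutations = n_perm)
  structure(list(
    statistic = unname(fit$statistic),
    p_value = unname(fit$signif),
    n_perm = n_perm,
    permuted = fit$perm
  ), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf(
    "ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
    x$statistic, x$p_value, x$n_perm
  ))
  invisible(x)
}
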