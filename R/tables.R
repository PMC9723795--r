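#' Remove singleton and low-prevalence features
#'
#' Zero-inflated metagenomic abundance tables carry a long tail of
#' features seen once or in very few samples; these are removed before
#' any compositional analysis.  A feature is dropped when its total count
#' across all samples equals one (a global singleton, when
#' `drop_total_singletons`) or when it has nonzero counts in fewer than
#' `min_samples` samples.  To filter jointly over both read fractions
#' (the intended use), pass a single table whose columns concatenate the
#' assembled and unassembled samples.
#'
#' @param table An abundance table (tibble, `feature_id` + sample columns).
#' @param min_samples Minimum number of samples a feature must be
#'   detected in (count >= `detect_min`) to be kept.  Default 20.
#' @param drop_total_singletons Drop features whose grand total is 1.
#' @param detect_min Count at which a feature is called detected in a
#'   sample; default 1.
#' @return The filtered table; sample columns unchanged.
#' @export
filter_low_prevalence <- function(table, min_samples = 20,
                                  drop_total_singletons = TRUE,
                                  detect_min = 1L) {
  validate_abundance(table)
  m <- abund_matrix(table)
  if (min_samples > ncol(m)) {
    abort("`min_samples` exceeds the number of samples")
  }
  prevalence <- rowSums(m >= detect_min)
  keep <- prevalence >= min_samples
  if (drop_total_singletons) keep <- keep & rowSums(m) != 1
  dplyr::filter(as_tibble(table), keep)
}

#' Bayesian-multiplicative zero replacement (czm)
#'
#' Converts a count table into strictly positive proportions suitable for
#' log-ratio analysis.  Within each sample, every zero count is imputed
#' as the proportion `0.5 / N` (half a count out of the sample total
#' `N`), and the observed nonzero proportions are multiplicatively shrunk
#' so the sample still sums to one — the count-zero-multiplicative
#' treatment of compositional zeros.  In degenerate samples (tiny totals
#' with many zeros) the raw rule would impute more mass than the sample
#' holds, so the imputed proportion is capped at 0.65 times the smallest
#' shrunk nonzero proportion, keeping every imputed value below every
#' observed one and all values positive.
#'
#' @inheritParams filter_low_prevalence
#' @return A tibble of the same shape holding strictly positive
#'   proportions; each sample column sums to 1.
#' @export
replace_zeros <- function(table) {
  validate_abundance(table)
  m <- abund_matrix(table)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0(
      "all-zero sample(s): ",
      paste(colnames(m)[totals == 0], collapse = ", ")
    ))
  }
  p <- sweep(m, 2L, totals, "/")
  out <- p
  for (j in seq_len(ncol(m))) {
    z <- m[, j] == 0
    if (!any(z)) next
    nz <- sum(z)
    p_min <- min(p[!z, j])
    # cap: delta = 0.65 * p_min * (1 - delta * nz) at equality
    delta <- min(0.5 / totals[j], 0.65 * p_min / (1 + 0.65 * p_min * nz))
    out[z, j] <- delta
    out[!z, j] <- p[!z, j] * (1 - delta * nz)
  }
  matrix_to_table(out)
}

#' Centred log-ratio transform
#'
#' Per sample, `clr(x)_i = ln(x_i) - mean_j ln(x_j)`, so each sample
#' column sums to zero.  Input must be strictly positive (run
#' [replace_zeros()] first on count data).
#'
#' @param composition A tibble (`feature_id` + sample columns) of
#'   strictly positive values.
#' @return A tibble of CLR values in the same shape.
#' @export
clr_transform <- function(composition) {
  if (names(composition)[1L] != "feature_id") {
    abort("expected a `feature_id` first column")
  }
  m <- as.matrix(composition[-1L])
  rownames(m) <- composition$feature_id
  if (any(m <= 0) || anyNA(m)) abort("CLR requires strictly positive input")
  lg <- log(m)
  matrix_to_table(sweep(lg, 2L, colMeans(lg), "-"))
}

#' Classify features as rare or abundant within each sample
#'
#' The rare biosphere is conventionally delimited by a within-sample
#' relative abundance cutoff of 0.01%: a feature is abundant in a sample
#' when its relative abundance exceeds `threshold` and rare when it is
#' below.  Exact equality with the cutoff falls in neither stated class
#' and is conservatively labelled rare (with a warning).
#'
#' @inheritParams filter_low_prevalence
#' @param threshold Relative-abundance cutoff; default `1e-4` (0.01%).
#' @return A long tibble with columns `feature_id`, `sample_id`,
#'   `rel_abundance`, `label` (`"rare"` or `"abundant"`).
#' @export
classify_rare_abundant <- function(table, threshold = 1e-4) {
  validate_abundance(table)
  if (nrow(table) == 0L) abort("empty table")
  m <- abund_matrix(table)
  rel <- sweep(m, 2L, pmax(colSums(m), 1), "/")
  if (any(rel == threshold)) {
    warn("relative abundance exactly at the cutoff classed as rare")
  }
  tidyr::pivot_longer(matrix_to_table(rel), -"feature_id",
    names_to = "sample_id", values_to = "rel_abundance"
  ) %>%
    dplyr::mutate(label = ifelse(.data$rel_abundance > threshold,
      "abundant", "rare"
    ))
}
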