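#' Dirichlet Monte-Carlo CLR instances
#'
#' Counts carry only relative information; to propagate the sampling
#' uncertainty of the underlying proportions, each sample's counts are
#' resampled `n_mc` times from a Dirichlet posterior (uniform prior 0.5
#' per feature) and every draw is CLR-transformed.  The same per-sample
#' draws serve all features (matrix-wise sampling).
#'
#' @param table_a,table_b Abundance tables over the same feature set
#'   (e.g. the unassembled and assembled fraction tables).
#' @param n_mc Number of Monte-Carlo instances (>= 2).
#' @param seed Integer seed; the instance stream is fully determined by it.
#' @return A list of `n_mc` CLR matrices (features x samples, samples of
#'   `table_a` first), with a `groups` attribute marking each sample's
#'   table of origin (`"A"`/`"B"`).
#' @export
mc_clr_instances <- function(table_a, table_b, n_mc = 128, seed = 1L) {
  if (n_mc < 2) abort("n_mc must be >= 2")
  counts <- bind_fraction_tables(table_a, table_b)
  set.seed(seed)
  nf <- nrow(counts)
  instances <- rep(list(matrix(0, nf, ncol(counts), dimnames = dimnames(counts))), n_mc)
  for (j in seq_len(ncol(counts))) {
    g <- matrix(rgamma(nf * n_mc, shape = counts[, j] + 0.5), nf, n_mc)
    lp <- log(sweep(g, 2L, colSums(g), "/"))
    clr <- sweep(lp, 2L, colMeans(lp), "-")
    for (i in seq_len(n_mc)) instances[[i]][, j] <- clr[, i]
  }
  attr(instances, "groups") <- rep(c("A", "B"), c(
    ncol(table_a) - 1L,
    ncol(table_b) - 1L
  ))
  instances
}

# align table_b's features to table_a's order and concatenate samples
bind_fraction_tables <- function(table_a, table_b) {
  validate_abundance(table_a)
  validate_abundance(table_b)
  if (!setequal(table_a$feature_id, table_b$feature_id)) {
    abort("table_a and table_b must share the same feature set")
  }
  overlap <- intersect(sample_ids(table_a), sample_ids(table_b))
  a <- abund_matrix(table_a)
  b <- abund_matrix(table_b)[table_a$feature_id, , drop = FALSE]
  if (length(overlap)) {
    colnames(a) <- paste0(colnames(a), ".A")
    colnames(b) <- paste0(colnames(b), ".B")
  }
  cbind(a, b)
}

#' Compositional differential abundance between two read fractions
#'
#' ALDEx2-style test: within every Monte-Carlo Dirichlet/CLR instance a
#' Welch t-test and a Wilcoxon rank-sum test compare the two groups per
#' feature; the expected p-value is the mean over instances, and a
#' feature is called significant when the two tests converge — both
#' expected p-values below `alpha`.  The effect size is the median over
#' instances of the between-group difference of median CLR values
#' (positive = enriched in `table_a`).  Benjamini-Hochberg adjusted
#' expected p-values are also reported; `use_bh = TRUE` makes them drive
#' the significance call (stricter than the raw-p convergence rule).
#'
#' @inheritParams mc_clr_instances
#' @param alpha Significance level for the convergence rule.
#' @param use_bh Use BH-adjusted expected p-values for the call.
#' @param name_a,name_b Labels used in the `direction` column; default to
#'   the tables' fraction attribute when present.
#' @return A tibble with one row per feature: `feature_id`,
#'   `expected_p_welch`, `expected_p_wilcoxon`, their BH-adjusted
#'   versions, `effect_clr`, `significant`, `direction` and
#'   `presence_class` (see [classify_presence()]).
#' @export
aldex_like_test <- function(table_a, table_b, n_mc = 128, alpha = 0.05,
                            seed = 1L, use_bh = FALSE,
                            name_a = NULL, name_b = NULL) {
  if (ncol(table_a) - 1L < 2 || ncol(table_b) - 1L < 2) {
    abort("each fraction needs at least 2 samples")
  }
  name_a <- name_a %||% attr(table_a, "fraction") %||% "A"
  name_b <- name_b %||% attr(table_b, "fraction") %||% "B"
  if (is.na(name_a)) name_a <- "A"
  if (is.na(name_b)) name_b <- "B"
  instances <- mc_clr_instances(table_a, table_b, n_mc = n_mc, seed = seed)
  res <- aldex_from_instances(instances, attr(instances, "groups"),
    alpha = alpha, use_bh = use_bh
  )
  presence <- classify_presence(table_a, table_b)
  res %>%
    dplyr::mutate(direction = dplyr::case_when(
      !.data$significant ~ "none",
      .data$effect_clr > 0 ~ name_a,
      TRUE ~ name_b
    )) %>%
    dplyr::left_join(presence, by = "feature_id")
}

# core test on precomputed CLR instances; groups is a vector of "A"/"B"
aldex_from_instances <- function(instances, groups, alpha = 0.05,
                                 use_bh = FALSE) {
  ia <- which(groups == "A")
  ib <- which(groups == "B")
  nf <- nrow(instances[[1L]])
  pw <- pt_mat <- eff <- matrix(NA_real_, nf, length(instances))
  degenerate <- FALSE
  for (i in seq_along(instances)) {
    x <- instances[[i]]
    w <- welch_rows(x[, ia, drop = FALSE], x[, ib, drop = FALSE])
    degenerate <- degenerate || w$degenerate
    pt_mat[, i] <- w$p
    pw[, i] <- wilcoxon_rows(x[, ia, drop = FALSE], x[, ib, drop = FALSE])
    eff[, i] <- apply(x[, ia, drop = FALSE], 1L, median) -
      apply(x[, ib, drop = FALSE], 1L, median)
  }
  if (degenerate) warn("constant CLR values in a group; Welch p set to 1 there")
  ep_welch <- rowMeans(pt_mat)
  ep_wil <- rowMeans(pw)
  out <- tibble(
    feature_id = rownames(instances[[1L]]),
    expected_p_welch = ep_welch,
    expected_p_wilcoxon = ep_wil,
    expected_p_welch_bh = p.adjust(ep_welch, "BH"),
    expected_p_wilcoxon_bh = p.adjust(ep_wil, "BH"),
    effect_clr = apply(eff, 1L, median)
  )
  if (use_bh) {
    out$significant <- out$expected_p_welch_bh < alpha &
      out$expected_p_wilcoxon_bh < alpha
  } else {
    out$significant <- out$expected_p_welch < alpha &
      out$expected_p_wilcoxon < alpha
  }
  out
}

# vectorised Welch t-test over rows; degenerate rows (zero pooled se) get p=1
welch_rows <- function(xa, xb) {
  n1 <- ncol(xa)
  n2 <- ncol(xb)
  m1 <- rowMeans(xa)
  m2 <- rowMeans(xb)
  v1 <- rowSums((xa - m1)^2) / (n1 - 1)
  v2 <- rowSums((xb - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  bad <- !is.finite(p)
  p[bad] <- 1
  list(p = p, degenerate = any(bad))
}

# vectorised two-sided Wilcoxon rank-sum p per row; exact when untied
# (as stats::wilcox.test for small n), normal approximation with tie
# correction and continuity correction otherwise
wilcoxon_rows <- function(xa, xb) {
  n1 <- ncol(xa)
  n2 <- ncol(xb)
  exact_ok <- n1 < 50 && n2 < 50
  vapply(seq_len(nrow(xa)), function(i) {
    r <- rank(c(xa[i, ], xb[i, ]))
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    if (exact_ok && all(ties == 1L)) {
      p <- if (w > n1 * n2 / 2) 1 - pwilcox(w - 1, n1, n2) else pwilcox(w, n1, n2)
      return(min(2 * p, 1))
    }
    z <- w - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) * ((n1 + n2 + 1) -
      sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    min(2 * min(pnorm(z), 1 - pnorm(z)), 1)
  }, numeric(1L))
}

#' Presence/absence classification between two fractions
#'
#' A feature is exclusive to a fraction when its total count is positive
#' there and zero in the other; features positive in both are shared and
#' features zero in both are absent.
#'
#' @inheritParams mc_clr_instances
#' @return A tibble `feature_id`, `presence_class` with values `only_a`,
#'   `only_b`, `shared`, `absent` (`a` = first argument).
#' @export
classify_presence <- function(table_a, table_b) {
  validate_abundance(table_a)
  validate_abundance(table_b)
  if (!setequal(table_a$feature_id, table_b$feature_id)) {
    abort("table_a and table_b must share the same feature universe")
  }
  ta <- rowSums(abund_matrix(table_a))
  tb <- rowSums(abund_matrix(table_b))[table_a$feature_id]
  tibble(
    feature_id = table_a$feature_id,
    presence_class = dplyr::case_when(
      ta > 0 & tb == 0 ~ "only_a",
      ta == 0 & tb > 0 ~ "only_b",
      ta > 0 & tb > 0 ~ "shared",
      TRUE ~ "absent"
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
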