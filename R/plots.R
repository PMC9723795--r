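#' Plot the lag-similarity curve
#'
#' Mean pairwise community similarity against the number of months
#' separating two samples; a seasonal community peaks at 12-month
#' multiples and dips at 6-month offsets.
#'
#' @param lag_tbl Tibble from [lag_similarity()], or several bound
#'   together with a distinguishing `fraction` column.
#' @return A ggplot object.
#' @export
plot_lag_similarity <- function(lag_tbl) {
  aes_args <- if ("fraction" %in% names(lag_tbl)) {
    ggplot2::aes(.data$lag_months, .data$mean_similarity,
      colour = .data$fraction
    )
  } else {
    ggplot2::aes(.data$lag_months, .data$mean_similarity)
  }
  ggplot2::ggplot(lag_tbl, aes_args) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 6)) +
    ggplot2::labs(
      x = "lag between samples (months)",
      y = "mean Bray-Curtis similarity", size = "pairs"
    ) +
    ggplot2::theme_minimal()
}

#' Effect-size versus significance plot for the fraction test
#'
#' @param results Tibble from [aldex_like_test()].
#' @param alpha Significance level used for colouring.
#' @return A ggplot object.
#' @export
plot_differential <- function(results, alpha = 0.05) {
  p_max <- pmax(results$expected_p_welch, results$expected_p_wilcoxon)
  df <- dplyr::mutate(results,
    neg_log_p = -log10(pmax(p_max, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$effect_clr, .data$neg_log_p,
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(
      x = "median CLR difference (A - B)",
      y = expression(-log[10] ~ "max expected p"),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot CAG temporal profiles
#'
#' @param profiles Long tibble from [cag_profiles()].
#' @param dates Optional metadata tibble (`sample_id`, `date`) to put
#'   calendar dates on the x axis.
#' @return A ggplot object.
#' @export
plot_cag_profiles <- function(profiles, dates = NULL) {
  df <- profiles
  if (!is.null(dates)) {
    df <- dplyr::left_join(df, dates[c("sample_id", "date")], by = "sample_id")
    x <- "date"
  } else {
    df$sample_index <- match(df$sample_id, unique(df$sample_id))
    x <- "sample_index"
  }
  ggplot2::ggplot(df, ggplot2::aes(
    .data[[x]], .data$value,
    colour = .data$cag_id, group = .data$cag_id
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "median member-gene abundance", colour = "CAG") +
    ggplot2::theme_minimal()
}

#' Plot the signed CAG-environment network
#'
#' Fruchterman-Reingold layout; grey edges are positive Spearman
#' correlations, red edges negative, mirroring the conventional
#' rendering of signed co-occurrence networks.
#'
#' @param object A `signed_network`.
#' @param clusters Optional tibble from [louvain_clusters()]; nodes are
#'   coloured by cluster when given.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signed_network
#' @export
autoplot.signed_network <- function(object, clusters = NULL, seed = 1L, ...) {
  g <- network_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(
    node = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L],
    type = igraph::V(g)$type
  )
  if (!is.null(clusters)) {
    nodes$cluster <- factor(clusters$cluster[match(nodes$node, clusters$node)])
  }
  edges <- object$edges %>%
    dplyr::left_join(nodes[c("node", "x", "y")], by = c(from = "node")) %>%
    dplyr::left_join(nodes[c("node", "x", "y")],
      by = c(to = "node"), suffix = c("", "end")
    ) %>%
    dplyr::mutate(sign = ifelse(.data$rho >= 0, "positive", "negative"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$sign, linewidth = abs(.data$rho)
      ), alpha = 0.7
    ) +
    ggplot2::scale_colour_manual(values = c(positive = "grey55", negative = "firebrick")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none")
  pt <- if (!is.null(clusters)) {
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, fill = .data$cluster, shape = .data$type),
      size = 3
    )
  } else {
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, shape = .data$type), size = 3, fill = "steelblue"
    )
  }
  p + pt +
    ggplot2::scale_shape_manual(values = c(cag = 21, env = 22)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
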