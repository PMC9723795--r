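#' Tidy a fitted PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A long tibble of loadings: `term` (feature id), `block`
#'   (`"otu"` weights / `"gene"` loadings), `component`, `value`.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  long <- function(mat, ids, block) {
    colnames(mat) <- seq_len(ncol(mat))
    as_tibble(mat) %>%
      dplyr::mutate(term = ids, block = block) %>%
      tidyr::pivot_longer(-c("term", "block"),
        names_to = "component", values_to = "value",
        names_transform = as.integer
      )
  }
  dplyr::bind_rows(
    long(x$x_weights, x$otu_ids, "otu"),
    long(x$y_loadings, x$gene_ids, "gene")
  ) %>% dplyr::select("term", "block", "component", "value")
}

#' @rdname tidy.pls_model
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_samples = length(x$sample_ids),
    n_otus = length(x$otu_ids),
    n_genes = length(x$gene_ids),
    sparse = !all(vapply(x$kept_x, length, integer(1L)) == length(x$otu_ids))
  )
}

#' Tidy a signed CAG-environment network
#'
#' @param x A `signed_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `rho`, `sign`).
#' @method tidy signed_network
#' @export
tidy.signed_network <- function(x, ...) {
  dplyr::mutate(x$edges, sign = ifelse(.data$rho >= 0, "positive", "negative"))
}

#' @rdname tidy.signed_network
#' @method glance signed_network
#' @export
glance.signed_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_negative = sum(x$edges$rho < 0),
    edge_threshold = x$edge_threshold
  )
}

#' Tidy an ANOSIM result
#'
#' @param x An `anosim_result`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p_value`, `n_perm`.
#' @method tidy anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n_perm = x$n_perm)
}

#' @rdname tidy.anosim_result
#' @method glance anosim_result
#' @export
glance.anosim_result <- function(x, ...) tidy(x)
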