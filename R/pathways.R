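#' Pathway coverage of a KO set
#'
#' Summarises the metabolic capability of a gene set (e.g. the KOs of a
#' network cluster) by the fraction of each pathway's KEGG orthologs it
#' contains.  A pathway is reported when at least `min_fraction` of its
#' KOs are present (inclusive: a pathway of 4 KOs with 1 present is
#' reported at the default 25%).  KOs absent from the map are ignored
#' with a logged count; a KO may belong to several pathways.
#'
#' @param ko_set Character vector of KO identifiers present in the set.
#' @param ko_to_pathway Tibble with columns `ko_id`, `pathway_id`.
#' @param min_fraction Reporting threshold on coverage (default 0.25).
#' @return A tibble `pathway_id`, `n_kos_in_pathway`, `n_kos_present`,
#'   `coverage`, `reported`, one row per pathway in the map.
#' @export
pathway_coverage <- function(ko_set, ko_to_pathway, min_fraction = 0.25) {
  if (!all(c("ko_id", "pathway_id") %in% names(ko_to_pathway)) ||
    nrow(ko_to_pathway) == 0L) {
    abort("ko_to_pathway must be a nonempty tibble with ko_id and pathway_id")
  }
  ko_set <- unique(ko_set)
  unknown <- setdiff(ko_set, ko_to_pathway$ko_id)
  if (length(unknown)) {
    inform(sprintf("%d KO id(s) absent from the map were ignored", length(unknown)))
  }
  ko_to_pathway %>%
    dplyr::distinct(.data$ko_id, .data$pathway_id) %>%
    dplyr::group_by(.data$pathway_id) %>%
    dplyr::summarise(
      n_kos_in_pathway = dplyr::n(),
      n_kos_present = sum(.data$ko_id %in% ko_set),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      coverage = .data$n_kos_present / .data$n_kos_in_pathway,
      reported = .data$coverage >= min_fraction
    ) %>%
    dplyr::arrange(dplyr::desc(.data$coverage), .data$pathway_id)
}

#' Read a two-column KO-to-pathway map
#'
#' @param path Tab-separated file with columns `ko_id`, `pathway_id`.
#' @return A tibble with those columns.
#' @export
read_ko_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("ko_id", "pathway_id") %in% names(x))) {
    abort(sprintf("%s must have columns ko_id and pathway_id", path))
  }
  x
}
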