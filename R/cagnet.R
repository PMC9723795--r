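#' Temporal abundance profiles of CAGs
#'
#' The temporal dynamics of a CAG are summarised, at each sampling date,
#' by the median abundance of its member genes (relative abundance
#' within the sample by default, raw counts with `normalize = FALSE`).
#'
#' @param cags CAG membership tibble (`cag_id`, `gene_id`, ...), e.g.
#'   from [extract_cags()] or [canopy_binning()].
#' @param gene_table Gene count abundance table.
#' @param normalize Use within-sample relative abundances (default).
#' @return A long tibble `cag_id`, `sample_id`, `value`.
#' @export
cag_profiles <- function(cags, gene_table, normalize = TRUE) {
  validate_abundance(gene_table)
  missing <- setdiff(cags$gene_id, gene_table$feature_id)
  if (length(missing)) {
    abort(paste0(
      "member gene(s) absent from the table: ",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  empty <- setdiff(unique(cags$cag_id), cags$cag_id[cags$gene_id %in% gene_table$feature_id])
  if (length(empty)) abort(paste0("CAG(s) with no genes in table: ", paste(empty, collapse = ", ")))
  m <- abund_matrix(gene_table)
  if (normalize) m <- sweep(m, 2L, pmax(colSums(m), 1), "/")
  cags %>%
    dplyr::distinct(.data$cag_id, .data$gene_id) %>%
    dplyr::group_by(.data$cag_id) %>%
    dplyr::reframe(
      sample_id = colnames(m),
      value = unname(apply(m[.data$gene_id, , drop = FALSE], 2L, median))
    )
}

#' Signed Spearman correlation network of CAGs and environment
#'
#' Every pair of series (CAG median profiles and environmental
#' covariates, treated identically) gets a Spearman rank correlation
#' with average-rank ties; an edge is retained only when
#' `rho > edge_threshold` or `rho < -edge_threshold` (strict, so a
#' correlation exactly at the threshold is dropped).  Constant series
#' have undefined correlations and are dropped with a warning.
#'
#' @param profiles Long profile tibble from [cag_profiles()].
#' @param env Optional metadata tibble (`sample_id` plus numeric
#'   environmental columns such as temperature, oxygen, nitrite).
#' @param edge_threshold Absolute correlation threshold (default 0.8).
#' @return A `signed_network`: list with `nodes` (tibble `node`, `type`)
#'   and `edges` (tibble `from`, `to`, `rho`).
#' @export
spearman_network <- function(profiles, env = NULL, edge_threshold = 0.8) {
  wide <- tidyr::pivot_wider(profiles,
    names_from = "sample_id", values_from = "value"
  )
  mat <- as.matrix(wide[-1L])
  rownames(mat) <- wide[[1L]]
  types <- rep("cag", nrow(mat))
  if (!is.null(env)) {
    ev <- env[match(colnames(mat), env$sample_id), , drop = FALSE]
    if (anyNA(ev$sample_id)) abort("env is missing some profile samples")
    num <- vapply(ev, is.numeric, logical(1L)) & names(ev) != "sample_id"
    emat <- t(as.matrix(ev[num]))
    colnames(emat) <- colnames(mat)
    mat <- rbind(mat, emat)
    types <- c(types, rep("env", sum(num)))
  }
  if (ncol(mat) < 3L) abort("need at least 3 shared dates")
  const <- apply(mat, 1L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warn(paste0(
      "constant series dropped: ",
      paste(rownames(mat)[const], collapse = ", ")
    ))
    types <- types[!const]
    mat <- mat[!const, , drop = FALSE]
  }
  rho <- cor(t(mat), method = "spearman")
  idx <- which(upper.tri(rho) & abs(rho) > edge_threshold, arr.ind = TRUE)
  edges <- tibble(
    from = rownames(rho)[idx[, 1L]],
    to = rownames(rho)[idx[, 2L]],
    rho = rho[idx]
  ) %>% dplyr::arrange(.data$from, .data$to)
  structure(list(
    nodes = tibble(node = rownames(mat), type = types),
    edges = edges, edge_threshold = edge_threshold
  ), class = "signed_network")
}

#' Collapse redundant CAGs
#'
#' Two CAGs are redundant when their full-profile Spearman correlation
#' exceeds `corr_cut`, they carry the same taxonomy label, and (when an
#' AAI matrix is supplied) their amino-acid identity exceeds `aai_cut`
#' percent.  Redundancy groups are the transitive closure of this
#' pairwise predicate; the representative of each group is the CAG with
#' the most member genes (ties by id).
#'
#' @param cags CAG membership tibble (`cag_id`, `gene_id`).
#' @param profiles Long profile tibble from [cag_profiles()].
#' @param taxonomy Tibble `cag_id`, `taxonomy` covering all CAGs.
#' @param aai Optional symmetric CAG x CAG AAI percentage matrix with
#'   dimnames; when absent the AAI condition is skipped (a notice is
#'   logged).
#' @param corr_cut,aai_cut Strict thresholds (defaults 0.95 and 95).
#' @return A tibble `cag_id`, `representative`, `redundant`; the
#'   non-redundant set is `dplyr::filter(out, !redundant)`.
#' @export
remove_redundant <- function(cags, profiles, taxonomy, aai = NULL,
                             corr_cut = 0.95, aai_cut = 95) {
  ids <- sort(unique(cags$cag_id))
  tax <- taxonomy$taxonomy[match(ids, taxonomy$cag_id)]
  if (anyNA(tax)) abort("taxonomy labels required for all CAGs")
  wide <- tidyr::pivot_wider(profiles, names_from = "sample_id", values_from = "value")
  mat <- as.matrix(wide[-1L])
  rownames(mat) <- wide[[1L]]
  mat <- mat[ids, , drop = FALSE]
  rho <- suppressWarnings(cor(t(mat), method = "spearman"))
  rho[!is.finite(rho)] <- 0
  same_tax <- outer(tax, tax, "==")
  pred <- rho > corr_cut & same_tax
  if (is.null(aai)) {
    inform("no AAI matrix supplied; amino-acid identity condition skipped")
  } else {
    pred <- pred & aai[ids, ids] > aai_cut
  }
  diag(pred) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(pred, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- cags %>% dplyr::count(.data$cag_id)
  n_genes <- sizes$n[match(ids, sizes$cag_id)]
  rep_of <- vapply(split(seq_along(ids), comp), function(members) {
    ids[members][order(-n_genes[members], ids[members])[1L]]
  }, character(1L))
  representative <- unname(rep_of[as.character(comp)])
  tibble(
    cag_id = ids,
    representative = representative,
    redundant = ids != representative
  )
}

# signed network -> igraph with |rho| weight and rho/sign attributes
network_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    transform(network$edges, weight = abs(rho), sign = sign(rho)),
    directed = FALSE, vertices = network$nodes
  )
  g
}

#' Louvain clusters of the signed network
#'
#' Greedy modularity optimisation on `|rho|` edge weights (modularity is
#' undefined for negative weights; the sign is kept on the edges for
#' display and for [expected_influence()]).  Isolated nodes form their
#' own singleton clusters.  Deterministic given `seed`.
#'
#' @param network A `signed_network`.
#' @param seed Integer seed for the Louvain refinement order.
#' @return A tibble `node`, `cluster` (integer ids).
#' @export
louvain_clusters <- function(network, seed = 1L) {
  if (nrow(network$nodes) == 0L) abort("empty network")
  g <- network_igraph(network)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  tibble(
    node = igraph::V(g)$name,
    cluster = as.integer(igraph::membership(cl))
  )
}

#' Expected-influence keystone ranking
#'
#' One-step expected influence of a node is the sum of the signed
#' correlations on its incident edges (negative edges subtract), the
#' centrality used to rank keystone taxa in signed association networks;
#' strength (sum of `|rho|`) is reported alongside.
#'
#' @param network A `signed_network`.
#' @return A tibble `node`, `expected_influence`, `strength`, sorted by
#'   decreasing expected influence (ties by node id).
#' @export
expected_influence <- function(network) {
  if (nrow(network$nodes) == 0L) abort("empty network")
  ei <- setNames(rep(0, nrow(network$nodes)), network$nodes$node)
  st <- ei
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    ei[e$from] <- ei[e$from] + e$rho
    ei[e$to] <- ei[e$to] + e$rho
    st[e$from] <- st[e$from] + abs(e$rho)
    st[e$to] <- st[e$to] + abs(e$rho)
  }
  tibble(
    node = names(ei), expected_influence = unname(ei),
    strength = unname(st)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$expected_influence), .data$node)
}

#' Export a signed network
#'
#' Writes GraphML (with `rho`, `sign`, and optional `cluster` and
#' `expected_influence` vertex attributes) or a tab-separated edge list.
#'
#' @param network A `signed_network`.
#' @param path Output file.
#' @param clusters Optional tibble from [louvain_clusters()].
#' @param centrality Optional tibble from [expected_influence()].
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, clusters = NULL, centrality = NULL,
                          format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    readr::write_tsv(network$edges, path, progress = FALSE)
    return(invisible(path))
  }
  g <- network_igraph(network)
  if (!is.null(clusters)) {
    igraph::V(g)$cluster <- clusters$cluster[match(igraph::V(g)$name, clusters$node)]
  }
  if (!is.null(centrality)) {
    igraph::V(g)$expected_influence <-
      centrality$expected_influence[match(igraph::V(g)$name, centrality$node)]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
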