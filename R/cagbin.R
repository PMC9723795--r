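#' Partial least squares regression of gene profiles on OTU profiles
#'
#' Fits a NIPALS PLS regression predicting the gene (protein) CLR table
#' from the OTU CLR table across shared samples.  Both blocks are
#' column-centred and unit-variance scaled.  With `keep_x` set, the
#' X-weight vector of each component is soft-thresholded so that only the
#' stated number of OTUs load on it (sparse PLS).  Y is deflated by the
#' X-scores (regression mode), so successive score vectors are mutually
#' orthogonal.
#'
#' @param otu_clr,gene_clr CLR tables (tibbles, `feature_id` + sample
#'   columns) over the same samples.
#' @param n_components Number of latent components (>= 1, at most
#'   `min(samples - 1, otus)`).
#' @param keep_x Optional number of OTUs retained per component (scalar
#'   or vector of length `n_components`); `NULL` fits dense PLS.
#' @param tol,max_iter NIPALS convergence controls.
#' @return A `pls_model` with `x_scores`, `x_weights`, `x_loadings`,
#'   `y_loadings`, `kept_x` and the dimension labels.  If the input rank
#'   is exhausted, fewer components are returned with a warning.
#' @export
fit_pls <- function(otu_clr, gene_clr, n_components = 2, keep_x = NULL,
                    tol = 1e-9, max_iter = 500L) {
  X <- t(clr_matrix(otu_clr))
  Y <- t(clr_matrix(gene_clr))
  if (!identical(rownames(X), rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y))) {
      abort("otu_clr and gene_clr must cover the same samples")
    }
    Y <- Y[rownames(X), , drop = FALSE]
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n_components < 1) abort("n_components must be >= 1")
  if (n_components > min(n - 1, p)) {
    abort("n_components must not exceed min(samples - 1, otus)")
  }
  if (!is.null(keep_x)) keep_x <- rep_len(as.integer(keep_x), n_components)

  scale_block <- function(M) {
    M <- sweep(M, 2L, colMeans(M), "-")
    s <- apply(M, 2L, sd)
    s[s == 0 | !is.finite(s)] <- 1
    sweep(M, 2L, s, "/")
  }
  Xd <- scale_block(X)
  Yd <- scale_block(Y)
  x0norm <- sum(Xd^2)

  Tm <- matrix(0, n, n_components)
  Wm <- matrix(0, p, n_components)
  Pm <- matrix(0, p, n_components)
  Cm <- matrix(0, ncol(Y), n_components)
  kept <- vector("list", n_components)
  h_done <- 0L
  for (h in seq_len(n_components)) {
    if (sum(Xd^2) < tol * max(x0norm, 1) || sum(Yd^2) < tol) {
      warn(sprintf("input rank exhausted; returning %d component(s)", h_done))
      break
    }
    u <- Yd[, which.max(apply(Yd, 2L, stats::var))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u))
      if (!is.null(keep_x) && keep_x[h] < p) {
        lambda <- sort(abs(w), decreasing = TRUE)[keep_x[h] + 1L]
        w <- sign(w) * pmax(abs(w) - lambda, 0)
      }
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tvec <- drop(Xd %*% w)
      cvec <- drop(crossprod(Yd, tvec)) / sum(tvec^2)
      u <- drop(Yd %*% cvec) / sum(cvec^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    if (sqrt(sum(w^2)) < tol || sum(tvec^2) < tol) {
      warn(sprintf("degenerate component; returning %d component(s)", h_done))
      break
    }
    pvec <- drop(crossprod(Xd, tvec)) / sum(tvec^2)
    Xd <- Xd - tcrossprod(tvec, pvec)
    Yd <- Yd - tcrossprod(tvec, cvec) # regression-mode deflation
    Tm[, h] <- tvec
    Wm[, h] <- w
    Pm[, h] <- pvec
    Cm[, h] <- cvec
    kept[[h]] <- colnames(X)[w != 0]
    h_done <- h
  }
  idx <- seq_len(h_done)
  structure(list(
    n_components = h_done,
    x_scores = Tm[, idx, drop = FALSE],
    x_weights = Wm[, idx, drop = FALSE],
    x_loadings = Pm[, idx, drop = FALSE],
    y_loadings = Cm[, idx, drop = FALSE],
    kept_x = kept[idx],
    otu_ids = colnames(X), gene_ids = colnames(Y),
    sample_ids = rownames(X)
  ), class = "pls_model")
}

clr_matrix <- function(x) {
  if (names(x)[1L] != "feature_id") abort("expected a `feature_id` first column")
  m <- as.matrix(x[-1L])
  rownames(m) <- x$feature_id
  m
}

#' Predict the gene block from a fitted PLS model (training samples)
#'
#' @param object A `pls_model`.
#' @param n_components Number of components to use (default all).
#' @param ... Unused.
#' @return Fitted Y matrix in the scaled coordinate system
#'   (samples x genes).
#' @export
predict_pls <- function(object, n_components = object$n_components, ...) {
  idx <- seq_len(n_components)
  object$x_scores[, idx, drop = FALSE] %*%
    t(object$y_loadings[, idx, drop = FALSE])
}

#' PLS relevance weights between OTUs and genes
#'
#' The bipartite association between OTU `o` and gene `g` is
#' reconstructed from the shared latent components as
#' `w(o, g) = sum_h cor(x_o, t_h) * cor(y_g, t_h)` where `t_h` are the
#' X-score vectors — the standard relevance-network weight for PLS.
#' Values are clipped to `[-1, 1]`.
#'
#' @inheritParams fit_pls
#' @param model A fitted `pls_model`.
#' @return An OTUs x genes numeric matrix of weights.
#' @export
relevance_weights <- function(model, otu_clr, gene_clr) {
  stopifnot(inherits(model, "pls_model"))
  X <- t(clr_matrix(otu_clr))[model$sample_ids, , drop = FALSE]
  Y <- t(clr_matrix(gene_clr))[model$sample_ids, , drop = FALSE]
  cx <- safe_cor(X, model$x_scores)
  cy <- safe_cor(Y, model$x_scores)
  w <- cx %*% t(cy)
  pmin(pmax(w, -1), 1)
}

# correlation with zero-variance columns mapped to 0 (with a warning)
safe_cor <- function(M, scores) {
  sds <- apply(M, 2L, sd)
  out <- matrix(0, ncol(M), ncol(scores), dimnames = list(colnames(M), NULL))
  if (any(sds == 0)) warn("zero-variance feature(s); correlations set to 0")
  ok <- sds > 0
  if (any(ok)) out[ok, ] <- cor(M[, ok, drop = FALSE], scores)
  out
}

#' Build the thresholded OTU-gene bipartite graph
#'
#' Keeps edges whose relevance weight is at least `threshold` (signed
#' comparison by default: strong negative associations are discarded,
#' since a CAG groups positively covarying genes; set
#' `mode = "absolute"` to threshold on `|weight|`), then removes orphan
#' vertices.
#'
#' @param weights OTUs x genes weight matrix from [relevance_weights()].
#' @param threshold Edge retention threshold (default 0.8).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return A `bipartite_graph`: list with an `edges` tibble
#'   (`otu`, `gene`, `weight`) and the retained `otu_nodes`/`gene_nodes`.
#' @export
build_bipartite <- function(weights, threshold = 0.8,
                            mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (any(!is.finite(weights))) abort("weights must be finite")
  keep <- if (mode == "signed") weights >= threshold else abs(weights) >= threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble(
    otu = rownames(weights)[idx[, 1L]],
    gene = colnames(weights)[idx[, 2L]],
    weight = weights[idx]
  ) %>% dplyr::arrange(.data$otu, .data$gene)
  structure(list(
    edges = edges,
    otu_nodes = sort(unique(edges$otu)),
    gene_nodes = sort(unique(edges$gene)),
    threshold = threshold, mode = mode
  ), class = "bipartite_graph")
}

#' Extract co-abundance gene groups from the bipartite graph
#'
#' A CAG gathers all genes linked to one OTU (its anchor).  In `unique`
#' mode (default) each gene joins only the OTU it links to with maximal
#' weight, so the CAGs partition the binned genes; ties are broken by
#' lexicographic OTU id (logged).  In `multi` mode a gene may belong to
#' every CAG it is linked to.
#'
#' @param graph A `bipartite_graph`.
#' @param assignment `"unique"` or `"multi"`.
#' @return A tibble with one row per CAG membership: `cag_id` (equal to
#'   the anchor OTU id), `anchor_otu`, `gene_id`, `weight`,
#'   `source = "pls"`.
#' @export
extract_cags <- function(graph, assignment = c("unique", "multi")) {
  assignment <- match.arg(assignment)
  edges <- graph$edges
  if (nrow(edges) == 0L) {
    return(tibble(
      cag_id = character(), anchor_otu = character(),
      gene_id = character(), weight = double(), source = character()
    ))
  }
  if (assignment == "unique") {
    ties <- edges %>%
      dplyr::group_by(.data$gene) %>%
      dplyr::filter(sum(.data$weight == max(.data$weight)) > 1L) %>%
      dplyr::ungroup()
    if (nrow(ties)) {
      inform(sprintf(
        "%d gene(s) tied between OTUs; assigned to the lexicographically first",
        length(unique(ties$gene))
      ))
    }
    edges <- edges %>%
      dplyr::group_by(.data$gene) %>%
      dplyr::arrange(dplyr::desc(.data$weight), .data$otu, .by_group = TRUE) %>%
      dplyr::slice(1L) %>%
      dplyr::ungroup()
  }
  edges %>%
    dplyr::transmute(
      cag_id = .data$otu, anchor_otu = .data$otu,
      gene_id = .data$gene, weight = .data$weight, source = "pls"
    ) %>%
    dplyr::arrange(.data$cag_id, .data$gene_id)
}

#' Canopy clustering of gene abundance profiles
#'
#' Correlation-canopy alternative to the PLS binning: genes are visited
#' in order of decreasing total abundance; each unassigned gene seeds a
#' canopy that absorbs the unassigned genes whose Pearson correlation to
#' the canopy centroid (mean profile) is at least `seed_corr`, the
#' centroid being recomputed until membership stabilises.  Canopies whose
#' centroids correlate at `merge_corr` or more are then merged
#' (transitively).  Deterministic given the visiting order.
#'
#' @param gene_table An abundance table of gene counts.
#' @param seed_corr Centroid-membership correlation threshold.
#' @param merge_corr Canopy-merging correlation threshold.
#' @param max_iter Maximum centroid refinement passes per canopy.
#' @return A tibble `cag_id`, `anchor_otu` (`NA`), `gene_id`,
#'   `source = "canopy"`.
#' @export
canopy_binning <- function(gene_table, seed_corr = 0.9, merge_corr = 0.97,
                           max_iter = 25L) {
  validate_abundance(gene_table, counts = FALSE)
  m <- abund_matrix(gene_table)
  if (ncol(m) < 3L) abort("canopy binning needs >= 3 samples")
  prof <- sweep(m, 2L, pmax(colSums(m), 1), "/")
  ord <- order(-rowSums(m), rownames(m))
  assigned <- setNames(rep(NA_integer_, nrow(prof)), rownames(prof))
  centroids <- list()
  k <- 0L
  cor0 <- function(a, B) {
    r <- suppressWarnings(cor(a, t(B)))
    r[!is.finite(r)] <- 0
    drop(r)
  }
  for (g in ord) {
    if (!is.na(assigned[g])) next
    k <- k + 1L
    members <- g
    centroid <- prof[g, ]
    for (it in seq_len(max_iter)) {
      cand <- union(which(is.na(assigned)), members)
      r <- cor0(centroid, prof[cand, , drop = FALSE])
      new_members <- cand[r >= seed_corr]
      if (!length(new_members)) new_members <- g
      if (setequal(new_members, members)) break
      members <- new_members
      centroid <- colMeans(prof[members, , drop = FALSE])
    }
    assigned[members] <- k
    centroids[[k]] <- colMeans(prof[members, , drop = FALSE])
  }
  # merge canopies with near-identical centroids (transitive closure)
  if (k > 1L) {
    cm <- do.call(rbind, centroids)
    r <- suppressWarnings(cor(t(cm)))
    r[!is.finite(r)] <- 0
    adj <- r >= merge_corr
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    assigned[] <- comp[assigned]
  }
  labels <- sprintf("canopy_%03d", match(assigned, sort(unique(assigned))))
  tibble(
    cag_id = labels, anchor_otu = NA_character_,
    gene_id = names(assigned), source = "canopy"
  ) %>% dplyr::arrange(.data$cag_id, .data$gene_id)
}

#' Run the full PLS-bipartite CAG binning pipeline
#'
#' Convenience wrapper: zero replacement and CLR on both count tables,
#' PLS fit, relevance weights, bipartite thresholding and CAG
#' extraction.
#'
#' @param otu_table,gene_table Count abundance tables over shared samples.
#' @inheritParams fit_pls
#' @inheritParams build_bipartite
#' @inheritParams extract_cags
#' @return The CAG membership tibble from [extract_cags()].
#' @export
bin_cags_pls <- function(otu_table, gene_table, n_components = 2,
                         keep_x = NULL, threshold = 0.8,
                         mode = c("signed", "absolute"),
                         assignment = c("unique", "multi")) {
  otu_clr <- clr_transform(replace_zeros(otu_table))
  gene_clr <- clr_transform(replace_zeros(gene_table))
  model <- fit_pls(otu_clr, gene_clr, n_components = n_components, keep_x = keep_x)
  w <- relevance_weights(model, otu_clr, gene_clr)
  graph <- build_bipartite(w, threshold = threshold, mode = match.arg(mode))
  extract_cags(graph, assignment = match.arg(assignment))
}
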