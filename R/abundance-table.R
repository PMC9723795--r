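#' Abundance tables
#'
#' An abundance table is a tibble whose first column, `feature_id`, holds
#' unique feature identifiers (OTUs, protein clusters or KEGG orthologs)
#' and whose remaining columns hold non-negative integer counts, one
#' column per sample.  All pipeline functions accept and return tables in
#' this shape so that calls chain with the pipe.  `abundance_table()`
#' validates a data frame and attaches the feature kind and the read
#' fraction it derives from as attributes.
#'
#' @param x A data frame with a `feature_id` character column followed by
#'   one numeric column per sample.
#' @param feature_kind One of `"otu"`, `"protein"`, `"ko"`, or `NA`.
#' @param fraction One of `"assembled"`, `"unassembled"`, or `NA`.
#'
#' @return A tibble of class `abund_tbl` with attributes `feature_kind`
#'   and `fraction`.
#' @export
#' @examples
#' abundance_table(
#'   tibble::tibble(feature_id = c("g1", "g2"), s1 = c(3L, 0L), s2 = c(1L, 5L)),
#'   feature_kind = "protein"
#' )
abundance_table <- function(x, feature_kind = NA_character_,
                            fraction = NA_character_) {
  x <- as_tibble(x)
  validate_abundance(x)
  if (!is.na(feature_kind)) {
    feature_kind <- match.arg(feature_kind, c("otu", "protein", "ko"))
  }
  if (!is.na(fraction)) {
    fraction <- match.arg(fraction, c("assembled", "unassembled"))
  }
  structure(x,
    class = c("abund_tbl", class(x)),
    feature_kind = feature_kind, fraction = fraction
  )
}

validate_abundance <- function(x, counts = TRUE) {
  if (ncol(x) < 2L || names(x)[1L] != "feature_id") {
    abort("an abundance table needs a `feature_id` first column and >= 1 sample column")
  }
  dup <- x$feature_id[duplicated(x$feature_id)]
  if (length(dup)) {
    abort(paste0("duplicate feature id(s): ", paste(unique(dup), collapse = ", ")))
  }
  dup_s <- names(x)[-1L][duplicated(names(x)[-1L])]
  if (length(dup_s)) {
    abort(paste0("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  vals <- as.matrix(x[-1L])
  if (!is.numeric(vals) || anyNA(vals)) {
    abort("abundance cells must be numeric and non-missing")
  }
  if (counts && (any(vals < 0) || any(vals != trunc(vals)))) {
    bad <- which(vals < 0 | vals != trunc(vals), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "counts must be non-negative integers (feature %s, sample %s)",
      x$feature_id[bad[1L]], names(x)[-1L][bad[2L]]
    ))
  }
  invisible(x)
}

# features x samples numeric matrix with dimnames, from a table tibble
abund_matrix <- function(x) {
  m <- as.matrix(x[-1L])
  rownames(m) <- x$feature_id
  m
}

# inverse of abund_matrix
matrix_to_table <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
}

sample_ids <- function(x) names(x)[-1L]

#' Read and write abundance tables
#'
#' Tab-separated format: header `feature_id` then one column per sample,
#' integer cells.  `read_abundance_table()` validates the header, cell
#' types and id uniqueness, reporting the offending row or column;
#' `write_abundance_table()` round-trips losslessly.
#'
#' @param path File path.
#' @param table An abundance table tibble.
#' @inheritParams abundance_table
#' @return `read_abundance_table()` returns an [abundance_table()];
#'   `write_abundance_table()` returns `path` invisibly.
#' @export
read_abundance_table <- function(path, feature_kind = NA_character_,
                                 fraction = NA_character_) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2L || names(x)[1L] != "feature_id") {
    abort(sprintf("malformed header in %s: first column must be `feature_id`", path))
  }
  for (j in seq(2L, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v) || anyNA(v) || any(v != trunc(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))) | v != trunc(v))[1L]
      abort(sprintf(
        "non-integer cell in %s at row %d, column %s", path,
        if (is.na(bad)) NA_integer_ else bad, names(x)[j]
      ))
    }
    x[[j]] <- as.integer(v)
  }
  abundance_table(x, feature_kind = feature_kind, fraction = fraction)
}

#' @rdname read_abundance_table
#' @export
write_abundance_table <- function(table, path) {
  validate_abundance(table)
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}
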