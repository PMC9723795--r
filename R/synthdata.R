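#' Configuration for the synthetic time-series generator
#'
#' Describes a monthly marine metagenomic survey: seasonally oscillating
#' OTUs, co-abundance gene groups (CAGs) riding on anchor OTUs, a pool of
#' aseasonal background ("housekeeping-like") genes, a long tail of rare
#' OTUs, and environmental covariates phase-locked to the annual cycle.
#' Defaults emulate a three-year, 40-sample monthly series.
#'
#' @param n_samples Number of monthly samples (default 40).
#' @param n_otus Number of OTUs.
#' @param n_cags Number of planted CAGs (anchored on distinct OTUs).
#' @param genes_per_cag Length-2 integer range; each CAG's gene count is
#'   drawn uniformly from it.
#' @param n_background_genes Genes belonging to no CAG; their expected
#'   abundance is aseasonal.
#' @param seasonal_amplitude Amplitude of the log-scale seasonal sinusoid.
#' @param seasonal_period Period in months (default 12).
#' @param noise_sd SD of lognormal multiplicative noise applied to gene
#'   expected abundances before count sampling.
#' @param library_size Reads per sample per table (multinomial total).
#' @param rare_fraction Proportion of OTUs given mean relative abundance
#'   below the 0.01% rare cutoff.
#' @param coverage_threshold Default anchor relative-abundance cutoff
#'   used by [assign_fractions()].
#' @param seed Master seed; every random stream derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 40, n_otus = 60, n_cags = 8,
                             genes_per_cag = c(20L, 40L),
                             n_background_genes = 150,
                             seasonal_amplitude = 1, seasonal_period = 12,
                             noise_sd = 0.2, library_size = 1e5,
                             rare_fraction = 0.3,
                             coverage_threshold = 1e-3, seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_otus = as.integer(n_otus),
    n_cags = as.integer(n_cags),
    genes_per_cag = as.integer(rep_len(genes_per_cag, 2L)),
    n_background_genes = as.integer(n_background_genes),
    seasonal_amplitude = seasonal_amplitude,
    seasonal_period = seasonal_period, noise_sd = noise_sd,
    library_size = as.integer(library_size),
    rare_fraction = rare_fraction,
    coverage_threshold = coverage_threshold, seed = as.integer(seed)
  )
  with(cfg, {
    if (n_samples < 1 || n_otus < 1 || n_cags < 1 || library_size < 1 ||
      any(genes_per_cag < 1)) {
      abort("all counts must be >= 1")
    }
    if (n_cags > n_otus) abort("n_cags must not exceed n_otus")
    if (rare_fraction < 0 || rare_fraction > 1) {
      abort("rare_fraction must lie in [0, 1]")
    }
    if (seasonal_period <= 0) abort("seasonal_period must be positive")
    if (seasonal_amplitude < 0 || noise_sd < 0) {
      abort("seasonal_amplitude and noise_sd must be >= 0")
    }
  })
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic metagenomic time series
#'
#' Latent model: OTU `i` has expected abundance
#' `exp(mu_i + A * sin(2*pi*(t - phase_i)/period))` at month `t`.  Each
#' CAG gene's expected abundance is its anchor OTU's expected abundance
#' times a fixed per-gene factor; lognormal noise (`noise_sd`) perturbs
#' the gene expectations before counts are drawn.  Counts are multinomial
#' per sample at `library_size` (per table), so sample sums are exact.
#' Anchor OTUs occupy staggered seasonal niches (phases evenly spaced
#' around the year with small jitter); non-anchor OTUs get uniform random
#' phases; background genes are aseasonal.  Roughly half the CAGs are
#' anchored on rare OTUs, so their genes fall almost entirely in the
#' unassembled fraction under the coverage proxy of [assign_fractions()].
#'
#' @param config A [generator_config()].
#' @return A `synthetic_dataset` list with elements `otu_table`,
#'   `gene_table` (abundance tables), `metadata` (tibble: `sample_id`,
#'   `date`, `temperature`, `oxygen`, `nitrite`), `otu_expected` and
#'   `gene_expected` (noise-free expected abundance tibbles, arbitrary
#'   units: each CAG gene's row is an exact scalar multiple of its
#'   anchor's), and `truth` (tibbles `genes`, `cags`, `otus`).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  P <- config$seasonal_period
  A <- config$seasonal_amplitude
  tt <- seq_len(config$n_samples) - 1

  otu_ids <- sprintf("otu_%03d", seq_len(config$n_otus))
  n_rare <- round(config$rare_fraction * config$n_otus)
  rare_idx <- sort(sample.int(config$n_otus, n_rare))
  status <- ifelse(seq_len(config$n_otus) %in% rare_idx, "rare", "abundant")

  # anchors: ~half rare (if available), rest abundant; staggered phases
  n_rare_anchor <- min(floor(config$n_cags / 2), n_rare)
  n_ab_anchor <- config$n_cags - n_rare_anchor
  ab_pool <- which(status == "abundant")
  if (n_ab_anchor > length(ab_pool)) {
    n_ab_anchor <- length(ab_pool)
    n_rare_anchor <- config$n_cags - n_ab_anchor
  }
  anchor_idx <- c(
    sample(rare_idx, n_rare_anchor),
    sample(ab_pool, n_ab_anchor)
  )
  phase <- runif(config$n_otus, 0, P)
  phase[anchor_idx] <- (seq_len(config$n_cags) - 1) * P / config$n_cags +
    rnorm(config$n_cags, 0, P / 60)

  mu <- rnorm(config$n_otus, 0, 1)
  E_otu <- t(vapply(
    seq_len(config$n_otus),
    function(i) exp(mu[i]) * exp(A * sin(2 * pi * (tt - phase[i]) / P)),
    numeric(config$n_samples)
  ))
  # rescale rare OTUs so mean relative abundance sits below the 0.01% cutoff
  if (n_rare > 0) {
    total_ab <- mean(colSums(E_otu[status == "abundant", , drop = FALSE]))
    if (!is.finite(total_ab) || total_ab == 0) total_ab <- 1
    target <- exp(runif(n_rare, log(1e-6), log(3e-5)))
    for (k in seq_len(n_rare)) {
      i <- rare_idx[k]
      E_otu[i, ] <- E_otu[i, ] * target[k] * total_ab / mean(E_otu[i, ])
    }
  }
  rownames(E_otu) <- otu_ids
  colnames(E_otu) <- sprintf("s%02d", seq_len(config$n_samples))

  # CAG membership and gene expectations
  cag_ids <- sprintf("cag_%02d", seq_len(config$n_cags))
  size_range <- seq(config$genes_per_cag[1], config$genes_per_cag[2])
  sizes <- size_range[sample.int(length(size_range), config$n_cags, replace = TRUE)]
  gene_cag <- rep(cag_ids, sizes)
  gene_anchor <- rep(anchor_idx, sizes)
  n_cag_genes <- length(gene_cag)
  # gene factor folds in 1/mean(anchor profile): the gene table is its own
  # composition, so a rare taxon's gene pool still carries observable mass
  # while staying an exact scalar multiple of the anchor profile
  gene_factor <- exp(rnorm(n_cag_genes, 0, 0.5)) /
    rowMeans(E_otu)[gene_anchor]
  E_gene <- E_otu[gene_anchor, , drop = FALSE] * gene_factor
  if (config$n_background_genes > 0) {
    bg_mu <- rnorm(config$n_background_genes, 0, 1)
    E_bg <- matrix(exp(bg_mu),
      nrow = config$n_background_genes,
      ncol = config$n_samples
    )
    E_gene <- rbind(E_gene, E_bg)
    gene_cag <- c(gene_cag, rep(NA_character_, config$n_background_genes))
    gene_anchor <- c(gene_anchor, rep(NA_integer_, config$n_background_genes))
  }
  gene_ids <- sprintf("gene_%04d", seq_len(nrow(E_gene)))
  rownames(E_gene) <- gene_ids
  colnames(E_gene) <- colnames(E_otu)

  noisy <- E_gene
  if (config$noise_sd > 0) {
    noisy <- E_gene * exp(matrix(
      rnorm(length(E_gene), 0, config$noise_sd),
      nrow(E_gene)
    ))
  }

  draw_counts <- function(E) {
    counts <- vapply(
      seq_len(ncol(E)),
      function(j) rmultinom(1L, config$library_size, E[, j])[, 1L],
      integer(nrow(E))
    )
    dimnames(counts) <- dimnames(E)
    counts
  }
  otu_counts <- draw_counts(E_otu)
  gene_counts <- draw_counts(noisy)

  dates <- seq(as.Date("2012-01-15"), by = "month", length.out = config$n_samples)
  metadata <- tibble(
    sample_id = colnames(E_otu),
    date = dates,
    temperature = 15 + 6 * sin(2 * pi * (tt - 4) / P) + rnorm(config$n_samples, 0, 0.5),
    oxygen = 250 - 30 * sin(2 * pi * (tt - 4) / P) + rnorm(config$n_samples, 0, 5),
    nitrite = pmax(0.02, 0.2 + 0.15 * sin(2 * pi * (tt - 10) / P) +
      rnorm(config$n_samples, 0, 0.02))
  )

  structure(list(
    otu_table = abundance_table(matrix_to_table(otu_counts), feature_kind = "otu"),
    gene_table = abundance_table(matrix_to_table(gene_counts), feature_kind = "protein"),
    metadata = metadata,
    otu_expected = matrix_to_table(E_otu),
    gene_expected = matrix_to_table(E_gene),
    truth = list(
      genes = tibble(gene_id = gene_ids, cag_id = gene_cag),
      cags = tibble(cag_id = cag_ids, anchor_otu = otu_ids[anchor_idx]),
      otus = tibble(otu_id = otu_ids, status = status)
    ),
    config = config
  ), class = "synthetic_dataset")
}

#' Split the gene table into assembled and unassembled fractions
#'
#' Assembly succeeds only for sufficiently covered genomes; here coverage
#' is proxied by the anchor OTU's relative abundance in the realised OTU
#' table.  A gene's counts in a sample go to the unassembled table when
#' its anchor's relative abundance there is below `coverage_threshold`,
#' otherwise to the assembled table.  Background genes, which have no
#' anchor, use their own relative abundance in the gene table as the
#' proxy.  The two fractions sum cell-wise to the original table.
#'
#' @param dataset A `synthetic_dataset`.
#' @param coverage_threshold Relative-abundance cutoff in `[0, 1]`;
#'   defaults to the generator config's value.
#' @return A list with abundance tables `assembled` and `unassembled`.
#' @export
assign_fractions <- function(dataset,
                             coverage_threshold = dataset$config$coverage_threshold) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (coverage_threshold < 0 || coverage_threshold > 1) {
    abort("coverage_threshold must lie in [0, 1]")
  }
  otu <- abund_matrix(dataset$otu_table)
  gene <- abund_matrix(dataset$gene_table)
  otu_rel <- sweep(otu, 2L, pmax(colSums(otu), 1), "/")
  gene_rel <- sweep(gene, 2L, pmax(colSums(gene), 1), "/")

  anchors <- dataset$truth$genes %>%
    dplyr::left_join(dataset$truth$cags, by = "cag_id")
  proxy <- matrix(NA_real_, nrow(gene), ncol(gene), dimnames = dimnames(gene))
  has_anchor <- !is.na(anchors$anchor_otu)
  proxy[has_anchor, ] <- otu_rel[anchors$anchor_otu[has_anchor], , drop = FALSE]
  proxy[!has_anchor, ] <- gene_rel[!has_anchor, , drop = FALSE]

  unasm <- gene * (proxy < coverage_threshold)
  asm <- gene - unasm
  list(
    assembled = abundance_table(matrix_to_table(asm),
      feature_kind = "protein", fraction = "assembled"
    ),
    unassembled = abundance_table(matrix_to_table(unasm),
      feature_kind = "protein", fraction = "unassembled"
    )
  )
}

#' Write / read a synthetic dataset as tab-separated files
#'
#' Emits `otu_table.tsv`, `gene_table.tsv`, `metadata.tsv` and the three
#' truth maps (`truth_gene_to_cag.tsv`, `truth_cag_anchor.tsv`,
#' `truth_rare_labels.tsv`); round-trips losslessly through
#' [read_abundance_table()] / `read_dataset()`.
#'
#' @param dataset A `synthetic_dataset` (or any list with the same
#'   tabular elements).
#' @param directory Output directory, created if needed.
#' @return `write_dataset()` returns the file paths invisibly;
#'   `read_dataset()` returns a list of the tables.
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    path <- file.path(directory, name)
    tryCatch(readr::write_tsv(as_tibble(x), path, progress = FALSE),
      error = function(e) abort(sprintf("failed writing %s: %s", path, conditionMessage(e)))
    )
    path
  }
  paths <- c(
    wr(dataset$otu_table, "otu_table.tsv"),
    wr(dataset$gene_table, "gene_table.tsv"),
    wr(dataset$metadata, "metadata.tsv"),
    wr(dataset$truth$genes, "truth_gene_to_cag.tsv"),
    wr(dataset$truth$cags, "truth_cag_anchor.tsv"),
    wr(dataset$truth$otus, "truth_rare_labels.tsv")
  )
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  rd <- function(name) {
    readr::read_tsv(file.path(directory, name),
      show_col_types = FALSE, progress = FALSE
    )
  }
  list(
    otu_table = read_abundance_table(file.path(directory, "otu_table.tsv"),
      feature_kind = "otu"
    ),
    gene_table = read_abundance_table(file.path(directory, "gene_table.tsv"),
      feature_kind = "protein"
    ),
    metadata = rd("metadata.tsv"),
    truth = list(
      genes = rd("truth_gene_to_cag.tsv"),
      cags = rd("truth_cag_anchor.tsv"),
      otus = rd("truth_rare_labels.tsv")
    )
  )
}
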