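toy_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  structure(
    list(
      nodes = tibble::tibble(node = nodes, type = "cag"),
      edges = edges, edge_threshold = 0
    ),
    class = "signed_network"
  )
}

test_that("CAG profiles are per-date medians of member genes", {
  m <- rbind(gA = c(1L, 5L), gB = c(2L, 6L), gC = c(9L, 7L))
  colnames(m) <- c("s1", "s2")
  tbl <- table_from_matrix(m)
  cags <- tibble::tibble(
    cag_id = c("c1", "c1", "c1"), gene_id = c("gA", "gB", "gC")
  )
  raw <- cag_profiles(cags, tbl, normalize = FALSE)
  expect_equal(raw$value[raw$sample_id == "s1"], 2)
  expect_equal(raw$value[raw$sample_id == "s2"], 6)

  one <- cag_profiles(tibble::tibble(cag_id = "c", gene_id = "gB"), tbl)
  rel <- sweep(m, 2, colSums(m), "/")
  expect_equal(one$value, unname(rel["gB", ]))

  expect_error(
    cag_profiles(tibble::tibble(cag_id = "c", gene_id = "nope"), tbl),
    "nope"
  )
})

test_that("random CAG profiles equal brute-force medians", {
  set.seed(14)
  tbl <- random_table(30, 8, lambda = 5, sparsity = 0.2)
  m <- tbl_matrix(tbl)
  cags <- tibble::tibble(
    cag_id = sample(paste0("c", 1:5), 30, replace = TRUE),
    gene_id = rownames(m)
  )
  got <- cag_profiles(cags, tbl, normalize = FALSE)
  for (cc in unique(cags$cag_id)) {
    genes <- cags$gene_id[cags$cag_id == cc]
    brute <- apply(m[genes, , drop = FALSE], 2, median)
    expect_equal(got$value[got$cag_id == cc], unname(brute))
  }
})

test_that("Spearman edges use strict thresholds and average-rank ties", {
  mat <- rbind(
    A = c(1, 2, 3, 4),
    B = c(2, 1, 3, 4), # spearman rho with A exactly 0.8
    C = c(10, 20, 30, 40) # strictly monotone with A -> rho 1
  )
  colnames(mat) <- paste0("s", 1:4)
  net <- spearman_network(toy_profiles(mat), edge_threshold = 0.8)
  expect_true(any(net$edges$from == "A" & net$edges$to == "C"))
  expect_equal(net$edges$rho[net$edges$from == "A" & net$edges$to == "C"], 1)
  # rho = 0.8 exactly is dropped (strict > 0.8)
  expect_false(any(net$edges$from == "A" & net$edges$to == "B"))
  expect_false(any(net$edges$from == "B" & net$edges$to == "C"))
})

test_that("environment nodes join the network like CAGs; constants drop", {
  set.seed(15)
  mat <- matrix(rnorm(40), 4, 10,
    dimnames = list(paste0("c", 1:4), sprintf("s%02d", 1:10))
  )
  env <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    temperature = mat[1, ] * 2 + 3, # monotone transform of c1
    flatline = rep(1, 10)
  )
  expect_warning(
    net <- spearman_network(toy_profiles(mat), env, edge_threshold = 0.8),
    "flatline"
  )
  expect_true("temperature" %in% net$nodes$node)
  expect_false("flatline" %in% net$nodes$node)
  e <- net$edges
  expect_true(any((e$from == "c1" & e$to == "temperature") |
    (e$from == "temperature" & e$to == "c1")))
})

test_that("random adjacency equals brute-force rank correlation thresholding", {
  for (seed in 1:10) {
    set.seed(seed)
    mat <- matrix(rnorm(6 * 12), 6, 12,
      dimnames = list(paste0("c", 1:6), sprintf("s%02d", 1:12))
    )
    thr <- 0.3
    net <- spearman_network(toy_profiles(mat), edge_threshold = thr)
    for (i in 1:5) {
      for (j in (i + 1):6) {
        rho <- cor(rank(mat[i, ]), rank(mat[j, ]))
        present <- any(net$edges$from == paste0("c", i) &
          net$edges$to == paste0("c", j))
        expect_identical(present, abs(rho) > thr)
        if (present) {
          expect_equal(
            net$edges$rho[net$edges$from == paste0("c", i) &
              net$edges$to == paste0("c", j)], rho,
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("redundant CAGs collapse only when all conditions hold", {
  base <- cumsum(rnorm(10))^2 + 1
  mat <- rbind(c1 = base, c2 = base * 2, c3 = rev(base))
  colnames(mat) <- sprintf("s%02d", 1:10)
  profiles <- toy_profiles(mat)
  cags <- tibble::tibble(
    cag_id = rep(c("c1", "c2", "c3"), times = c(3, 2, 2)),
    gene_id = paste0("g", 1:7)
  )
  tax_same <- tibble::tibble(cag_id = c("c1", "c2", "c3"), taxonomy = "Flavo")
  aai <- matrix(100, 3, 3, dimnames = list(c("c1", "c2", "c3"), c("c1", "c2", "c3")))

  out <- remove_redundant(cags, profiles, tax_same, aai)
  expect_identical(out$representative[out$cag_id == "c2"], "c1") # c1 has more genes
  expect_true(out$redundant[out$cag_id == "c2"])
  expect_false(out$redundant[out$cag_id == "c3"])

  tax_diff <- tibble::tibble(
    cag_id = c("c1", "c2", "c3"),
    taxonomy = c("Flavo", "Gamma", "Flavo")
  )
  out2 <- remove_redundant(cags, profiles, tax_diff, aai)
  expect_false(any(out2$redundant))

  # low AAI also blocks the collapse
  aai_low <- aai
  aai_low["c1", "c2"] <- aai_low["c2", "c1"] <- 50
  out3 <- remove_redundant(cags, profiles, tax_same, aai_low)
  expect_false(any(out3$redundant))
})

test_that("redundancy groups equal brute-force transitive closure", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 7
    ids <- paste0("c", 1:n)
    mat <- matrix(rnorm(n * 12), n, 12, dimnames = list(ids, sprintf("s%02d", 1:12)))
    # clone some profiles to create redundancy chains
    mat[2, ] <- mat[1, ] + 1e-9 * rnorm(12)
    mat[3, ] <- mat[2, ] * 1.5
    tax <- tibble::tibble(cag_id = ids, taxonomy = sample(c("t1", "t2"), n, TRUE))
    cags <- tibble::tibble(
      cag_id = rep(ids, times = sample(1:4, n, TRUE)),
    ) %>% dplyr::mutate(gene_id = paste0("g", dplyr::row_number()))
    out <- remove_redundant(cags, toy_profiles(mat), tax, corr_cut = 0.95)

    rho <- cor(t(mat), method = "spearman")
    pred <- rho > 0.95 & outer(tax$taxonomy, tax$taxonomy, "==")
    diag(pred) <- TRUE
    # brute-force closure: repeated boolean matrix product
    repeat {
      nxt <- (pred %*% pred) > 0
      if (identical(nxt, pred > 0)) break
      pred <- nxt
    }
    comp_brute <- apply(pred, 1, function(r) min(which(r)))
    grp_got <- match(out$representative, out$representative)
    expect_equal(ari(comp_brute, grp_got), 1)

    # idempotence and non-increase
    kept <- out$cag_id[!out$redundant]
    out2 <- remove_redundant(
      dplyr::filter(cags, .data$cag_id %in% kept),
      dplyr::filter(toy_profiles(mat), .data$cag_id %in% kept),
      tax,
      corr_cut = 0.95
    )
    expect_false(any(out2$redundant))
    expect_lte(length(kept), n)
  }
})

test_that("Louvain separates cliques and leaves singletons alone", {
  clique <- function(nodes, rho = 0.9) {
    pairs <- t(combn(nodes, 2))
    tibble::tibble(from = pairs[, 1], to = pairs[, 2], rho = rho)
  }
  edges <- dplyr::bind_rows(
    clique(paste0("a", 1:4)), clique(paste0("b", 1:4)),
    tibble::tibble(from = "a1", to = "b1", rho = 0.15)
  )
  cl <- louvain_clusters(toy_network(edges), seed = 1)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[grepl("^a", cl$node)])), 1L)

  lonely <- toy_network(
    tibble::tibble(from = character(), to = character(), rho = double()),
    nodes = paste0("n", 1:5)
  )
  cl2 <- louvain_clusters(lonely, seed = 1)
  expect_equal(length(unique(cl2$cluster)), 5L)
})

test_that("Louvain recovers planted three-block partitions", {
  for (seed in 1:20) {
    set.seed(seed)
    blocks <- rep(1:3, each = 10)
    nodes <- sprintf("n%02d", 1:30)
    pairs <- t(combn(30, 2))
    same <- blocks[pairs[, 1]] == blocks[pairs[, 2]]
    keep <- ifelse(same, runif(nrow(pairs)) < 0.9, runif(nrow(pairs)) < 0.05)
    edges <- tibble::tibble(
      from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]], rho = 0.85
    )
    cl <- louvain_clusters(toy_network(edges, nodes), seed = seed)
    expect_gte(ari(blocks, cl$cluster[match(nodes, cl$node)]), 0.9)
  }
})

test_that("expected influence is the signed incident-weight sum", {
  edges <- tibble::tibble(
    from = c("x", "x"), to = c("y", "z"), rho = c(0.9, -0.3)
  )
  ei <- expected_influence(toy_network(edges, c("x", "y", "z", "lone")))
  expect_equal(ei$expected_influence[ei$node == "x"], 0.6)
  expect_equal(ei$expected_influence[ei$node == "lone"], 0)
  expect_equal(ei$strength[ei$node == "x"], 1.2)

  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    nodes <- paste0("n", 1:n)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.4
    edges <- tibble::tibble(
      from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
      rho = runif(sum(keep), -1, 1)
    )
    net <- toy_network(edges, nodes)
    ei <- expected_influence(net)
    brute <- vapply(nodes, function(v) {
      sum(edges$rho[edges$from == v]) + sum(edges$rho[edges$to == v])
    }, numeric(1))
    expect_equal(
      ei$expected_influence[match(nodes, ei$node)], unname(brute),
      tolerance = 1e-12
    )
    # conservation: total EI is twice the total signed weight
    expect_equal(sum(ei$expected_influence), 2 * sum(edges$rho),
      tolerance = 1e-12
    )
  }
})

test_that("networks export to GraphML and edge lists", {
  edges <- tibble::tibble(from = "a", to = "b", rho = -0.9)
  net <- toy_network(edges)
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "net.graphml"),
    clusters = louvain_clusters(net),
    centrality = expected_influence(net)
  )
  g <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$rho, -0.9)
  write_network(net, file.path(dir, "net.tsv"), format = "edgelist")
  expect_match(readLines(file.path(dir, "net.tsv"))[1], "from\tto\trho")
})
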