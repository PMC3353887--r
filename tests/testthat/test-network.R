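test_that("build_network dedups edges and drops self-loops", {
  g <- suppressMessages(build_network(
    data.frame(a = c("A", "B", "A"), b = c("B", "A", "A"))))
  expect_equal(sort(igraph::V(g)$name), c("A", "B"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(build_network(data.frame(a = character(),
                                                       b = character()))), 0)
  expect_error(build_network(data.frame(a = c("A", NA), b = c("B", "C"))),
               "line")
})

test_that("build_network on random rows equals naive set construction", {
  withr::local_seed(21)
  rows <- data.frame(a = sample(LETTERS[1:12], 500, replace = TRUE),
                     b = sample(LETTERS[1:12], 500, replace = TRUE))
  g <- suppressMessages(build_network(rows))
  keep <- rows$a != rows$b
  want_edges <- unique(ifelse(rows$a[keep] < rows$b[keep],
                              paste(rows$a[keep], rows$b[keep]),
                              paste(rows$b[keep], rows$a[keep])))
  el <- igraph::as_edgelist(g)
  got_edges <- ifelse(el[, 1] < el[, 2], paste(el[, 1], el[, 2]),
                      paste(el[, 2], el[, 1]))
  expect_setequal(got_edges, want_edges)
  expect_setequal(igraph::V(g)$name, unique(c(rows$a[keep], rows$b[keep])))
})

test_that("SIF and edge-TSV readers build the same graph", {
  dir <- withr::local_tempdir()
  writeLines(c("A pp B C", "B pp D", "# comment"), file.path(dir, "n.sif"))
  g1 <- read_sif(file.path(dir, "n.sif"))
  expect_equal(igraph::ecount(g1), 3)
  write_ortho_tsv(tibble::tibble(a = c("A", "A", "B"),
                                 b = c("B", "C", "D")),
                  file.path(dir, "n.tsv"))
  g2 <- read_edge_tsv(file.path(dir, "n.tsv"))
  expect_true(igraph::isomorphic(g1, g2))
  write_sif(g1, file.path(dir, "out.sif"))
  expect_true(igraph::isomorphic(read_sif(file.path(dir, "out.sif")), g1))
})

test_that("induced_lcc handles paths, absent queries and ties deterministically", {
  g <- build_network(data.frame(a = c("A", "B", "X", "D"),
                                b = c("B", "C", "Y", "E")))
  r <- induced_lcc(g, c("A", "B", "C"))
  expect_equal(r$lcc_size, 3)
  expect_equal(r$lcc_fraction, 1)

  miss <- induced_lcc(g, c("Q1", "Q2"))
  expect_equal(miss$in_network, 0)
  expect_true(is.na(miss$lcc_size))
  expect_true(is.na(miss$lcc_fraction))

  # two components of size 2: tie broken by lexicographically smallest member
  tie <- induced_lcc(g, c("X", "Y", "D", "E"))
  expect_equal(tie$lcc_size, 2)
  expect_identical(tie$lcc_members, c("D", "E"))
})

test_that("induced_lcc equals union-find on random graphs up to 50 nodes", {
  withr::local_seed(23)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.02, 0.2))
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    q <- sample(igraph::V(g)$name, sample(seq_len(n), 1))
    got <- induced_lcc(g, q)$lcc_size
    want <- oracle_lcc_size(igraph::as_edgelist(g), q)
    expect_equal(got, as.integer(want))
  }
})

test_that("adding an edge between induced components never shrinks the LCC", {
  withr::local_seed(29)
  g <- igraph::sample_gnp(30, 0.05)
  igraph::V(g)$name <- sprintf("N%02d", 1:30)
  q <- sample(igraph::V(g)$name, 15)
  base <- induced_lcc(g, q)$lcc_size
  non_edges <- t(combn(q, 2))
  for (i in sample(nrow(non_edges), 10)) {
    u <- non_edges[i, 1]; v <- non_edges[i, 2]
    if (igraph::are_adjacent(g, u, v)) next
    g2 <- igraph::add_edges(g, c(u, v))
    expect_gte(induced_lcc(g2, q)$lcc_size, base)
  }
})

test_that("permutation p matches exact enumeration on the 5-node two-edge graph", {
  # edges A-B and C-D plus isolated E; for query size 2 the exact
  # P(LCC = 2) is 2/10 over all C(5,2) subsets
  g <- build_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  g <- igraph::add_vertices(g, 1, name = "E")
  null <- oracle_lcc_null(g, 2)
  expect_equal(mean(null >= 2), 0.2)
  res <- permutation_test_lcc(g, c("A", "B"), n_permutations = 10000,
                              seed = 31)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(res$p_estimate - 0.2), 3 * se + 1 / 10001)
  expect_false(res$p_is_upper_bound)
})

test_that("permutation test reports bound semantics and errors correctly", {
  g <- igraph::make_ring(6)
  igraph::V(g)$name <- LETTERS[1:6]
  # query = entire node set: every permutation identical, p = 1
  full <- permutation_test_lcc(g, LETTERS[1:6], n_permutations = 50,
                               seed = 1)
  expect_equal(full$p_estimate, 1)
  expect_error(permutation_test_lcc(g, c("Z1", "Z2"), 10), "no query gene")
  expect_error(permutation_test_lcc(g, "A", 0), "n_permutations")
  # a planted clique in a sparse background is unreachable under the null
  cfg <- sim_config(n_human_genes = 2000, planted_module_size = 30,
                    planted_edge_prob = 1, seed = 33)
  mods <- human_gene_names(2000)[1:60]
  net <- simulate_ppi_network(cfg, mods)
  res <- permutation_test_lcc(net, mods, n_permutations = 1000, seed = 2)
  expect_equal(res$p_estimate, 1 / 1001)
  expect_true(res$p_is_upper_bound)
})

test_that("degree-matched null preserves the query degree-bin profile", {
  cfg <- sim_config(n_human_genes = 500, seed = 35)
  g <- simulate_ppi_network(cfg)
  q <- sample(igraph::V(g)$name, 40)
  res <- permutation_test_lcc(g, q, n_permutations = 50,
                              null_model = "degree_matched", seed = 3)
  expect_s3_class(glance(res), "tbl_df")
  expect_true(res$p_estimate > 0 && res$p_estimate <= 1)
})

test_that("hypergeometric enrichment matches exact enumeration for N <= 25", {
  withr::local_seed(37)
  for (rep in 1:10) {
    N <- sample(8:25, 1)
    bg <- sprintf("G%02d", seq_len(N))
    n <- sample(2:(N - 1), 1)
    query <- sample(bg, n)
    K <- sample(1:N, 1)
    ann <- tibble::tibble(gene = sample(bg, K), term = "T1")
    res <- hypergeom_enrichment(query, bg, ann)
    k <- sum(ann$gene %in% query)
    if (k == 0) {
      expect_equal(nrow(res), 0)
    } else {
      expect_equal(res$p_hypergeom, oracle_hyper_upper(k, K, n, N),
                   tolerance = 1e-12)
      expect_equal(res$fold, (k / n) / (K / N))
    }
  }
  # closed-form spot check: N=10, K=5, n=4, k=4 -> 5/210
  bg <- sprintf("G%02d", 1:10)
  ann <- tibble::tibble(gene = bg[1:5], term = "T")
  res <- hypergeom_enrichment(bg[1:4], bg, ann)
  expect_equal(res$p_hypergeom, 5 / 210, tolerance = 1e-12)
  # certain event: k = K = n = N -> p = 1
  res1 <- hypergeom_enrichment(bg, bg, tibble::tibble(gene = bg, term = "T"))
  expect_equal(res1$p_hypergeom, 1)
  expect_error(hypergeom_enrichment(c("ZZ"), bg, ann), "not in background")
})
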