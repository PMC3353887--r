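test_that("homology_table validates and indexes multiplicity", {
  h <- homology_table(tibble::tibble(
    yeast_orf = c("YAL001C", "YAL001C", "YBR002W"),
    human_gene = c("g1", "G2", "g1"),
    source = "ensembl"))
  expect_identical(sort(unique(h$human_gene)), c("G1", "G2"))  # upper-cased
  m <- multiplicity(h)
  expect_equal(m$yeast$n_human[m$yeast$yeast_orf == "YAL001C"], 2L)
  expect_equal(m$human$n_yeast[m$human$human_gene == "G1"], 2L)
  expect_error(homology_table(tibble::tibble(
    yeast_orf = c("YA", "YA"), human_gene = c("G", "G"),
    source = c("s", "s"))), "duplicate")
  expect_error(homology_table(tibble::tibble(
    yeast_orf = "", human_gene = "G", source = "s")), "empty")
})

test_that("merging obeys set algebra on small hand cases", {
  a <- homology_table(tibble::tibble(yeast_orf = c("X", "X"),
                                     human_gene = c("G", "H"),
                                     source = "a"))
  b <- homology_table(tibble::tibble(yeast_orf = "X", human_gene = "G",
                                     source = "b"))
  u <- merge_ortholog_sources(a, b, "union")
  i <- merge_ortholog_sources(a, b, "intersection")
  expect_equal(nrow(u), 2)
  expect_equal(nrow(i), 1)
  expect_equal(i$source, "a,b")
  expect_equal(multiplicity(u)$yeast$n_human, 2L)

  empty <- homology_table(tibble::tibble(yeast_orf = character(),
                                         human_gene = character(),
                                         source = character()))
  expect_equal(nrow(merge_ortholog_sources(empty, b, "union")), 1)
  expect_equal(nrow(merge_ortholog_sources(empty, b, "intersection")), 0)
})

test_that("merging random tables equals the brute-force set oracle", {
  withr::local_seed(11)
  for (rep in 1:5) {
    mk <- function(src) homology_table(tibble::tibble(
      yeast_orf = sample(sprintf("Y%03d", 1:20), 50, replace = TRUE),
      human_gene = sample(sprintf("G%03d", 1:20), 50, replace = TRUE),
      source = src) |> dplyr::distinct())
    a <- mk("a"); b <- mk("b")
    for (mode in c("union", "intersection")) {
      got <- merge_ortholog_sources(a, b, mode)
      want <- oracle_merge_pairs(a, b, mode)
      expect_equal(tibble::as_tibble(got)[c("yeast_orf", "human_gene")],
                   want)
    }
  }
})

test_that("phenotype projection applies the any-ortholog rule", {
  h <- homology_table(tibble::tibble(
    yeast_orf = c("X", "Y", "Z"),
    human_gene = c("G", "G", "H"),
    source = "s"))
  phen <- tibble::tibble(
    yeast_orf = rep(c("X", "Y", "Z"), each = 2),
    agent = rep(c("MMS", "UV"), 3),
    sensitive = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  part <- project_phenotypes(h, phen)
  # G has a sensitive and a non-sensitive ortholog -> modulator
  expect_identical(part$modulator_homologs, "G")
  expect_identical(part$nonmodulator_homologs, "H")
  expect_identical(part$core_all_agent_homologs, character())
  expect_equal(part$provenance,
               tibble::tibble(human_gene = "G", yeast_orf = "X",
                              agent = "MMS"))
  expect_error(project_phenotypes(
    homology_table(tibble::tibble(yeast_orf = character(),
                                  human_gene = character(),
                                  source = character())), phen), "empty")
})

test_that("projection matches the double-loop oracle on a simulated instance", {
  cfg <- sim_config(n_yeast_genes = 500, n_human_genes = 1000,
                    ortholog_coverage = 0.5, seed = 13)
  src <- simulate_ortholog_sources(cfg)
  h <- merge_ortholog_sources(src$ensembl, src$inparanoid)
  phen <- simulate_phenotypes(cfg)
  part <- project_phenotypes(h, phen)
  want <- oracle_projection(tibble::as_tibble(h), phen)
  expect_identical(part$modulator_homologs, sort(want$modulator))
  expect_identical(part$nonmodulator_homologs, sort(want$nonmodulator))
  expect_identical(part$core_all_agent_homologs, sort(want$core))
})

test_that("projection invariants: disjoint partition, core subset, order-independence", {
  cfg <- sim_config(n_yeast_genes = 300, n_human_genes = 500, seed = 17)
  src <- simulate_ortholog_sources(cfg)
  h <- merge_ortholog_sources(src$ensembl, src$inparanoid)
  phen <- simulate_phenotypes(cfg)
  part <- project_phenotypes(h, phen)
  expect_length(intersect(part$modulator_homologs,
                          part$nonmodulator_homologs), 0)
  expect_true(all(part$core_all_agent_homologs %in%
                    part$modulator_homologs))
  n_screened_homologs <- length(unique(tibble::as_tibble(h)$human_gene))
  expect_equal(length(part$modulator_homologs) +
                 length(part$nonmodulator_homologs), n_screened_homologs)
  # permuting pair order changes nothing
  shuf <- homology_table(dplyr::slice_sample(tibble::as_tibble(h),
                                             prop = 1))
  part2 <- project_phenotypes(shuf, phen)
  expect_identical(part$modulator_homologs, part2$modulator_homologs)
  # idempotence of the reported sets under re-projection
  expect_identical(project_phenotypes(h, phen)$modulator_homologs,
                   part$modulator_homologs)
})

test_that("unscreened ORFs are dropped with a warning, not treated as insensitive", {
  h <- homology_table(tibble::tibble(yeast_orf = c("X", "Q"),
                                     human_gene = c("G", "H"),
                                     source = "s"))
  phen <- tibble::tibble(yeast_orf = "X", agent = "MMS", sensitive = FALSE)
  expect_warning(part <- project_phenotypes(h, phen), "no phenotype data")
  expect_equal(part$n_unscreened_orfs, 1)
  # H's only ortholog is unscreened: H appears in neither set
  expect_false("H" %in% c(part$modulator_homologs,
                          part$nonmodulator_homologs))
})

test_that("TSV and cluster readers round-trip the homology formats", {
  dir <- withr::local_tempdir()
  pairs <- tibble::tibble(yeast_orf = c("YAL001C", "YBR002W"),
                          human_gene = c("G1", "G2"), source = "ensembl")
  write_ortho_tsv(pairs, file.path(dir, "pairs.tsv"))
  expect_equal(nrow(read_orthologs(file.path(dir, "pairs.tsv"))), 2)

  clusters <- tibble::tibble(
    cluster_id = c(1, 1, 1, 2, 2),
    species = c("yeast", "human", "human", "yeast", "human"),
    gene = c("YAL001C", "G1", "G2", "YBR002W", "G3"))
  write_ortho_tsv(clusters, file.path(dir, "clu.tsv"))
  inp <- read_inparanoid(file.path(dir, "clu.tsv"))
  expect_equal(nrow(inp), 3)  # cluster 1 expands to 2 pairs, cluster 2 to 1

  wide <- tibble::tibble(orf = c("YAL001C", "YBR002W"),
                         MMS = c(1, 0), UV = c(0, 0))
  write_ortho_tsv(wide, file.path(dir, "phen.tsv"))
  long <- read_phenotypes(file.path(dir, "phen.tsv"))
  expect_equal(nrow(long), 4)
  expect_equal(sum(long$sensitive), 1)
})
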