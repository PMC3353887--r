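#' Synthetic inputs for the ortholog-projection screen
#'
#' These generators emulate every input the pipeline consumes: two ortholog
#' databases, a genome-wide yeast damage-sensitivity table, a human
#' interactome with a planted modulator module, clonogenic survival assays
#' with knockdown-efficiency qRT-PCR, expression and annotation tables, and
#' per-cell autophagosome puncta counts. All randomness derives from
#' `config$seed` through a per-generator sub-stream (seed + a stable
#' generator index), so the same `sim_config()` always reproduces the same
#' outputs and adding a generator never perturbs the others.
#'
#' @name simulate
NULL

yeast_orf_names <- function(n) {
  i <- seq_len(n) - 1L
  num <- i %% 999L + 1L
  block <- i %/% 999L
  chr <- LETTERS[block %% 16L + 1L]
  arm <- c("L", "R")[(block %/% 16L) %% 2L + 1L]
  strand <- c("W", "C")[(block %/% 32L) %% 2L + 1L]
  sprintf("Y%s%s%03d%s", chr, arm, num, strand)
}

human_gene_names <- function(n) sprintf("HSG%04d", seq_len(n))

#' Simulate two partially overlapping ortholog databases
#'
#' Draws a latent yeast-to-human ortholog truth (configured coverage; a
#' configured fraction of orthologous yeast genes map to two human genes),
#' then lets each of two sources independently retain
#' `config$source_retention` of the true pairs, mimicking the partial
#' overlap of real ortholog databases.
#'
#' @param config a [sim_config()].
#' @return a list of two [homology_table()] objects named `ensembl` and
#'   `inparanoid`.
#' @export
#' @examples
#' src <- simulate_ortholog_sources(sim_config(n_yeast_genes = 50,
#'                                             n_human_genes = 100))
#' nrow(src$ensembl)
simulate_ortholog_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(sub_seed(config$seed, "orthologs"))
  yeast <- yeast_orf_names(config$n_yeast_genes)
  human <- human_gene_names(config$n_human_genes)

  n_ortho <- round(config$ortholog_coverage * config$n_yeast_genes)
  empty <- tibble::tibble(yeast_orf = character(), human_gene = character(),
                          source = character())
  if (n_ortho == 0) {
    return(list(ensembl = homology_table(dplyr::mutate(empty, source = "ensembl")),
                inparanoid = homology_table(dplyr::mutate(empty, source = "inparanoid"))))
  }
  ortho_orfs <- sort(sample(yeast, n_ortho))
  # primary targets drawn with replacement: several yeast genes may share a
  # human co-ortholog, as in real homology tables
  primary <- sample(human, n_ortho, replace = TRUE)
  truth <- tibble::tibble(yeast_orf = ortho_orfs, human_gene = primary)
  many <- runif(n_ortho) < config$one_to_many_prob
  if (any(many)) {
    second <- vapply(which(many), function(i) {
      sample(setdiff(human, truth$human_gene[i]), 1L)
    }, character(1))
    truth <- dplyr::bind_rows(
      truth,
      tibble::tibble(yeast_orf = ortho_orfs[many], human_gene = second)
    )
  }
  truth <- dplyr::arrange(truth, .data$yeast_orf, .data$human_gene)

  draw_source <- function(label) {
    keep <- runif(nrow(truth)) < config$source_retention
    homology_table(dplyr::mutate(truth[keep, ], source = label))
  }
  list(ensembl = draw_source("ensembl"),
       inparanoid = draw_source("inparanoid"))
}

#' Simulate a genome-wide yeast damage-sensitivity table
#'
#' Each yeast gene is sensitive to each agent independently with probability
#' `frac_sensitive_per_agent`; a random core of `n_core_sensitive` genes is
#' forced sensitive to every agent, emulating the small set of genes that
#' modulate toxicity of all four agents in genome-wide screens.
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `yeast_orf`, `agent`, `sensitive` (logical),
#'   one row per gene x agent.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(sub_seed(config$seed, "phenotypes"))
  yeast <- yeast_orf_names(config$n_yeast_genes)
  core <- if (config$n_core_sensitive > 0) {
    sample(yeast, config$n_core_sensitive)
  } else character()
  tidyr::expand_grid(yeast_orf = yeast, agent = config$agents) |>
    dplyr::mutate(
      sensitive = runif(dplyr::n()) < config$frac_sensitive_per_agent,
      sensitive = .data$sensitive | .data$yeast_orf %in% core
    )
}

#' Simulate a human interactome with a planted modulator module
#'
#' The background is a degree-heterogeneous preferential-attachment graph
#' over all `n_human_genes` genes (names assigned by random permutation so
#' node age does not correlate with gene identity). A random subset of
#' `planted_module_size` modulator genes then receives extra within-subset
#' edges with probability `planted_edge_prob`, creating the enriched
#' connectivity signal the permutation test is meant to detect. The result
#' is a simple graph: no self-loops, no multi-edges.
#'
#' @param config a [sim_config()].
#' @param modulator_genes character vector of modulator-homolog gene symbols
#'   (must be a subset of the human gene universe); `NULL` disables
#'   planting.
#' @return an undirected [igraph::graph] with vertex names.
#' @export
simulate_ppi_network <- function(config, modulator_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(sub_seed(config$seed, "ppi"))
  human <- human_gene_names(config$n_human_genes)
  if (!is.null(modulator_genes)) {
    bad <- setdiff(modulator_genes, human)
    if (length(bad) > 0) {
      abort(sprintf("modulator_genes outside the human gene universe: %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  m <- max(1L, round(config$ppi_mean_degree / 2))
  g <- igraph::sample_pa(config$n_human_genes, power = 1, m = m,
                         directed = FALSE)
  igraph::V(g)$name <- sample(human)

  if (!is.null(modulator_genes) && config$planted_module_size > 0 &&
      config$planted_edge_prob > 0) {
    if (config$planted_module_size > length(modulator_genes)) {
      abort(sprintf(
        "planted_module_size (%d) exceeds the number of modulator genes (%d)",
        config$planted_module_size, length(modulator_genes)))
    }
    module <- sample(modulator_genes, config$planted_module_size)
    pairs <- t(combn(sort(module), 2L))
    keep <- runif(nrow(pairs)) < config$planted_edge_prob
    if (any(keep)) {
      g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
    }
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Simulate clonogenic survival assays and knockdown qRT-PCR
#'
#' For every line x agent x dose x replicate, true relative survival is
#' `2^(-decay * dose + effect_log2)` perturbed by multiplicative log-normal
#' noise (CV = `replicate_cv`, mean 1) and truncated to (0, 1]. Observations
#' are emitted as colony counts: cells seeded per dose are chosen in the
#' 50-5000 range so that roughly 150 control colonies are expected, and
#' colonies = round(survival x plating efficiency x seeded). A non-targeting
#' control line (`shNT`, effect 0) and `n_nonsilenced_lines` non-silenced
#' shRNA lines (effect 0, residual mRNA above 0.60) are always included;
#' designated test lines receive residual mRNA inside
#' `knockdown_residual_range` (below 0.60).
#'
#' @param config a [sim_config()].
#' @param line_effects named list: line -> injected log2 survival shift,
#'   either a single number (applied to every agent) or a named vector by
#'   agent. Unknown agent names are an error.
#' @return a list with `observations` (tibble: line, agent, dose, replicate,
#'   colonies, cells_seeded, role) and `residuals` (tibble: line, role,
#'   residual).
#' @export
simulate_survival <- function(config, line_effects) {
  stopifnot(inherits(config, "sim_config"))
  if (length(line_effects) > 0 && is.null(names(line_effects))) {
    abort("`line_effects` must be a named list (line -> effect)")
  }
  withr::local_seed(sub_seed(config$seed, "survival"))
  decay <- per_agent_decay(config)
  pe <- config$plating_efficiency

  expand_effects <- function(eff) {
    if (length(eff) == 1 && is.null(names(eff))) {
      return(setNames(rep(as.numeric(eff), length(config$agents)),
                      config$agents))
    }
    bad <- setdiff(names(eff), config$agents)
    if (length(bad) > 0) {
      abort(sprintf("unknown agent label(s) in line_effects: %s",
                    paste(bad, collapse = ", ")))
    }
    out <- setNames(rep(0, length(config$agents)), config$agents)
    out[names(eff)] <- as.numeric(eff)
    out
  }

  lines <- tibble::tibble(
    line = c(names(line_effects), "shNT",
             if (config$n_nonsilenced_lines > 0)
               sprintf("shNS_%02d", seq_len(config$n_nonsilenced_lines))),
    role = c(rep("test", length(line_effects)), "nontargeting",
             rep("nonsilenced", config$n_nonsilenced_lines))
  )
  ctrl_lines <- setdiff(lines$line, names(line_effects))
  zero_effect <- setNames(rep(0, length(config$agents)), config$agents)
  effects <- c(lapply(line_effects, expand_effects),
               setNames(rep(list(zero_effect), length(ctrl_lines)),
                        ctrl_lines))

  grid <- tidyr::expand_grid(
    lines,
    agent = config$agents
  ) |>
    dplyr::mutate(doses = purrr::map(.data$agent,
                                     ~ config$doses_per_agent[[.x]])) |>
    tidyr::unnest("doses") |>
    dplyr::rename(dose = "doses") |>
    tidyr::expand_grid(replicate = seq_len(config$n_replicates))

  sdlog <- sqrt(log(1 + config$replicate_cv^2))
  noise <- if (config$replicate_cv > 0) {
    rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, nrow(grid))
  }

  obs <- grid |>
    dplyr::mutate(
      effect = purrr::map2_dbl(.data$line, .data$agent,
                               ~ effects[[.x]][[.y]]),
      true_surv = ifelse(.data$dose == 0, 1,
                         2^(-decay[.data$agent] * .data$dose + .data$effect)),
      surv = pmin(.data$true_surv * noise, 1),
      cells_seeded = pmin(pmax(round(150 / (pe * 2^(-decay[.data$agent] *
                                                      .data$dose))), 50),
                          5000),
      colonies = as.integer(round(.data$surv * pe * .data$cells_seeded))
    ) |>
    dplyr::select("line", "agent", "dose", "replicate", "colonies",
                  "cells_seeded", "role")

  kr <- config$knockdown_residual_range
  residuals <- lines |>
    dplyr::mutate(residual = dplyr::case_when(
      .data$role == "test" ~ runif(dplyr::n(), kr[1], kr[2]),
      .data$role == "nontargeting" ~ 1,
      TRUE ~ runif(dplyr::n(), 0.65, 0.95)
    ))

  list(observations = obs, residuals = residuals)
}

#' Simulate a microarray expression table
#'
#' Log-normal intensities over the human gene universe; downstream,
#' intensities above the selection threshold (default 100) count as
#' expressed.
#'
#' @param config a [sim_config()].
#' @return tibble with columns `gene`, `intensity`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(sub_seed(config$seed, "expression"))
  tibble::tibble(
    gene = human_gene_names(config$n_human_genes),
    intensity = rlnorm(config$n_human_genes, config$expr_log_mean,
                       config$expr_log_sd)
  )
}

default_annotation_terms <- c(
  "DNA repair", "cell cycle control", "ribosomal protein",
  "transcription", "chromatin remodeling", "vesicle transport",
  "protein degradation", "mRNA degradation", "autophagy",
  "lipid metabolism"
)

#' Simulate a gene-to-functional-category annotation table
#'
#' Every gene receives each vocabulary term independently with probability
#' `term_prob`; genes may carry zero terms.
#'
#' @param config a [sim_config()].
#' @param terms vocabulary of category labels.
#' @param term_prob per-gene per-term assignment probability.
#' @return long tibble with columns `gene`, `term`.
#' @export
simulate_annotations <- function(config, terms = default_annotation_terms,
                                 term_prob = 0.08) {
  stopifnot(inherits(config, "sim_config"))
  check_fraction(term_prob, "term_prob")
  withr::local_seed(sub_seed(config$seed, "annotation"))
  genes <- human_gene_names(config$n_human_genes)
  tidyr::expand_grid(gene = genes, term = terms) |>
    dplyr::filter(runif(dplyr::n()) < term_prob)
}

#' Simulate per-cell autophagosome puncta counts
#'
#' Each condition is a two-component Poisson mixture: a basal population
#' with mean `puncta_lambda_basal` and an induced population (configured
#' fraction per condition) with mean `puncta_lambda_induced`. Cells with
#' more than the scoring threshold of puncta (default 5) will be called
#' autophagic downstream.
#'
#' @param config a [sim_config()].
#' @param conditions named numeric vector: condition label -> induced
#'   fraction in \[0, 1\].
#' @return tibble with columns `condition`, `cell_id`, `puncta`.
#' @export
simulate_puncta <- function(config, conditions) {
  stopifnot(inherits(config, "sim_config"))
  if (length(conditions) < 1 || is.null(names(conditions))) {
    abort("`conditions` must be a non-empty named vector of induced fractions")
  }
  for (f in conditions) check_fraction(f, "induced fraction")
  withr::local_seed(sub_seed(config$seed, "puncta"))
  n <- config$puncta_cells_per_condition
  purrr::imap(conditions, function(frac, cond) {
    induced <- runif(n) < frac
    lambda <- ifelse(induced, config$puncta_lambda_induced,
                     config$puncta_lambda_basal)
    tibble::tibble(condition = cond, cell_id = seq_len(n),
                   puncta = rpois(n, lambda))
  }) |>
    purrr::list_rbind()
}
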