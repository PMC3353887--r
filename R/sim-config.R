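#' Configuration for the synthetic screen generator
#'
#' Bundles every knob of the synthetic-data module. The defaults describe a
#' desk-scale analogue of a genome-wide yeast damage screen projected onto a
#' human interactome: roughly 30% of yeast genes sensitive per agent, four
#' damaging agents (MMS, 4NQO, tBuOOH, UV), a preferential-attachment
#' background interactome with a planted connected module among the
#' modulator homologs, and clonogenic survival curves with multiplicative
#' log-normal replicate noise.
#'
#' @param n_yeast_genes number of yeast ORFs in the simulated deletion
#'   library.
#' @param n_human_genes number of human genes in the universe (interactome
#'   node set).
#' @param ortholog_coverage fraction of yeast genes with at least one human
#'   ortholog.
#' @param one_to_many_prob probability that an orthologous yeast gene maps to
#'   more than one human gene (simulated as exactly two).
#' @param source_retention per-source probability that a true ortholog pair
#'   is retained, so the two simulated databases partially overlap.
#' @param frac_sensitive_per_agent marginal fraction of yeast genes sensitive
#'   per agent.
#' @param n_core_sensitive number of yeast genes forced sensitive to every
#'   agent (the "core" set).
#' @param agents character vector of damaging-agent labels.
#' @param ppi_mean_degree expected degree of the background interactome.
#' @param planted_module_size number of modulator-homolog genes wired into
#'   one planted module.
#' @param planted_edge_prob within-module edge probability (1 = clique,
#'   0 = no planted signal).
#' @param expr_log_mean,expr_log_sd parameters of the log-normal microarray
#'   intensity distribution (natural-log scale).
#' @param doses_per_agent named list of strictly increasing non-negative dose
#'   vectors, one per agent; each must start at 0 (the untreated
#'   normalizer). Doses are abstract equitoxic units.
#' @param survival_decay per-agent log2 kill slope; default calibrated so
#'   the top default dose leaves ~10% control survival. Single value is
#'   recycled across agents.
#' @param n_replicates replicates per line x agent x dose.
#' @param replicate_cv coefficient of variation of the multiplicative
#'   log-normal replicate noise.
#' @param plating_efficiency fraction of seeded untreated cells that form
#'   colonies.
#' @param effect_log2 default injected log2 survival shift for test lines
#'   (0 = null).
#' @param knockdown_residual_range interval the residual mRNA fraction of
#'   "silenced" lines is drawn from (must lie below 0.60).
#' @param n_nonsilenced_lines number of non-silenced shRNA control lines
#'   (residual above 0.60) that join the noise region.
#' @param puncta_lambda_basal,puncta_lambda_induced Poisson mean puncta
#'   counts of basal and induced cells.
#' @param puncta_cells_per_condition cells scored per condition.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs from every generator.
#'
#' @return an object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_yeast_genes = 100, n_human_genes = 200, seed = 1)
#' cfg$agents
sim_config <- function(n_yeast_genes = 1000,
                       n_human_genes = 2000,
                       ortholog_coverage = 0.30,
                       one_to_many_prob = 0.20,
                       source_retention = 0.80,
                       frac_sensitive_per_agent = 0.30,
                       n_core_sensitive = 28,
                       agents = c("MMS", "4NQO", "tBuOOH", "UV"),
                       ppi_mean_degree = 4,
                       planted_module_size = 30,
                       planted_edge_prob = 0.30,
                       expr_log_mean = 5,
                       expr_log_sd = 1.5,
                       doses_per_agent = NULL,
                       survival_decay = log2(10) / 2,
                       n_replicates = 3,
                       replicate_cv = 0.10,
                       plating_efficiency = 0.5,
                       effect_log2 = 0,
                       knockdown_residual_range = c(0.10, 0.50),
                       n_nonsilenced_lines = 4,
                       puncta_lambda_basal = 1,
                       puncta_lambda_induced = 15,
                       puncta_cells_per_condition = 200,
                       seed = 1L) {
  if (is.null(doses_per_agent)) {
    doses_per_agent <- setNames(rep(list(c(0, 0.5, 1, 2)), length(agents)),
                                agents)
  }
  cfg <- structure(
    list(
      n_yeast_genes = check_count(n_yeast_genes, "n_yeast_genes"),
      n_human_genes = check_count(n_human_genes, "n_human_genes"),
      ortholog_coverage = check_fraction(ortholog_coverage,
                                         "ortholog_coverage"),
      one_to_many_prob = check_fraction(one_to_many_prob, "one_to_many_prob"),
      source_retention = check_fraction(source_retention, "source_retention"),
      frac_sensitive_per_agent = check_fraction(frac_sensitive_per_agent,
                                                "frac_sensitive_per_agent"),
      n_core_sensitive = check_count(n_core_sensitive, "n_core_sensitive",
                                     min = 0L),
      agents = agents,
      ppi_mean_degree = check_positive(ppi_mean_degree, "ppi_mean_degree"),
      planted_module_size = check_count(planted_module_size,
                                        "planted_module_size", min = 0L),
      planted_edge_prob = check_fraction(planted_edge_prob,
                                         "planted_edge_prob"),
      expr_log_mean = expr_log_mean,
      expr_log_sd = check_nonnegative(expr_log_sd, "expr_log_sd"),
      doses_per_agent = doses_per_agent,
      survival_decay = survival_decay,
      n_replicates = check_count(n_replicates, "n_replicates"),
      replicate_cv = check_nonnegative(replicate_cv, "replicate_cv"),
      plating_efficiency = check_fraction(plating_efficiency,
                                          "plating_efficiency"),
      effect_log2 = effect_log2,
      knockdown_residual_range = knockdown_residual_range,
      n_nonsilenced_lines = check_count(n_nonsilenced_lines,
                                        "n_nonsilenced_lines", min = 0L),
      puncta_lambda_basal = check_nonnegative(puncta_lambda_basal,
                                              "puncta_lambda_basal"),
      puncta_lambda_induced = check_nonnegative(puncta_lambda_induced,
                                                "puncta_lambda_induced"),
      puncta_cells_per_condition = check_count(puncta_cells_per_condition,
                                               "puncta_cells_per_condition"),
      seed = check_count(seed, "seed", min = 0L)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.character(cfg$agents) || length(cfg$agents) < 1 ||
      anyDuplicated(cfg$agents)) {
    abort("`agents` must be a non-empty character vector without duplicates",
          class = "orthotox_config_error")
  }
  if (!is.list(cfg$doses_per_agent) ||
      !setequal(names(cfg$doses_per_agent), cfg$agents)) {
    abort("`doses_per_agent` must be a named list with one entry per agent",
          class = "orthotox_config_error")
  }
  for (ag in cfg$agents) {
    d <- cfg$doses_per_agent[[ag]]
    if (!is.numeric(d) || length(d) < 2 || any(d < 0) ||
        any(diff(d) <= 0)) {
      abort(sprintf(
        "`doses_per_agent[['%s']]` must be strictly increasing and non-negative",
        ag), class = "orthotox_config_error")
    }
    if (d[1] != 0) {
      abort(sprintf(
        "`doses_per_agent[['%s']]` must start at dose 0 (the normalizer)",
        ag), class = "orthotox_config_error")
    }
  }
  decay <- cfg$survival_decay
  if (!is.numeric(decay) || any(decay <= 0) ||
      !(length(decay) == 1 || length(decay) == length(cfg$agents))) {
    abort("`survival_decay` must be positive, length 1 or one per agent",
          class = "orthotox_config_error")
  }
  kr <- cfg$knockdown_residual_range
  if (!is.numeric(kr) || length(kr) != 2 || kr[1] < 0 || kr[2] <= kr[1] ||
      kr[2] >= 0.60) {
    abort(paste("`knockdown_residual_range` must be an increasing interval",
                "below 0.60 (the silenced/non-silenced boundary)"),
          class = "orthotox_config_error")
  }
  if (cfg$n_core_sensitive > cfg$n_yeast_genes) {
    abort("`n_core_sensitive` cannot exceed `n_yeast_genes`",
          class = "orthotox_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d yeast genes, %d human genes, coverage %.2f\n",
              x$n_yeast_genes, x$n_human_genes, x$ortholog_coverage))
  cat(sprintf("  agents: %s\n", paste(x$agents, collapse = ", ")))
  cat(sprintf("  planted module: %d genes @ edge prob %.2f\n",
              x$planted_module_size, x$planted_edge_prob))
  cat(sprintf("  survival: %d replicates, cv %.2f, effect_log2 %.2f\n",
              x$n_replicates, x$replicate_cv, x$effect_log2))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

per_agent_decay <- function(cfg) {
  d <- cfg$survival_decay
  if (length(d) == 1) d <- rep(d, length(cfg$agents))
  setNames(d, cfg$agents)
}
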