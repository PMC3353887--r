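#' Configuration of an end-to-end pipeline run
#'
#' Bundles the stage configurations and the run-level knobs. A single
#' `seed` drives every stochastic stage (it overrides `sim$seed` and seeds
#' the permutation test and the effect-assignment draw), so identical
#' configurations yield byte-identical outputs.
#'
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param selection a [selection_config()].
#' @param caller a [caller_config()].
#' @param merge_mode ortholog source combination rule, `"union"` or
#'   `"intersection"`.
#' @param n_permutations permutations for the LCC significance test.
#' @param null_model permutation null, `"uniform"` or `"degree_matched"`.
#' @param n_test_lines number of candidate knockdown lines carried into the
#'   survival screen.
#' @param effect_fraction fraction of test lines given a true injected
#'   effect of magnitude `sim$effect_log2` (random sign); the rest are
#'   null.
#' @param autophagy_conditions named vector of induced fractions for the
#'   optional autophagy stage (first entry is the reference condition);
#'   `NULL` skips the stage.
#' @param seed integer master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            selection = selection_config(),
                            caller = caller_config(),
                            merge_mode = c("union", "intersection"),
                            n_permutations = 1000,
                            null_model = c("uniform", "degree_matched"),
                            n_test_lines = 34,
                            effect_fraction = 0.5,
                            autophagy_conditions = NULL,
                            seed = 1L) {
  structure(
    list(sim = sim, selection = selection, caller = caller,
         merge_mode = match.arg(merge_mode),
         n_permutations = check_count(n_permutations, "n_permutations"),
         null_model = match.arg(null_model),
         n_test_lines = check_count(n_test_lines, "n_test_lines"),
         effect_fraction = check_fraction(effect_fraction,
                                          "effect_fraction"),
         autophagy_conditions = autophagy_conditions,
         seed = check_count(seed, "seed", min = 0L)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain `sim`, `selection`, `caller` and `pipeline`
#' sections whose keys override the corresponding constructor defaults.
#' Schema violations are collected across all sections and reported
#' together, not first-only.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  errors <- character()
  build <- function(ctor, args, section) {
    tryCatch(do.call(ctor, as.list(args %||% list())),
             error = function(e) {
               errors <<- c(errors,
                            sprintf("[%s] %s", section, conditionMessage(e)))
               NULL
             })
  }
  sim <- build(sim_config, y$sim, "sim")
  selection <- build(selection_config, y$selection, "selection")
  caller <- build(caller_config, y$caller, "caller")
  pargs <- as.list(y$pipeline %||% list())
  if (!is.null(pargs$autophagy_conditions)) {
    pargs$autophagy_conditions <- unlist(pargs$autophagy_conditions)
  }
  cfg <- if (length(errors) == 0) {
    build(pipeline_config,
          c(list(sim = sim, selection = selection, caller = caller), pargs),
          "pipeline")
  }
  if (length(errors) > 0) {
    abort(paste0("invalid pipeline configuration:\n",
                 paste("-", errors, collapse = "\n")))
  }
  cfg
}

#' Run the full projection-and-screen pipeline on simulated inputs
#'
#' Executes the stages in order: simulate the inputs; merge the ortholog
#' sources and project the yeast phenotypes; build the interactome,
#' extract the modulator-homolog LCC and test its significance by
#' permutation; select knockdown candidates; simulate and call the
#' clonogenic screen on the selected lines (only lines whose simulated
#' knockdown is silenced, residual mRNA < 0.60, are called); optionally
#' score autophagy; and assemble a run report. Any stage failure aborts
#' with the stage name and cause.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `run_report`: stage outputs plus a `headline`
#'   list (LCC size and fractions, permutation p, candidate count,
#'   category counts, screen percentages). Write it out with
#'   [write_report()].
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim
  sim$seed <- cfg$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  sources <- stage("simulate", simulate_ortholog_sources(sim))
  phen <- stage("simulate", simulate_phenotypes(sim))
  expr_tab <- stage("simulate", simulate_expression(sim))
  ann <- stage("simulate", simulate_annotations(sim))

  merged <- stage("homology",
                  merge_ortholog_sources(sources$ensembl,
                                         sources$inparanoid,
                                         mode = cfg$merge_mode))
  partition <- stage("homology", project_phenotypes(merged, phen))

  net <- stage("network",
               simulate_ppi_network(sim, partition$modulator_homologs))
  lcc <- stage("network", induced_lcc(net, partition$modulator_homologs))
  perm <- stage("network",
                permutation_test_lcc(net, partition$modulator_homologs,
                                     n_permutations = cfg$n_permutations,
                                     null_model = cfg$null_model,
                                     seed = cfg$seed))
  enrichment <- stage("network",
                      hypergeom_enrichment(lcc$lcc_members,
                                           human_gene_names(sim$n_human_genes),
                                           ann))

  selection <- stage("selection",
                     select_candidates(partition, lcc, merged, expr_tab,
                                       ann, cfg$selection, net = net))

  lines <- head(selection$candidates$gene, cfg$n_test_lines)
  if (length(lines) == 0) {
    abort("pipeline stage 'toxicity' failed: no candidate lines to screen")
  }
  n_eff <- round(cfg$effect_fraction * length(lines))
  effects <- withr::with_seed((cfg$seed + 97L) %% .Machine$integer.max, {
    eff_lines <- sample(lines, n_eff)
    signs <- sample(c(-1, 1), n_eff, replace = TRUE)
    e <- setNames(rep(0, length(lines)), lines)
    e[eff_lines] <- signs * sim$effect_log2
    as.list(e)
  })
  names(effects) <- paste0("sh", names(effects))

  surv <- stage("toxicity", simulate_survival(sim, effects))
  curves <- stage("toxicity", relative_survival(surv$observations))
  kd <- surv$residuals |>
    dplyr::mutate(status = classify_knockdown(.data$residual,
                                              cfg$caller$knockdown_residual_max))
  silenced <- kd$line[kd$status == "silenced" & kd$role == "test"]
  curves_called <- dplyr::filter(curves,
                                 .data$role != "test" |
                                   .data$line %in% silenced)
  noise <- stage("toxicity", build_noise_region(curves_called))
  calls <- stage("toxicity",
                 call_toxicity(curves_called, noise, cfg$caller))
  summary <- stage("toxicity", summarize_screen(calls))

  autophagy <- NULL
  if (!is.null(cfg$autophagy_conditions) &&
      length(cfg$autophagy_conditions) > 0) {
    puncta <- stage("autophagy",
                    simulate_puncta(sim, cfg$autophagy_conditions))
    autophagy <- stage("autophagy",
                       autophagy_test(puncta,
                                      names(cfg$autophagy_conditions)[1]))
  }

  headline <- list(
    n_ortholog_pairs = nrow(merged),
    n_modulator_homologs = length(partition$modulator_homologs),
    n_nonmodulator_homologs = length(partition$nonmodulator_homologs),
    lcc_size = lcc$lcc_size,
    lcc_fraction = lcc$lcc_fraction,
    lcc_fraction_of_query = lcc$lcc_fraction_of_query,
    permutation_p = perm$p_estimate,
    p_is_upper_bound = perm$p_is_upper_bound,
    n_candidates = nrow(selection$candidates),
    n_called_lines = summary$n_called_lines,
    pct_modulating = summary$pct_modulating,
    pct_sensitivity = summary$pct_sensitivity,
    pct_resistance = summary$pct_resistance,
    pct_high = summary$pct_high,
    fisher_p = summary$fisher_p
  )

  structure(
    list(config = cfg, merged = merged, partition = partition, net = net,
         lcc = lcc, permutation = perm, enrichment = enrichment,
         selection = selection, curves = curves_called, noise = noise,
         knockdown = kd, calls = calls, summary = summary,
         autophagy = autophagy, headline = headline,
         version = as.character(utils::packageVersion("orthotox"))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  h <- x$headline
  cat("<run_report>\n")
  cat(sprintf("  %d merged ortholog pairs -> %d modulator homologs\n",
              h$n_ortholog_pairs, h$n_modulator_homologs))
  cat(sprintf("  LCC %d (%.0f%% of mapped genes), permutation p %s %.3g\n",
              h$lcc_size, 100 * h$lcc_fraction,
              if (h$p_is_upper_bound) "<" else "=", h$permutation_p))
  cat(sprintf("  %d candidates, %d lines called, %d%% modulating (%d%% sens, %d%% res, %d%% high)\n",
              h$n_candidates, h$n_called_lines, h$pct_modulating,
              h$pct_sensitivity, h$pct_resistance, h$pct_high))
  invisible(x)
}

#' Write a pipeline run report to disk
#'
#' Emits machine-readable TSVs for every stage (partition, LCC members,
#' permutation summary, enrichment, candidates with audit trail, noise
#' region, calls, five-symbol call matrix, screen summary, knockdown
#' classification, autophagy results when present) and, for
#' `format = "markdown"`, a human-readable `report.md` whose numbers are
#' rendered from the same objects (single-source rule). The markdown
#' contains no timestamps, so identical runs produce identical files.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param format `"tsv"`, `"markdown"`, or both.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("tsv", "markdown")) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(x, name) {
    p <- file.path(dir, name)
    write_ortho_tsv(x, p)
    paths <<- c(paths, p)
  }
  if ("tsv" %in% format) {
    put(tibble::as_tibble(report$merged), "merged_orthologs.tsv")
    put(tidy(report$partition), "partition.tsv")
    put(tidy(report$lcc), "lcc_members.tsv")
    put(glance(report$permutation), "permutation.tsv")
    put(report$enrichment, "enrichment.tsv")
    put(report$selection$candidates, "candidates.tsv")
    put(report$selection$trace, "selection_trace.tsv")
    put(report$noise, "noise_region.tsv")
    put(tibble::as_tibble(report$calls), "calls.tsv")
    put(format_call_matrix(report$calls), "call_matrix.tsv")
    put(glance(report$summary), "screen_summary.tsv")
    put(report$knockdown, "knockdown.tsv")
    if (!is.null(report$autophagy)) {
      put(tibble::as_tibble(report$autophagy), "autophagy.tsv")
    }
  }
  if ("markdown" %in% format) {
    h <- report$headline
    md <- c(
      "# Screen run report",
      "",
      sprintf("orthotox version %s, seed %d", report$version,
              report$config$seed),
      "",
      "## Homology projection",
      sprintf("- merged ortholog pairs: %d", h$n_ortholog_pairs),
      sprintf("- modulator homologs: %d; non-modulator homologs: %d",
              h$n_modulator_homologs, h$n_nonmodulator_homologs),
      "",
      "## Network connectivity",
      sprintf("- LCC size: %d of %d mapped (%.0f%%; %.0f%% of the query)",
              h$lcc_size, report$lcc$in_network, 100 * h$lcc_fraction,
              100 * h$lcc_fraction_of_query),
      sprintf("- permutation p %s %.3g (%s null, %d permutations)",
              if (h$p_is_upper_bound) "<" else "=", h$permutation_p,
              report$permutation$null_model,
              report$permutation$n_permutations),
      "",
      "## Screen",
      sprintf("- candidates selected: %d; lines called: %d",
              h$n_candidates, h$n_called_lines),
      sprintf("- modulating: %d%% (sensitivity %d%%, resistance %d%%, high tier %d%%)",
              h$pct_modulating, h$pct_sensitivity, h$pct_resistance,
              h$pct_high),
      "",
      "## Call matrix",
      "",
      knit_call_matrix(report$calls)
    )
    if (!is.null(report$autophagy)) {
      ref <- attr(report$autophagy, "reference")
      md <- c(md, "", "## Autophagy",
              sprintf("- reference condition: %s", ref),
              purrr::pmap_chr(report$autophagy, function(condition,
                                                         fraction,
                                                         fold_vs_reference,
                                                         stars, ...) {
                sprintf("- %s: %.1f%% autophagic, fold %.2f %s",
                        condition, 100 * fraction, fold_vs_reference,
                        stars)
              }))
    }
    p <- file.path(dir, "report.md")
    writeLines(md, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

knit_call_matrix <- function(calls) {
  m <- format_call_matrix(calls)
  header <- paste(names(m), collapse = " | ")
  sep <- paste(rep("---", ncol(m)), collapse = " | ")
  rows <- apply(as.data.frame(m), 1, paste, collapse = " | ")
  paste(c(header, sep, rows), collapse = "\n")
}
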