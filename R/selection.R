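#' Configuration of the candidate selection rules
#'
#' Defaults mirror a screen that prioritises novel biology: genes already
#' known as DNA repair, cell cycle control or ribosomal proteins are
#' excluded; transcription, chromatin remodeling, vesicle transport and
#' protein/mRNA degradation are preferred; candidates must sit in the
#' modulator-homolog LCC and be expressed above 100 intensity units
#' (strictly greater). A `telomere_addon` list can append genes chosen on
#' biological grounds outside the rules (telomere capping is not conserved
#' by homology, so such genes can never enter via projection).
#'
#' @param expression_threshold microarray intensity a candidate must
#'   strictly exceed to count as expressed.
#' @param excluded_categories annotation terms that disqualify a
#'   (non-core) gene.
#' @param preferred_categories annotation terms that raise a gene's rank.
#' @param require_in_lcc restrict the pool to LCC members?
#' @param telomere_addon genes appended unconditionally, flagged as addon.
#' @param max_candidates total list size including addons.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(expression_threshold = 100,
                             excluded_categories = c("DNA repair",
                                                     "cell cycle control",
                                                     "ribosomal protein"),
                             preferred_categories = c("transcription",
                                                      "chromatin remodeling",
                                                      "vesicle transport",
                                                      "protein degradation",
                                                      "mRNA degradation"),
                             require_in_lcc = TRUE,
                             telomere_addon = character(),
                             max_candidates = 45) {
  check_nonnegative(expression_threshold, "expression_threshold")
  check_count(max_candidates, "max_candidates")
  structure(
    list(expression_threshold = expression_threshold,
         excluded_categories = excluded_categories,
         preferred_categories = preferred_categories,
         require_in_lcc = isTRUE(require_in_lcc),
         telomere_addon = toupper(telomere_addon),
         max_candidates = as.integer(max_candidates)),
    class = "selection_config"
  )
}

#' Select knockdown candidates from the modulator-homolog set
#'
#' Applies an ordered rule pipeline with a per-gene audit trail:
#' 1. homologs of yeast genes sensitive to *every* agent (the core set)
#'    are auto-included, bypassing the exclusion rules;
#' 2. the remaining pool is restricted to LCC members (if configured);
#' 3. genes carrying any excluded category are dropped;
#' 4. genes not expressed strictly above the threshold are dropped (a gene
#'    missing from the expression table counts as not expressed and is
#'    logged, not an error);
#' 5. survivors are ranked by (core membership, one-to-one orthology,
#'    preferred category, network degree) descending with the gene symbol
#'    as final tiebreak;
#' 6. the ranked list is truncated so that, after step 7, it never exceeds
#'    `max_candidates`;
#' 7. `telomere_addon` genes are appended unconditionally, flagged.
#'
#' A gene counts as one-to-one when at least one of its yeast orthologs
#' maps to exactly one human gene in the merged table. "Several
#' protein-protein interactions" is treated as a ranking criterion
#' (network degree), not a hard cutoff.
#'
#' @param partition a `modulator_partition` from [project_phenotypes()].
#' @param lcc an `lcc_result` from [induced_lcc()] on the modulator set.
#' @param homology the merged [homology_table()].
#' @param expression data frame (`gene`, `intensity`) or named numeric
#'   vector of microarray intensities.
#' @param annotations data frame (`gene`, `term`).
#' @param cfg a [selection_config()].
#' @param net optional [igraph::graph] used for the degree rank component
#'   (0 for all genes when absent).
#' @return object of class `candidate_selection`: list with `candidates`
#'   (ranked tibble of included genes), `evaluated` (per-gene verdict and
#'   first failing rule) and `trace` (long tibble gene/rule/verdict/detail).
#' @export
select_candidates <- function(partition, lcc, homology, expression,
                              annotations, cfg = selection_config(),
                              net = NULL) {
  stopifnot(inherits(partition, "modulator_partition"),
            inherits(cfg, "selection_config"))
  pool <- partition$modulator_homologs
  core <- partition$core_all_agent_homologs

  if (is.data.frame(expression)) {
    check_columns(expression, c("gene", "intensity"), "expression table")
    expr <- setNames(expression$intensity, toupper(expression$gene))
  } else {
    expr <- setNames(as.numeric(expression), toupper(names(expression)))
  }
  annotations <- tibble::as_tibble(annotations)
  check_columns(annotations, c("gene", "term"), "annotation table")
  ann <- annotations |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::distinct(.data$gene, .data$term)
  known_terms <- c(cfg$excluded_categories, cfg$preferred_categories)
  unknown <- setdiff(unique(ann$term), known_terms)
  terms_by_gene <- split(ann$term, ann$gene)

  ymult <- multiplicity(homology)$yeast
  one_to_one_orfs <- ymult$yeast_orf[ymult$n_human == 1]
  pairs <- dplyr::distinct(tibble::as_tibble(homology), .data$yeast_orf,
                           .data$human_gene)
  o2o_genes <- unique(pairs$human_gene[pairs$yeast_orf %in% one_to_one_orfs])

  deg <- if (!is.null(net)) igraph::degree(net) else numeric()

  trace <- list()
  note <- function(gene, rule, verdict, detail = "") {
    trace[[length(trace) + 1]] <<-
      tibble::tibble(gene = gene, rule = rule, verdict = verdict,
                     detail = detail)
  }

  eval_gene <- function(g) {
    terms <- terms_by_gene[[g]] %||% character()
    is_core <- g %in% core
    if (is_core) note(g, "core_include", "bonus",
                      "ortholog sensitive to all agents")
    in_lcc <- !cfg$require_in_lcc || g %in% lcc$lcc_members
    if (cfg$require_in_lcc) {
      note(g, "in_lcc", if (in_lcc) "pass" else "fail",
           if (in_lcc) "" else "not a member of the LCC")
    }
    hit_excl <- intersect(terms, cfg$excluded_categories)
    note(g, "excluded_category",
         if (length(hit_excl) == 0) "pass" else "fail",
         paste(hit_excl, collapse = ","))
    e <- expr[g]
    expressed <- !is.na(e) && e > cfg$expression_threshold
    note(g, "expressed",
         if (expressed) "pass" else "fail",
         if (is.na(e)) "missing from expression table"
         else sprintf("intensity %.1f vs threshold %g", e,
                      cfg$expression_threshold))
    first_fail <- if (!in_lcc) "in_lcc"
      else if (length(hit_excl) > 0) "excluded_category"
      else if (!expressed) "expressed"
      else NA_character_
    tibble::tibble(
      gene = g, core = is_core,
      eligible = is_core || is.na(first_fail),
      first_fail = if (is_core) NA_character_ else first_fail,
      one_to_one = g %in% o2o_genes,
      preferred = length(intersect(terms, cfg$preferred_categories)) > 0,
      degree = if (g %in% names(deg)) unname(deg[g]) else 0
    )
  }

  evaluated <- if (length(pool) > 0) {
    purrr::map(sort(pool), eval_gene) |> purrr::list_rbind()
  } else {
    tibble::tibble(gene = character(), core = logical(),
                   eligible = logical(), first_fail = character(),
                   one_to_one = logical(), preferred = logical(),
                   degree = numeric())
  }

  budget <- max(0L, cfg$max_candidates - length(cfg$telomere_addon))
  ranked <- evaluated |>
    dplyr::filter(.data$eligible) |>
    dplyr::arrange(dplyr::desc(.data$core), dplyr::desc(.data$one_to_one),
                   dplyr::desc(.data$preferred), dplyr::desc(.data$degree),
                   .data$gene) |>
    head(budget) |>
    dplyr::mutate(addon = FALSE)

  addon <- setdiff(cfg$telomere_addon, ranked$gene)
  if (length(addon) > 0) {
    for (g in addon) note(g, "telomere_addon", "bonus",
                          "appended unconditionally")
    ranked <- dplyr::bind_rows(
      ranked,
      tibble::tibble(gene = addon, core = FALSE, eligible = TRUE,
                     first_fail = NA_character_, one_to_one = FALSE,
                     preferred = FALSE, degree = 0, addon = TRUE))
  }
  candidates <- dplyr::mutate(ranked, rank = dplyr::row_number()) |>
    dplyr::select("rank", "gene", "core", "addon", "one_to_one",
                  "preferred", "degree")

  if (length(unknown) > 0) {
    inform(sprintf(
      "select_candidates: %d annotation term(s) outside the configured categories ignored for rules",
      length(unknown)))
  }

  structure(
    list(candidates = candidates, evaluated = evaluated,
         trace = purrr::list_rbind(trace), config = cfg,
         unknown_terms = unknown),
    class = "candidate_selection"
  )
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat("<candidate_selection>\n")
  cat(sprintf("  %d candidate(s) of %d evaluated (%d core, %d addon)\n",
              nrow(x$candidates), nrow(x$evaluated),
              sum(x$candidates$core), sum(x$candidates$addon)))
  invisible(x)
}

#' @describeIn select_candidates ranked candidate tibble.
#' @param x a `candidate_selection`.
#' @param ... unused.
#' @exportS3Method
tidy.candidate_selection <- function(x, ...) x$candidates

#' @describeIn select_candidates one-row summary of pool and list sizes.
#' @exportS3Method
glance.candidate_selection <- function(x, ...) {
  tibble::tibble(n_evaluated = nrow(x$evaluated),
                 n_eligible = sum(x$evaluated$eligible),
                 n_candidates = nrow(x$candidates),
                 n_core = sum(x$candidates$core),
                 n_addon = sum(x$candidates$addon))
}
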