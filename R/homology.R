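#' Construct a validated ortholog table
#'
#' An ortholog table is a tibble with one row per (yeast ORF, human gene,
#' source) triple, optionally carrying a `confidence` score in \[0, 1\].
#' Gene identifiers are case-normalized to upper case; no alias resolution
#' is attempted. Per-gene multiplicity indices (yeast -> number of human
#' co-orthologs and vice versa, counted over distinct pairs) are attached as
#' an attribute and can always be recomputed with [multiplicity()].
#'
#' @param pairs data frame with columns `yeast_orf`, `human_gene`, `source`
#'   and optionally `confidence`.
#' @return a tibble of class `homology_table`.
#' @export
#' @examples
#' homology_table(data.frame(yeast_orf = "YHR004C", human_gene = "NT5C3A",
#'                           source = "ensembl"))
homology_table <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  check_columns(pairs, c("yeast_orf", "human_gene", "source"),
                "ortholog table")
  pairs <- pairs |>
    dplyr::mutate(yeast_orf = toupper(as.character(.data$yeast_orf)),
                  human_gene = toupper(as.character(.data$human_gene)),
                  source = as.character(.data$source))
  if (nrow(pairs) > 0) {
    if (any(!nzchar(pairs$yeast_orf)) || any(!nzchar(pairs$human_gene)) ||
        anyNA(pairs$yeast_orf) || anyNA(pairs$human_gene)) {
      abort("ortholog table has empty or missing gene identifiers")
    }
    if ("confidence" %in% names(pairs)) {
      bad <- !is.na(pairs$confidence) &
        (pairs$confidence < 0 | pairs$confidence > 1)
      if (any(bad)) abort("`confidence` values must lie in [0, 1]")
    }
    dup <- pairs |>
      dplyr::count(.data$yeast_orf, .data$human_gene, .data$source) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0(
        "duplicate (yeast_orf, human_gene, source) rows: ",
        paste(sprintf("%s/%s/%s", dup$yeast_orf, dup$human_gene, dup$source),
              collapse = ", ")))
    }
  }
  new_homology_table(pairs)
}

new_homology_table <- function(pairs) {
  structure(pairs,
            multiplicity = compute_multiplicity(pairs),
            class = c("homology_table", class(tibble::tibble())))
}

compute_multiplicity <- function(pairs) {
  distinct_pairs <- dplyr::distinct(tibble::as_tibble(pairs),
                                    .data$yeast_orf, .data$human_gene)
  list(
    yeast = dplyr::count(distinct_pairs, .data$yeast_orf,
                         name = "n_human"),
    human = dplyr::count(distinct_pairs, .data$human_gene,
                         name = "n_yeast")
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.homology_table <- function(x, ...) {
  attr(x, "multiplicity") <- NULL
  class(x) <- setdiff(class(x), "homology_table")
  tibble::as_tibble(x, ...)
}

#' Per-gene ortholog multiplicity
#'
#' @param h a [homology_table()].
#' @return list with tibbles `yeast` (yeast_orf, n_human) and `human`
#'   (human_gene, n_yeast), counted over distinct (yeast, human) pairs.
#' @export
multiplicity <- function(h) {
  stopifnot(inherits(h, "homology_table"))
  compute_multiplicity(h)
}

#' Merge two ortholog sources
#'
#' `union` keeps every distinct (yeast, human) pair found in either source;
#' `intersection` keeps pairs present in both. In either mode the source
#' labels supporting a pair are collapsed (sorted, comma-separated) into the
#' `source` column and multiplicity indices are rebuilt. Union is the
#' default: when screening for candidates, recall matters more than
#' per-source agreement.
#'
#' @param a,b [homology_table()] objects.
#' @param mode `"union"` or `"intersection"`.
#' @return a merged [homology_table()] with one row per retained pair.
#' @export
merge_ortholog_sources <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!inherits(a, "homology_table")) a <- homology_table(a)
  if (!inherits(b, "homology_table")) b <- homology_table(b)
  long <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b))
  if (nrow(long) == 0) {
    return(new_homology_table(tibble::tibble(yeast_orf = character(),
                                             human_gene = character(),
                                             source = character())))
  }
  pairs_a <- dplyr::distinct(tibble::as_tibble(a), .data$yeast_orf,
                             .data$human_gene)
  pairs_b <- dplyr::distinct(tibble::as_tibble(b), .data$yeast_orf,
                             .data$human_gene)
  merged <- long |>
    dplyr::group_by(.data$yeast_orf, .data$human_gene) |>
    dplyr::summarise(
      source = paste(sort(unique(.data$source)), collapse = ","),
      .groups = "drop"
    )
  if (mode == "intersection") {
    merged <- merged |>
      dplyr::semi_join(pairs_a, by = c("yeast_orf", "human_gene")) |>
      dplyr::semi_join(pairs_b, by = c("yeast_orf", "human_gene"))
  }
  merged <- dplyr::arrange(merged, .data$yeast_orf, .data$human_gene)
  new_homology_table(merged)
}

normalize_phenotypes <- function(p) {
  p <- tibble::as_tibble(p)
  if (all(c("yeast_orf", "agent", "sensitive") %in% names(p))) {
    long <- p
  } else if ("orf" %in% names(p) && "agent" %in% names(p)) {
    long <- dplyr::rename(p, yeast_orf = "orf")
  } else {
    # wide layout: one identifier column then one 0/1 column per agent
    id_col <- intersect(c("yeast_orf", "orf"), names(p))[1]
    if (is.na(id_col)) {
      abort("phenotype table needs a `yeast_orf` (or `orf`) column")
    }
    long <- tidyr::pivot_longer(p, -dplyr::all_of(id_col),
                                names_to = "agent",
                                values_to = "sensitive") |>
      dplyr::rename(yeast_orf = dplyr::all_of(id_col))
  }
  long |>
    dplyr::mutate(yeast_orf = toupper(as.character(.data$yeast_orf)),
                  sensitive = as.logical(.data$sensitive))
}

#' Project yeast damage phenotypes onto human genes
#'
#' Partitions the human genes carrying at least one screened yeast ortholog
#' into modulator homologs (some ortholog sensitive to at least one agent)
#' and non-modulator homologs (every screened ortholog insensitive to every
#' agent). Human genes whose yeast orthologs were sensitive to *all* agents
#' form the core set, which candidate selection later auto-includes. Yeast
#' ORFs absent from the phenotype table are dropped with a warning count,
#' never treated as insensitive.
#'
#' @param h a [homology_table()] (typically the merged table).
#' @param phenotypes yeast phenotype table: long (`yeast_orf`, `agent`,
#'   `sensitive`) or wide (one 0/1 column per agent).
#' @return object of class `modulator_partition`: a list with character
#'   vectors `modulator_homologs`, `nonmodulator_homologs`,
#'   `core_all_agent_homologs`, a `provenance` tibble (human_gene,
#'   yeast_orf, agent of each sensitive ortholog call), the agent list and
#'   the number of unscreened ORFs dropped. Use [tidy()] for a per-gene
#'   tibble.
#' @export
project_phenotypes <- function(h, phenotypes) {
  if (!inherits(h, "homology_table")) h <- homology_table(h)
  if (nrow(h) == 0) abort("empty ortholog table: nothing to project")
  p <- normalize_phenotypes(phenotypes)
  agents <- sort(unique(p$agent))

  pairs <- dplyr::distinct(tibble::as_tibble(h), .data$yeast_orf,
                           .data$human_gene)
  screened <- unique(p$yeast_orf)
  unscreened <- setdiff(unique(pairs$yeast_orf), screened)
  if (length(unscreened) > 0) {
    warn(sprintf(
      "%d yeast ORF(s) in the ortholog table have no phenotype data and were dropped",
      length(unscreened)))
  }
  pairs <- dplyr::filter(pairs, .data$yeast_orf %in% screened)
  if (nrow(pairs) == 0) {
    abort("no ortholog pair has phenotype data; cannot project")
  }

  joined <- dplyr::inner_join(pairs, p, by = "yeast_orf",
                              relationship = "many-to-many")
  per_orf <- joined |>
    dplyr::group_by(.data$human_gene, .data$yeast_orf) |>
    dplyr::summarise(any_sensitive = any(.data$sensitive),
                     all_sensitive = all(.data$sensitive) &&
                       dplyr::n() == length(agents),
                     .groups = "drop")
  per_gene <- per_orf |>
    dplyr::group_by(.data$human_gene) |>
    dplyr::summarise(modulator = any(.data$any_sensitive),
                     core = any(.data$all_sensitive),
                     .groups = "drop")

  provenance <- joined |>
    dplyr::filter(.data$sensitive) |>
    dplyr::select("human_gene", "yeast_orf", "agent") |>
    dplyr::arrange(.data$human_gene, .data$yeast_orf, .data$agent)

  structure(
    list(
      modulator_homologs = sort(per_gene$human_gene[per_gene$modulator]),
      nonmodulator_homologs = sort(per_gene$human_gene[!per_gene$modulator]),
      core_all_agent_homologs = sort(per_gene$human_gene[per_gene$core]),
      provenance = provenance,
      agents = agents,
      n_unscreened_orfs = length(unscreened)
    ),
    class = "modulator_partition"
  )
}

#' @export
print.modulator_partition <- function(x, ...) {
  cat("<modulator_partition>\n")
  cat(sprintf("  modulator homologs:     %d\n",
              length(x$modulator_homologs)))
  cat(sprintf("  non-modulator homologs: %d\n",
              length(x$nonmodulator_homologs)))
  cat(sprintf("  core (all-agent) set:   %d\n",
              length(x$core_all_agent_homologs)))
  cat(sprintf("  agents: %s; unscreened ORFs dropped: %d\n",
              paste(x$agents, collapse = ", "), x$n_unscreened_orfs))
  invisible(x)
}

#' @describeIn project_phenotypes per-gene tibble (gene, status in
#'   modulator/nonmodulator, core flag).
#' @param x a `modulator_partition`.
#' @param ... unused.
#' @exportS3Method
tidy.modulator_partition <- function(x, ...) {
  tibble::tibble(
    gene = c(x$modulator_homologs, x$nonmodulator_homologs),
    status = rep(c("modulator", "nonmodulator"),
                 c(length(x$modulator_homologs),
                   length(x$nonmodulator_homologs))),
    core = .data$gene %in% x$core_all_agent_homologs
  ) |>
    dplyr::arrange(.data$gene)
}

#' Read ortholog pair and cluster files
#'
#' `read_orthologs()` reads the flat pair layout (columns `yeast_orf`,
#' `human_gene`, `source`, optional `confidence`). `read_inparanoid()`
#' reads a cluster layout (columns `cluster_id`, `species` in
#' yeast/human, `gene`) and expands every cluster into all yeast x human
#' pairs.
#'
#' @param path TSV file path.
#' @param source source label to attach to expanded cluster pairs.
#' @return a [homology_table()].
#' @export
read_orthologs <- function(path) {
  homology_table(read_ortho_tsv(path))
}

#' @rdname read_orthologs
#' @export
read_inparanoid <- function(path, source = "inparanoid") {
  clusters <- read_ortho_tsv(path)
  check_columns(clusters, c("cluster_id", "species", "gene"),
                "cluster file")
  pairs <- clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_map(function(g, key) {
      y <- g$gene[g$species == "yeast"]
      h <- g$gene[g$species == "human"]
      if (length(y) == 0 || length(h) == 0) return(NULL)
      tidyr::expand_grid(yeast_orf = y, human_gene = h)
    }) |>
    purrr::list_rbind()
  homology_table(dplyr::mutate(pairs, source = source))
}

#' Read a yeast phenotype table (long or wide layout)
#'
#' @param path TSV path; long layout has columns `yeast_orf`/`orf`,
#'   `agent`, `sensitive` (0/1); wide layout has one 0/1 column per agent.
#' @return long tibble (`yeast_orf`, `agent`, `sensitive`).
#' @export
read_phenotypes <- function(path) {
  normalize_phenotypes(read_ortho_tsv(path))
}
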