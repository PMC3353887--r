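#' Build a simple undirected interactome from an edge list
#'
#' Self-loops are dropped and duplicate edges (in either orientation)
#' collapsed; the numbers removed are reported as a message and attached as
#' graph attributes `n_self_loops` / `n_duplicates`. Gene symbols are
#' upper-cased to match the homology tables.
#'
#' @param edge_rows two-column data frame or matrix of interacting gene
#'   symbols (extra columns ignored).
#' @return an undirected simple [igraph::graph] with named vertices.
#' @export
#' @examples
#' g <- build_network(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
#' igraph::ecount(g)  # 1
build_network <- function(edge_rows) {
  edge_rows <- as.data.frame(edge_rows)
  if (nrow(edge_rows) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (ncol(edge_rows) < 2) abort("edge rows must have two gene columns")
  ends <- edge_rows[, 1:2]
  bad <- which(is.na(ends[[1]]) | is.na(ends[[2]]) |
                 !nzchar(as.character(ends[[1]])) |
                 !nzchar(as.character(ends[[2]])))
  if (length(bad) > 0) {
    abort(sprintf("malformed edge row(s) at line(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  a <- toupper(as.character(ends[[1]]))
  b <- toupper(as.character(ends[[2]]))
  self <- a == b
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  dup <- duplicated(key) & !self
  g <- igraph::graph_from_edgelist(
    cbind(a[!self & !dup], b[!self & !dup]), directed = FALSE)
  if (sum(self) + sum(dup) > 0) {
    inform(sprintf("build_network: dropped %d self-loop(s), %d duplicate edge(s)",
                   sum(self), sum(dup)))
  }
  g <- igraph::set_graph_attr(g, "n_self_loops", sum(self))
  igraph::set_graph_attr(g, "n_duplicates", sum(dup))
}

#' Read / write interactome files
#'
#' `read_sif()` parses the simple interaction format (`nodeA pp nodeB
#' [nodeC ...]`, whitespace-separated); `read_edge_tsv()` reads a
#' two-column TSV. `write_sif()` and `write_graphml()` export a graph.
#'
#' @param path file path.
#' @param g an [igraph::graph].
#' @param relation SIF relation label.
#' @return `read_*` return an [igraph::graph] via [build_network()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- purrr::map(lines, function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(parts) < 3) {
      abort(sprintf("malformed SIF line: '%s'", l))
    }
    tibble::tibble(a = parts[1], b = parts[3:length(parts)])
  }) |>
    purrr::list_rbind()
  build_network(rows)
}

#' @rdname read_sif
#' @export
read_edge_tsv <- function(path) {
  build_network(read_ortho_tsv(path))
}

#' @rdname read_sif
#' @export
write_sif <- function(g, path, relation = "pp") {
  el <- igraph::as_edgelist(g)
  writeLines(sprintf("%s\t%s\t%s", el[, 1], relation, el[, 2]), path)
  invisible(path)
}

#' @rdname read_sif
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Largest connected component induced by a gene set
#'
#' Takes the subgraph induced on `query` genes present in the network and
#' returns its largest connected component. Ties between equally large
#' components are broken deterministically by the lexicographically
#' smallest member. When no query gene is in the network the LCC and its
#' fractions are explicitly undefined (`NA`), never 0. Because query genes
#' can be absent from the interactome, the LCC fraction is reported against
#' both denominators: genes present in the network (`lcc_fraction`) and the
#' full query (`lcc_fraction_of_query`).
#'
#' @param net an [igraph::graph] with named vertices.
#' @param query character vector of gene symbols.
#' @return object of class `lcc_result`; see [tidy()] / [glance()].
#' @export
induced_lcc <- function(net, query) {
  query <- unique(toupper(query))
  nodes <- igraph::V(net)$name
  present <- intersect(query, nodes)
  if (length(present) == 0) {
    res <- list(query_size = length(query), in_network = 0L,
                lcc_size = NA_integer_, lcc_members = character(),
                lcc_fraction = NA_real_, lcc_fraction_of_query = NA_real_,
                component_sizes = integer())
    return(structure(res, class = "lcc_result"))
  }
  sub <- igraph::induced_subgraph(net, present)
  comp <- igraph::components(sub)
  sizes <- as.integer(comp$csize)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_member <- vapply(best, function(ci) {
      min(igraph::V(sub)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(first_member)][1]
  }
  members <- sort(igraph::V(sub)$name[comp$membership == best])
  structure(
    list(query_size = length(query),
         in_network = length(present),
         lcc_size = length(members),
         lcc_members = members,
         lcc_fraction = length(members) / length(present),
         lcc_fraction_of_query = length(members) / length(query),
         component_sizes = sort(sizes, decreasing = TRUE)),
    class = "lcc_result"
  )
}

#' @export
print.lcc_result <- function(x, ...) {
  cat("<lcc_result>\n")
  if (x$in_network == 0) {
    cat(sprintf("  %d query genes, none in the network; LCC undefined\n",
                x$query_size))
  } else {
    cat(sprintf("  query %d genes, %d in network; LCC %d (%.0f%% of mapped, %.0f%% of query)\n",
                x$query_size, x$in_network, x$lcc_size,
                100 * x$lcc_fraction, 100 * x$lcc_fraction_of_query))
  }
  invisible(x)
}

#' @describeIn induced_lcc one-row summary tibble.
#' @param x an `lcc_result`.
#' @param ... unused.
#' @exportS3Method
glance.lcc_result <- function(x, ...) {
  tibble::tibble(query_size = x$query_size, in_network = x$in_network,
                 lcc_size = x$lcc_size, lcc_fraction = x$lcc_fraction,
                 lcc_fraction_of_query = x$lcc_fraction_of_query)
}

#' @describeIn induced_lcc per-member tibble of the LCC.
#' @exportS3Method
tidy.lcc_result <- function(x, ...) {
  tibble::tibble(gene = x$lcc_members)
}

degree_bin <- function(deg) {
  ifelse(deg == 0, 0L, as.integer(ceiling(log2(pmax(deg, 1)))) + 1L)
}

#' Permutation test for induced-LCC size
#'
#' Assesses whether a gene set is more internally connected than random
#' sets of the same size. Each permutation draws, without replacement, as
#' many network nodes as the query has in the network — either uniformly or
#' matched on degree (within geometric degree bins 1, 2, 3-4, 5-8, ...,
#' with isolated nodes in their own bin) — and records the induced-LCC
#' size. The p-value uses the add-one estimator `(n_geq + 1) /
#' (n_permutations + 1)`; when no permutation reaches the observed size the
#' estimate is flagged as an upper bound and is never reported as 0.
#'
#' @param net an [igraph::graph] with named vertices.
#' @param query character vector of gene symbols.
#' @param n_permutations number of permutations (>= 1).
#' @param null_model `"uniform"` (default) or `"degree_matched"`. Hub genes
#'   inflate connectivity, so the degree-matched null is stricter.
#' @param seed integer seed for the permutation stream.
#' @return object of class `lcc_permutation` with the observed LCC size,
#'   `p_estimate`, `p_is_upper_bound`, and the null LCC-size distribution.
#' @export
permutation_test_lcc <- function(net, query, n_permutations = 1000,
                                 null_model = c("uniform", "degree_matched"),
                                 seed = 1L) {
  null_model <- match.arg(null_model)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  obs <- induced_lcc(net, query)
  if (obs$in_network == 0) {
    abort("no query gene is present in the network; permutation test undefined")
  }
  nodes <- igraph::V(net)$name
  k <- obs$in_network

  withr::local_seed(as.integer(seed))
  if (null_model == "uniform") {
    draw <- function() sample(nodes, k)
  } else {
    deg <- igraph::degree(net)
    bins <- degree_bin(deg)
    pool <- split(nodes, bins)
    qbins <- bins[match(intersect(toupper(query), nodes), nodes)]
    need <- table(qbins)
    draw <- function() {
      unlist(lapply(names(need), function(b) {
        sample(pool[[b]], need[[b]])
      }), use.names = FALSE)
    }
  }

  null_sizes <- vapply(seq_len(n_permutations), function(i) {
    sub <- igraph::induced_subgraph(net, draw())
    max(igraph::components(sub)$csize)
  }, numeric(1))

  n_geq <- sum(null_sizes >= obs$lcc_size)
  structure(
    list(observed_lcc = obs$lcc_size,
         in_network = obs$in_network,
         n_permutations = as.integer(n_permutations),
         n_geq = as.integer(n_geq),
         p_estimate = (n_geq + 1) / (n_permutations + 1),
         p_is_upper_bound = n_geq == 0,
         null_model = null_model,
         seed = as.integer(seed),
         null_mean = mean(null_sizes),
         null_sd = stats::sd(null_sizes),
         null_max = max(null_sizes),
         null_sizes = as.integer(null_sizes)),
    class = "lcc_permutation"
  )
}

#' @export
print.lcc_permutation <- function(x, ...) {
  cat("<lcc_permutation>\n")
  cat(sprintf("  observed LCC %d (of %d in network), null %s: mean %.1f, max %d\n",
              x$observed_lcc, x$in_network, x$null_model, x$null_mean,
              x$null_max))
  cat(sprintf("  p %s %.3g (%d of %d permutations >= observed)\n",
              if (x$p_is_upper_bound) "<" else "=",
              x$p_estimate, x$n_geq, x$n_permutations))
  invisible(x)
}

#' @describeIn permutation_test_lcc one-row summary tibble.
#' @param x an `lcc_permutation`.
#' @param ... unused.
#' @exportS3Method
glance.lcc_permutation <- function(x, ...) {
  tibble::tibble(observed_lcc = x$observed_lcc, in_network = x$in_network,
                 n_permutations = x$n_permutations, n_geq = x$n_geq,
                 p_estimate = x$p_estimate,
                 p_is_upper_bound = x$p_is_upper_bound,
                 null_model = x$null_model, null_mean = x$null_mean,
                 null_sd = x$null_sd, null_max = x$null_max)
}

#' @describeIn permutation_test_lcc per-permutation null LCC sizes.
#' @exportS3Method
tidy.lcc_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_permutations),
                 null_lcc = x$null_sizes)
}

#' @describeIn permutation_test_lcc histogram of the null LCC distribution
#'   with the observed value marked.
#' @param object an `lcc_permutation`.
#' @exportS3Method
autoplot.lcc_permutation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_lcc)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_lcc,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "null LCC size", y = "permutations",
      title = sprintf("Observed LCC = %d, p %s %.3g (%s null)",
                      object$observed_lcc,
                      if (object$p_is_upper_bound) "<" else "=",
                      object$p_estimate, object$null_model)) +
    ggplot2::theme_minimal()
}

#' Hypergeometric functional-category enrichment
#'
#' For every annotation term with at least one member in the query, tests
#' over-representation of the term in the query against the background with
#' the upper-tail hypergeometric probability P(X >= k), and attaches
#' Benjamini-Hochberg adjusted values.
#'
#' @param query character vector of genes (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param annotation data frame with columns `gene`, `term`.
#' @return tibble with columns `term`, `k`, `K`, `n`, `N`, `p_hypergeom`,
#'   `fold`, `p_adjusted`, sorted by p.
#' @export
hypergeom_enrichment <- function(query, background, annotation) {
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  extra <- setdiff(query, background)
  if (length(extra) > 0) {
    abort(sprintf("query gene(s) not in background: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  annotation <- tibble::as_tibble(annotation)
  check_columns(annotation, c("gene", "term"), "annotation table")
  ann <- annotation |>
    dplyr::mutate(gene = toupper(.data$gene)) |>
    dplyr::distinct(.data$gene, .data$term) |>
    dplyr::filter(.data$gene %in% background)
  N <- length(background)
  n <- length(query)
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(k = sum(.data$gene %in% query), K = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(
      n = n, N = N,
      p_hypergeom = phyper(.data$k - 1, .data$K, N - .data$K, n,
                           lower.tail = FALSE),
      fold = (.data$k / n) / (.data$K / N)
    ) |>
    dplyr::arrange(.data$p_hypergeom, .data$term)
  res$p_adjusted <- p.adjust(res$p_hypergeom, method = "BH")
  res
}
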