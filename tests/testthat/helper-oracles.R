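# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and stats::fisher.test / stats::phyper) so that each test
# compares two independent routes to the same number.

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, summing probabilities <= that of the observed table.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  avals <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(avals, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[avals == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Largest-connected-component size of the subgraph induced on `query`,
# via union-find on the edge list.
oracle_lcc_size <- function(edges, query) {
  nodes <- query
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1]; v <- edges[i, 2]
      if (u %in% nodes && v %in% nodes && u != v) {
        ru <- find(u); rv <- find(v)
        if (ru != rv) parent[[ru]] <- rv
      }
    }
  }
  if (length(nodes) == 0) return(0L)
  max(table(vapply(nodes, find, character(1))))
}

# Exact null distribution of the induced-LCC size under uniform node
# sampling: enumerate all size-k subsets of the graph's nodes.
oracle_lcc_null <- function(g, k) {
  nodes <- igraph::V(g)$name
  edges <- igraph::as_edgelist(g)
  subsets <- utils::combn(nodes, k, simplify = FALSE)
  vapply(subsets, function(s) oracle_lcc_size(edges, s), numeric(1))
}

# Set-algebra oracle for ortholog-table merging over (yeast, human) tuples.
oracle_merge_pairs <- function(a, b, mode) {
  key <- function(df) unique(paste(df$yeast_orf, df$human_gene, sep = "\r"))
  ka <- key(a); kb <- key(b)
  keys <- if (mode == "union") union(ka, kb) else intersect(ka, kb)
  parts <- strsplit(sort(keys), "\r", fixed = TRUE)
  tibble::tibble(yeast_orf = vapply(parts, `[`, "", 1),
                 human_gene = vapply(parts, `[`, "", 2))
}

# Direct double-loop oracle for phenotype projection.
oracle_projection <- function(pairs, phen) {
  genes <- sort(unique(pairs$human_gene))
  agents <- unique(phen$agent)
  sens_of <- function(orf) phen$sensitive[phen$yeast_orf == orf]
  out <- list(modulator = character(), nonmodulator = character(),
              core = character())
  for (g in genes) {
    orfs <- unique(pairs$yeast_orf[pairs$human_gene == g])
    orfs <- orfs[orfs %in% phen$yeast_orf]
    if (length(orfs) == 0) next
    any_sens <- any(vapply(orfs, function(o) any(sens_of(o)), logical(1)))
    all_sens <- any(vapply(orfs, function(o) {
      s <- sens_of(o); length(s) == length(agents) && all(s)
    }, logical(1)))
    if (any_sens) out$modulator <- c(out$modulator, g)
    else out$nonmodulator <- c(out$nonmodulator, g)
    if (all_sens) out$core <- c(out$core, g)
  }
  out
}

# Small complete survival-observation fixture: one control and test lines
# with exact per-dose survival multipliers (no noise), 2+ replicates.
make_survival_fixture <- function(lines_mult, doses = c(0, 1, 2),
                                  n_rep = 3, cells = 1000, pe = 0.5,
                                  agent = "MMS",
                                  control_surv = c(1, 0.5, 0.1)) {
  rows <- list()
  for (ln in names(lines_mult)) {
    role <- attr(lines_mult[[ln]], "role") %||% "test"
    mult <- as.numeric(lines_mult[[ln]])  # recycled over replicates
    for (di in seq_along(doses)) {
      for (r in seq_len(n_rep)) {
        m <- mult[(r - 1) %% length(mult) + 1]
        s <- control_surv[di] * if (doses[di] == 0) 1 else m
        rows[[length(rows) + 1]] <- tibble::tibble(
          line = ln, agent = agent, dose = doses[di], replicate = r,
          colonies = as.integer(round(min(s, 1) * pe * cells)),
          cells_seeded = cells, role = role)
      }
    }
  }
  purrr::list_rbind(rows)
}

with_role <- function(x, role) { attr(x, "role") <- role; x }

# Fixture call table with chosen per-line categories across 4 agents:
# the line's strongest category at agent 1, none elsewhere.
make_call_table <- function(categories,
                            agents = c("MMS", "4NQO", "tBuOOH", "UV")) {
  purrr::imap(categories, function(cat, i) {
    tibble::tibble(line = sprintf("L%02d", i), agent = agents,
                   category = c(cat, rep("none", length(agents) - 1)))
  }) |> purrr::list_rbind()
}
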