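# small deterministic jitter so replicate groups have nonzero variance
jit <- function(x) x * 2^c(-0.01, 0, 0.01)

test_that("relative survival normalizes by plating efficiency", {
  obs <- tibble::tibble(
    line = "L", agent = "MMS", dose = c(0, 0, 1, 1, 2, 2),
    replicate = rep(1:2, 3),
    colonies = c(50L, 50L, 10L, 10L, 0L, 60L),
    cells_seeded = 100L)
  curves <- suppressMessages(relative_survival(obs))
  expect_equal(curves$rel_survival[curves$dose == 0], c(1, 1))
  # PE = 0.5; 10/100 / 0.5 = 0.2
  expect_equal(curves$rel_survival[curves$dose == 1], c(0.2, 0.2))
  # zero colonies -> 0.5-colony continuity correction, flagged
  expect_equal(curves$rel_survival[curves$dose == 2][1], 0.01)
  expect_true(curves$corrected[curves$dose == 2][1])
  # 60/100 / 0.5 = 1.2 capped at 1
  expect_equal(curves$rel_survival[curves$dose == 2][2], 1)
  expect_error(relative_survival(dplyr::filter(obs, dose > 0)),
               "L/MMS")
  expect_error(relative_survival(dplyr::mutate(obs, colonies = 200L)),
               "colonies")
})

test_that("relative survival equals a naive per-row recomputation", {
  withr::local_seed(41)
  obs <- tidyr::expand_grid(line = c("A", "B"), agent = c("MMS", "UV"),
                            dose = c(0, 1, 2), replicate = 1:3) |>
    dplyr::mutate(cells_seeded = 200L,
                  colonies = as.integer(rbinom(dplyr::n(), 100, 0.5)))
  curves <- suppressMessages(relative_survival(obs))
  for (i in sample(nrow(curves), 10)) {
    row <- curves[i, ]
    sub <- obs[obs$line == row$line & obs$agent == row$agent, ]
    pe <- mean(pmax(sub$colonies[sub$dose == 0], 0.5) /
                 sub$cells_seeded[sub$dose == 0])
    col <- sub$colonies[sub$dose == row$dose &
                          sub$replicate == row$replicate]
    expect_equal(row$rel_survival,
                 min(max(col, 0.5) / 200 / pe, 1))
  }
})

test_that("noise region is min/max of control log2 ratios and contains 0", {
  fx <- make_survival_fixture(list(
    shNT = with_role(1, "nontargeting"),
    NS1 = with_role(2^-0.1, "nonsilenced"),
    NS2 = with_role(2^0.05, "nonsilenced")), cells = 1e5)
  curves <- relative_survival(fx)
  nz <- build_noise_region(curves)
  top <- nz[nz$dose == 2, ]
  expect_lt(abs(top$lo - -0.1), 0.01)
  expect_lt(abs(top$hi - 0.05), 0.01)
  expect_true(all(nz$lo <= 0 & nz$hi >= 0))

  only_nt <- relative_survival(
    make_survival_fixture(list(shNT = with_role(1, "nontargeting"))))
  nz0 <- build_noise_region(only_nt)
  expect_true(all(nz0$lo == 0 & nz0$hi == 0))

  no_ctrl <- dplyr::mutate(only_nt, role = "test")
  expect_error(build_noise_region(no_ctrl), "non-targeting")
})

test_that("noise region width grows with replicate noise", {
  width_at <- function(cv) {
    cfg <- sim_config(n_yeast_genes = 20, n_human_genes = 20,
                      n_core_sensitive = 0, replicate_cv = cv,
                      n_nonsilenced_lines = 4, agents = "MMS", seed = 43)
    out <- simulate_survival(cfg, list())
    nz <- build_noise_region(
      suppressMessages(relative_survival(out$observations)))
    mean(nz$hi[nz$dose > 0] - nz$lo[nz$dose > 0])
  }
  expect_lt(width_at(0.02), width_at(0.30))
})

test_that("calls respect direction and the 0.26 / 0.32 tier thresholds", {
  mk <- function(mult) {
    fx <- make_survival_fixture(list(shNT = with_role(jit(1), "nontargeting"),
                                     KD = jit(mult)), cells = 1e5)
    curves <- relative_survival(fx)
    call_toxicity(curves, build_noise_region(curves))
  }
  # noise region from the non-targeting line alone is [0, 0] up to jitter,
  # so the excess is essentially the injected log2 shift
  expect_equal(as.character(mk(2^-0.40)$category), "high_sensitivity")
  expect_equal(as.character(mk(2^0.40)$category), "high_resistance")
  expect_equal(as.character(mk(2^-0.28)$category), "low_sensitivity")
  expect_equal(as.character(mk(2^0.28)$category), "low_resistance")
  expect_equal(as.character(mk(2^-0.20)$category), "none")
  # identical curve -> none with zero excess
  same <- mk(1)
  expect_equal(as.character(same$category), "none")
  expect_equal(same$effect_log2_beyond_noise, 0)
})

test_that("call table carries per-dose details and enforces its contract", {
  fx <- make_survival_fixture(list(shNT = with_role(jit(1), "nontargeting"),
                                   KD = jit(2^-0.5)), cells = 1e5)
  curves <- relative_survival(fx)
  nz <- build_noise_region(curves)
  calls <- call_toxicity(curves, nz)
  det <- attr(calls, "details")
  expect_true(all(c("ratio_log2", "excess", "p") %in% names(det)))
  # no call with p >= alpha or |excess| below the low threshold
  called <- dplyr::filter(tibble::as_tibble(calls), category != "none")
  expect_true(all(called$p_value < 0.05))
  expect_true(all(abs(called$effect_log2_beyond_noise) >= 0.26))

  # mismatched dose grid
  expect_error(
    call_toxicity(dplyr::filter(curves, !(line == "KD" & dose == 2)), nz),
    "dose grids")
  # single replicate
  fx1 <- make_survival_fixture(list(shNT = with_role(1, "nontargeting"),
                                    KD = 2^-0.5), n_rep = 1, cells = 1e5)
  c1 <- relative_survival(fx1)
  expect_error(call_toxicity(c1, build_noise_region(c1)), "replicates")
})

test_that("knockdown classification uses a strict 0.60 boundary", {
  got <- classify_knockdown(c(0.59, 0.60, 0, 0.99))
  expect_equal(as.character(got),
               c("silenced", "non_silenced", "silenced", "non_silenced"))
  expect_error(classify_knockdown(-0.1), "non-negative")
})

test_that("screen summary reproduces percentages from category counts", {
  calls <- make_call_table(c(rep("high_sensitivity", 11),
                             rep("low_sensitivity", 3),
                             rep("high_resistance", 8),
                             rep("low_resistance", 3),
                             rep("none", 9)))
  s <- summarize_screen(calls)
  expect_equal(s$n_called_lines, 34)
  expect_equal(s$pct_sensitivity, 41)
  expect_equal(s$pct_resistance, 32)
  expect_equal(s$pct_high, 56)
  expect_equal(s$pct_modulating, 74)
  # percentages recompute exactly from the per-line table
  expect_equal(s$pct_modulating,
               round_half_up(100 * sum(s$per_line$modulator) /
                               nrow(s$per_line)))
  # per-agent category counts sum to the number of lines
  counts <- s$category_counts
  expect_true(all(rowSums(counts[, -1]) == 34))
  expect_error(summarize_screen(calls[0, ]), "empty")
})

test_that("screen-vs-comparison contingency uses two-sided Fisher", {
  screen <- make_call_table(c(rep("high_sensitivity", 25), rep("none", 9)))
  comp <- make_call_table(c("low_sensitivity", rep("none", 3)))
  s <- summarize_screen(screen, comp)
  expect_equal(unname(s$contingency),
               matrix(c(25, 9, 1, 3), 2, byrow = TRUE))
  expect_equal(s$fisher_p, oracle_fisher_2x2(s$contingency),
               tolerance = 1e-10)
})

test_that("fisher_exact_2x2 matches enumeration and handles degenerate tables", {
  tab <- matrix(c(25, 9, 1, 3), 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  expect_equal(round(res$p_value, 2), 0.08)
  expect_equal(res$p_value, oracle_fisher_2x2(tab), tolerance = 1e-10)
  # diagonal extreme with equal counts: p = 2 / C(k+m, k)
  for (k in c(2, 3, 5)) {
    d <- fisher_exact_2x2(matrix(c(k, 0, 0, k), 2))
    expect_equal(d$p_value, 2 / choose(2 * k, k), tolerance = 1e-10)
  }
  z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("the five-symbol call matrix renders the heatmap convention", {
  calls <- tibble::tibble(
    line = "L1", agent = c("MMS", "4NQO", "tBuOOH", "UV"),
    category = c("high_resistance", "low_resistance", "none",
                 "high_sensitivity"))
  m <- format_call_matrix(calls)
  expect_equal(unlist(m[1, c("MMS", "4NQO", "tBuOOH", "UV")],
                      use.names = FALSE),
               c("++", "+", ".", "--"))
})
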