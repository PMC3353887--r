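#' Configuration of the toxicity caller
#'
#' The defaults are the screen's printed constants: two-sided significance
#' at `alpha = 0.05`; a call requires at least a 20% survival change beyond
#' the noise region (`log2(1.20) = 0.26` in log2 space) and the high tier
#' requires 25% (`log2(1.25) = 0.32`); knockdown counts as achieved below
#' 60% residual mRNA.
#'
#' @param alpha significance level of the per-dose Welch t-test.
#' @param low_threshold_log2 minimum |excess| beyond the noise-region
#'   boundary for any call, in log2 units.
#' @param high_threshold_log2 minimum |excess| for the high tier.
#' @param knockdown_residual_max residual mRNA fraction strictly below
#'   which a line counts as silenced.
#' @return object of class `caller_config`.
#' @export
caller_config <- function(alpha = 0.05,
                          low_threshold_log2 = 0.26,
                          high_threshold_log2 = 0.32,
                          knockdown_residual_max = 0.60) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (low_threshold_log2 <= 0 || high_threshold_log2 <= low_threshold_log2) {
    abort("thresholds must satisfy 0 < low_threshold_log2 < high_threshold_log2")
  }
  check_fraction(knockdown_residual_max, "knockdown_residual_max")
  structure(list(alpha = alpha,
                 low_threshold_log2 = low_threshold_log2,
                 high_threshold_log2 = high_threshold_log2,
                 knockdown_residual_max = knockdown_residual_max),
            class = "caller_config")
}

toxicity_categories <- c("high_resistance", "low_resistance", "none",
                         "low_sensitivity", "high_sensitivity")

call_symbols <- c(high_resistance = "++", low_resistance = "+",
                  none = ".", low_sensitivity = "-",
                  high_sensitivity = "--")

#' Relative survival from colony counts
#'
#' Converts raw clonogenic observations to plating-efficiency-normalized
#' relative survival: per line x agent, PE = mean(colonies / cells seeded)
#' over the untreated (dose 0) replicates, and each replicate's relative
#' survival is (colonies / cells seeded) / PE, capped at 1. Zero-colony
#' replicates get a 0.5-colony continuity correction (flagged in the
#' `corrected` column) so log2 ratios stay finite.
#'
#' @param obs tibble with columns `line`, `agent`, `dose`, `replicate`,
#'   `colonies`, `cells_seeded` and optionally `role` (test /
#'   nontargeting / nonsilenced; defaults to test).
#' @return tibble with columns `line`, `agent`, `dose`, `replicate`,
#'   `rel_survival`, `corrected`, `role`.
#' @export
relative_survival <- function(obs) {
  obs <- tibble::as_tibble(obs)
  check_columns(obs, c("line", "agent", "dose", "replicate", "colonies",
                       "cells_seeded"), "survival observations")
  if (!"role" %in% names(obs)) obs$role <- "test"
  if (any(obs$colonies < 0) || any(obs$cells_seeded <= 0) ||
      any(obs$colonies > obs$cells_seeded)) {
    abort("observations must satisfy 0 <= colonies <= cells_seeded, cells_seeded > 0")
  }
  missing0 <- obs |>
    dplyr::group_by(.data$line, .data$agent) |>
    dplyr::summarise(has0 = any(.data$dose == 0), .groups = "drop") |>
    dplyr::filter(!.data$has0)
  if (nrow(missing0) > 0) {
    abort(sprintf("missing dose-0 observations for: %s",
                  paste(sprintf("%s/%s", missing0$line, missing0$agent),
                        collapse = ", ")))
  }
  out <- obs |>
    dplyr::mutate(corrected = .data$colonies == 0,
                  colonies_adj = ifelse(.data$colonies == 0, 0.5,
                                        .data$colonies)) |>
    dplyr::group_by(.data$line, .data$agent) |>
    dplyr::mutate(pe = mean(.data$colonies_adj[.data$dose == 0] /
                              .data$cells_seeded[.data$dose == 0])) |>
    dplyr::ungroup() |>
    dplyr::mutate(rel_survival = pmin(
      (.data$colonies_adj / .data$cells_seeded) / .data$pe, 1)) |>
    dplyr::select("line", "agent", "dose", "replicate", "rel_survival",
                  "corrected", "role")
  n_corr <- sum(out$corrected)
  if (n_corr > 0) {
    inform(sprintf(
      "relative_survival: %d zero-colony replicate(s) given the 0.5-colony continuity correction",
      n_corr))
  }
  out
}

#' Control-derived noise region of the screen
#'
#' Per agent and dose, each control line (the non-targeting shRNA line(s)
#' and any non-silenced shRNA lines) contributes log2(mean survival of the
#' line / mean survival of the non-targeting control); the noise region is
#' the \[min, max\] interval of these ratios. The non-targeting control's
#' self-ratio is 0, so the region always contains 0; calls later require
#' exceeding its boundary. The region widens with replicate noise and with
#' the off-target variability of the non-silenced lines — these are the
#' detection limits of the screen.
#'
#' @param curves output of [relative_survival()]; control lines are the
#'   rows with `role` `"nontargeting"` or `"nonsilenced"`.
#' @return tibble with columns `agent`, `dose`, `lo`, `hi`.
#' @export
build_noise_region <- function(curves) {
  ctrl <- dplyr::filter(curves,
                        .data$role %in% c("nontargeting", "nonsilenced"))
  agents <- unique(curves$agent)
  no_nt <- setdiff(agents,
                   unique(ctrl$agent[ctrl$role == "nontargeting"]))
  if (length(no_nt) > 0) {
    abort(sprintf("no non-targeting control for agent(s): %s",
                  paste(no_nt, collapse = ", ")))
  }
  nt_mean <- ctrl |>
    dplyr::filter(.data$role == "nontargeting") |>
    dplyr::group_by(.data$agent, .data$dose) |>
    dplyr::summarise(nt = mean(.data$rel_survival), .groups = "drop")
  ctrl |>
    dplyr::group_by(.data$agent, .data$dose, .data$line) |>
    dplyr::summarise(m = mean(.data$rel_survival), .groups = "drop") |>
    dplyr::inner_join(nt_mean, by = c("agent", "dose")) |>
    dplyr::mutate(ratio = log2(.data$m / .data$nt)) |>
    dplyr::group_by(.data$agent, .data$dose) |>
    dplyr::summarise(lo = min(c(.data$ratio, 0)),
                     hi = max(c(.data$ratio, 0)), .groups = "drop") |>
    dplyr::arrange(.data$agent, .data$dose)
}

#' Call toxicity modulation per line and agent
#'
#' For each test line, agent and treatment dose, computes the log2 ratio of
#' mean relative survival versus the contemporaneous non-targeting control,
#' the *excess* of that ratio beyond the nearest noise-region boundary
#' (0 inside the region), and a two-sided Welch t-test on the log2
#' replicate survivals against the control replicates. A dose qualifies at
#' the low tier when p < alpha and |excess| >= `low_threshold_log2`
#' (a 20% survival change beyond the noise region), and at the high tier
#' when additionally |excess| >= `high_threshold_log2` (25%). The call
#' uses the qualifying dose with the largest |excess|; resistance when the
#' excess is positive, sensitivity when negative; `none` when no dose
#' qualifies. No multiple-testing correction is applied across lines or
#' doses.
#'
#' @param curves output of [relative_survival()] containing the test lines
#'   and at least one `nontargeting` line per agent.
#' @param noise noise region from [build_noise_region()].
#' @param cfg a [caller_config()].
#' @return tibble of class `toxicity_calls`: `line`, `agent`, `category`
#'   (factor over high_resistance, low_resistance, none, low_sensitivity,
#'   high_sensitivity), `best_dose`, `effect_log2_beyond_noise`,
#'   `p_value`. Per-dose statistics are attached as attribute
#'   `"details"`.
#' @export
call_toxicity <- function(curves, noise, cfg = caller_config()) {
  stopifnot(inherits(cfg, "caller_config"))
  test <- dplyr::filter(curves, .data$role == "test")
  nt <- dplyr::filter(curves, .data$role == "nontargeting")
  if (nrow(test) == 0) abort("no test lines in `curves`")
  if (nrow(nt) == 0) abort("no non-targeting control in `curves`")

  groups <- dplyr::distinct(test, .data$line, .data$agent)
  details <- vector("list", nrow(groups))
  calls <- vector("list", nrow(groups))

  for (i in seq_len(nrow(groups))) {
    ln <- groups$line[i]
    ag <- groups$agent[i]
    cur <- dplyr::filter(test, .data$line == ln, .data$agent == ag)
    ctl <- dplyr::filter(nt, .data$agent == ag)
    doses <- sort(unique(cur$dose[cur$dose > 0]))
    ctl_doses <- sort(unique(ctl$dose[ctl$dose > 0]))
    if (!setequal(doses, ctl_doses)) {
      abort(sprintf("dose grids differ between %s and the control for %s",
                    ln, ag))
    }
    nz <- dplyr::filter(noise, .data$agent == ag)
    if (!all(doses %in% nz$dose)) {
      abort(sprintf("noise region missing dose(s) for %s", ag))
    }
    per_dose <- purrr::map(doses, function(d) {
      xs <- cur$rel_survival[cur$dose == d]
      ys <- ctl$rel_survival[ctl$dose == d]
      if (length(xs) < 2 || length(ys) < 2) {
        abort(sprintf(
          "need >= 2 replicates per dose for a t-test (%s/%s, dose %g)",
          ln, ag, d))
      }
      r <- log2(mean(xs) / mean(ys))
      lo <- nz$lo[nz$dose == d]
      hi <- nz$hi[nz$dose == d]
      excess <- if (r > hi) r - hi else if (r < lo) r - lo else 0
      lx <- log2(xs); ly <- log2(ys)
      p <- if (stats::sd(c(lx, ly)) == 0) 1 else t.test(lx, ly)$p.value
      tibble::tibble(line = ln, agent = ag, dose = d, ratio_log2 = r,
                     lo = lo, hi = hi, excess = excess, p = p)
    }) |>
      purrr::list_rbind() |>
      dplyr::mutate(
        qualifies_low = .data$p < cfg$alpha &
          abs(.data$excess) >= cfg$low_threshold_log2,
        qualifies_high = .data$qualifies_low &
          abs(.data$excess) >= cfg$high_threshold_log2
      )
    details[[i]] <- per_dose

    qual <- dplyr::filter(per_dose, .data$qualifies_low)
    if (nrow(qual) == 0) {
      calls[[i]] <- tibble::tibble(line = ln, agent = ag,
                                   category = "none",
                                   best_dose = NA_real_,
                                   effect_log2_beyond_noise = 0,
                                   p_value = NA_real_)
    } else {
      best <- qual[which.max(abs(qual$excess)), ]
      tier <- if (best$qualifies_high) "high" else "low"
      dir <- if (best$excess > 0) "resistance" else "sensitivity"
      calls[[i]] <- tibble::tibble(line = ln, agent = ag,
                                   category = paste(tier, dir, sep = "_"),
                                   best_dose = best$dose,
                                   effect_log2_beyond_noise = best$excess,
                                   p_value = best$p)
    }
  }

  out <- purrr::list_rbind(calls) |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = toxicity_categories))
  structure(out,
            details = purrr::list_rbind(details),
            class = c("toxicity_calls", class(tibble::tibble())))
}

#' Classify knockdown efficiency from qRT-PCR residual mRNA
#'
#' A line is `silenced` when its residual mRNA fraction versus control is
#' strictly below `residual_max` (default 0.60); lines at or above the
#' boundary are `non_silenced` and belong in the noise-region control
#' pool, not among the test lines.
#'
#' @param residual numeric vector of residual mRNA fractions (>= 0).
#' @param residual_max the silenced / non-silenced boundary.
#' @return factor with levels `silenced`, `non_silenced`.
#' @export
#' @examples
#' classify_knockdown(c(0.59, 0.60, 0))
classify_knockdown <- function(residual, residual_max = 0.60) {
  if (any(is.na(residual)) || any(residual < 0)) {
    abort("residual mRNA fractions must be non-negative and non-missing")
  }
  factor(ifelse(residual < residual_max, "silenced", "non_silenced"),
         levels = c("silenced", "non_silenced"))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Standard two-sided rule: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. A table with a zero margin
#' carries no information; its p is defined as 1 and flagged.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p_value`, `degenerate` (zero-margin flag) and the
#'   table.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(25, 1, 9, 3), 2))$p_value  # 0.0842
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab))) {
    abort("`tab` must be a 2x2 matrix of non-negative integer counts")
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  list(p_value = p, degenerate = degenerate, table = tab)
}

#' Screen-level summary of toxicity calls
#'
#' Aggregates per-line calls across agents: a line is a *modulator* when
#' any agent's category differs from `none`, a *sensitivity modulator*
#' when any category is a sensitivity call (likewise resistance), and a
#' *high modulator* when any category is a high-tier call. Percentages are
#' reported to the whole percent, halves rounded away from zero. When
#' `comparison_calls` is given (e.g. a random gene selection screened the
#' same way), a 2x2 modulator-vs-not contingency table and its two-sided
#' Fisher's exact p compare the two screens.
#'
#' @param calls a `toxicity_calls` tibble (or any tibble with `line`,
#'   `agent`, `category`).
#' @param comparison_calls optional second call table.
#' @return object of class `screen_summary`.
#' @export
summarize_screen <- function(calls, comparison_calls = NULL) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) abort("empty call table")
  check_columns(calls, c("line", "agent", "category"), "call table")
  n_agents <- length(unique(calls$agent))
  ragged <- calls |>
    dplyr::count(.data$line) |>
    dplyr::filter(.data$n != n_agents)
  if (nrow(ragged) > 0) {
    warn(sprintf("line(s) without calls for every agent: %s",
                 paste(ragged$line, collapse = ", ")))
  }

  per_line <- calls |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(
      modulator = any(.data$category != "none"),
      sensitivity = any(.data$category %in% c("low_sensitivity",
                                              "high_sensitivity")),
      resistance = any(.data$category %in% c("low_resistance",
                                             "high_resistance")),
      high = any(.data$category %in% c("high_sensitivity",
                                       "high_resistance")),
      .groups = "drop"
    )
  n <- nrow(per_line)
  pct <- function(k) round_half_up(100 * k / n)
  category_counts <- calls |>
    dplyr::count(.data$agent, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)

  contingency <- NULL
  fisher_p <- NA_real_
  if (!is.null(comparison_calls)) {
    comp <- summarize_screen(comparison_calls)
    contingency <- matrix(
      c(sum(per_line$modulator), n - sum(per_line$modulator),
        sum(comp$per_line$modulator),
        comp$n_called_lines - sum(comp$per_line$modulator)),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("screen", "comparison"),
                      c("modulator", "not_modulator")))
    fisher_p <- fisher_exact_2x2(contingency)$p_value
  }

  structure(
    list(n_called_lines = n,
         per_line = per_line,
         category_counts = category_counts,
         n_modulating = sum(per_line$modulator),
         pct_modulating = pct(sum(per_line$modulator)),
         pct_sensitivity = pct(sum(per_line$sensitivity)),
         pct_resistance = pct(sum(per_line$resistance)),
         pct_high = pct(sum(per_line$high)),
         contingency = contingency,
         fisher_p = fisher_p),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>\n")
  cat(sprintf("  %d lines called; %d (%d%%) modulate toxicity\n",
              x$n_called_lines, x$n_modulating, x$pct_modulating))
  cat(sprintf("  sensitivity %d%%, resistance %d%%, high tier %d%%\n",
              x$pct_sensitivity, x$pct_resistance, x$pct_high))
  if (!is.na(x$fisher_p)) {
    cat(sprintf("  vs comparison set: Fisher two-sided p = %.3g\n",
                x$fisher_p))
  }
  invisible(x)
}

#' @describeIn summarize_screen one-row tibble of the headline numbers.
#' @param x a `screen_summary`.
#' @param ... unused.
#' @exportS3Method
glance.screen_summary <- function(x, ...) {
  tibble::tibble(n_called_lines = x$n_called_lines,
                 n_modulating = x$n_modulating,
                 pct_modulating = x$pct_modulating,
                 pct_sensitivity = x$pct_sensitivity,
                 pct_resistance = x$pct_resistance,
                 pct_high = x$pct_high,
                 fisher_p = x$fisher_p)
}

#' @describeIn summarize_screen per-line modulator flags.
#' @exportS3Method
tidy.screen_summary <- function(x, ...) x$per_line

#' Five-symbol text heatmap of a call table
#'
#' Renders calls as a line x agent table of `++` (high resistance), `+`
#' (low resistance), `.` (none), `-` (low sensitivity) and `--` (high
#' sensitivity). ASCII stand-ins are used for the typographic middle dot
#' and minus so the table survives any text encoding.
#'
#' @param calls a `toxicity_calls` tibble.
#' @return wide tibble, one row per line, one column per agent.
#' @export
format_call_matrix <- function(calls) {
  tibble::as_tibble(calls) |>
    dplyr::mutate(symbol = call_symbols[as.character(.data$category)]) |>
    dplyr::select("line", "agent", "symbol") |>
    tidyr::pivot_wider(names_from = "agent", values_from = "symbol") |>
    dplyr::arrange(.data$line)
}

#' @describeIn call_toxicity tile heatmap of calls (lines x agents).
#' @param object a `toxicity_calls` tibble.
#' @param ... unused.
#' @exportS3Method
autoplot.toxicity_calls <- function(object, ...) {
  pal <- c(high_resistance = "#2166ac", low_resistance = "#92c5de",
           none = "grey92", low_sensitivity = "#f4a582",
           high_sensitivity = "#b2182b")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$agent, y = .data$line,
                               fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call") +
    ggplot2::theme_minimal()
}

#' Survival curves with the screen's noise region
#'
#' Plots per-line mean relative survival against dose (log2 y scale),
#' with the control-derived noise region shown as a ribbon around the
#' non-targeting control.
#'
#' @param curves output of [relative_survival()].
#' @param noise optional noise region from [build_noise_region()].
#' @return a ggplot object, faceted by agent.
#' @export
plot_survival_curves <- function(curves, noise = NULL) {
  means <- curves |>
    dplyr::group_by(.data$line, .data$agent, .data$dose, .data$role) |>
    dplyr::summarise(m = mean(.data$rel_survival), .groups = "drop")
  p <- ggplot2::ggplot(means,
                       ggplot2::aes(x = .data$dose, y = .data$m,
                                    group = .data$line,
                                    colour = .data$role)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(ggplot2::vars(.data$agent)) +
    ggplot2::labs(x = "dose (equitoxic units)",
                  y = "relative survival", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(noise)) {
    nt <- means |>
      dplyr::filter(.data$role == "nontargeting") |>
      dplyr::group_by(.data$agent, .data$dose) |>
      dplyr::summarise(nt = mean(.data$m), .groups = "drop")
    band <- dplyr::inner_join(noise, nt, by = c("agent", "dose")) |>
      dplyr::mutate(ymin = .data$nt * 2^.data$lo,
                    ymax = .data$nt * 2^.data$hi)
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$dose, ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p
}
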