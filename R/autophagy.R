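#' Score autophagic cells from per-cell puncta counts
#'
#' A cell is autophagic when it shows strictly more than `threshold`
#' fluorescent LC3 puncta (default > 5, each punctum marking an
#' autophagosome). Returns per-condition totals and the autophagic
#' fraction.
#'
#' @param data tibble with columns `condition` and `puncta` (non-negative
#'   integer counts); a `cell_id` column is allowed and ignored.
#' @param threshold scoring threshold; counts must *exceed* it.
#' @return tibble with columns `condition`, `n_cells`, `n_autophagic`,
#'   `fraction`.
#' @export
#' @examples
#' score_autophagy(data.frame(condition = "u", puncta = c(0, 6, 7, 3)))
score_autophagy <- function(data, threshold = 5) {
  data <- tibble::as_tibble(data)
  check_columns(data, c("condition", "puncta"), "puncta table")
  if (threshold < 0) abort("`threshold` must be >= 0")
  if (any(is.na(data$puncta)) || any(data$puncta < 0) ||
      any(data$puncta != round(data$puncta))) {
    abort("`puncta` must be non-negative integer counts")
  }
  data |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_autophagic = sum(.data$puncta > threshold),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_autophagic / .data$n_cells)
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Compare autophagic fractions between two conditions
#'
#' Two-sided Fisher's exact test on the autophagic / non-autophagic counts
#' (a chi-square option is available for large samples), fold induction of
#' condition `a` over condition `b`, and the significance stars used in
#' figure legends (* p < 0.05, ** p < 0.01). The fold is an explicit `NA`
#' when the reference fraction is 0.
#'
#' @param a,b one-row data frames (or lists) with `n_cells` and
#'   `n_autophagic`, as produced by [score_autophagy()].
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return one-row tibble with `p_value`, `fold`, `stars`.
#' @export
compare_conditions <- function(a, b, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (a$n_cells < 1 || b$n_cells < 1) {
    abort("both conditions need at least one scored cell")
  }
  tab <- matrix(c(a$n_autophagic, a$n_cells - a$n_autophagic,
                  b$n_autophagic, b$n_cells - b$n_autophagic),
                nrow = 2, byrow = TRUE)
  p <- if (method == "fisher") {
    fisher_exact_2x2(tab)$p_value
  } else {
    stats::chisq.test(tab)$p.value
  }
  fa <- a$n_autophagic / a$n_cells
  fb <- b$n_autophagic / b$n_cells
  tibble::tibble(p_value = p,
                 fold = if (fb == 0) NA_real_ else fa / fb,
                 stars = p_stars(p))
}

#' Autophagy induction relative to a reference condition
#'
#' Scores every condition with [score_autophagy()] and tests each against
#' the reference (typically the untreated culture of the same cell line),
#' reporting fold induction and significance stars.
#'
#' @param data per-cell puncta tibble (`condition`, `puncta`).
#' @param reference label of the reference condition (must be present).
#' @param threshold puncta-count threshold, see [score_autophagy()].
#' @param method test passed to [compare_conditions()].
#' @return tibble of class `autophagy_result` with one row per condition:
#'   counts, `fraction`, `fold_vs_reference`, `p_vs_reference`, `stars`
#'   (reference row has fold 1, p `NA`).
#' @export
autophagy_test <- function(data, reference, threshold = 5,
                           method = c("fisher", "chisq")) {
  method <- match.arg(method)
  scores <- score_autophagy(data, threshold = threshold)
  if (!reference %in% scores$condition) {
    abort(sprintf("reference condition '%s' not found", reference))
  }
  ref <- scores[scores$condition == reference, ]
  res <- scores |>
    dplyr::rowwise() |>
    dplyr::mutate(cmp = list(
      if (.data$condition == reference) {
        tibble::tibble(p_value = NA_real_, fold = 1, stars = "")
      } else {
        compare_conditions(
          list(n_cells = .data$n_cells, n_autophagic = .data$n_autophagic),
          ref, method = method)
      })) |>
    dplyr::ungroup() |>
    tidyr::unnest("cmp") |>
    dplyr::rename(fold_vs_reference = "fold", p_vs_reference = "p_value")
  structure(res, reference = reference,
            class = c("autophagy_result", class(tibble::tibble())))
}

#' @describeIn autophagy_test bar chart of autophagic fractions with
#'   significance stars over each tested condition.
#' @param object an `autophagy_result`.
#' @param ... unused.
#' @exportS3Method
autoplot.autophagy_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       vjust = -0.3, size = 6) +
    ggplot2::labs(x = NULL, y = "fraction of autophagic cells") +
    ggplot2::theme_minimal()
}
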