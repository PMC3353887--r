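#' Round half away from zero
#'
#' Screen-level percentages are reported to the whole percent with halves
#' rounded away from zero (so 25/34 -> 74, 19/34 -> 56), unlike base
#' [round()] which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(-0.5)  # -1
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Per-generator sub-seed: one global seed plus a stable generator index, so
# adding a generator never perturbs the streams of existing ones.
.stream_index <- c(
  orthologs  = 1L,
  phenotypes = 2L,
  ppi        = 3L,
  survival   = 4L,
  puncta     = 5L,
  expression = 6L,
  annotation = 7L
)

sub_seed <- function(seed, stream) {
  idx <- .stream_index[[stream]]
  (as.integer(seed) + idx) %% .Machine$integer.max
}

# Validation helpers: errors name the offending field.
check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  field, deparse(x)), class = "orthotox_config_error")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  field, min, deparse(x)), class = "orthotox_config_error")
  }
  invisible(as.integer(x))
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number, got %s",
                  field, deparse(x)), class = "orthotox_config_error")
  }
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number, got %s",
                  field, deparse(x)), class = "orthotox_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read / write the package's TSV dialect
#'
#' Tab-separated, header row, UTF-8, `#` comment lines ignored. All pipeline
#' inputs and outputs use this dialect.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_ortho_tsv()` returns a tibble; `write_ortho_tsv()` returns
#'   `x` invisibly.
#' @export
read_ortho_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_ortho_tsv
#' @export
write_ortho_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
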