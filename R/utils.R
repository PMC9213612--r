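#' Round half away from zero
#'
#' Fixed-point rounding in which exact halves round up (13.35 -> 13.4),
#' matching how percentages and summary statistics are conventionally
#' reported in publications.  Base `round()` rounds halves to even, which
#' would report 6.25% as 6.2 or 6.3 depending on the digit before it.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(13.35, 6.25, 19.5389), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared argument checks ------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Normalise a sample -> cohort assignment into a two-column tibble with
# cohort as a factor whose levels order young before old when those labels
# are used, so "delta" is consistently old minus young.
as_cohort_tbl <- function(groups, samples = NULL) {
  if (is.data.frame(groups)) {
    check_cols(groups, c("sample_id", "cohort"), "groups")
    tbl <- tibble(sample_id = as.character(groups$sample_id),
                  cohort = as.character(groups$cohort))
  } else if (!is.null(names(groups))) {
    tbl <- tibble(sample_id = names(groups), cohort = as.character(groups))
  } else {
    abort("`groups` must be a data frame (sample_id, cohort) or a named vector.")
  }
  if (anyDuplicated(tbl$sample_id)) {
    abort("`groups` assigns some sample more than one cohort.")
  }
  if (!is.null(samples)) {
    unknown <- setdiff(tbl$sample_id, samples)
    if (length(unknown) > 0) {
      abort(sprintf("`groups` names unknown sample(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  tbl
}

cohort_levels <- function(cohorts) {
  lv <- unique(cohorts)
  if (setequal(lv, c("young", "old"))) c("young", "old") else sort(lv)
}
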