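#' Cohort-averaged PSI per exon
#'
#' Arithmetic mean of the defined per-sample PSI values within each
#' cohort.  Exons with fewer than `min_defined_samples` defined values in
#' either cohort are dropped from the comparison — a cohort mean built on
#' one or two covered samples says little about the cohort.
#'
#' @param psi_tbl Long PSI tibble from [psi_matrix()].
#' @param groups Sample-to-cohort assignment with cohorts `"young"` and
#'   `"old"` (tibble `sample_id`, `cohort`, or named vector).
#' @param min_defined_samples Minimum defined PSI values per cohort
#'   (default 3).
#' @return A tibble: `exon_key`, `mean_psi_young`, `mean_psi_old`,
#'   `n_young`, `n_old`.
#' @export
cohort_mean_psi <- function(psi_tbl, groups, min_defined_samples = 3) {
  check_cols(psi_tbl, c("exon_key", "sample_id", "psi"), "psi_tbl")
  grp <- as_cohort_tbl(groups)
  unknown <- setdiff(unique(psi_tbl$sample_id), grp$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("Sample(s) without a cohort assignment: %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (!all(c("young", "old") %in% grp$cohort)) {
    abort("`groups` must assign samples to cohorts 'young' and 'old'.")
  }
  psi_tbl |>
    left_join(grp, by = "sample_id") |>
    group_by(.data$exon_key, .data$cohort) |>
    summarise(mean_psi = mean(.data$psi, na.rm = TRUE),
              n_defined = sum(!is.na(.data$psi)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cohort",
                       values_from = c("mean_psi", "n_defined")) |>
    rename(mean_psi_young = "mean_psi_young", mean_psi_old = "mean_psi_old",
           n_young = "n_defined_young", n_old = "n_defined_old") |>
    filter(.data$n_young >= min_defined_samples,
           .data$n_old >= min_defined_samples) |>
    mutate(mean_psi_young = if_else(is.nan(.data$mean_psi_young), NA_real_,
                                    .data$mean_psi_young),
           mean_psi_old = if_else(is.nan(.data$mean_psi_old), NA_real_,
                                  .data$mean_psi_old))
}

#' Flag exons with divergent cohort PSI
#'
#' Computes `delta_psi = mean_psi_old - mean_psi_young` (positive means
#' more inclusion in the old cohort) and flags exons whose absolute
#' difference strictly exceeds the threshold — a 20% difference in
#' average inclusion by default.
#'
#' @param means Tibble from [cohort_mean_psi()].
#' @param delta_threshold Flagging threshold on `|delta_psi|`, strict
#'   (default 0.20).
#' @param gene_map Optional tibble (`exon_key`, `gene_id`) for the
#'   gene-level rollup.
#' @return A tibble sorted by `|delta_psi|` descending with added columns
#'   `delta_psi`, `flagged` and (given `gene_map`) `gene_id`.
#' @export
flag_divergent <- function(means, delta_threshold = 0.20, gene_map = NULL) {
  check_number(delta_threshold, "delta_threshold", lower = 1e-9, upper = 1 - 1e-9)
  check_cols(means, c("exon_key", "mean_psi_young", "mean_psi_old"), "means")
  out <- means |>
    mutate(delta_psi = .data$mean_psi_old - .data$mean_psi_young,
           flagged = abs(.data$delta_psi) > delta_threshold) |>
    arrange(dplyr::desc(abs(.data$delta_psi)))
  if (!is.null(gene_map)) {
    check_cols(gene_map, c("exon_key", "gene_id"), "gene_map")
    out <- left_join(out, distinct(gene_map, .data$exon_key, .data$gene_id),
                     by = "exon_key")
  }
  out
}

#' Rank correlation of cohort mean PSI
#'
#' Spearman's rho between the young and old cohort mean PSI vectors,
#' summarising how concordant exon inclusion is between cohorts overall.
#'
#' @param means Tibble from [cohort_mean_psi()].
#' @return Spearman's rho (scalar); `NA` with a warning when fewer than 3
#'   complete pairs are available.
#' @export
psi_concordance <- function(means) {
  check_cols(means, c("mean_psi_young", "mean_psi_old"), "means")
  ok <- !is.na(means$mean_psi_young) & !is.na(means$mean_psi_old)
  if (sum(ok) < 3) {
    warn("Fewer than 3 complete exon pairs; rank correlation undefined.")
    return(NA_real_)
  }
  cor(means$mean_psi_young[ok], means$mean_psi_old[ok], method = "spearman")
}

#' Compare cassette-exon splicing between cohorts
#'
#' One-stop wrapper: cohort means, divergence flagging, gene rollup and
#' rank concordance from a per-sample PSI table.
#'
#' @inheritParams cohort_mean_psi
#' @inheritParams flag_divergent
#' @return An object of class `"splice_comparison"`: list with
#'   `comparison` (the [flag_divergent()] tibble), `summary` (one-row
#'   tibble: `n_exons`, `n_flagged_exons`, `n_flagged_genes`, `rho`,
#'   `delta_threshold`).  [tidy()], [glance()] and [autoplot()] methods
#'   are provided.
#' @export
compare_splicing <- function(psi_tbl, groups, delta_threshold = 0.20,
                             min_defined_samples = 3, gene_map = NULL) {
  means <- cohort_mean_psi(psi_tbl, groups,
                           min_defined_samples = min_defined_samples)
  comparison <- flag_divergent(means, delta_threshold = delta_threshold,
                               gene_map = gene_map)
  n_flagged_genes <- if ("gene_id" %in% names(comparison)) {
    dplyr::n_distinct(comparison$gene_id[comparison$flagged])
  } else {
    NA_integer_
  }
  structure(list(
    comparison = comparison,
    summary = tibble(
      n_exons = nrow(comparison),
      n_flagged_exons = sum(comparison$flagged),
      n_flagged_genes = n_flagged_genes,
      rho = psi_concordance(means),
      delta_threshold = delta_threshold
    )
  ), class = "splice_comparison")
}

#' @method tidy splice_comparison
#' @export
tidy.splice_comparison <- function(x, ...) x$comparison

#' @method glance splice_comparison
#' @export
glance.splice_comparison <- function(x, ...) x$summary

#' @export
print.splice_comparison <- function(x, ...) {
  cat("Cassette-exon splicing comparison (old vs young)\n")
  print(x$summary)
  invisible(x)
}

#' @method autoplot splice_comparison
#' @export
autoplot.splice_comparison <- function(object, ...) {
  ggplot2::ggplot(object$comparison,
                  ggplot2::aes(x = .data$mean_psi_young,
                               y = .data$mean_psi_old,
                               colour = .data$flagged)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 labels = c(`FALSE` = "stable", `TRUE` = "divergent")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean PSI, young", y = "Mean PSI, old",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
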