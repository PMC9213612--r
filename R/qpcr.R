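#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, the target gene's cycle threshold is normalized to a
#' housekeeping reference gene (`dCt = Ct_target - Ct_reference`); the
#' difference of cohort means (`ddCt = mean dCt(test) - mean
#' dCt(calibrator)`) then gives the relative expression `FC = 2^(-ddCt)`
#' of the test cohort versus the calibrator.  Replicate wells for the same
#' sample and gene are averaged before normalization.
#'
#' @param ct Tibble with columns `sample_id`, `gene_id`, `ct` (one row per
#'   well or per sample).
#' @param target_gene Target gene id(s).
#' @param groups Sample-to-cohort assignment (tibble or named vector).
#' @param group_test,group_calibrator Cohort labels compared (default old
#'   vs young).
#' @param reference_gene Housekeeping gene id (default `"GAPDH"`).
#' @return A tibble with one row per target gene: `gene_id`, `n_test`,
#'   `n_calibrator`, `mean_dct_test`, `mean_dct_calibrator`, `ddct`,
#'   `fold_change`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   gene_id = rep(c("TP53", "GAPDH"), 2),
#'   ct = c(24, 20, 26, 20))
#' ddct_fold_change(ct, "TP53", c(s1 = "old", s2 = "young"))
ddct_fold_change <- function(ct, target_gene, groups,
                             group_test = "old", group_calibrator = "young",
                             reference_gene = "GAPDH") {
  check_cols(ct, c("sample_id", "gene_id", "ct"), "ct")
  if (any(ct$ct <= 0)) abort("Ct values must be positive.")
  ct_mean <- ct |>
    group_by(.data$sample_id, .data$gene_id) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  grp <- as_cohort_tbl(groups, unique(ct_mean$sample_id))
  used <- filter(grp, .data$cohort %in% c(group_test, group_calibrator))
  if (!all(c(group_test, group_calibrator) %in% used$cohort)) {
    abort("Both the test and the calibrator cohort need at least one sample.")
  }
  ref <- ct_mean |>
    filter(.data$gene_id == reference_gene) |>
    select("sample_id", ref_ct = "ct")
  no_ref <- setdiff(used$sample_id, ref$sample_id)
  if (length(no_ref) > 0) {
    abort(sprintf("Reference gene '%s' has no Ct for sample(s): %s.",
                  reference_gene, paste(no_ref, collapse = ", ")))
  }
  purrr::map(target_gene, function(gene) {
    dct <- ct_mean |>
      filter(.data$gene_id == gene) |>
      inner_join(used, by = "sample_id") |>
      inner_join(ref, by = "sample_id") |>
      mutate(dct = .data$ct - .data$ref_ct)
    by_grp <- dct |>
      group_by(.data$cohort) |>
      summarise(n = n(), mean_dct = mean(.data$dct), .groups = "drop")
    if (!all(c(group_test, group_calibrator) %in% by_grp$cohort)) {
      abort(sprintf("Target gene '%s' lacks Ct values in one of the cohorts.",
                    gene))
    }
    mt <- by_grp$mean_dct[by_grp$cohort == group_test]
    mc <- by_grp$mean_dct[by_grp$cohort == group_calibrator]
    tibble(gene_id = gene,
           n_test = by_grp$n[by_grp$cohort == group_test],
           n_calibrator = by_grp$n[by_grp$cohort == group_calibrator],
           mean_dct_test = mt, mean_dct_calibrator = mc,
           ddct = mt - mc, fold_change = 2^(-(mt - mc)))
  }) |> bind_rows()
}

#' Concordance of qPCR and RNA-seq fold changes
#'
#' Pearson correlation of the two platforms' fold changes on the log2
#' scale, with the usual t-distribution p-value.
#'
#' @param fc Tibble with columns `gene_id`, `qpcr_fc`, `rnaseq_fc`
#'   (linear fold changes, > 0).
#' @return A one-row tibble: `r`, `p_value`, `n_genes`.
#' @export
qpcr_concordance <- function(fc) {
  check_cols(fc, c("gene_id", "qpcr_fc", "rnaseq_fc"), "fc")
  fc <- filter(fc, !is.na(.data$qpcr_fc), !is.na(.data$rnaseq_fc))
  if (nrow(fc) < 3) abort("Concordance needs at least 3 shared genes.")
  if (any(fc$qpcr_fc <= 0 | fc$rnaseq_fc <= 0)) {
    abort("Fold changes must be positive.")
  }
  ct <- cor.test(log2(fc$qpcr_fc), log2(fc$rnaseq_fc), method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n_genes = nrow(fc))
}
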