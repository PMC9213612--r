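#' Gene-set overrepresentation test
#'
#' For every annotation term, compares the number of target-list genes
#' annotated to the term against the expectation under random sampling
#' from the reference list: `expected = n_term_in_reference * n_target /
#' n_reference`, `fold_enrichment = observed / expected`.  Significance is
#' the two-sided Fisher exact (hypergeometric) p-value of the 2x2 table,
#' so both over- and underrepresented terms are detected; p-values are
#' adjusted across tested terms with [bh_fdr()].
#'
#' @param target Character vector of target gene ids (e.g. differentially
#'   expressed or differentially spliced genes).  Must be a subset of
#'   `reference`.
#' @param reference Character vector of background gene ids (e.g. all
#'   genes expressed in the tissue).
#' @param annotation Tibble with columns `term_id`, `gene_id` and
#'   optionally `term_name`.  Genes outside `reference` are ignored.
#' @param min_term_size Smallest reference-intersected term tested
#'   (default 2).
#' @return A tibble of class `"enrichment_result"`, one row per tested
#'   term, sorted by p-value: `term_id`, `term_name`, `n_reference`,
#'   `observed`, `expected`, `fold_enrichment`, `p_value`, `fdr`.
#' @export
overrepresentation_test <- function(target, reference, annotation,
                                    min_term_size = 2) {
  check_cols(annotation, c("term_id", "gene_id"), "annotation")
  target <- unique(target)
  reference <- unique(reference)
  stray <- setdiff(target, reference)
  if (length(stray) > 0) {
    abort(sprintf("Target gene(s) missing from the reference list: %s.",
                  paste(head(stray, 10), collapse = ", ")))
  }
  ann <- annotation |>
    filter(.data$gene_id %in% reference) |>
    distinct(.data$term_id, .data$gene_id,
             .keep_all = TRUE)
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  n_ref <- length(reference)
  n_tgt <- length(target)
  terms <- ann |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(n_reference = n(),
              observed = sum(.data$gene_id %in% target),
              .groups = "drop") |>
    filter(.data$n_reference >= min_term_size)
  if (nrow(terms) == 0) {
    return(structure(tibble(term_id = character(), term_name = character(),
                            n_reference = integer(), observed = integer(),
                            expected = numeric(), fold_enrichment = numeric(),
                            p_value = numeric(), fdr = numeric()),
                     class = c("enrichment_result", "tbl_df", "tbl", "data.frame"),
                     n_target = n_tgt, n_reference = n_ref))
  }
  terms <- terms |>
    mutate(
      expected = .data$n_reference * n_tgt / n_ref,
      fold_enrichment = .data$observed / .data$expected,
      p_value = purrr::map2_dbl(.data$observed, .data$n_reference, function(k, m) {
        tab <- matrix(c(k, m - k, n_tgt - k, n_ref - m - n_tgt + k), nrow = 2)
        # fisher.test can overshoot 1 by floating error
        min(fisher.test(tab, alternative = "two.sided")$p.value, 1)
      }),
      fdr = bh_fdr(.data$p_value)
    ) |>
    arrange(.data$p_value)
  structure(terms,
            class = c("enrichment_result", class(tibble())),
            n_target = n_tgt, n_reference = n_ref)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment with monotonicity enforcement; the output is
#' order-preserving (adjusted values are returned in the input order).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms_tested = nrow(x),
         n_significant = sum(x$fdr < 0.05),
         n_target = attr(x, "n_target"),
         n_reference = attr(x, "n_reference"))
}

#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, fdr_max = 0.05, ...) {
  df <- filter(as_tibble(unclass(object)[names(object)]), .data$fdr < fdr_max)
  if (nrow(df) == 0) {
    warn("No term passes the FDR cutoff; plotting all tested terms.")
    df <- as_tibble(unclass(object)[names(object)])
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fold_enrichment,
    y = stats::reorder(.data$term_name, .data$fold_enrichment),
    fill = .data$fdr)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Fold enrichment", y = NULL, fill = "FDR") +
    ggplot2::theme_minimal()
}
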