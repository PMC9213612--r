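#' Counts per million
#'
#' Scales each sample's counts to the number of reads per million
#' sequenced, `cpm = count / library_size * 1e6`.  With library sizes
#' taken as column sums every CPM column sums to exactly one million.
#'
#' @param counts Count tibble: a `gene_id` column plus one numeric column
#'   per sample.
#' @param library_sizes Optional named vector overriding the per-sample
#'   totals (e.g. total sequenced rather than total counted reads).
#' @return A tibble of the same shape holding CPM values, with the library
#'   sizes attached as attribute `"library_sizes"`.
#' @export
#' @examples
#' cpm(tibble::tibble(gene_id = "g", s1 = 20), library_sizes = c(s1 = 66666667))
cpm <- function(counts, library_sizes = NULL) {
  check_cols(counts, "gene_id", "counts")
  samples <- setdiff(names(counts), "gene_id")
  mat <- as.matrix(counts[samples])
  if (any(mat < 0)) abort("Counts must be >= 0.")
  lib <- library_sizes %||% colSums(mat)
  lib <- lib[samples]
  if (any(is.na(lib)) || any(lib <= 0)) {
    abort("Every sample needs a positive library size.")
  }
  out <- sweep(mat, 2, lib, "/") * 1e6
  res <- bind_cols(counts["gene_id"], as_tibble(out))
  attr(res, "library_sizes") <- lib
  res
}

#' Cohort detection and exclusive-gene partition
#'
#' A gene is *detected* in a cohort when its CPM reaches the detection
#' threshold in at least one sample of that cohort; 0.3 CPM corresponds to
#' roughly 20 reads at ~70M-read depth.  Genes detected in exactly one
#' cohort are that cohort's exclusive genes.  For each exclusive gene the
#' result also reports what fraction of the *other* cohort's samples sit
#' below the threshold.
#'
#' @param cpm_tbl CPM tibble from [cpm()].
#' @param groups Sample-to-cohort assignment (tibble `sample_id`,
#'   `cohort`, or named vector).
#' @param detect_threshold Detection level in CPM (default 0.3).
#' @return A list: `detected` (named list of per-cohort gene sets),
#'   `exclusive` (named list), `shared` (character vector), `summary`
#'   (one-row tibble of set sizes) and `exclusive_detail` (tibble
#'   `gene_id`, `cohort`, `frac_other_below`).
#' @export
detected_genes <- function(cpm_tbl, groups, detect_threshold = 0.3) {
  check_number(detect_threshold, "detect_threshold", lower = 1e-12)
  check_cols(cpm_tbl, "gene_id", "cpm_tbl")
  samples <- setdiff(names(cpm_tbl), "gene_id")
  grp <- as_cohort_tbl(groups, samples)
  lv <- cohort_levels(grp$cohort)
  mat <- as.matrix(cpm_tbl[samples])
  rownames(mat) <- cpm_tbl$gene_id
  det <- lapply(lv, function(co) {
    cols <- grp$sample_id[grp$cohort == co]
    rownames(mat)[rowSums(mat[, cols, drop = FALSE] >= detect_threshold) >= 1]
  })
  names(det) <- lv
  all_detected <- unique(unlist(det))
  in_n <- vapply(all_detected,
                 function(g) sum(vapply(det, function(s) g %in% s, logical(1))),
                 integer(1))
  shared <- all_detected[in_n == length(lv)]
  exclusive <- lapply(lv, function(co) {
    setdiff(det[[co]], unlist(det[setdiff(lv, co)]))
  })
  names(exclusive) <- lv
  detail <- purrr::imap(exclusive, function(genes, co) {
    if (length(genes) == 0) return(NULL)
    other_cols <- grp$sample_id[grp$cohort != co]
    tibble(gene_id = genes, cohort = co,
           frac_other_below = unname(rowMeans(mat[genes, other_cols, drop = FALSE] <
                                                detect_threshold)))
  }) |> bind_rows()
  list(
    detected = det,
    exclusive = exclusive,
    shared = shared,
    summary = tibble(
      n_detected_total = length(all_detected),
      !!!setNames(lapply(lv, function(co) length(exclusive[[co]])),
                  paste0("n_exclusive_", lv)),
      n_shared = length(shared)
    ),
    exclusive_detail = detail
  )
}

#' Categorize differential-expression fold changes
#'
#' Splits a DEG table (linear fold changes, old over young) into
#' up/downregulated genes and magnitude bins: upregulated with more than a
#' 1.5-fold increase, downregulated to half or less, and small
#' (0.5 < FC < 1.5) versus large changes.  Shares are reported as
#' percentages rounded half-up to one decimal.
#'
#' @param degs Tibble with columns `gene_id` and `fold_change` (linear,
#'   > 0); extra columns such as `q_value` are ignored.
#' @return A one-row tibble of counts and percentage shares.
#' @export
fold_change_categories <- function(degs) {
  check_cols(degs, c("gene_id", "fold_change"), "degs")
  fc <- degs$fold_change
  if (any(is.na(fc)) || any(fc <= 0)) abort("Fold changes must be positive.")
  if (any(fc == 1)) {
    warn(sprintf("%d gene(s) with fold change exactly 1 counted neither up nor down.",
                 sum(fc == 1)))
  }
  n_up <- sum(fc > 1)
  n_down <- sum(fc < 1)
  n_up_gt_1.5 <- sum(fc > 1.5)
  n_down_le_0.5 <- sum(fc <= 0.5)
  n_small <- sum(fc > 0.5 & fc < 1.5)
  tibble(
    n_total = length(fc),
    n_up = n_up,
    n_down = n_down,
    n_unchanged = sum(fc == 1),
    n_up_gt_1.5 = n_up_gt_1.5,
    n_down_le_0.5 = n_down_le_0.5,
    n_small_change = n_small,
    n_large_change = length(fc) - n_small,
    pct_up_gt_1.5 = if (n_up > 0) round_half_up(100 * n_up_gt_1.5 / n_up, 1) else 0,
    pct_down_le_0.5 = if (n_down > 0) round_half_up(100 * n_down_le_0.5 / n_down, 1) else 0
  )
}

#' Default red-blood-cell marker transcripts
#'
#' Canine genes whose human homologs are highly expressed in red blood
#' cells; their CPM levels gauge residual blood content in brain tissue.
#' @export
rbc_markers <- c("ENSCAFG00000032615", "ENSCAFG00000029224",
                 "ENSCAFG00000028569", "ENSCAFG00000030286")

#' Blood-marker expression report
#'
#' Restricts a CPM table to a set of marker genes and reports per-sample
#' values plus cohort means; markers absent from the matrix are reported
#' as absent rather than raising an error.
#'
#' @param cpm_tbl CPM tibble from [cpm()].
#' @param marker_ids Marker gene ids (default [rbc_markers]).
#' @param groups Optional cohort assignment for cohort means.
#' @return A list: `per_sample` (long tibble `gene_id`, `sample_id`,
#'   `cpm`, `present`) and `cohort_means` (tibble, `NULL` without
#'   `groups`).
#' @export
blood_marker_report <- function(cpm_tbl, marker_ids = rbc_markers,
                                groups = NULL) {
  if (length(marker_ids) == 0) abort("Supply at least one marker id.")
  check_cols(cpm_tbl, "gene_id", "cpm_tbl")
  samples <- setdiff(names(cpm_tbl), "gene_id")
  long <- tidyr::expand_grid(gene_id = marker_ids, sample_id = samples) |>
    left_join(
      tidyr::pivot_longer(cpm_tbl[cpm_tbl$gene_id %in% marker_ids, ],
                          -"gene_id", names_to = "sample_id",
                          values_to = "cpm"),
      by = c("gene_id", "sample_id")) |>
    mutate(present = !is.na(.data$cpm))
  means <- NULL
  if (!is.null(groups)) {
    grp <- as_cohort_tbl(groups, samples)
    means <- long |>
      left_join(grp, by = "sample_id") |>
      group_by(.data$gene_id, .data$cohort) |>
      summarise(mean_cpm = mean(.data$cpm), .groups = "drop")
  }
  list(per_sample = long, cohort_means = means)
}

#' Cohort metadata summary
#'
#' Per-cohort body-mass mean and sample (n-1) standard deviation, age
#' range and sex counts, with mass statistics rounded half-up to one
#' decimal as conventionally reported.
#'
#' @param meta Tibble with columns `sample_id`, `cohort`, `age`, `sex`,
#'   `body_mass` (kg).
#' @return A tibble with one row per cohort.
#' @export
metadata_summary <- function(meta) {
  check_cols(meta, c("sample_id", "cohort", "age", "sex", "body_mass"), "meta")
  if (any(meta$body_mass <= 0)) abort("Body mass must be positive.")
  meta |>
    mutate(cohort = factor(.data$cohort, levels = cohort_levels(.data$cohort))) |>
    group_by(.data$cohort) |>
    summarise(
      n = n(),
      mass_mean = round_half_up(mean(.data$body_mass), 1),
      mass_sd = round_half_up(sd(.data$body_mass), 1),
      age_min = min(.data$age),
      age_max = max(.data$age),
      n_female = sum(tolower(.data$sex) %in% c("female", "f")),
      n_male = sum(tolower(.data$sex) %in% c("male", "m")),
      .groups = "drop"
    )
}

#' Venn-region cardinalities of gene sets
#'
#' Counts every region of the Venn partition of two or more named gene
#' sets (a plain set-intersection utility; no homolog mapping is
#' attempted).
#'
#' @param sets Named list of character vectors.
#' @return A tibble with one row per non-empty membership pattern:
#'   `region` (set names joined by `&`), a logical column per set, and
#'   `count`.
#' @export
homolog_overlap <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets))) {
    abort("`sets` must be a named list of at least two gene sets.")
  }
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, paste, collapse = "")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  combos$region <- apply(combos, 1, function(r) {
    paste(names(sets)[as.logical(r)], collapse = " & ")
  })
  combos$count <- apply(combos[names(sets)], 1, function(r) {
    sum(pattern == paste(as.logical(r), collapse = ""))
  })
  as_tibble(combos[c("region", names(sets), "count")])
}
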