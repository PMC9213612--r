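#' Multidimensional scaling of expression profiles
#'
#' Embeds samples in two dimensions from pairwise expression distances,
#' the standard first look at cohort structure in a bulk RNA-seq study.
#' Two distance definitions are offered:
#'
#' * `"logfc"` (leading log fold change): for each sample pair, the
#'   root-mean-square of the `top_n` largest absolute log2 ratios
#'   `log2((cpm_s + prior) / (cpm_t + prior))` over genes.  `top_n = Inf`
#'   uses all genes.
#' * `"bcv"`: a pairwise coefficient-of-variation proxy.  Genes are first
#'   ranked by variance of their log2 CPM across all samples; over the
#'   `top_n` most variable genes the per-gene quantity for pair (s, t) is
#'   the two-point CV `|a - b| / (sqrt(2) * mean(a, b))` with
#'   `a = cpm_s + prior`, `b = cpm_t + prior`, and the distance is the
#'   root-mean-square of these CVs.  This is a deliberate simplification
#'   of dispersion-based (BCV) MDS and is not numerically identical to
#'   edgeR's tagwise version.
#'
#' The embedding itself is classical (Torgerson) metric MDS of the
#' distance matrix.
#'
#' @param cpm_tbl CPM tibble from [cpm()].
#' @param top_n Number of genes entering each pairwise distance
#'   (default 500); capped at the gene count with a warning.
#' @param prior_count Pseudo-CPM added before taking logs (default 2).
#' @param mode `"logfc"` or `"bcv"`.
#' @param groups Optional cohort assignment carried into the coordinates
#'   for plotting.
#' @return An object of class `"cpm_mds"`: list with `points` (tibble
#'   `sample_id`, `dim1`, `dim2`, optional `cohort`), `dist` (matrix),
#'   `eig`, `mode`, `top_n`.  [tidy()], [glance()] and [autoplot()]
#'   methods are provided.
#' @export
mds_embedding <- function(cpm_tbl, top_n = 500, prior_count = 2,
                          mode = c("logfc", "bcv"), groups = NULL) {
  mode <- match.arg(mode)
  check_number(prior_count, "prior_count", lower = 0)
  check_cols(cpm_tbl, "gene_id", "cpm_tbl")
  samples <- setdiff(names(cpm_tbl), "gene_id")
  if (length(samples) < 3) abort("MDS needs at least 3 samples.")
  mat <- as.matrix(cpm_tbl[samples]) + prior_count
  n_genes <- nrow(mat)
  if (top_n > n_genes) {
    if (is.finite(top_n)) {
      warn(sprintf("top_n (%s) exceeds the gene count (%d); using all genes.",
                   format(top_n), n_genes))
    }
    top_n <- n_genes
  }
  lmat <- log2(mat)
  d <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  if (mode == "bcv") {
    keep <- order(apply(lmat, 1, stats::var), decreasing = TRUE)[seq_len(top_n)]
  }
  for (i in seq_along(samples)) {
    for (j in seq_len(i - 1L)) {
      if (mode == "logfc") {
        lfc <- abs(lmat[, i] - lmat[, j])
        top <- sort(lfc, decreasing = TRUE)[seq_len(top_n)]
        d[i, j] <- d[j, i] <- sqrt(mean(top^2))
      } else {
        a <- mat[keep, i]
        b <- mat[keep, j]
        cv <- abs(a - b) / (sqrt(2) * (a + b) / 2)
        d[i, j] <- d[j, i] <- sqrt(mean(cv^2))
      }
    }
  }
  fit <- cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  points <- tibble(sample_id = samples,
                   dim1 = fit$points[, 1], dim2 = fit$points[, 2])
  if (!is.null(groups)) {
    points <- left_join(points, as_cohort_tbl(groups, samples), by = "sample_id")
  }
  structure(list(points = points, dist = d, eig = fit$eig,
                 mode = mode, top_n = top_n, prior_count = prior_count),
            class = "cpm_mds")
}

#' @method tidy cpm_mds
#' @export
tidy.cpm_mds <- function(x, ...) x$points

#' @method glance cpm_mds
#' @export
glance.cpm_mds <- function(x, ...) {
  pos <- x$eig[x$eig > 0]
  tibble(n_samples = nrow(x$points), mode = x$mode, top_n = x$top_n,
         prior_count = x$prior_count,
         var_explained_2d = sum(x$eig[1:2]) / sum(pos))
}

#' @method autoplot cpm_mds
#' @export
autoplot.cpm_mds <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if ("cohort" %in% names(object$points)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$cohort), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                  title = sprintf("MDS (%s distance, top %s genes)",
                                  object$mode, format(object$top_n))) +
    ggplot2::theme_minimal()
}
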