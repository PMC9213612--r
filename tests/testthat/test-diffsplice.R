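toy_psi_tbl <- function(values) {
  # values: named list exon_key -> named psi vector by sample
  purrr::imap_dfr(values, function(v, key) {
    tibble::tibble(exon_key = key, sample_id = names(v),
                   ir_raw = 50L, er_raw = 50L, ir_n = 1, er_n = 1,
                   psi = unname(v))
  })
}

six_seven <- tibble::tibble(
  sample_id = c(paste0("y", 1:6), paste0("o", 1:7)),
  cohort = rep(c("young", "old"), c(6, 7)))

test_that("cohort means average defined values and drop sparse exons", {
  tbl <- toy_psi_tbl(list(
    e1 = c(y1 = 0.2, y2 = 0.4, y3 = 0.3, o1 = 0.5, o2 = 0.5, o3 = 0.5),
    e2 = c(y1 = NA, y2 = NA, y3 = NA, o1 = 0.5, o2 = 0.5, o3 = 0.5)))
  m <- cohort_mean_psi(tbl, six_seven, min_defined_samples = 3)
  expect_equal(nrow(m), 1)  # e2 has an all-undefined cohort -> excluded
  expect_equal(m$mean_psi_young[m$exon_key == "e1"], 0.3)

  expect_error(
    cohort_mean_psi(toy_psi_tbl(list(e = c(zz = 0.5))), six_seven),
    "zz")
})

test_that("divergence flagging is strict at the threshold", {
  means <- tibble::tibble(
    exon_key = c("a", "b", "c"),
    mean_psi_young = c(0.50, 0.50, 0.50),
    mean_psi_old = c(0.69, 0.75, 0.71),
    n_young = 6L, n_old = 7L)
  fl <- flag_divergent(means, delta_threshold = 0.20)
  expect_equal(fl$flagged[match(c("a", "b", "c"), fl$exon_key)],
               c(FALSE, TRUE, TRUE))  # 0.19 no, 0.25 yes, 0.21 yes
  expect_equal(fl$exon_key[1], "b")   # sorted by |delta| descending
  expect_error(flag_divergent(means, delta_threshold = 1.5), "delta_threshold")
})

test_that("gene rollup counts distinct flagged genes", {
  means <- tibble::tibble(
    exon_key = c("a", "b", "c"),
    mean_psi_young = c(0.1, 0.1, 0.1),
    mean_psi_old = c(0.6, 0.6, 0.6))
  gm <- tibble::tibble(exon_key = c("a", "b", "c"),
                       gene_id = c("g1", "g1", "g2"))
  fl <- flag_divergent(means, gene_map = gm)
  expect_equal(dplyr::n_distinct(fl$gene_id[fl$flagged]), 2)
})

test_that("rank concordance matches the hand-ranked formula", {
  expect_equal(psi_concordance(tibble::tibble(
    mean_psi_young = c(0.1, 0.2, 0.3, 0.4),
    mean_psi_old = c(0.1, 0.2, 0.3, 0.4))), 1)
  expect_equal(psi_concordance(tibble::tibble(
    mean_psi_young = c(0.1, 0.2, 0.3, 0.4),
    mean_psi_old = c(0.4, 0.3, 0.2, 0.1))), -1)
  # 5 hand-ranked pairs: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  y <- c(0.10, 0.30, 0.20, 0.50, 0.40)
  o <- c(0.15, 0.20, 0.40, 0.45, 0.30)
  d <- rank(y) - rank(o)
  expect_equal(
    psi_concordance(tibble::tibble(mean_psi_young = y, mean_psi_old = o)),
    1 - 6 * sum(d^2) / (5 * 24))
  expect_warning(
    expect_true(is.na(psi_concordance(tibble::tibble(
      mean_psi_young = c(0.1, 0.2), mean_psi_old = c(0.1, 0.2))))),
    "3")
})

test_that("flagging is invariant to sample order and label swap up to sign", {
  tbl <- toy_psi_tbl(list(
    e1 = setNames(c(0.1, 0.15, 0.2, 0.7, 0.75, 0.8, 0.7),
                  c("y1", "y2", "y3", "o1", "o2", "o3", "o4")),
    e2 = setNames(rep(0.5, 7),
                  c("y1", "y2", "y3", "o1", "o2", "o3", "o4"))))
  grp <- six_seven
  a <- suppressWarnings(compare_splicing(tbl, grp))       # 2 exons: rho undefined
  b <- suppressWarnings(compare_splicing(tbl[sample(nrow(tbl)), ], grp))
  expect_equal(tidy(a)$delta_psi, tidy(b)$delta_psi)
  swapped <- dplyr::mutate(grp, cohort = ifelse(cohort == "young", "old", "young"))
  c <- suppressWarnings(compare_splicing(tbl, swapped))
  expect_equal(tidy(c)$delta_psi[match(tidy(a)$exon_key, tidy(c)$exon_key)],
               -tidy(a)$delta_psi)
  expect_equal(glance(c)$n_flagged_exons, glance(a)$n_flagged_exons)
})

test_that("the comparison object tidies, glances and plots", {
  tbl <- toy_psi_tbl(list(
    e1 = setNames(c(0.1, 0.2, 0.15, 0.8, 0.9, 0.85, 0.8),
                  c("y1", "y2", "y3", "o1", "o2", "o3", "o4")),
    e2 = setNames(c(0.5, 0.5, 0.5, 0.52, 0.51, 0.5, 0.5),
                  c("y1", "y2", "y3", "o1", "o2", "o3", "o4")),
    e3 = setNames(c(0.9, 0.8, 0.85, 0.9, 0.8, 0.85, 0.9),
                  c("y1", "y2", "y3", "o1", "o2", "o3", "o4"))))
  cmp <- compare_splicing(tbl, six_seven,
                          gene_map = tibble::tibble(exon_key = c("e1", "e2", "e3"),
                                                    gene_id = c("g1", "g2", "g3")))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(glance(cmp)$n_flagged_exons, 1)
  expect_equal(glance(cmp)$n_flagged_genes, 1)
  expect_s3_class(autoplot(cmp), "ggplot")
})
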