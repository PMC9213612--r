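# the canonical cassette event of the three-exon fixture gene:
# inclusion junctions (199->300) and (399->500), skip junction (199->500)
fixture_catalog <- function() cassette_exon_catalog(three_exon_models())

test_that("junction counting separates inclusion and exclusion evidence", {
  cat <- fixture_catalog()
  # 10 reads across the skip junction only
  skip <- toy_sam(rep(150L, 10), rep("50M300N50M", 10))
  counts <- count_junction_reads(read_sam(skip), cat)
  expect_equal(counts$ir_raw, 0L)
  expect_equal(counts$er_raw, 10L)

  # 5 upstream + 5 downstream inclusion + 10 skip
  sam <- toy_sam(
    c(rep(150L, 5), rep(350L, 5), rep(150L, 10)),
    c(rep("50M100N50M", 5), rep("50M100N50M", 5), rep("50M300N50M", 10)))
  counts <- count_junction_reads(read_sam(sam), cat)
  expect_equal(counts$ir_raw, 10L)
  expect_equal(counts$er_raw, 10L)
})

test_that("junction matching is exact: one base off is not counted", {
  cat <- fixture_catalog()
  # skip junction shifted right by one base: (200 -> 501) instead of (199 -> 500)
  off <- toy_sam(151L, "50M300N50M")
  counts <- count_junction_reads(read_sam(off), cat)
  expect_equal(counts$er_raw, 0L)
  # brute-force check that the read junction really is offset by 1
  j <- read_junctions(151L, "50M300N50M")
  expect_equal(j$donor_end, cat$skip_donor + 1L)
})

test_that("the anchor filter drops weakly anchored junction reads", {
  cat <- fixture_catalog()
  weak <- toy_sam(195L, "5M100N95M")   # 5 bases on the donor side
  expect_equal(count_junction_reads(read_sam(weak), cat, anchor_min = 8)$ir_raw, 0L)
  expect_equal(count_junction_reads(read_sam(weak), cat, anchor_min = 5)$ir_raw, 1L)
})

test_that("a read spanning both inclusion junctions counts once", {
  cat <- fixture_catalog()
  both <- toy_sam(180L, "20M100N100M100N20M")  # 199->300 and 399->500
  counts <- count_junction_reads(read_sam(both), cat)
  expect_equal(counts$ir_raw, 1L)
})

test_that("normalization puts inclusion and exclusion on a per-junction scale", {
  r <- normalize_rates(20, 10, read_length = 124, anchor_min = 8)
  expect_equal(r$ir_n, 20 / 218)
  expect_equal(r$er_n, 10 / 109)
  expect_equal(psi(r$ir_n, r$er_n), 0.5)

  expect_equal(normalize_rates(0, 10)$ir_n, 0)
  # doubling both raw counts leaves PSI unchanged
  r2 <- normalize_rates(40, 20, read_length = 124, anchor_min = 8)
  expect_equal(psi(r2$ir_n, r2$er_n), psi(r$ir_n, r$er_n))
  expect_error(normalize_rates(1, 1, read_length = 16, anchor_min = 8), "anchor")
})

test_that("PSI endpoints and worked values", {
  expect_equal(psi(0.5, 0), 1)     # exon included in all transcripts
  expect_equal(psi(1, 9), 0.1)     # included in 10% of transcripts
  expect_true(is.na(psi(0, 0)))
  expect_true(is.na(psi(1, 9, ir_raw = 3, er_raw = 2, min_junction_reads = 10)))
})

test_that("PSI is bounded, complementary and monotone", {
  set.seed(5)
  ir <- runif(200, 0, 50)
  er <- runif(200, 0, 50)
  p <- psi(ir, er)
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
  expect_equal(p + psi(er, ir), rep(1, 200))
  # monotone: increasing ir_raw never lowers PSI, increasing er_raw never raises it
  r0 <- normalize_rates(10, 10)
  r_up <- normalize_rates(11, 10)
  r_dn <- normalize_rates(10, 11)
  expect_gt(psi(r_up$ir_n, r_up$er_n), psi(r0$ir_n, r0$er_n))
  expect_lt(psi(r_dn$ir_n, r_dn$er_n), psi(r0$ir_n, r0$er_n))
})

test_that("psi_matrix grids events by sample and is reproducible", {
  models <- three_exon_models()
  cat <- fixture_catalog()
  # two samples, all reads inclusion -> PSI 1 in both
  s1 <- toy_sam(rep(c(150L, 350L), each = 10), rep("50M100N50M", 20))
  s2 <- toy_sam(rep(c(150L, 350L), each = 6), rep("50M100N50M", 12))
  pm <- psi_matrix(c(a = s1, b = s2), cat, read_length = 100)
  expect_equal(nrow(pm), 2)
  expect_equal(pm$psi, c(1, 1))

  # a sample with no reads for the event -> undefined cell
  s3 <- toy_sam(integer(), character())
  pm3 <- psi_matrix(c(a = s1, z = s3), cat, read_length = 100)
  expect_true(is.na(pm3$psi[pm3$sample_id == "z"]))

  expect_identical(psi_matrix(c(a = s1, b = s2), cat, read_length = 100), pm)
  expect_error(psi_matrix(c(x = tempfile()), cat), "x")
})

test_that("counting on simulator output reproduces emitted read counts exactly", {
  models <- simulate_gene_models(6, seed = 2)
  catalog <- cassette_exon_catalog(models)
  truth <- cassette_truth(catalog, 6, psi_young = c(0, 0.25, 0.5, 0.75, 1, 0.6),
                          psi_old = c(1, 0.75, 0.5, 0.25, 0, 0.6), seed = 3)
  cfg <- sim_config(seed = 9, junction_depth_mean = 80)
  sim <- simulate_splice_reads(cfg, models, truth)
  pm <- psi_matrix(sim$sam_paths, dplyr::semi_join(catalog, truth, by = "exon_key"),
                   min_junction_reads = 0)
  joined <- dplyr::inner_join(pm, sim$truth, by = c("exon_key", "sample_id"))
  expect_equal(nrow(joined), 6 * 13)
  expect_equal(joined$ir_raw, joined$n_inclusion)
  expect_equal(joined$er_raw, joined$n_exclusion)
  # extremes carry through: psi_true = 1 has no skip reads, 0 no inclusion
  ext <- joined[joined$psi_true == 1, ]
  expect_true(all(ext$er_raw == 0))
  expect_true(all(joined$ir_raw[joined$psi_true == 0] == 0))
})
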