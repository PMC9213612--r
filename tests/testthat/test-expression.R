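test_that("CPM arithmetic and identities", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(20, 0))
  out <- cpm(counts, library_sizes = c(s1 = 66666667))
  expect_equal(round(out$s1[1], 2), 0.30)  # ~20 reads at ~70M depth
  expect_equal(out$s1[2], 0)

  set.seed(1)
  mat <- tibble::tibble(gene_id = paste0("g", 1:50),
                        a = rpois(50, 100), b = rpois(50, 50))
  cc <- cpm(mat)
  expect_equal(colSums(as.matrix(cc[c("a", "b")])), c(a = 1e6, b = 1e6))
  # scaling counts and library sizes by k leaves CPM unchanged
  scaled <- dplyr::mutate(mat, a = a * 3, b = b * 3)
  expect_equal(cpm(scaled)$a, cc$a)
  # zero pattern preserved
  expect_equal(cc$a == 0, mat$a == 0)
  expect_error(cpm(mat, library_sizes = c(a = 0, b = 1)), "positive")
})

test_that("detection partitions genes into exclusive and shared sets", {
  grp <- tibble::tibble(sample_id = c("y1", "y2", "o1", "o2"),
                        cohort = c("young", "young", "old", "old"))
  cpm_tbl <- tibble::tibble(
    gene_id = c("only_young", "both", "only_old", "nowhere"),
    y1 = c(0.5, 1, 0, 0.1), y2 = c(0, 2, 0, 0.2),
    o1 = c(0, 3, 0.4, 0.1), o2 = c(0.1, 4, 0, 0.05))
  det <- detected_genes(cpm_tbl, grp, detect_threshold = 0.3)
  expect_equal(det$exclusive$young, "only_young")
  expect_equal(det$exclusive$old, "only_old")
  expect_equal(det$shared, "both")
  # partition: exclusive + shared = all detected, disjoint
  expect_equal(sort(c(det$exclusive$young, det$exclusive$old, det$shared)),
               sort(unique(unlist(det$detected))))
  expect_equal(det$summary$n_detected_total, 3)
  expect_equal(
    det$exclusive_detail$frac_other_below[det$exclusive_detail$gene_id == "only_young"],
    1)
})

test_that("detection set sizes match brute force on a planted toy", {
  set.seed(33)
  grp <- tibble::tibble(sample_id = c(paste0("y", 1:3), paste0("o", 1:3)),
                        cohort = rep(c("young", "old"), each = 3))
  mat <- matrix(runif(60, 0, 1), nrow = 10,
                dimnames = list(paste0("g", 1:10), grp$sample_id))
  cpm_tbl <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)),
                              tibble::as_tibble(mat))
  det <- detected_genes(cpm_tbl, grp, detect_threshold = 0.5)
  brute_young <- rownames(mat)[apply(mat[, 1:3] >= 0.5, 1, any)]
  brute_old <- rownames(mat)[apply(mat[, 4:6] >= 0.5, 1, any)]
  expect_setequal(det$detected$young, brute_young)
  expect_setequal(det$exclusive$old, setdiff(brute_old, brute_young))
})

test_that("fold-change categorization counts and shares", {
  degs <- tibble::tibble(
    gene_id = paste0("g", 1:8),
    fold_change = c(2.0, 1.6, 1.2, 1.01, 0.9, 0.5, 0.4, 0.8))
  fc <- fold_change_categories(degs)
  expect_equal(fc$n_up, 4)
  expect_equal(fc$n_down, 4)
  expect_equal(fc$n_up_gt_1.5, 2)
  expect_equal(fc$n_down_le_0.5, 2)
  expect_equal(fc$n_small_change + fc$n_large_change, fc$n_total)
  expect_equal(fc$pct_up_gt_1.5, 50.0)

  empty <- fold_change_categories(tibble::tibble(gene_id = character(),
                                                 fold_change = numeric()))
  expect_equal(empty$n_total, 0)
  expect_equal(empty$pct_up_gt_1.5, 0)

  expect_warning(
    fold_change_categories(tibble::tibble(gene_id = "g", fold_change = 1)),
    "neither")
  expect_error(
    fold_change_categories(tibble::tibble(gene_id = "g", fold_change = -1)),
    "positive")
})

test_that("blood-marker report restricts, flags absentees and averages", {
  grp <- tibble::tibble(sample_id = c("y1", "o1"), cohort = c("young", "old"))
  cpm_tbl <- tibble::tibble(gene_id = c(rbc_markers[1], "other"),
                            y1 = c(2, 10), o1 = c(4, 20))
  rep <- blood_marker_report(cpm_tbl, groups = grp)
  expect_equal(nrow(rep$per_sample), 4 * 2)
  expect_equal(sum(!rep$per_sample$present), 3 * 2)  # 3 markers absent
  present <- rep$per_sample[rep$per_sample$gene_id == rbc_markers[1], ]
  expect_equal(present$cpm[present$sample_id == "y1"], 2)
  means <- rep$cohort_means
  expect_equal(means$mean_cpm[means$gene_id == rbc_markers[1] &
                                means$cohort == "old"], 4)
})

test_that("metadata summary reports rounded mass statistics", {
  same <- tibble::tibble(sample_id = c("a", "b", "c"), cohort = "young",
                         age = c(1, 2, 3), sex = "Female",
                         body_mass = c(10, 10, 10))
  s <- metadata_summary(same)
  expect_equal(s$mass_sd, 0)
  expect_equal(s$n_female, 3)
  expect_equal(s$age_min, 1)
  expect_equal(s$age_max, 3)
})

test_that("Venn regions match brute force on toy sets", {
  ab <- homolog_overlap(list(A = c("x", "y"), B = c("z")))
  expect_equal(ab$count[ab$region == "A & B"], 0)
  same <- homolog_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$region == "A & B"], 2)
  expect_equal(sum(same$count[same$region %in% c("A", "B")]), 0)

  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "d", "e"))
  v <- homolog_overlap(sets)
  expect_equal(v$count[v$region == "A & B & C"], 1)          # c
  expect_equal(v$count[v$region == "B & C"], 1)              # d
  expect_equal(v$count[v$region == "A"], 1)                  # a
  expect_equal(sum(v$count), length(unique(unlist(sets))))
})

test_that("MDS distances behave as metric expectations demand", {
  set.seed(8)
  base <- tibble::tibble(gene_id = paste0("g", 1:100),
                         s1 = runif(100, 0, 100))
  cpm_tbl <- dplyr::mutate(base, s2 = s1, s3 = s1 * 2)
  fit <- suppressWarnings(mds_embedding(cpm_tbl, top_n = 100))
  expect_equal(fit$dist["s1", "s2"], 0)          # identical columns
  expect_equal(fit$dist, t(fit$dist))            # symmetry
  expect_equal(unname(diag(fit$dist)), rep(0, 3))
  expect_warning(mds_embedding(cpm_tbl, top_n = 5000), "top_n")
})

test_that("cohort-shifted expression separates cohorts in the embedding", {
  cfg <- sim_config(seed = 21, n_genes = 400, depth_factor = 1e-3,
                    deg_fraction = 0.4, logfc_sd = 1.5, dispersion = 0.05)
  sim <- simulate_counts(cfg)
  fit <- mds_embedding(cpm(sim$counts), top_n = 400, groups = sim$groups)
  pts <- tidy(fit)
  d2 <- as.matrix(dist(as.matrix(pts[c("dim1", "dim2")])))
  same <- outer(pts$cohort, pts$cohort, "==")
  sil <- vapply(seq_len(nrow(pts)), function(i) {
    a <- mean(d2[i, same[i, ] & seq_len(ncol(d2)) != i])
    b <- mean(d2[i, !same[i, ]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # embedding is invariant to sample order up to sign
  perm <- c(3, 1, 2, 8, 13, 4:7, 9:12)
  fit2 <- mds_embedding(cpm(sim$counts)[c("gene_id", pts$sample_id[perm])],
                        top_n = 400)
  d_orig <- fit$dist[pts$sample_id[perm], pts$sample_id[perm]]
  expect_equal(fit2$dist, d_orig)
})

test_that("bcv mode gives a valid alternative distance", {
  cfg <- sim_config(seed = 22, n_genes = 300, depth_factor = 1e-3,
                    deg_fraction = 0.4, logfc_sd = 1.5, dispersion = 0.05)
  sim <- simulate_counts(cfg)
  fit <- mds_embedding(cpm(sim$counts), top_n = 200, mode = "bcv",
                       groups = sim$groups)
  expect_true(all(is.finite(fit$dist)))
  expect_equal(fit$dist, t(fit$dist))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(fit)$mode, "bcv")
})

test_that("cpm agrees with the edgeR reference implementation", {
  set.seed(14)
  counts <- tibble::tibble(gene_id = paste0("g", 1:80),
                           a = rpois(80, 30), b = rpois(80, 300),
                           c = rpois(80, 3))
  mine <- cpm(counts)
  ref <- edgeR::cpm(as.matrix(counts[-1]), lib.size = colSums(as.matrix(counts[-1])))
  expect_equal(as.matrix(mine[-1]), ref, ignore_attr = TRUE)
})
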