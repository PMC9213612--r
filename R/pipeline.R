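#' Read a flat key-value pipeline configuration file
#'
#' Minimal TOML-style `key = value` format: one pair per line, `#`
#' comments, strings optionally quoted, numbers parsed as numerics.
#'
#' @param path Path to the config file.
#' @return A named list of parsed values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("Config line is not 'key = value': %s", ln))
    }
    key <- stringr::str_trim(sub("=.*$", "", ln))
    val <- stringr::str_trim(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the cohort splicing and expression pipeline
#'
#' Orchestrates the package stages over a configuration list: `simulate`
#' writes a synthetic fixture bundle; `psi` quantifies PSI over the SAM
#' files; `diffsplice` compares cohorts; `summarize` computes CPM,
#' detection sets, fold-change categories and the MDS embedding; `enrich`
#' runs the overrepresentation test; `qpcr` the ddCt validation.  Every
#' stage writes TSV artifacts into `outdir` and a `run_manifest.json`
#' records the configuration, seed and per-stage record counts.
#'
#' @param config Named list (see [read_pipeline_config()]).  Recognised
#'   keys: `outdir` (required), `seed`, `gtf`, `sam_dir`, `counts`,
#'   `groups`, `deg_table`, `metadata`, `annotation`, `target_genes`,
#'   `ct_table`, and the numeric parameters `anchor_min`,
#'   `min_junction_reads`, `delta_threshold`, `detect_threshold`, `top_n`,
#'   `prior_count`, `depth_factor`, `n_genes`, `n_events`,
#'   `junction_depth_mean`.
#' @param stages Character vector of stages to run, in order; `"all"`
#'   expands to every stage whose inputs are configured.
#' @return The run manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.null(config$outdir)) abort("`config$outdir` is required.")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1)
  all_stages <- c("simulate", "psi", "diffsplice", "summarize", "enrich", "qpcr")
  if (identical(stages, "all")) {
    stages <- all_stages
    # optional stages run only when their inputs are configured
    if (is.null(config$annotation)) stages <- setdiff(stages, "enrich")
    if (is.null(config$ct_table)) stages <- setdiff(stages, "qpcr")
    if (is.null(config$groups) && !"simulate" %in% stages) {
      stages <- setdiff(stages, c("diffsplice", "summarize"))
    }
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s. Available: %s.",
                  paste(bad, collapse = ", "), paste(all_stages, collapse = ", ")))
  }
  manifest <- list(seed = seed, config = config, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] done", stage))
  }
  need <- function(key) {
    path <- config[[key]]
    if (is.null(path)) abort(sprintf("Stage needs config key `%s`.", key))
    if (!file.exists(path)) abort(sprintf("Input not found (`%s`): %s", key, path))
    path
  }

  if ("simulate" %in% stages) {
    sc <- sim_config(
      seed = seed,
      depth_factor = config$depth_factor %||% 1e-3,
      n_genes = config$n_genes %||% 1000,
      junction_depth_mean = config$junction_depth_mean %||% 200,
      anchor_min = config$anchor_min %||% 8
    )
    bundle_dir <- file.path(outdir, "fixtures")
    mf <- write_fixture_bundle(sc, bundle_dir,
                               n_events = config$n_events %||% 20,
                               psi_young = config$psi_young %||% 0.5,
                               psi_old = config$psi_old %||% 0.5)
    config$gtf <- config$gtf %||% file.path(bundle_dir, "models.gtf")
    config$sam_dir <- config$sam_dir %||% file.path(bundle_dir, "sam")
    config$counts <- config$counts %||% file.path(bundle_dir, "counts.tsv")
    config$groups <- config$groups %||% file.path(bundle_dir, "groups.tsv")
    note("simulate", outdir = bundle_dir, n_sam = length(mf$sam))
  }

  groups <- NULL
  if (!is.null(config$groups) && file.exists(config$groups)) {
    groups <- readr::read_tsv(config$groups, show_col_types = FALSE)
  }

  if ("psi" %in% stages) {
    gtf <- need("gtf")
    sam_dir <- need("sam_dir")
    sams <- list.files(sam_dir, pattern = "\\.sam$", full.names = TRUE)
    names(sams) <- sub("\\.sam$", "", basename(sams))
    catalog <- cassette_exon_catalog(read_gtf(gtf))
    psi_tbl <- psi_matrix(sams, catalog,
                          anchor_min = config$anchor_min %||% 8,
                          min_junction_reads = config$min_junction_reads %||% 10)
    readr::write_tsv(psi_tbl, file.path(outdir, "psi_matrix.tsv"))
    readr::write_tsv(select(catalog, "exon_key", "gene_id"),
                     file.path(outdir, "exon_genes.tsv"))
    note("psi", n_records = nrow(psi_tbl), n_samples = length(sams))
  }

  if ("diffsplice" %in% stages) {
    psi_path <- file.path(outdir, "psi_matrix.tsv")
    if (!file.exists(psi_path)) abort("Run the `psi` stage first (psi_matrix.tsv missing).")
    if (is.null(groups)) abort("`diffsplice` needs a `groups` table.")
    psi_tbl <- readr::read_tsv(psi_path, show_col_types = FALSE)
    gene_map <- readr::read_tsv(file.path(outdir, "exon_genes.tsv"),
                                show_col_types = FALSE)
    cmp <- compare_splicing(psi_tbl, groups,
                            delta_threshold = config$delta_threshold %||% 0.20,
                            min_defined_samples = config$min_defined_samples %||% 3,
                            gene_map = gene_map)
    readr::write_tsv(tidy(cmp), file.path(outdir, "splicing_comparison.tsv"))
    readr::write_tsv(glance(cmp), file.path(outdir, "splicing_summary.tsv"))
    note("diffsplice", n_exons = cmp$summary$n_exons,
         n_flagged = cmp$summary$n_flagged_exons)
  }

  if ("summarize" %in% stages) {
    counts <- readr::read_tsv(need("counts"), show_col_types = FALSE)
    cpm_tbl <- cpm(counts)
    readr::write_tsv(cpm_tbl, file.path(outdir, "cpm.tsv"))
    n_det <- NA_integer_
    if (!is.null(groups)) {
      det <- detected_genes(cpm_tbl, groups,
                            detect_threshold = config$detect_threshold %||% 0.3)
      readr::write_tsv(det$summary, file.path(outdir, "detection_summary.tsv"))
      n_det <- det$summary$n_detected_total
      mds <- mds_embedding(cpm_tbl, top_n = config$top_n %||% 500,
                           prior_count = config$prior_count %||% 2,
                           groups = groups)
      readr::write_tsv(tidy(mds), file.path(outdir, "mds_coordinates.tsv"))
      blood <- blood_marker_report(cpm_tbl, groups = groups)
      readr::write_tsv(blood$per_sample, file.path(outdir, "blood_markers.tsv"))
    }
    if (!is.null(config$deg_table)) {
      degs <- readr::read_tsv(need("deg_table"), show_col_types = FALSE)
      readr::write_tsv(fold_change_categories(degs),
                       file.path(outdir, "fold_change_categories.tsv"))
    }
    if (!is.null(config$metadata)) {
      meta <- readr::read_tsv(need("metadata"), show_col_types = FALSE)
      readr::write_tsv(metadata_summary(meta),
                       file.path(outdir, "metadata_summary.tsv"))
    }
    note("summarize", n_genes = nrow(cpm_tbl), n_detected = n_det)
  }

  if ("enrich" %in% stages) {
    ann <- readr::read_tsv(need("annotation"), show_col_types = FALSE)
    tgt_path <- file.path(outdir, "splicing_comparison.tsv")
    if (!is.null(config$target_genes)) {
      target <- readr::read_lines(need("target_genes"))
    } else if (file.exists(tgt_path)) {
      cmp <- readr::read_tsv(tgt_path, show_col_types = FALSE)
      if (!"gene_id" %in% names(cmp)) abort("splicing_comparison.tsv lacks gene_id.")
      target <- unique(cmp$gene_id[cmp$flagged])
    } else {
      abort("`enrich` needs `target_genes` or a prior diffsplice stage.")
    }
    reference <- unique(ann$gene_id)
    target <- intersect(target, reference)
    enr <- overrepresentation_test(target, reference, ann,
                                   min_term_size = config$min_term_size %||% 2)
    readr::write_tsv(tidy(enr), file.path(outdir, "enrichment.tsv"))
    note("enrich", n_terms = nrow(enr), n_target = length(target))
  }

  if ("qpcr" %in% stages) {
    ct <- readr::read_tsv(need("ct_table"), show_col_types = FALSE)
    if (is.null(groups)) abort("`qpcr` needs a `groups` table.")
    targets <- setdiff(unique(ct$gene_id), config$reference_gene %||% "GAPDH")
    fc <- ddct_fold_change(ct, targets, groups,
                           reference_gene = config$reference_gene %||% "GAPDH")
    readr::write_tsv(fc, file.path(outdir, "qpcr_fold_changes.tsv"))
    note("qpcr", n_genes = nrow(fc))
  }

  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
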