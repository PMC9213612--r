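#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort generator.
#' Defaults describe the study design the package targets: two cohorts of
#' 6 and 7 dogs, libraries near 74 million reads, uniform 124 bp reads,
#' and splice junctions covered at a mean depth of 200 split reads.
#'
#' @param n_young,n_old Samples per cohort (defaults 6 and 7).
#' @param library_size_mean Mean sequenced reads per library (default
#'   74e6), scaled by `depth_factor`.
#' @param depth_factor Multiplier applied to `library_size_mean` so the
#'   same statistical structure can be generated at bench scale.
#' @param read_length Uniform read length in bp (default 124).
#' @param n_genes Number of genes in the count simulation.
#' @param deg_fraction Fraction of genes given a planted fold change
#'   between cohorts (default 0.2).
#' @param logfc_sd Standard deviation of planted log2 fold changes.
#' @param dispersion Negative-binomial dispersion of counts (0 gives
#'   Poisson counts).
#' @param junction_depth_mean Mean split-read depth per junction for the
#'   splice simulator (default 200).
#' @param anchor_min Minimum anchor the emitted reads guarantee on the
#'   primary junction (default 8).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_young = 6, n_old = 7, library_size_mean = 74e6,
                       depth_factor = 1, read_length = 124, n_genes = 1000,
                       deg_fraction = 0.2, logfc_sd = 0.8, dispersion = 0.1,
                       junction_depth_mean = 200, anchor_min = 8, seed = 1) {
  check_number(n_young, "n_young", lower = 1)
  check_number(n_old, "n_old", lower = 1)
  check_number(library_size_mean, "library_size_mean", lower = 1)
  check_number(depth_factor, "depth_factor", lower = 1e-9)
  check_number(read_length, "read_length", lower = 20)
  check_number(n_genes, "n_genes", lower = 1)
  check_number(deg_fraction, "deg_fraction", lower = 0, upper = 1)
  check_number(logfc_sd, "logfc_sd", lower = 0)
  check_number(dispersion, "dispersion", lower = 0)
  check_number(junction_depth_mean, "junction_depth_mean", lower = 1)
  check_number(anchor_min, "anchor_min", lower = 1)
  check_number(seed, "seed", lower = 0, upper = 2^31 - 1)
  if (read_length <= 2 * anchor_min) {
    abort("`read_length` must exceed 2 * anchor_min.")
  }
  structure(list(
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    library_size_mean = library_size_mean, depth_factor = depth_factor,
    read_length = as.integer(read_length), n_genes = as.integer(n_genes),
    deg_fraction = deg_fraction, logfc_sd = logfc_sd,
    dispersion = dispersion, junction_depth_mean = junction_depth_mean,
    anchor_min = as.integer(anchor_min), seed = as.integer(seed)
  ), class = "sim_config")
}

sample_ids <- function(config) {
  c(sprintf("young_%d", seq_len(config$n_young)),
    sprintf("old_%d", seq_len(config$n_old)))
}

cohort_of <- function(config) {
  setNames(rep(c("young", "old"), c(config$n_young, config$n_old)),
           sample_ids(config))
}

#' Simulate cohort gene counts with planted fold changes
#'
#' Gene relative abundances are drawn log-normal, library sizes log-normal
#' around `library_size_mean * depth_factor` (coefficient of variation
#' ~17%, matching typical per-library sequencing depth spread), and counts
#' negative-binomial around `abundance x library size`, with the old
#' cohort's mean multiplied by the planted fold change for DEG genes.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_counts"`: `counts` (tibble, `gene_id`
#'   plus one column per sample), `truth` (tibble `gene_id`, `is_deg`,
#'   `log2_fc_true`, `fc_true`), `library_sizes` (named vector of column
#'   sums), `groups` (tibble `sample_id`, `cohort`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  samples <- sample_ids(config)
  cohorts <- cohort_of(config)
  n <- config$n_genes
  rel <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  rel <- rel / sum(rel)
  n_deg <- round(config$deg_fraction * n)
  is_deg <- seq_len(n) <= n_deg
  log2_fc <- ifelse(is_deg, rnorm(n, mean = 0, sd = config$logfc_sd), 0)
  fc <- 2^log2_fc
  lib_target <- rlnorm(length(samples),
                       meanlog = log(config$library_size_mean * config$depth_factor),
                       sdlog = 0.17)
  draw <- function(mu) {
    mu <- pmax(mu, 1e-8)
    if (config$dispersion <= 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  mat <- vapply(seq_along(samples), function(s) {
    mult <- if (cohorts[[s]] == "old") fc else rep(1, n)
    draw(rel * mult * lib_target[[s]])
  }, numeric(n))
  colnames(mat) <- samples
  gene_id <- sprintf("gene_%04d", seq_len(n))
  counts <- bind_cols(tibble(gene_id = gene_id), as_tibble(mat))
  structure(list(
    counts = counts,
    truth = tibble(gene_id = gene_id, is_deg = is_deg,
                   log2_fc_true = log2_fc, fc_true = fc),
    library_sizes = colSums(mat),
    groups = tibble(sample_id = samples, cohort = unname(cohorts))
  ), class = "sim_counts")
}

#' Simulate multi-exon gene models
#'
#' Lays out `n_genes` single-transcript gene models along one chromosome,
#' each with `n_exons` exons separated by introns, for use as the
#' annotation substrate of [simulate_splice_reads()].  Flanking exons are
#' kept at least one read length long so simulated split reads never run
#' off an exon end.
#'
#' @param n_genes Number of genes.
#' @param n_exons Exons per transcript (default 3: one cassette candidate
#'   per gene, which keeps junction evidence unambiguous between events).
#' @param exon_length,intron_length Length ranges (bp) sampled uniformly.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return An exon tibble in the internal 0-based half-open convention,
#'   as returned by [read_gtf()].
#' @export
simulate_gene_models <- function(n_genes, n_exons = 3,
                                 exon_length = c(150, 300),
                                 intron_length = c(500, 2000),
                                 chrom = "chr1", seed = 1) {
  check_number(n_genes, "n_genes", lower = 1)
  check_number(n_exons, "n_exons", lower = 2)
  withr::local_seed(seed)
  cursor <- 1000L
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    lens <- sample(seq(exon_length[1], exon_length[2]), n_exons, replace = TRUE)
    gaps <- sample(seq(intron_length[1], intron_length[2]), n_exons - 1,
                   replace = TRUE)
    starts <- cursor + cumsum(c(0L, lens[-n_exons] + gaps))
    rows[[g]] <- tibble(
      gene_id = sprintf("sgene_%04d", g),
      transcript_id = sprintf("stx_%04d", g),
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = "+",
      exon_id = sprintf("sgene_%04d.e%d", g, seq_len(n_exons)),
      exon_length = as.integer(lens)
    )
    cursor <- as.integer(starts[n_exons] + lens[n_exons] + 5000L)
  }
  bind_rows(rows)
}

#' Assign true inclusion fractions to cassette events
#'
#' Picks `n_events` events from a catalog (at most one per gene, so no two
#' simulated events share a junction) and attaches per-cohort true PSI
#' values.
#'
#' @param catalog Tibble from [cassette_exon_catalog()].
#' @param n_events Number of events to plant.
#' @param psi_young,psi_old True inclusion fractions, recycled across the
#'   chosen events.
#' @param seed Integer seed for the event draw.
#' @return `catalog` rows with added `psi_young_true`, `psi_old_true`.
#' @export
cassette_truth <- function(catalog, n_events, psi_young, psi_old, seed = 1) {
  withr::local_seed(seed)
  pool <- catalog |> group_by(.data$gene_id) |> slice_head(n = 1) |> ungroup()
  if (n_events > nrow(pool)) {
    abort(sprintf("Requested %d events but only %d genes provide candidates.",
                  n_events, nrow(pool)))
  }
  chosen <- pool[sort(sample.int(nrow(pool), n_events)), ]
  mutate(chosen,
         psi_young_true = rep_len(psi_young, n_events),
         psi_old_true = rep_len(psi_old, n_events))
}

#' Simulate splice-junction reads and write per-sample SAM files
#'
#' For every sample and every cassette event, split reads are emitted per
#' junction: the included isoform leaves evidence at *both* inclusion
#' junctions, each at Poisson depth `junction_depth_mean x psi_true`,
#' while the skipped isoform leaves evidence at the skip junction at
#' depth `junction_depth_mean x (1 - psi_true)`.  The junction position
#' within each read is uniform subject to `anchor_min` aligned bases on
#' each side, so anchor filtering is exercised; reads that overrun a short
#' cassette exon continue across the second inclusion junction as
#' three-block alignments.
#'
#' @param config A [sim_config()].
#' @param models Exon tibble containing every event's gene model.
#' @param truth Event truth tibble from [cassette_truth()].
#' @param outdir Directory for the SAM files (created if needed).
#' @return A list: `sam_paths` (named by sample), `truth` (per sample and
#'   event: emitted inclusion/exclusion read counts and true PSI),
#'   `config`.
#' @export
simulate_splice_reads <- function(config, models, truth, outdir = tempfile("sim_sam_")) {
  stopifnot(inherits(config, "sim_config"))
  check_cols(truth, c("exon_key", "chrom", "exon_start", "exon_end",
                      "up_donor", "up_acceptor", "down_donor", "down_acceptor",
                      "skip_donor", "skip_acceptor",
                      "psi_young_true", "psi_old_true"), "truth")
  if (any(truth$psi_young_true < 0 | truth$psi_young_true > 1 |
            truth$psi_old_true < 0 | truth$psi_old_true > 1)) {
    abort("True PSI values must lie in [0, 1].")
  }
  catalog_keys <- cassette_exon_catalog(models)$exon_key
  absent <- setdiff(truth$exon_key, catalog_keys)
  if (length(absent) > 0) {
    abort(sprintf("Cassette event(s) absent from `models`: %s.",
                  paste(absent, collapse = ", ")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  withr::local_seed(config$seed)
  samples <- sample_ids(config)
  cohorts <- cohort_of(config)
  rl <- config$read_length
  amin <- config$anchor_min
  lambda <- config$junction_depth_mean
  chrom_len <- max(models$end) + 1000L
  truth_rows <- vector("list", length(samples))
  sam_paths <- setNames(file.path(outdir, paste0(samples, ".sam")), samples)
  for (s in seq_along(samples)) {
    p <- if (cohorts[[s]] == "young") truth$psi_young_true else truth$psi_old_true
    n_up <- rpois(nrow(truth), lambda * p)
    n_down <- rpois(nrow(truth), lambda * p)
    n_skip <- rpois(nrow(truth), lambda * (1 - p))
    recs <- purrr::pmap(
      list(seq_len(nrow(truth)), n_up, n_down, n_skip),
      function(i, nu, nd, ns) {
        ev <- truth[i, ]
        bind_rows(
          junction_reads(nu, ev$up_donor, ev$up_acceptor, rl, amin,
                         right_limit = ev$exon_end,
                         next_donor = ev$down_donor, next_acceptor = ev$down_acceptor),
          junction_reads(nd, ev$down_donor, ev$down_acceptor, rl, amin,
                         left_limit = ev$exon_start,
                         prev_donor = ev$up_donor, prev_acceptor = ev$up_acceptor),
          junction_reads(ns, ev$skip_donor, ev$skip_acceptor, rl, amin)
        ) |>
          mutate(exon_key = ev$exon_key, chrom = ev$chrom)
      }
    ) |> bind_rows()
    write_sam(recs, sam_paths[[s]], chrom_lengths = setNames(chrom_len, unique(models$chrom)),
              sample_id = samples[[s]], read_length = rl)
    truth_rows[[s]] <- tibble(
      sample_id = samples[[s]], cohort = unname(cohorts[[s]]),
      exon_key = truth$exon_key, psi_true = p,
      n_inclusion = n_up + n_down, n_exclusion = n_skip
    )
  }
  list(sam_paths = sam_paths, truth = bind_rows(truth_rows), config = config)
}

# Build read records across one junction.  The left block ends at `donor`
# (last base, 0-based) and the right block starts at `acceptor`.  The split
# point is uniform with >= amin bases on each side.  If the right block
# would overrun `right_limit` (the cassette exon end, half-open), the read
# continues across the event's other inclusion junction; symmetrically for
# the left side.
junction_reads <- function(n, donor, acceptor, rl, amin,
                           right_limit = NULL, next_donor = NULL,
                           next_acceptor = NULL, left_limit = NULL,
                           prev_donor = NULL, prev_acceptor = NULL) {
  if (n == 0) {
    return(tibble(pos = integer(), cigar = character()))
  }
  left <- sample(seq(amin, rl - amin), n, replace = TRUE)
  right <- rl - left
  pos <- donor - left + 1L
  cigar <- sprintf("%dM%dN%dM", left, acceptor - donor - 1L, right)
  if (!is.null(right_limit)) {
    room <- right_limit - acceptor
    over <- right > room
    if (any(over)) {
      cigar[over] <- sprintf("%dM%dN%dM%dN%dM",
                             left[over], acceptor - donor - 1L, room,
                             next_acceptor - next_donor - 1L, right[over] - room)
    }
  }
  if (!is.null(left_limit)) {
    room <- donor + 1L - left_limit
    over <- left > room
    if (any(over)) {
      pos[over] <- prev_donor - (left[over] - room) + 1L
      cigar[over] <- sprintf("%dM%dN%dM%dN%dM",
                             left[over] - room, prev_acceptor - prev_donor - 1L,
                             room, acceptor - donor - 1L, right[over])
    }
  }
  tibble(pos = pos, cigar = cigar)
}

#' Write alignment records as a SAM text file
#'
#' @param recs Tibble with columns `chrom`, `pos` (0-based) and `cigar`.
#' @param path Output path.
#' @param chrom_lengths Named vector of reference lengths for the header.
#' @param sample_id Used to build read names.
#' @param read_length Length of the placeholder sequence field.
#' @return `path`, invisibly.
#' @export
write_sam <- function(recs, path, chrom_lengths, sample_id = "sample",
                      read_length = 124) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  seq_field <- strrep("A", read_length)
  body <- if (nrow(recs) == 0) character() else sprintf(
    "%s_r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
    sample_id, seq_len(nrow(recs)), recs$chrom, recs$pos + 1L, recs$cigar,
    seq_field)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates gene models, planted cassette events, per-sample splice-read
#' SAM files and a cohort count matrix, and writes everything with a JSON
#' manifest so a downstream run is fully reproducible from disk.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param n_events Number of cassette events to plant.
#' @param psi_young,psi_old True inclusion fractions (recycled).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_bundle <- function(config, outdir, n_events = 10,
                                 psi_young = 0.5, psi_old = 0.5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  models <- simulate_gene_models(max(n_events, 1), seed = config$seed)
  catalog <- cassette_exon_catalog(models)
  truth <- cassette_truth(catalog, n_events, psi_young, psi_old,
                          seed = config$seed)
  write_gtf(models, file.path(outdir, "models.gtf"))
  sim <- simulate_splice_reads(config, models, truth,
                               outdir = file.path(outdir, "sam"))
  cnt <- simulate_counts(config)
  readr::write_tsv(cnt$counts, file.path(outdir, "counts.tsv"))
  readr::write_tsv(cnt$truth, file.path(outdir, "counts_truth.tsv"))
  readr::write_tsv(sim$truth, file.path(outdir, "splice_truth.tsv"))
  readr::write_tsv(cnt$groups, file.path(outdir, "groups.tsv"))
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    gtf = "models.gtf",
    sam = file.path("sam", basename(sim$sam_paths)),
    counts = "counts.tsv",
    counts_truth = "counts_truth.tsv",
    splice_truth = "splice_truth.tsv",
    groups = "groups.tsv"
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
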