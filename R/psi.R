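#' Count inclusion and exclusion split reads for cassette events
#'
#' For each cassette event, a split read supports *exclusion* when it
#' carries a junction exactly matching the skip junction, and *inclusion*
#' when it carries a junction exactly matching either inclusion junction.
#' A read whose alignment spans both inclusion junctions (possible when
#' the cassette exon is shorter than the read) is counted once.  Junction
#' coordinates must match exactly — no fuzz window — and both flanking
#' blocks must align at least `anchor_min` reference bases.
#'
#' @param reads Alignment tibble from [read_sam()].
#' @param catalog Cassette-event tibble from [cassette_exon_catalog()]
#'   (one or more rows).
#' @param anchor_min Minimum aligned bases required on each side of a
#'   junction (default 8).
#' @return A tibble with one row per catalog event: `exon_key`, `ir_raw`,
#'   `er_raw`.
#' @export
count_junction_reads <- function(reads, catalog, anchor_min = 8) {
  check_number(anchor_min, "anchor_min", lower = 0)
  check_cols(catalog, c("exon_key", "chrom", "up_donor", "up_acceptor",
                        "down_donor", "down_acceptor", "skip_donor",
                        "skip_acceptor"), "catalog")
  juncs <- alignment_junctions(reads)
  juncs <- filter(juncs, .data$left_anchor >= anchor_min,
                  .data$right_anchor >= anchor_min)
  # inclusion: union of reads over the two inclusion junctions, so a read
  # spanning both still counts once
  ir <- vapply(seq_len(nrow(catalog)), function(i) {
    sel <- juncs$chrom == catalog$chrom[i] &
      ((juncs$donor_end == catalog$up_donor[i] &
          juncs$acceptor_start == catalog$up_acceptor[i]) |
         (juncs$donor_end == catalog$down_donor[i] &
            juncs$acceptor_start == catalog$down_acceptor[i]))
    length(unique(juncs$read_idx[sel]))
  }, integer(1))
  er <- vapply(seq_len(nrow(catalog)), function(i) {
    sel <- juncs$chrom == catalog$chrom[i] &
      juncs$donor_end == catalog$skip_donor[i] &
      juncs$acceptor_start == catalog$skip_acceptor[i]
    length(unique(juncs$read_idx[sel]))
  }, integer(1))
  tibble(exon_key = catalog$exon_key, ir_raw = ir, er_raw = er)
}

#' Normalize raw junction counts to per-placement rates
#'
#' Raw inclusion/exclusion counts are not directly comparable: an included
#' exon is supported by two junctions while skipping is supported by one,
#' and each junction can be hit by `read_length - 2 * anchor_min + 1`
#' distinct read placements.  Dividing by (supporting junctions) x
#' (placements per junction) yields rates on a common per-junction,
#' per-placement scale.  With uniform read length the placement factor
#' cancels inside the PSI ratio, but the junction-count factor does not.
#'
#' @param ir_raw,er_raw Raw inclusion / exclusion read counts (vectors).
#' @param read_length Uniform read length in bp.
#' @param anchor_min Anchor requirement used during counting.
#' @param n_inclusion_junctions Junctions supporting inclusion (default 2:
#'   upstream and downstream).
#' @return A tibble with columns `ir_n`, `er_n`.
#' @export
#' @examples
#' normalize_rates(20, 10, read_length = 124, anchor_min = 8)
normalize_rates <- function(ir_raw, er_raw, read_length = 124, anchor_min = 8,
                            n_inclusion_junctions = 2) {
  if (any(ir_raw < 0) || any(er_raw < 0)) abort("Raw counts must be >= 0.")
  placements <- read_length - 2 * anchor_min + 1
  if (read_length <= 2 * anchor_min) {
    abort(sprintf(
      "read_length (%d) must exceed 2 * anchor_min (%d): no valid junction placement exists.",
      read_length, 2 * anchor_min))
  }
  tibble(ir_n = ir_raw / (n_inclusion_junctions * placements),
         er_n = er_raw / placements)
}

#' Percent spliced in
#'
#' The PSI of an exon is the normalized inclusion rate over the total
#' normalized junction rate, `psi = ir_n / (ir_n + er_n)`: 1 means the
#' exon is included in every transcript sequenced, 0.1 that it is
#' included in 10% of them.  When raw junction coverage for the exon is
#' below `min_junction_reads` the estimate is considered unreliable and
#' `NA` is returned.
#'
#' @param ir_n,er_n Normalized inclusion / exclusion rates (vectors), from
#'   [normalize_rates()].
#' @param ir_raw,er_raw Optional raw counts backing the rates; used only
#'   for the coverage filter.  When omitted, coverage is assumed
#'   sufficient.
#' @param min_junction_reads Minimum raw junction reads (inclusion +
#'   exclusion) for a defined PSI (default 10; 0 disables).
#' @return Numeric vector of PSI values in \[0, 1\], `NA` where undefined.
#' @export
#' @examples
#' psi(1, 9)       # exon included in 10% of transcripts
#' psi(0.5, 0)     # no exclusion evidence: constitutively included
psi <- function(ir_n, er_n, ir_raw = NULL, er_raw = NULL,
                min_junction_reads = 10) {
  if (any(ir_n < 0, na.rm = TRUE) || any(er_n < 0, na.rm = TRUE)) {
    abort("Normalized rates must be >= 0.")
  }
  total <- ir_n + er_n
  out <- if_else(total > 0, ir_n / total, NA_real_)
  if (!is.null(ir_raw) || !is.null(er_raw)) {
    ir_raw <- ir_raw %||% 0
    er_raw <- er_raw %||% 0
    out[ir_raw + er_raw < min_junction_reads] <- NA_real_
  }
  out
}

#' PSI matrix across samples
#'
#' Runs junction counting, normalization and PSI over one SAM file per
#' sample, for every event in the cassette catalog.
#'
#' @param sam_paths Named character vector of SAM paths; names are sample
#'   ids.
#' @param catalog Cassette-event tibble from [cassette_exon_catalog()].
#' @param anchor_min,min_junction_reads,n_inclusion_junctions See
#'   [count_junction_reads()], [psi()], [normalize_rates()].
#' @param read_length Uniform read length; if `NULL`, taken per sample as
#'   the most common aligned read length.
#' @return A long tibble (one row per event per sample): `exon_key`,
#'   `sample_id`, `ir_raw`, `er_raw`, `ir_n`, `er_n`, `psi`.
#' @export
psi_matrix <- function(sam_paths, catalog, anchor_min = 8,
                       min_junction_reads = 10, n_inclusion_junctions = 2,
                       read_length = NULL) {
  if (length(sam_paths) == 0) abort("`sam_paths` must name at least one sample.")
  if (is.null(names(sam_paths)) || any(!nzchar(names(sam_paths)))) {
    abort("`sam_paths` must be a named vector (names are sample ids).")
  }
  missing <- sam_paths[!file.exists(sam_paths)]
  if (length(missing) > 0) {
    abort(sprintf("SAM file missing for sample(s): %s.",
                  paste(names(missing), collapse = ", ")))
  }
  purrr::imap(sam_paths, function(path, sample_id) {
    reads <- read_sam(path)
    rl <- read_length %||%
      (if (nrow(reads) > 0) {
        as.integer(names(sort(table(reads$read_length), decreasing = TRUE))[1])
      } else 124L)
    counts <- count_junction_reads(reads, catalog, anchor_min = anchor_min)
    rates <- normalize_rates(counts$ir_raw, counts$er_raw, read_length = rl,
                             anchor_min = anchor_min,
                             n_inclusion_junctions = n_inclusion_junctions)
    tibble(
      exon_key = counts$exon_key,
      sample_id = sample_id,
      ir_raw = counts$ir_raw,
      er_raw = counts$er_raw,
      ir_n = rates$ir_n,
      er_n = rates$er_n,
      psi = psi(rates$ir_n, rates$er_n, counts$ir_raw, counts$er_raw,
                min_junction_reads = min_junction_reads)
    )
  }) |>
    bind_rows()
}
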