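#' Read exon annotation from a GTF file
#'
#' Parses a GTF 2.2 annotation and returns the exon features as a tidy
#' table, one row per exon per transcript.  Coordinates are converted from
#' the GTF's 1-based inclusive convention to the package-internal 0-based
#' half-open convention; the conversion happens only here and in
#' [write_gtf()], so all downstream junction arithmetic is unambiguous.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `exon_id` and
#'   `exon_length`.  Non-exon feature lines are ignored.
#' @seealso [cassette_exon_catalog()], [write_gtf()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9) {
      abort(sprintf("Malformed GTF line %d: expected 9 tab-separated columns, found %d.",
                    i, length(fields)))
    }
    if (identical(fields[[3]], "exon") && !grepl("gene_id", fields[[9]], fixed = TRUE)) {
      abort(sprintf("Malformed GTF line %d: exon feature lacks a gene_id attribute.", i))
    }
  }
  if (!any(keep)) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), exon_id = character(),
                  exon_length = integer()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  exon_id <- if ("exon_id" %in% names(S4Vectors::mcols(gr))) gr$exon_id else NA_character_
  out <- tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_id = as.character(exon_id)
  )
  out <- mutate(out,
    strand = if_else(.data$strand %in% c("+", "-"), .data$strand, "+"),
    exon_id = if_else(is.na(.data$exon_id),
                      sprintf("%s:%d-%d", .data$chrom, .data$start + 1L, .data$end),
                      .data$exon_id),
    exon_length = .data$end - .data$start
  )
  arrange(out, .data$chrom, .data$start, .data$end, .data$transcript_id)
}

#' Write an exon table back to GTF
#'
#' Inverse of [read_gtf()]: converts the internal 0-based half-open
#' coordinates back to GTF's 1-based inclusive convention and writes one
#' `exon` feature line per row.
#'
#' @param exons Exon tibble as produced by [read_gtf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  check_cols(exons, c("gene_id", "transcript_id", "chrom", "start", "end", "strand"),
             "exons")
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand
  )
  gr$source <- "agesplice"
  gr$type <- "exon"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  if ("exon_id" %in% names(exons)) gr$exon_id <- exons$exon_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Enumerate cassette-exon events from an exon table
#'
#' A cassette exon is an internal exon (neither first nor last within some
#' transcript) that can be either retained in or skipped from the mature
#' transcript.  For every internal exon of every transcript this returns
#' the three splice junctions whose split-read support quantifies the
#' event: the two inclusion junctions joining the exon to its flanking
#' exons, and the skip junction joining the flanking exons directly.
#'
#' Junction coordinates follow the genomic (forward) orientation
#' regardless of strand: `*_donor` is the last aligned base of the left
#' block (0-based) and `*_acceptor` the first aligned base of the right
#' block, matching the junctions reported by [read_junctions()].
#'
#' @param exons Exon tibble as produced by [read_gtf()] (0-based half-open
#'   coordinates).
#' @return A tibble with one row per distinct cassette event, sorted by
#'   `chrom`, `exon_start`, `exon_end`: columns `exon_key`, `gene_id`,
#'   `chrom`, `strand`, `exon_start`, `exon_end`, `exon_length`,
#'   `up_donor`, `up_acceptor`, `down_donor`, `down_acceptor`,
#'   `skip_donor`, `skip_acceptor`.  Transcripts with fewer than three
#'   exons contribute no events.
#' @export
cassette_exon_catalog <- function(exons) {
  check_cols(exons, c("gene_id", "transcript_id", "chrom", "start", "end", "strand"),
             "exons")
  if (nrow(exons) == 0) return(empty_catalog())
  out <- exons |>
    group_by(.data$gene_id, .data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      prev_end = dplyr::lag(.data$end),
      next_start = dplyr::lead(.data$start)
    ) |>
    ungroup() |>
    filter(!is.na(.data$prev_end), !is.na(.data$next_start)) |>
    mutate(
      exon_start = .data$start,
      exon_end = .data$end,
      exon_length = .data$end - .data$start,
      up_donor = .data$prev_end - 1L,
      up_acceptor = .data$exon_start,
      down_donor = .data$exon_end - 1L,
      down_acceptor = .data$next_start,
      skip_donor = .data$prev_end - 1L,
      skip_acceptor = .data$next_start
    ) |>
    select("gene_id", "chrom", "strand", "exon_start", "exon_end", "exon_length",
           "up_donor", "up_acceptor", "down_donor", "down_acceptor",
           "skip_donor", "skip_acceptor") |>
    distinct() |>
    arrange(.data$chrom, .data$exon_start, .data$exon_end,
            .data$skip_donor, .data$skip_acceptor)
  out <- mutate(out,
    exon_key = sprintf("%s:%d-%d", .data$chrom, .data$exon_start + 1L, .data$exon_end))
  # the same exon can recur with different flanking contexts; keep keys unique
  dup <- duplicated(out$exon_key) | duplicated(out$exon_key, fromLast = TRUE)
  if (any(dup)) {
    out$exon_key[dup] <- sprintf("%s@%d-%d", out$exon_key[dup],
                                 out$skip_donor[dup] + 1L, out$skip_acceptor[dup] + 1L)
  }
  select(out, "exon_key", dplyr::everything())
}

empty_catalog <- function() {
  tibble(exon_key = character(), gene_id = character(), chrom = character(),
         strand = character(), exon_start = integer(), exon_end = integer(),
         exon_length = integer(), up_donor = integer(), up_acceptor = integer(),
         down_donor = integer(), down_acceptor = integer(),
         skip_donor = integer(), skip_acceptor = integer())
}
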