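#' Parse a SAM CIGAR string
#'
#' @param cigar_text A single CIGAR string, or `"*"` for an unavailable
#'   alignment.
#' @return A tibble with columns `op` (one of `M I D N S H P = X`) and
#'   `len`; zero rows for `"*"`.
#' @export
#' @examples
#' parse_cigar("50M1000N74M")
parse_cigar <- function(cigar_text) {
  if (length(cigar_text) != 1L || is.na(cigar_text)) {
    abort("`cigar_text` must be a single CIGAR string.")
  }
  if (identical(cigar_text, "*")) {
    return(tibble(op = character(), len = integer()))
  }
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar_text)) {
    abort(sprintf("Not a valid CIGAR string: '%s'.", cigar_text))
  }
  len <- as.integer(regmatches(cigar_text, gregexpr("[0-9]+", cigar_text))[[1]])
  op <- regmatches(cigar_text, gregexpr("[MIDNSHP=X]", cigar_text))[[1]]
  tibble(op = op, len = len)
}

# ops classified by what they consume
REF_OPS <- c("M", "D", "N", "=", "X")   # advance the reference cursor
READ_OPS <- c("M", "I", "S", "=", "X")  # consume read bases
ALN_OPS <- c("M", "D", "=", "X")        # aligned blocks (D merged into block)

#' Reference intervals covered by an alignment
#'
#' Walks the CIGAR over the reference and returns one half-open interval
#' per maximal aligned block.  Blocks are split at every `N` (skipped
#' region / splice gap); deletions (`D`) stay inside the current block
#' because they consume reference without interrupting the alignment.
#'
#' @param pos Leftmost aligned reference position, 0-based.
#' @param cigar CIGAR string (or a tibble from [parse_cigar()]).
#' @return A tibble of `start`, `end` intervals (0-based half-open),
#'   sorted left to right.
#' @export
#' @examples
#' aligned_blocks(100, "50M200N74M")
aligned_blocks <- function(pos, cigar) {
  ops <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  if (nrow(ops) == 0) abort("Cannot compute blocks of an unmapped read.")
  cursor <- as.integer(pos)
  starts <- integer()
  ends <- integer()
  open <- FALSE
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[[i]]
    len <- ops$len[[i]]
    if (op %in% ALN_OPS) {
      if (!open) {
        starts <- c(starts, cursor)
        ends <- c(ends, cursor)
        open <- TRUE
      }
      cursor <- cursor + len
      ends[length(ends)] <- cursor
    } else if (op == "N") {
      cursor <- cursor + len
      open <- FALSE
    }
    # I, S, H, P do not advance the reference
  }
  tibble(start = starts, end = ends)
}

#' Splice junctions implied by a gapped alignment
#'
#' Every `N` operation in the CIGAR corresponds to one splice junction.
#' The junction is reported as the last aligned base before the gap
#' (`donor_end`) and the first aligned base after it (`acceptor_start`),
#' both 0-based, in genomic orientation.  `left_anchor` / `right_anchor`
#' give the reference-aligned length of the blocks flanking the gap, used
#' by the anchor filter in [count_junction_reads()].
#'
#' @inheritParams aligned_blocks
#' @return A tibble with columns `donor_end`, `acceptor_start`,
#'   `left_anchor`, `right_anchor`; zero rows for an unsplit read.
#' @export
#' @examples
#' read_junctions(100, "50M200N74M")
read_junctions <- function(pos, cigar) {
  blocks <- aligned_blocks(pos, cigar)
  n <- nrow(blocks)
  if (n < 2) {
    return(tibble(donor_end = integer(), acceptor_start = integer(),
                  left_anchor = integer(), right_anchor = integer()))
  }
  tibble(
    donor_end = blocks$end[-n] - 1L,
    acceptor_start = blocks$start[-1],
    left_anchor = blocks$end[-n] - blocks$start[-n],
    right_anchor = blocks$end[-1] - blocks$start[-1]
  )
}

#' Read a SAM file into a tidy alignment table
#'
#' Minimal text-SAM reader for junction counting: keeps primary mapped
#' alignments only (unmapped 0x4, secondary 0x100 and supplementary 0x800
#' records are skipped, so each sequenced read contributes junction
#' evidence at most once) and converts positions to the internal 0-based
#' convention.
#'
#' @param path Path to a SAM text file.
#' @param min_mapq Minimum mapping quality; the default 0 applies no
#'   filter.
#' @return A tibble with columns `read_id`, `flag`, `chrom`, `pos`
#'   (0-based), `mapq`, `cigar`, `read_length` (bases consumed by
#'   M/I/S/=/X ops).
#' @export
read_sam <- function(path, min_mapq = 0) {
  if (!file.exists(path)) abort(sprintf("SAM file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), flag = integer(), chrom = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  read_length = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- which(nf < 11)[1]
    abort(sprintf("Malformed SAM record (line body %d): %d columns, need >= 11.",
                  bad, nf[bad]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(
    read_id = col(1),
    flag = as.integer(col(2)),
    chrom = col(3),
    pos = as.integer(col(4)) - 1L,
    mapq = as.integer(col(5)),
    cigar = col(6),
    seq = col(10)
  )
  out <- filter(out,
    bitwAnd(.data$flag, 0x4L) == 0L,
    bitwAnd(.data$flag, 0x100L) == 0L,
    bitwAnd(.data$flag, 0x800L) == 0L,
    .data$mapq >= min_mapq)
  out <- mutate(out, read_length = cigar_read_length(.data$cigar))
  select(out, "read_id", "flag", "chrom", "pos", "mapq", "cigar", "read_length")
}

# vectorised read length from CIGAR (M/I/S/=/X consume read bases)
cigar_read_length <- function(cigar) {
  toks <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, toks), function(tk) {
    op <- substring(tk, nchar(tk), nchar(tk))
    sum(as.integer(substring(tk, 1, nchar(tk) - 1L))[op %in% READ_OPS])
  }, integer(1))
}

# Vectorised junction extraction over a whole alignment table: one row per
# (read, N-gap), with flanking-block anchors.  This is the workhorse behind
# count_junction_reads(); the scalar read_junctions() is its oracle-friendly
# twin and the two are cross-checked in the test suite.
alignment_junctions <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble(read_idx = integer(), chrom = character(),
                  donor_end = integer(), acceptor_start = integer(),
                  left_anchor = integer(), right_anchor = integer()))
  }
  split_reads <- which(grepl("N", reads$cigar, fixed = TRUE))
  if (length(split_reads) == 0) {
    return(tibble(read_idx = integer(), chrom = character(),
                  donor_end = integer(), acceptor_start = integer(),
                  left_anchor = integer(), right_anchor = integer()))
  }
  cigars <- reads$cigar[split_reads]
  toks <- regmatches(cigars, gregexpr("[0-9]+[MIDNSHP=X]", cigars))
  n_tok <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  long <- tibble(
    ridx = rep(split_reads, n_tok),
    op = substring(flat, nchar(flat), nchar(flat)),
    len = as.integer(substring(flat, 1, nchar(flat) - 1L))
  )
  long <- long |>
    mutate(ref_len = if_else(.data$op %in% REF_OPS, .data$len, 0L)) |>
    group_by(.data$ridx) |>
    mutate(
      ref_before = cumsum(.data$ref_len) - .data$ref_len,
      block_id = cumsum(.data$op == "N") - (.data$op == "N")
    ) |>
    ungroup()
  block_len <- long |>
    filter(.data$op %in% ALN_OPS) |>
    group_by(.data$ridx, .data$block_id) |>
    summarise(anchor = sum(.data$len), .groups = "drop")
  gaps <- long |>
    filter(.data$op == "N") |>
    mutate(gap_id = .data$block_id)
  gaps <- gaps |>
    left_join(rename(block_len, left_anchor = "anchor"),
              by = c("ridx", gap_id = "block_id")) |>
    mutate(next_block = .data$gap_id + 1L) |>
    left_join(rename(block_len, right_anchor = "anchor"),
              by = c("ridx", next_block = "block_id"))
  pos0 <- reads$pos[gaps$ridx]
  tibble(
    read_idx = gaps$ridx,
    chrom = reads$chrom[gaps$ridx],
    donor_end = pos0 + gaps$ref_before - 1L,
    acceptor_start = pos0 + gaps$ref_before + gaps$len,
    left_anchor = dplyr::coalesce(as.integer(gaps$left_anchor), 0L),
    right_anchor = dplyr::coalesce(as.integer(gaps$right_anchor), 0L)
  )
}
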