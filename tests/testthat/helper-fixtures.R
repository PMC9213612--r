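# Shared in-code fixtures: a canonical three-exon gene and small builders.

# GTF text for one gene, one transcript, exons 101-200, 301-400, 501-600
# (1-based inclusive, as on disk).
three_exon_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    'chr1\ttest\texon\t%d\t%d\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    c(101L, 301L, 501L), c(200L, 400L, 600L))
  writeLines(lines, path)
  path
}

# the same gene as an internal-coordinate exon tibble
three_exon_models <- function() {
  tibble::tibble(
    gene_id = "g1", transcript_id = "t1", chrom = "chr1",
    start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
    strand = "+", exon_id = paste0("e", 1:3), exon_length = 100L
  )
}

# one SAM file from (pos, cigar) pairs on chr1
toy_sam <- function(pos, cigar, path = tempfile(fileext = ".sam"),
                    read_length = NULL, mapq = 60, flag = 0L) {
  n <- length(pos)
  rl <- read_length
  body <- vapply(seq_len(n), function(i) {
    ops <- agesplice::parse_cigar(cigar[[i]])
    nb <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
    sprintf("r%03d\t%d\tchr1\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            i, flag, pos[[i]] + 1L, mapq, cigar[[i]], strrep("A", nb))
  }, character(1))
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000", body), path)
  path
}

# per-base reference-cursor simulation: the independent oracle for
# aligned_blocks()
blocks_by_cursor <- function(pos, cigar) {
  ops <- agesplice::parse_cigar(cigar)
  cursor <- pos
  covered <- integer()
  for (i in seq_len(nrow(ops))) {
    if (ops$op[[i]] %in% c("M", "D", "=", "X")) {
      covered <- c(covered, seq(cursor, cursor + ops$len[[i]] - 1L))
      cursor <- cursor + ops$len[[i]]
    } else if (ops$op[[i]] == "N") {
      cursor <- cursor + ops$len[[i]]
    }
  }
  runs <- split(covered, cumsum(c(1L, diff(covered) != 1L)))
  tibble::tibble(
    start = vapply(runs, min, integer(1), USE.NAMES = FALSE),
    end = vapply(runs, max, integer(1), USE.NAMES = FALSE) + 1L
  )
}

# random valid CIGAR with <= max_ops operations, always starting and
# ending with an aligned block
random_cigar <- function(max_ops = 8) {
  n_ops <- sample(1:max_ops, 1)
  ops <- character(n_ops)
  ops[1] <- "M"
  if (n_ops > 1) {
    ops[n_ops] <- "M"
    if (n_ops > 2) {
      prev <- "M"
      for (i in 2:(n_ops - 1)) {
        pool <- setdiff(c("M", "I", "D", "N", "S", "=", "X"),
                        if (prev %in% c("N", "D", "I")) prev else character())
        pool <- setdiff(pool, if (i == 2 || prev == "S") "S" else character())
        ops[i] <- sample(pool, 1)
        prev <- ops[i]
      }
    }
  }
  lens <- sample(1:60, n_ops, replace = TRUE)
  paste0(lens, ops, collapse = "")
}

# Table 1 cohort metadata (subjects of the target study design)
table1_metadata <- function() {
  tibble::tibble(
    sample_id = sprintf("CL_eto%d", 1:13),
    cohort = rep(c("young", "old"), c(6, 7)),
    age = c(4, 3, 3, 1, 1, 3, 14, 14, 17, 17, 14, 15, 14),
    sex = c(rep("Female", 11), "Male", "Male"),
    body_mass = c(20.2, 10.3, 11.2, 10.7, 20.1, 7.5,
                  29.7, 13.2, 22.0, 12.7, 25.4, 25.0, 21.5)
  )
}

sim_groups <- function(config) {
  tibble::tibble(
    sample_id = c(sprintf("young_%d", seq_len(config$n_young)),
                  sprintf("old_%d", seq_len(config$n_old))),
    cohort = rep(c("young", "old"), c(config$n_young, config$n_old))
  )
}
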