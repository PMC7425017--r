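# Shared fixtures: the eight-fragment toy layout and small builders.

toy_lengths <- c(1100L, 1300L, 1700L, 1900L, 2300L, 2900L, 3100L, 3700L)

# Eight consecutive fragments F1..F8 (0-based indices 0..7) on one chromosome.
toy_map <- function(lengths = toy_lengths, chrom = "chrT") {
  simulate_fragment_map(lengths = lengths, chrom = chrom)
}

# Build USF-shaped records from (index1, index2, score) triples.
make_records <- function(map, triples) {
  purrr::pmap_dfr(triples, function(i, j, score) {
    a <- map[map$index == min(i, j), ]
    b <- map[map$index == max(i, j), ]
    tibble::tibble(
      chrom1 = a$chrom, start1 = a$start, end1 = a$end, index1 = a$index,
      chrom2 = b$chrom, start2 = b$start, end2 = b$end, index2 = b$index,
      score = as.integer(score)
    )
  })
}

# The worked four-interaction instance: F1-F8:4, F2-F7:4, F3-F5:5, F4-F6:3
# (1-based fragment labels; indices are 0-based).
toy_records <- function(map = toy_map()) {
  make_records(map, tibble::tibble(
    i = c(0L, 1L, 2L, 3L),
    j = c(7L, 6L, 4L, 5L),
    score = c(4L, 4L, 5L, 3L)
  ))
}

# An FDR table whose gate passes every score (fp identically zero).
open_fdr_table <- function(max_score = 100L) {
  tibble::tibble(score = 0:max_score, fp = 0, tp = 1, fdr = 0, fdr_mono = 0)
}

# Simple pairs-tibble builder.
make_pairs <- function(chrom1, pos1, chrom2, pos2,
                       strand1 = "+", strand2 = "-") {
  n <- max(length(pos1), length(pos2))
  normalize_pairs(tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    chrom1 = rep_len(chrom1, n), pos1 = as.integer(rep_len(pos1, n)),
    strand1 = rep_len(strand1, n),
    chrom2 = rep_len(chrom2, n), pos2 = as.integer(rep_len(pos2, n)),
    strand2 = rep_len(strand2, n)
  ))
}

# Disjoint single-bin loop set on one or more chromosomes, far from the
# diagonal; used by evaluation tests.
make_loops <- function(n, chrom = "chrE", spacing = 1e6, width = 1000,
                       offset = 5e7) {
  s1 <- (seq_len(n) - 1) * spacing + 1e5
  s2 <- s1 + offset
  tibble::tibble(
    chrom1 = chrom, start1 = as.integer(s1), end1 = as.integer(s1 + width),
    chrom2 = chrom, start2 = as.integer(s2), end2 = as.integer(s2 + width),
    name = sprintf("loop%05d", seq_len(n)), score = 1L
  )
}
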