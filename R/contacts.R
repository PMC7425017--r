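#' Classify ligation products
#'
#' Assigns each paired-end contact to a ligation class from the positions of
#' its two ends on the restriction-fragment map: both ends in the same
#' fragment is a self-ligation (re-circularised fragment), ends in
#' immediately adjacent fragments of the same chromosome is a re-ligation
#' (the original cut re-joined), anything else — including every
#' inter-chromosomal pair — is a valid ligation. Strand-orientation
#' refinements (dangling ends) are intentionally not modelled.
#'
#' @param pairs Pairs tibble (see [read_pairs()]).
#' @param map Fragment map tibble.
#' @return The input tibble with added columns `index1`, `index2` (0-based
#'   fragment ordinals; `index2` refers to end 2's chromosome) and `class`
#'   (factor: `self_ligation`, `re_ligation`, `valid`).
#' @export
classify_pairs <- function(pairs, map) {
  f1 <- fragment_index_of(map, pairs$chrom1, pairs$pos1)
  f2 <- fragment_index_of(map, pairs$chrom2, pairs$pos2)
  same_chrom <- pairs$chrom1 == pairs$chrom2
  cls <- rep("valid", nrow(pairs))
  cls[same_chrom & f1$index == f2$index] <- "self_ligation"
  cls[same_chrom & abs(f1$index - f2$index) == 1L] <- "re_ligation"
  dplyr::mutate(
    pairs,
    index1 = f1$index, index2 = f2$index,
    class = factor(cls, levels = c("self_ligation", "re_ligation", "valid"))
  )
}

#' Remove PCR duplicates
#'
#' Collapses pairs identical in all six mapping coordinates
#' (`chrom1,pos1,strand1,chrom2,pos2,strand2`) to a single record; PCR
#' duplicates would otherwise inflate interaction scores.
#'
#' @param pairs Pairs tibble.
#' @return Deduplicated pairs tibble (first occurrence kept).
#' @export
dedup_pairs <- function(pairs) {
  dplyr::distinct(pairs, .data$chrom1, .data$pos1, .data$strand1,
                  .data$chrom2, .data$pos2, .data$strand2,
                  .keep_all = TRUE)
}

#' Build the fragment-pair interaction score table
#'
#' Tallies valid ligation pairs into one record per unordered restriction
#' fragment pair; the record's score is the number of (deduplicated) pairs
#' whose ends map to that fragment pair. By default only intra-chromosomal
#' pairs are kept, since the distance-dependent background model is undefined
#' between chromosomes.
#'
#' @param pairs Pairs tibble. If it lacks a `class` column it is classified
#'   against `map` first; only `valid`-class pairs are counted.
#' @param map Fragment map tibble.
#' @param intra_only Keep intra-chromosomal records only (default `TRUE`).
#' @param dedup Collapse PCR duplicates before counting (default `TRUE`).
#' @return A tibble of interaction records: `chrom1`, `start1`, `end1`,
#'   `index1`, `chrom2`, `start2`, `end2`, `index2`, `score`, with fragment 1
#'   not after fragment 2 in genome order.
#' @export
build_usf_table <- function(pairs, map, intra_only = TRUE, dedup = TRUE) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(
      chrom1 = character(), start1 = integer(), end1 = integer(),
      index1 = integer(), chrom2 = character(), start2 = integer(),
      end2 = integer(), index2 = integer(), score = integer()
    ))
  }
  if (dedup) pairs <- dedup_pairs(pairs)
  if (!"class" %in% names(pairs)) pairs <- classify_pairs(pairs, map)
  pairs <- pairs[pairs$class == "valid", ]
  if (intra_only) pairs <- pairs[pairs$chrom1 == pairs$chrom2, ]

  f1 <- fragment_index_of(map, pairs$chrom1, pairs$pos1)
  f2 <- fragment_index_of(map, pairs$chrom2, pairs$pos2)
  # order fragments within the pair: genome order of (chrom, start)
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom1 == pairs$chrom2 & f2$start < f1$start)
  rec <- tibble::tibble(
    chrom1 = ifelse(swap, pairs$chrom2, pairs$chrom1),
    start1 = ifelse(swap, f2$start, f1$start),
    end1   = ifelse(swap, f2$end, f1$end),
    index1 = ifelse(swap, f2$index, f1$index),
    chrom2 = ifelse(swap, pairs$chrom1, pairs$chrom2),
    start2 = ifelse(swap, f1$start, f2$start),
    end2   = ifelse(swap, f1$end, f2$end),
    index2 = ifelse(swap, f1$index, f2$index)
  )
  out <- dplyr::count(rec, dplyr::across(dplyr::everything()), name = "score")
  out <- dplyr::arrange(out, .data$chrom1, .data$start1, .data$chrom2,
                        .data$start2)
  out$score <- as.integer(out$score)
  out
}

#' Empirical ligation-distance distribution
#'
#' Computes the distribution of genomic distance between the two ends of
#' intra-chromosomal pairs: the count of pairs at each distance bin divided
#' by the total is the ligation probability. Default bins are logarithmic
#' (50 per decade), which stabilises power-law fitting across the four
#' decades a chromosome spans.
#'
#' @param pairs Pairs tibble (intra-chromosomal pairs are used; others
#'   ignored).
#' @param breaks Optional numeric vector of bin breakpoints (bp, strictly
#'   increasing). Defaults to log-spaced bins, 50 per decade, from `d_min` to
#'   the largest observed distance.
#' @param d_min Lower bound of the default binning (default 1000 bp).
#' @param bins_per_decade Bins per decade for the default binning.
#' @return A tibble `bin_start`, `bin_end`, `mid` (geometric midpoint),
#'   `width`, `count`, `prob`, with `sum(prob) == 1`.
#' @export
distance_profile <- function(pairs, breaks = NULL, d_min = 1000,
                             bins_per_decade = 50) {
  intra <- pairs[pairs$chrom1 == pairs$chrom2, ]
  if (nrow(intra) == 0L) {
    stop("No intra-chromosomal pairs; distance profile undefined",
         call. = FALSE)
  }
  d <- abs(intra$pos2 - intra$pos1)
  if (is.null(breaks)) {
    d_max <- max(max(d), d_min * 10)
    breaks <- 10^seq(log10(d_min), log10(d_max),
                     by = 1 / bins_per_decade)
    if (breaks[length(breaks)] < d_max) breaks <- c(breaks, d_max)
    breaks[length(breaks)] <- breaks[length(breaks)] + 1  # right-open top
    d <- d[d >= d_min]
    if (length(d) == 0L) {
      stop("No pairs at or beyond d_min = ", d_min, call. = FALSE)
    }
  }
  if (any(diff(breaks) <= 0)) {
    stop("`breaks` must be strictly increasing", call. = FALSE)
  }
  cut_idx <- findInterval(d, breaks, rightmost.closed = FALSE)
  in_range <- cut_idx >= 1L & cut_idx < length(breaks)
  counts <- tabulate(cut_idx[in_range], nbins = length(breaks) - 1L)
  tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1L],
    mid = sqrt(breaks[-length(breaks)] * breaks[-1L]),
    width = diff(breaks),
    count = counts,
    prob = counts / sum(counts)
  )
}

#' Reservoir-subsample read pairs
#'
#' Draws a uniform random subset of exactly `min(n, nrow(pairs))` pairs in a
#' single pass using reservoir sampling (Algorithm R): the first `n` pairs
#' fill the reservoir and each subsequent pair `i` replaces a random
#' reservoir slot with probability `n / i`. Every pair has equal inclusion
#' probability, and the draw is reproducible for a given seed. Used to
#' emulate lower sequencing depths.
#'
#' @param pairs Pairs tibble.
#' @param n Target number of pairs.
#' @param seed Integer seed for the pseudo-random number generator; `NULL`
#'   uses the current RNG state.
#' @return A tibble of the sampled pairs, in order of first appearance in
#'   the reservoir.
#' @export
subsample_pairs <- function(pairs, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  m <- nrow(pairs)
  if (n == 0L) return(pairs[0, ])
  if (n >= m) return(pairs)
  draw <- function() {
    reservoir <- seq_len(n)
    # pre-draw slot candidates for the streaming phase
    u <- stats::runif(m - n)
    for (i in (n + 1L):m) {
      j <- floor(u[i - n] * i) + 1L
      if (j <= n) reservoir[j] <- i
    }
    reservoir
  }
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pairs[idx, ]
}

#' Quality-control report for a pair set
#'
#' @param pairs Classified pairs tibble (from [classify_pairs()]).
#' @return A one-row tibble with counts `n_total`, `n_self`, `n_re`,
#'   `n_valid` and the corresponding fractions.
#' @export
qc_report <- function(pairs) {
  stopifnot("class" %in% names(pairs))
  n <- nrow(pairs)
  tab <- table(pairs$class)
  tibble::tibble(
    n_total = n,
    n_self = as.integer(tab[["self_ligation"]]),
    n_re = as.integer(tab[["re_ligation"]]),
    n_valid = as.integer(tab[["valid"]]),
    frac_self = n_self / n,
    frac_re = n_re / n,
    frac_valid = n_valid / n
  )
}
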