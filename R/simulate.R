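#' Simulate a restriction-fragment map
#'
#' Builds a single synthetic chromosome tiled by fragments whose lengths are
#' drawn from a geometric distribution with the given mean — the
#' length distribution in-silico digestion of random sequence produces
#' (6-cutters average ~4 kb on mammalian genomes, 4-cutters ~256 bp).
#' Fixed lengths can be supplied instead, e.g. to build small worked-example
#' layouts.
#'
#' @param n_fragments Number of fragments (>= 2). Ignored when `lengths` is
#'   given.
#' @param mean_length Mean fragment length in bp (default 4000, a 6-cutter).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param chrom Chromosome name.
#' @param lengths Optional integer vector of fixed fragment lengths.
#' @return A fragment map tibble (see [digest_genome()]).
#' @export
simulate_fragment_map <- function(n_fragments = 1000L, mean_length = 4000L,
                                  seed = NULL, chrom = "chrS",
                                  lengths = NULL) {
  if (is.null(lengths)) {
    stopifnot(n_fragments >= 2L)
    draw <- function() stats::rgeom(n_fragments, 1 / mean_length) + 1L
    lengths <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  ends <- cumsum(as.numeric(lengths))
  starts <- c(0, ends[-length(ends)])
  new_fragment_map(
    tibble::tibble(chrom = chrom, start = as.integer(starts),
                   end = as.integer(ends),
                   index = seq_along(lengths) - 1L),
    enzyme = "simulated", chrom_sizes = stats::setNames(
      as.integer(ends[length(ends)]), chrom)
  )
}

#' Ground truth for a simulated Hi-C library
#'
#' Chooses planted true loops (distal fragment pairs that will receive
#' proximate-ligation counts) and records every generative parameter so that
#' downstream tests can score calls against truth.
#'
#' @param map Fragment map tibble (single chromosome).
#' @param n_loops Number of planted loops.
#' @param lambda1 Background (random-ligation) Poisson mean per touched
#'   fragment pair.
#' @param lambda2 Proximate-ligation Poisson mean per planted loop.
#' @param alpha Power-law exponent of the background distance distribution.
#' @param efficiency Digestion efficiency assumed by the scenario.
#' @param n_background Number of background fragment pairs touched by the
#'   random-ligation process.
#' @param rate_self,rate_re Fractions of the read stream converted to
#'   self- and re-ligation artifacts.
#' @param min_offset Minimum fragment-index offset of planted loops (keeps
#'   them clear of the near-diagonal background regime).
#' @param d_min Short-range cut-off of the background distance draw (bp).
#' @param seed Integer seed for the loop placement.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(map, n_loops = 50L, lambda1 = 1, lambda2 = 8,
                      alpha = -1, efficiency = 0.7, n_background = 2500L,
                      rate_self = 0.05, rate_re = 0.05, min_offset = 30L,
                      d_min = 1000, seed = NULL) {
  stopifnot(lambda1 > 0, lambda2 > 0, n_loops >= 0)
  chrom <- unique(map$chrom)
  stopifnot(length(chrom) == 1L)
  n_frag <- nrow(map)
  if (n_frag <= min_offset + 1L && n_loops > 0) {
    stop("Too few fragments for the requested loop offset", call. = FALSE)
  }
  draw <- function() {
    picked <- character(0)
    loops <- tibble::tibble(index1 = integer(0), index2 = integer(0))
    while (nrow(loops) < n_loops) {
      i <- sample.int(n_frag - min_offset, 1L) - 1L
      j <- i + min_offset + sample.int(n_frag - min_offset - i, 1L) - 1L
      key <- paste(i, j)
      if (j <= n_frag - 1L && !key %in% picked) {
        picked <- c(picked, key)
        loops <- dplyr::bind_rows(loops,
                                  tibble::tibble(index1 = i, index2 = j))
      }
    }
    loops
  }
  loops <- if (n_loops == 0L) {
    tibble::tibble(index1 = integer(0), index2 = integer(0))
  } else if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  loops$chrom <- rep(chrom, nrow(loops))
  structure(
    list(loops = loops, lambda1 = lambda1, lambda2 = lambda2, alpha = alpha,
         efficiency = efficiency, n_background = as.integer(n_background),
         rate_self = rate_self, rate_re = rate_re,
         min_offset = as.integer(min_offset), d_min = d_min, seed = seed),
    class = "sim_truth"
  )
}

# inverse-CDF sample from p(d) ~ d^alpha on [a, b]
sample_power_law <- function(n, alpha, a, b) {
  u <- stats::runif(n)
  if (abs(alpha + 1) < 1e-12) {
    a * (b / a)^u
  } else {
    e <- alpha + 1
    (a^e + u * (b^e - a^e))^(1 / e)
  }
}

#' Simulate a paired-end Hi-C contact stream
#'
#' Generates reads with the statistical structure the calling model assumes:
#' each planted loop receives a Poisson(`lambda2`) number of reads placed
#' uniformly within its two fragments; background ligations touch
#' `n_background` fragment pairs — an anchor drawn uniformly along the
#' chromosome and a partner at a distance drawn from the power law
#' `p(d) ~ d^alpha` on `[d_min, chromosome span)` — each receiving a
#' Poisson(`lambda1`) number of reads (pairs drawing zero reads are
#' unobservable). A fraction of the read stream is converted to
#' self-ligation (both ends in one random fragment) and re-ligation (ends in
#' adjacent fragments) artifacts at the configured rates. The output order
#' is shuffled.
#'
#' @param map Fragment map tibble (single chromosome).
#' @param truth A [sim_truth()].
#' @param seed Integer seed; the whole stream is reproducible given the
#'   seed.
#' @return A list with `pairs` (a pairs tibble) and `truth` (the input
#'   truth, with added `observed_score` per planted loop).
#' @export
simulate_contacts <- function(map, truth, seed = NULL) {
  chrom <- unique(map$chrom)
  stopifnot(length(chrom) == 1L)
  chrom_len <- max(map$end)

  gen <- function() {
    frag_start <- map$start
    frag_end <- map$end
    upos <- function(idx) {
      # uniform position within fragment idx (0-based index)
      s <- frag_start[idx + 1L]
      e <- frag_end[idx + 1L]
      floor(stats::runif(length(idx), s, e))
    }

    # planted loops
    loop_counts <- stats::rpois(nrow(truth$loops), truth$lambda2)
    li <- rep(truth$loops$index1, loop_counts)
    lj <- rep(truth$loops$index2, loop_counts)

    # background: anchor + power-law distance -> fragment pair
    d <- sample_power_law(truth$n_background, truth$alpha, truth$d_min,
                          chrom_len - 1)
    p1 <- floor(stats::runif(truth$n_background, 0, chrom_len - d))
    p2 <- floor(p1 + d)
    bi <- fragment_index_of(map, rep(chrom, truth$n_background), p1)$index
    bj <- fragment_index_of(map, rep(chrom, truth$n_background), p2)$index
    bg_counts <- stats::rpois(truth$n_background, truth$lambda1)
    gi <- rep(bi, bg_counts)
    gj <- rep(bj, bg_counts)

    vi <- c(li, gi)
    vj <- c(lj, gj)
    pos1 <- upos(vi)
    pos2 <- upos(vj)
    n_valid <- length(vi)

    # artifact reads on top of the valid stream
    f <- truth$rate_self + truth$rate_re
    n_total <- round(n_valid / (1 - f))
    n_self <- round(n_total * truth$rate_self)
    n_re <- round(n_total * truth$rate_re)
    sf <- sample.int(nrow(map), n_self, replace = TRUE) - 1L
    s1 <- upos(sf)
    s2 <- upos(sf)
    rf <- sample.int(nrow(map) - 1L, n_re, replace = TRUE) - 1L
    r1 <- upos(rf)
    r2 <- upos(rf + 1L)

    all1 <- c(pos1, s1, r1)
    all2 <- c(pos2, s2, r2)
    n <- length(all1)
    out <- tibble::tibble(
      read_id = sprintf("read%07d", seq_len(n)),
      chrom1 = chrom, pos1 = as.integer(all1),
      strand1 = sample(c("+", "-"), n, replace = TRUE),
      chrom2 = chrom, pos2 = as.integer(all2),
      strand2 = sample(c("+", "-"), n, replace = TRUE)
    )
    out <- out[sample.int(n), ]
    normalize_pairs(out)
  }
  pairs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  # attach observed per-loop valid scores for truth-based scoring
  usf <- build_usf_table(pairs, map)
  key <- paste(usf$index1, usf$index2)
  lk <- paste(pmin(truth$loops$index1, truth$loops$index2),
              pmax(truth$loops$index1, truth$loops$index2))
  truth$loops$observed_score <- usf$score[match(lk, key)]
  truth$loops$observed_score[is.na(truth$loops$observed_score)] <- 0L
  list(pairs = pairs, truth = truth)
}

#' Simulate a complete Hi-C scenario
#'
#' Convenience wrapper bundling [simulate_fragment_map()], [sim_truth()] and
#' [simulate_contacts()] under one seed. The `"default"` preset — 1000
#' fragments of mean length 4 kb, 50 planted loops, background mean 1,
#' proximate mean 8, distance exponent -1, digestion efficiency 0.7, 2500
#' background pairs, 5% self- and 5% re-ligation artifacts — emulates a
#' fragment-level Hi-C library at modest sequencing depth.
#'
#' @param seed Integer seed driving the whole scenario.
#' @param ... Overrides passed to [sim_truth()] (e.g. `n_loops`,
#'   `lambda2`, `alpha`).
#' @param n_fragments,mean_length Fragment-map geometry.
#' @return A list `map`, `truth`, `pairs`.
#' @export
simulate_hic_scenario <- function(seed = 1L, ..., n_fragments = 1000L,
                                  mean_length = 4000L) {
  map <- simulate_fragment_map(n_fragments, mean_length, seed = seed)
  truth <- sim_truth(map, ..., seed = seed + 1L)
  sim <- simulate_contacts(map, truth, seed = seed + 2L)
  list(map = map, truth = sim$truth, pairs = sim$pairs)
}

#' Write a simulated scenario to disk
#'
#' Writes the fragment map (BED), the pair stream (pairs format) and the
#' ground truth (JSON) into a directory; every file header records the seed
#' and parameters.
#'
#' @param scenario A list from [simulate_hic_scenario()].
#' @param dir Output directory (created if needed).
#' @param seed The seed used (recorded in headers).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("seed=%s lambda1=%g lambda2=%g alpha=%g n_loops=%d",
                 ifelse(is.null(seed), "NA", seed),
                 scenario$truth$lambda1, scenario$truth$lambda2,
                 scenario$truth$alpha, nrow(scenario$truth$loops))
  write_fragment_bed(scenario$map, file.path(dir, "fragments.bed"))
  write_pairs(scenario$pairs, file.path(dir, "contacts.pairs"), header = hdr)
  truth <- scenario$truth
  jsonlite::write_json(
    list(loops = truth$loops, lambda1 = truth$lambda1,
         lambda2 = truth$lambda2, alpha = truth$alpha,
         efficiency = truth$efficiency, n_background = truth$n_background,
         rate_self = truth$rate_self, rate_re = truth$rate_re,
         seed = seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
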