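#' Fit a power-law decay to the ligation-distance distribution
#'
#' Background (random) ligation probability decays with genomic distance
#' approximately as a power law, `p(d) ~ d^alpha`. The exponent is estimated
#' by least squares on the log-log relationship between per-bp ligation
#' density and distance: each bin's probability is divided by its width in
#' bp before taking logs, so the estimate is invariant to the binning scheme
#' (with logarithmic bins the raw per-bin probability would instead have
#' slope `alpha + 1`).
#'
#' @param profile A distance profile from [distance_profile()] (columns
#'   `mid`, `width`, `prob`; bins with zero probability are skipped).
#' @param d_min,d_max Distance range (bp) over which to fit; defaults to the
#'   full profile range.
#' @return An object of class `power_law_fit`: a list with `alpha` (the
#'   exponent), `intercept` (log10 density at d = 1), `d_min`, `d_max`,
#'   `n_bins`, `r_squared` and `residuals` (a tibble of the fitted bins).
#' @export
fit_power_law <- function(profile, d_min = NULL, d_max = NULL) {
  if (is.null(d_min)) d_min <- min(profile$bin_start)
  if (is.null(d_max)) d_max <- max(profile$bin_end)
  stopifnot(d_min < d_max)
  use <- profile$prob > 0 & profile$mid >= d_min & profile$mid <= d_max
  if (sum(use) < 3L) {
    stop("Need at least 3 non-empty bins inside [d_min, d_max]",
         call. = FALSE)
  }
  sub <- profile[use, ]
  x <- log10(sub$mid)
  y <- log10(sub$prob / sub$width)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(
      alpha = unname(co[2]),
      intercept = unname(co[1]),
      d_min = d_min, d_max = d_max, n_bins = sum(use),
      r_squared = r2,
      residuals = tibble::tibble(mid = sub$mid, log10_density = y,
                                 fitted = unname(stats::fitted(fit)),
                                 residual = unname(stats::resid(fit)))
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law background: alpha = %.4f (intercept %.4f, R^2 %.3f)\n",
    x$alpha, x$intercept, x$r_squared))
  cat(sprintf("  fitted over [%g, %g] bp, %d bins\n",
              x$d_min, x$d_max, x$n_bins))
  invisible(x)
}

#' Background ligation probability at a genomic distance
#'
#' Evaluates the fitted power law `10^intercept * d^alpha`, clamped to
#' `[0, 1]`. Distances below the fitted range are evaluated at `d_min`
#' (a short-range plateau, mirroring the flattening of contact probability
#' below the fragment scale).
#'
#' @param d Genomic distance(s) in bp, all positive.
#' @param params A `power_law_fit`.
#' @return Probability vector the same length as `d`.
#' @export
ligation_probability <- function(d, params) {
  if (any(d <= 0)) stop("Distances must be positive", call. = FALSE)
  d_eff <- pmax(d, params$d_min)
  p <- 10^(params$intercept + params$alpha * log10(d_eff))
  pmin(pmax(p, 0), 1)
}

#' Background configuration for the digestion-efficiency filter
#'
#' @param efficiency Digestion efficiency E in `[0, 1]`: the probability
#'   that a restriction site was actually cut. Runs of undigested sites make
#'   near-diagonal ligation artifacts likely. Default 0.7.
#' @param k_neighbors Neighbourhood half-width K (fragments on each side of
#'   the second anchor). Default 5.
#' @param threshold Likelihood threshold above which a record is flagged
#'   background; `"auto"` uses the 99th percentile of the likelihood over
#'   records at fragment offset > 20 (a distal set where linear-closeness
#'   artifacts are absent).
#' @return A list of class `background_config`.
#' @export
background_config <- function(efficiency = 0.7, k_neighbors = 5L,
                              threshold = "auto") {
  stopifnot(efficiency >= 0, efficiency <= 1, k_neighbors >= 0)
  structure(list(efficiency = efficiency,
                 k_neighbors = as.integer(k_neighbors),
                 threshold = threshold),
            class = "background_config")
}

#' Likelihood that a fragment pair is a background ligation
#'
#' For an intra-chromosomal record (F_i, F_j), the background likelihood is
#' the product over the K digested fragments on each side of F_j (excluding
#' F_j itself, truncated at chromosome ends) of
#' `(1 - E)^|k - j| * P(F_i, F_j)`, where E is the digestion efficiency and
#' `P(F_i, F_j)` the power-law ligation probability evaluated at the
#' fragment-midpoint distance. Undigested neighbour runs (probability
#' `(1 - E)^offset`) make short-range ligations likely under the background
#' model, so near-diagonal artifact records score a high likelihood. The
#' window is applied around the second anchor only, so the value is not
#' symmetric in the two anchors.
#'
#' @param records USF record tibble (see [build_usf_table()]),
#'   intra-chromosomal.
#' @param map Fragment map tibble.
#' @param config A [background_config()].
#' @param params A `power_law_fit`.
#' @return Numeric likelihood vector, one value per record.
#' @export
interaction_likelihood <- function(records, map, config, params) {
  if (any(records$chrom1 != records$chrom2)) {
    stop("Background likelihood is defined for intra-chromosomal records only",
         call. = FALSE)
  }
  if (nrow(records) == 0L) return(numeric(0))
  K <- config$k_neighbors
  E <- config$efficiency

  mid1 <- (records$start1 + records$end1) / 2
  mid2 <- (records$start2 + records$end2) / 2
  p_ij <- ligation_probability(pmax(abs(mid2 - mid1), 1), params)

  # number of neighbours actually available within K on each side of F_j
  n_frag <- tapply(map$index, map$chrom, function(i) max(i) + 1L)
  nf <- as.integer(n_frag[records$chrom2])
  j <- records$index2
  left <- pmin(K, j)                    # neighbours j-1 ... j-left
  right <- pmin(K, nf - 1L - j)         # neighbours j+1 ... j+right
  n_neighbors <- left + right
  # sum of |k - j| over the truncated window
  off_sum <- left * (left + 1) / 2 + right * (right + 1) / 2

  if (E == 1) {
    lik <- ifelse(n_neighbors > 0, 0, 1)
  } else {
    lik <- (1 - E)^off_sum * p_ij^n_neighbors
  }
  lik[n_neighbors == 0] <- 1  # empty product
  lik
}

#' Filter background ligations by likelihood
#'
#' Annotates each record with its background likelihood and removes records
#' whose likelihood exceeds the configured threshold — linear-closeness
#' artifacts sit at short range where the power law and undigested-neighbour
#' terms make the background model confident.
#'
#' @param records Intra-chromosomal USF record tibble.
#' @param map Fragment map tibble.
#' @param config A [background_config()]; `threshold = "auto"` derives the
#'   cut-off from the 99th percentile of the likelihood among records at
#'   fragment offset > 20.
#' @param params A `power_law_fit`.
#' @return A list with `retained` and `removed` record tibbles (both carry a
#'   `bg_likelihood` column), the `threshold` used, and counts `n_retained`,
#'   `n_removed`.
#' @export
filter_background <- function(records, map, config, params) {
  lik <- interaction_likelihood(records, map, config, params)
  records$bg_likelihood <- lik
  threshold <- config$threshold
  if (identical(threshold, "auto")) {
    distal <- abs(records$index2 - records$index1) > 20
    threshold <- if (any(distal)) {
      stats::quantile(lik[distal], 0.99, names = FALSE)
    } else {
      Inf
    }
  }
  keep <- lik <= threshold
  list(
    retained = records[keep, ],
    removed = records[!keep, ],
    threshold = threshold,
    n_retained = sum(keep),
    n_removed = sum(!keep)
  )
}

#' Estimate digestion efficiency (diagnostic)
#'
#' A crude diagnostic estimator: the fraction of read ends falling within
#' `window` bp of a restriction cut site. Provided for inspection only — the
#' filter takes E as a user parameter.
#'
#' @param pairs Pairs tibble.
#' @param map Fragment map tibble.
#' @param window Distance to a fragment boundary (bp) counting as "at a cut
#'   site".
#' @return Estimated efficiency in `[0, 1]`.
#' @export
estimate_digestion_efficiency <- function(pairs, map, window = 500L) {
  ends <- tibble::tibble(
    chrom = c(pairs$chrom1, pairs$chrom2),
    pos = c(pairs$pos1, pairs$pos2)
  )
  f <- fragment_index_of(map, ends$chrom, ends$pos)
  near <- (ends$pos - f$start) <= window | (f$end - ends$pos) <= window
  mean(near)
}
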