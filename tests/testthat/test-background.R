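# Build a profile directly from equal-width point-like bins around given
# distances, with probabilities proportional to p.
point_profile <- function(d, p, half_width = 0.5) {
  tibble::tibble(
    bin_start = d - half_width, bin_end = d + half_width,
    mid = d, width = 2 * half_width,
    count = NA_integer_, prob = p / sum(p)
  )
}

test_that("log-log regression recovers exact and flat power laws", {
  d <- c(1e3, 1e4, 1e5)
  fit <- fit_power_law(point_profile(d, d^-1))
  expect_equal(fit$alpha, -1, tolerance = 1e-9)

  flat <- fit_power_law(point_profile(c(1e3, 1e4, 1e5, 1e6), rep(1, 4)))
  expect_equal(flat$alpha, 0, tolerance = 1e-9)

  expect_error(fit_power_law(point_profile(c(1e3, 1e4), c(1, 1))),
               "at least 3")
})

test_that("the exponent is recovered from sampled distances", {
  set.seed(31)
  d <- rpowerlaw(1e5, -1.08, 1e3, 1e6)
  pairs <- make_pairs("chrS", 0L, "chrS", as.integer(round(d)))
  prof <- distance_profile(pairs, d_min = 1000)
  fit <- fit_power_law(prof, d_min = 1000, d_max = 1e6)
  expect_lt(abs(fit$alpha - (-1.08)), 0.05)
})

test_that("ligation probability scales, plateaus and stays monotone", {
  # alpha = -1 with p(1e4) = 1e-3  =>  intercept = 1
  params <- structure(list(alpha = -1, intercept = 1, d_min = 1e3,
                           d_max = 1e6), class = "power_law_fit")
  expect_equal(ligation_probability(1e4, params), 1e-3)
  expect_equal(ligation_probability(1e5, params), 1e-4)
  # below d_min: plateau at the d_min value
  expect_equal(ligation_probability(10, params),
               ligation_probability(1e3, params))
  expect_error(ligation_probability(0, params), "positive")

  set.seed(32)
  d <- sort(runif(1000, 1, 1e7))
  p <- ligation_probability(d, params)
  expect_true(all(diff(p) <= 1e-15))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("background likelihood follows the digestion-efficiency product", {
  map <- simulate_fragment_map(lengths = rep(1000L, 60), chrom = "chrS")
  params <- structure(list(alpha = -1, intercept = 1, d_min = 1e2,
                           d_max = 1e6), class = "power_law_fit")

  rec <- make_records(map, tibble::tibble(i = 10L, j = 30L, score = 5L))

  # K = 0: empty product
  expect_equal(
    interaction_likelihood(rec, map, background_config(0.5, 0), params), 1)

  # E = 1 with neighbours: any neighbour term is zero
  expect_equal(
    interaction_likelihood(rec, map, background_config(1, 2), params), 0)

  # E = 0.5, K = 1, engineered P = 0.01: [(0.5)^1 * 0.01]^2 = 2.5e-5
  d_mid <- abs((rec$start2 + rec$end2) / 2 - (rec$start1 + rec$end1) / 2)
  params2 <- params
  params2$intercept <- log10(0.01) + log10(d_mid)  # p(d_mid) = 0.01
  expect_equal(
    interaction_likelihood(rec, map, background_config(0.5, 1), params2),
    2.5e-5, tolerance = 1e-12)

  # window truncation at the chromosome end uses fewer neighbours
  edge <- make_records(map, tibble::tibble(i = 10L, j = 59L, score = 2L))
  lik_edge <- interaction_likelihood(edge, map, background_config(0.5, 3),
                                     params2)
  # only 3 left neighbours exist: (1-E)^(1+2+3) * P^3
  p_edge <- ligation_probability(
    abs((edge$start2 + edge$end2) / 2 - (edge$start1 + edge$end1) / 2),
    params2)
  expect_equal(lik_edge, 0.5^6 * p_edge^3, tolerance = 1e-12)

  # the window sits around the second anchor only: swapping anchors can
  # change the value when truncation differs (documented asymmetry)
  sw <- tibble::tibble(
    chrom1 = edge$chrom2, start1 = edge$start2, end1 = edge$end2,
    index1 = edge$index2,
    chrom2 = edge$chrom1, start2 = edge$start1, end2 = edge$end1,
    index2 = edge$index1, score = edge$score
  )
  lik_sw <- interaction_likelihood(sw, map, background_config(0.5, 3),
                                   params2)
  expect_gt(lik_edge / lik_sw, 1e3)

  expect_error(
    interaction_likelihood(dplyr::mutate(rec, chrom2 = "chrZ"), map,
                           background_config(0.5, 1), params),
    "intra-chromosomal")
})

test_that("background filtering removes the high-likelihood near-diagonal set", {
  map <- simulate_fragment_map(lengths = rep(1000L, 200), chrom = "chrS")
  params <- structure(list(alpha = -1.2, intercept = 0, d_min = 5e2,
                           d_max = 1e6), class = "power_law_fit")
  cfg <- background_config(0.7, 3, threshold = Inf)

  near <- make_records(map, tibble::tibble(i = c(20L, 50L, 80L),
                                           j = c(22L, 53L, 81L),
                                           score = 1L))
  far <- make_records(map, tibble::tibble(i = c(10L, 30L, 60L),
                                          j = c(110L, 150L, 190L),
                                          score = 1L))
  recs <- dplyr::bind_rows(near, far)
  lik <- interaction_likelihood(recs, map, cfg, params)
  expect_gt(min(lik[1:3]) / max(lik[4:6]), 100)  # constructed separation

  # threshold = Inf keeps everything; threshold = 0 removes everything
  keep_all <- filter_background(recs, map, cfg, params)
  expect_equal(keep_all$n_removed, 0L)
  cfg0 <- background_config(0.7, 3, threshold = 0)
  drop_all <- filter_background(recs, map, cfg0, params)
  expect_equal(drop_all$n_retained, 0L)

  # an intermediate threshold removes exactly the near-diagonal subset
  thr <- sqrt(min(lik[1:3]) * max(lik[4:6]))
  cfg_mid <- background_config(0.7, 3, threshold = thr)
  mid <- filter_background(recs, map, cfg_mid, params)
  expect_equal(sort(mid$removed$index1), sort(near$index1))
  expect_equal(mid$n_removed + mid$n_retained, nrow(recs))
})
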