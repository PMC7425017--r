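test_that("simulated fragment maps tile, reproduce and match the mean", {
  m1 <- simulate_fragment_map(500, 4000, seed = 71)
  m2 <- simulate_fragment_map(500, 4000, seed = 71)
  expect_identical(m1, m2)
  expect_equal(m1$start[-1], m1$end[-nrow(m1)])  # tiling

  big <- simulate_fragment_map(10000, 4000, seed = 72)
  expect_lt(abs(mean(big$end - big$start) - 4000) / 4000, 0.05)

  toy <- toy_map()
  expect_equal(toy$end - toy$start, toy_lengths)
  expect_equal(toy$index, 0:7)
})

test_that("contact streams are reproducible and carry the configured rates", {
  map <- simulate_fragment_map(800, 4000, seed = 73)
  truth <- sim_truth(map, n_loops = 30, n_background = 2000, seed = 74)
  s1 <- simulate_contacts(map, truth, seed = 75)
  s2 <- simulate_contacts(map, truth, seed = 75)
  expect_identical(s1$pairs, s2$pairs)

  cls <- classify_pairs(s1$pairs, map)
  n <- nrow(cls)
  frac_self <- mean(cls$class == "self_ligation")
  frac_re <- mean(cls$class == "re_ligation")
  # artifacts at the configured rates, plus background ligations that land
  # in the same or adjacent fragments by chance, so the observed fractions
  # bound the configured rates from above
  se <- sqrt(0.05 * 0.95 / n)
  expect_gt(frac_self, 0.05 - 3 * se)
  expect_gt(frac_re, 0.05 - 3 * se)
  expect_lt(frac_self, 0.20)
  expect_lt(frac_re, 0.20)
})

test_that("generated distances reproduce the configured decay exponent", {
  map <- simulate_fragment_map(4000, 4000, seed = 76)
  truth <- sim_truth(map, n_loops = 0, n_background = 1e5,
                     lambda1 = 1, alpha = -1, rate_self = 0, rate_re = 0,
                     seed = 77)
  sim <- simulate_contacts(map, truth, seed = 78)
  prof <- distance_profile(sim$pairs, d_min = 1000)
  fit <- fit_power_law(prof, d_min = 2000, d_max = 5e6)
  expect_lt(abs(fit$alpha - (-1)), 0.05)
})

test_that("scores from the default scenario are bimodal and recoverable", {
  sc <- simulate_hic_scenario(seed = 79)
  usf <- build_usf_table(sc$pairs, sc$map)
  fit <- em_fit(usf$score)
  # the proximate mean is recovered near the planted value
  expect_lt(abs(fit$lambda[2] - 8), 1.6)
  # the random-ligation estimand is the zero-truncated mean of Poisson(1):
  # lambda / (1 - exp(-lambda)) = 1.582, not 1 (zero-score pairs are
  # unobservable); allow the misspecification pull towards the loop tail
  ztp_mean <- 1 / (1 - exp(-1))
  expect_lt(abs(fit$lambda[1] - ztp_mean), 0.35)
  expect_gt(fit$weights[2], 0.01)

  # with no planted loops and flat-ish decay, BIC sees one component or, at
  # worst, a marginal second component absorbing the truncation shape
  map <- simulate_fragment_map(1000, 4000, seed = 80)
  t0 <- sim_truth(map, n_loops = 0, n_background = 2500, seed = 81)
  s0 <- simulate_contacts(map, t0, seed = 82)
  u0 <- build_usf_table(s0$pairs, map)
  sel <- select_components(u0$score)
  f0 <- em_fit(u0$score)
  expect_true(sel$preferred[sel$k == 1] ||
                f0$lambda[2] - f0$lambda[1] < 2)
})

test_that("truth objects validate and record observed loop scores", {
  map <- simulate_fragment_map(100, 4000, seed = 83)
  expect_error(sim_truth(map, n_loops = 5, min_offset = 99), "Too few")
  truth <- sim_truth(map, n_loops = 10, n_background = 200, seed = 84)
  expect_true(all(truth$loops$index2 - truth$loops$index1 >= 30))
  sim <- simulate_contacts(map, truth, seed = 85)
  expect_true(all(sim$truth$loops$observed_score >= 0))
  expect_gt(mean(sim$truth$loops$observed_score), 4)
})

test_that("scenario files round-trip through the standard formats", {
  sc <- simulate_hic_scenario(seed = 86, n_fragments = 200,
                              n_loops = 10, n_background = 300)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir, seed = 86)
  map2 <- read_fragment_bed(file.path(dir, "fragments.bed"))
  expect_equal(map2$start, sc$map$start)
  pairs2 <- read_pairs(file.path(dir, "contacts.pairs"))
  expect_equal(nrow(pairs2), nrow(sc$pairs))
  expect_equal(sort(pairs2$pos1), sort(sc$pairs$pos1))
  truth2 <- jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  expect_equal(truth2$lambda2, sc$truth$lambda2)
  expect_equal(nrow(truth2$loops), nrow(sc$truth$loops))
})
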