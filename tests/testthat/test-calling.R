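test_that("the resampled null reproduces the observed score distribution", {
  expect_error(empirical_null(integer(0)), "zero records")

  null <- empirical_null(rep(4L, 50), np = 1000, seed = 1)
  expect_equal(null$fp[null$score == 4], 1)
  expect_equal(sum(null$fp), 1)

  one <- empirical_null(c(2L, 5L, 9L), np = 1, seed = 2)
  expect_equal(sum(one$fp), 1)
  expect_equal(sum(one$fp == 1), 1L)  # indicator at a single observed score

  # binomial oracle: density at score 1 for a 9:1 multiset
  scores <- c(rep(1L, 900), rep(8L, 100))
  np <- 50000
  null2 <- empirical_null(scores, np = np, seed = 3)
  se <- sqrt(0.9 * 0.1 / np)
  expect_lt(abs(null2$fp[null2$score == 1] - 0.9), 3 * se)
})

test_that("the true-positive density is the proximate Poisson pmf", {
  fit <- structure(list(weights = c(0.9, 0.1), lambda = c(1, 8), k = 2L),
                   class = "pmm_fit")
  tp <- tp_density(fit)
  expect_equal(tp$tp[tp$score == 8], exp(-8) * 8^8 / factorial(8),
               tolerance = 1e-12)
  expect_equal(sum(tp$tp), 1, tolerance = 1e-4)
  # Poisson mode tie at lambda integer: pmf equal at 7 and 8
  expect_equal(tp$tp[tp$score == 7], tp$tp[tp$score == 8], tolerance = 1e-12)

  bad <- structure(list(weights = c(0.5, 0.5), lambda = c(3, 3), k = 2L),
                   class = "pmm_fit")
  expect_error(tp_density(bad), "indistinct")
})

test_that("local FDR follows FP / (FP + TP)", {
  expect_equal(local_fdr(0, 0.2), 0)
  expect_equal(local_fdr(0.1, 0.1), 0.5)
  expect_equal(local_fdr(0.03, 0.12), 0.2)
  expect_true(is.na(local_fdr(0, 0)))
  expect_error(local_fdr(-0.1, 0.2), "non-negative")
})

test_that("the applied FDR is monotone and inherits the tail value", {
  set.seed(41)
  scores <- c(rpois(2000, 1) + 1L, rpois(60, 9))
  fit <- em_fit(scores)
  tab <- build_fdr_table(scores, fit, np = 5e4, seed = 5)
  mono <- tab$fdr_mono[!is.na(tab$fdr_mono)]
  expect_true(all(diff(mono) <= 1e-15))
  expect_true(all(tab$fdr >= tab$fdr_mono, na.rm = TRUE))
  # scores above the support inherit the last defined value
  expect_equal(sifcall:::fdr_at_score(tab, max(tab$score) + 50),
               mono[length(mono)])
})

test_that("the worked eight-fragment instance is called and merged", {
  map <- toy_map()
  recs <- toy_records(map)
  gate <- open_fdr_table()

  called <- call_sifs(recs, gate, ftr = 3, fdr_threshold = 0.1)
  # F4-F6 (score 3) is discarded at FTR 3; the other three are retained
  expect_equal(nrow(called), 3L)
  expect_false(any(purrr::map_lgl(called$frags1, ~ 3L %in% .x)))

  merged <- merge_equal_score(called, map)
  expect_equal(nrow(merged), 2L)
  L <- toy_lengths
  # F1-F8 and F2-F7 (both score 4) merge: resolutions L1+L2 and L7+L8
  m1 <- merged[purrr::map_lgl(merged$frags1, ~ setequal(.x, c(0L, 1L))), ]
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$res1, L[1] + L[2])
  expect_equal(m1$res2, L[7] + L[8])
  expect_equal(m1$score, 4L)
  # F3-F5 (score 5) stays alone: resolutions L3 and L5
  m2 <- merged[purrr::map_lgl(merged$frags1, ~ setequal(.x, 2L)), ]
  expect_equal(m2$res1, L[3])
  expect_equal(m2$res2, L[5])

  # FTR = Inf retains nothing
  expect_equal(nrow(call_sifs(recs, gate, ftr = Inf)), 0L)
})

test_that("the double filter matches brute-force enumeration", {
  map <- simulate_fragment_map(lengths = rep(1500L, 400), chrom = "chrS")
  set.seed(42)
  n <- 1000
  recs <- make_records(map, tibble::tibble(
    i = sample(0:380, n, replace = TRUE)
  ) |>
    dplyr::mutate(j = i + sample(2:19, n, replace = TRUE),
                  score = rpois(n, 3) + 1L) |>
    dplyr::distinct(i, j, .keep_all = TRUE))

  fdr_vals <- setNames(runif(30), 0:29)
  tab <- tibble::tibble(score = 0:29, fp = 0.1, tp = 0.1,
                        fdr = unname(fdr_vals), fdr_mono = unname(fdr_vals))
  ftr <- 3
  cut <- 0.4
  called <- call_sifs(recs, tab, ftr = ftr, fdr_threshold = cut)

  # oracle: exhaustive row-by-row filtering
  keep <- vapply(seq_len(nrow(recs)), function(r) {
    s <- recs$score[r]
    s > ftr && fdr_vals[[as.character(s)]] < cut
  }, logical(1))
  expect_equal(nrow(called), sum(keep))
  expect_equal(sort(called$score), sort(recs$score[keep]))
  # conservation
  expect_equal(sum(keep) + sum(!keep), nrow(recs))
})

test_that("merging is transitive and leaves non-adjacent calls alone", {
  map <- simulate_fragment_map(lengths = rep(1000L, 40), chrom = "chrS")
  gate <- open_fdr_table()

  # a chain of three equal-score calls merges into one
  chain <- make_records(map, tibble::tibble(
    i = c(5L, 6L, 7L), j = c(30L, 29L, 28L), score = 6L))
  sifs <- call_sifs(chain, gate, ftr = 1)
  merged <- merge_equal_score(sifs, map)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$frags1[[1]], c(5L, 6L, 7L))
  expect_equal(merged$res1, 3000L)
  expect_equal(merged$score, 6L)

  # equal scores but non-adjacent anchors stay separate
  apart <- make_records(map, tibble::tibble(
    i = c(2L, 10L), j = c(25L, 35L), score = 4L))
  sifs2 <- call_sifs(apart, gate, ftr = 1)
  expect_equal(nrow(merge_equal_score(sifs2, map)), 2L)

  # adjacent anchors with different scores stay separate
  diff_score <- make_records(map, tibble::tibble(
    i = c(5L, 6L), j = c(30L, 29L), score = c(4L, 5L)))
  sifs3 <- call_sifs(diff_score, gate, ftr = 1)
  expect_equal(nrow(merge_equal_score(sifs3, map)), 2L)

  # merging preserves distinct fragment-pair coverage
  cov_before <- unlist(purrr::map2(sifs$frags1, sifs$frags2,
                                   ~ paste(.x, .y)))
  merged_cov <- tidyr::expand_grid(a = merged$frags1[[1]],
                                   b = merged$frags2[[1]])
  expect_true(all(cov_before %in% paste(merged_cov$a, merged_cov$b)))
})
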