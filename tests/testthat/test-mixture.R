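test_that("identical scores give the degenerate tie with kept weights", {
  fit <- em_fit(rep(4L, 20))
  expect_true(fit$degenerate)
  expect_true(fit$converged)
  expect_equal(fit$lambda, c(4, 4))
  expect_equal(fit$weights, c(0.9, 0.1))  # init weights retained
})

test_that("scores are validated", {
  expect_error(em_fit(c(3L)), "at least 2")
  expect_error(em_fit(c(0L, 0L, 0L)), "zero")
  expect_error(em_fit(c(1.5, 2)), "integers")
  expect_error(em_fit(c(-1L, 2L)), "non-negative")
})

test_that("EM recovers generative parameters on a 9:1 Poisson mixture", {
  set.seed(101)
  d <- c(rpois(9000, 1), rpois(1000, 8))
  fit <- em_fit(d)
  expect_true(fit$converged)
  # 3 Monte-Carlo standard errors (asymptotic scale at n = 10,000)
  expect_lt(abs(fit$lambda[1] - 1), 0.1)
  expect_lt(abs(fit$lambda[2] - 8), 0.35)
  expect_lt(abs(fit$weights[2] - 0.1), 0.02)
})

test_that("EM attains the grid-search optimum on small instances", {
  scores <- c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 8L, 9L, 10L)
  fit <- em_fit(scores, tol = 1e-12)
  # coarse grid to bracket the basin, then a direct Nelder-Mead polish of
  # the likelihood itself (EM-free)
  g <- grid_max_loglik(scores, omega2_step = 0.02, lambda_step = 0.05)
  expect_gte(fit$loglik, g$loglik - 1e-6)
  polished <- polish_loglik(scores, g$omega2, g$lambda1, g$lambda2)
  expect_lt(abs(fit$loglik - polished), 1e-6)
})

test_that("EM invariants hold across random instances", {
  set.seed(102)
  for (rep in 1:10) {
    d <- c(rpois(300, runif(1, 0.5, 2)), rpois(60, runif(1, 6, 12)))
    if (all(d == 0)) next
    fit <- em_fit(d, tol = 1e-10)
    # monotone log-likelihood, to numerical noise
    expect_true(all(diff(fit$trace) > -1e-8))
    # weight conservation after every M-step
    expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
    # fixed point: lambda_k equals the responsibility-weighted mean of D
    r <- fit$responsibilities
    expect_equal(fit$lambda[1], sum(r[, 1] * d) / sum(r[, 1]),
                 tolerance = 1e-6)
    expect_equal(fit$lambda[2], sum(r[, 2] * d) / sum(r[, 2]),
                 tolerance = 1e-6)
    # responsibilities are a proper posterior
    expect_true(all(abs(rowSums(r) - 1) < 1e-12))
    # label order
    expect_lte(fit$lambda[1], fit$lambda[2])
  }
})

test_that("BIC separates one- and two-component data", {
  set.seed(103)
  uni <- rpois(10000, 3)
  sel <- select_components(uni)
  expect_true(sel$preferred[sel$k == 1])

  bim <- c(rpois(5000, 1), rpois(5000, 20))
  sel2 <- select_components(bim)
  expect_true(sel2$preferred[sel2$k == 2])

  # N = 1: the sample-size term vanishes
  expect_equal(bic_mixture(list(loglik = -2.5, k = 1L, n = 1L)), 5)
})

test_that("bootstrap trims inner-fence outliers and matches single fit on
           constant data", {
  fit <- bootstrap_fit(rep(7L, 30), n_boot = 10, seed = 1)
  expect_equal(fit$lambda, c(7, 7))
  expect_equal(fit$weights, em_fit(rep(7L, 30))$weights)

  # inner fences: one absurd estimate among sane ones leaves the trimmed
  # mean unchanged; the untrimmed mean shifts
  x <- c(rep(c(7.9, 8.0, 8.1), 16), 8.05, 1e6)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  keep <- x >= q[1] - 1.5 * (q[2] - q[1]) & x <= q[2] + 1.5 * (q[2] - q[1])
  expect_false(keep[length(x)])
  expect_equal(signif(mean(x[keep]), 3), signif(mean(x[-length(x)]), 3))
  expect_gt(mean(x), 100)
})

test_that("bootstrap aggregation reduces estimator variance", {
  set.seed(104)
  lam2_single <- numeric(12)
  lam2_boot <- numeric(12)
  for (s in seq_len(12)) {
    d <- c(rpois(700, 1), rpois(80, 8))
    lam2_single[s] <- em_fit(d)$lambda[2]
    lam2_boot[s] <- bootstrap_fit(d, n_boot = 40, seed = s)$lambda[2]
  }
  expect_lt(var(lam2_boot), var(lam2_single) * 1.5)
  expect_lt(abs(mean(lam2_boot) - mean(lam2_single)), 0.5)
})

test_that("tidy, glance and JSON serialisation expose the fit", {
  set.seed(105)
  d <- c(rpois(900, 1), rpois(100, 8))
  fit <- em_fit(d)
  td <- tidy(fit)
  expect_equal(td$component, c("random", "proximate"))
  expect_equal(td$lambda, fit$lambda)
  gl <- glance(fit)
  expect_equal(gl$loglik, fit$loglik)
  expect_equal(gl$bic, bic_mixture(fit))

  path <- withr::local_tempfile(fileext = ".json")
  write_mixture_json(fit, path)
  back <- read_mixture_json(path)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$weights, fit$weights)
})
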