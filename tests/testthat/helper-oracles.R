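# Independent oracles kept free of the implementation paths they check.

# Dense grid search maximising the two-component Poisson mixture
# log-likelihood directly (no EM). Returns the grid maximum and its argmax.
grid_max_loglik <- function(scores, omega2_step = 0.01, lambda_step = 0.01,
                            lambda1_max = 4, lambda2_range = c(4, 12)) {
  tab <- table(scores)
  d <- as.integer(names(tab))
  m <- as.numeric(tab)
  omega2 <- seq(0.01, 0.99, by = omega2_step)
  lam1 <- seq(lambda_step, lambda1_max, by = lambda_step)
  lam2 <- seq(lambda2_range[1], lambda2_range[2], by = lambda_step)
  G1 <- outer(lam1, d, function(l, x) dpois(x, l))   # |lam1| x |d|
  G2 <- outer(lam2, d, function(l, x) dpois(x, l))
  best <- -Inf
  arg <- c(NA, NA, NA)
  for (w2 in omega2) {
    w1 <- 1 - w2
    A <- w1 * G1
    for (j in seq_along(lam2)) {
      mix <- A + matrix(w2 * G2[j, ], nrow = nrow(A), ncol = ncol(A),
                        byrow = TRUE)
      ll <- as.vector(log(mix) %*% m)
      i <- which.max(ll)
      if (ll[i] > best) {
        best <- ll[i]
        arg <- c(w2, lam1[i], lam2[j])
      }
    }
  }
  list(loglik = best, omega2 = arg[1], lambda1 = arg[2], lambda2 = arg[3])
}

# Nelder-Mead polish of the mixture log-likelihood from a starting point, on
# unconstrained scales (logit weight, log means).
polish_loglik <- function(scores, omega2, lambda1, lambda2) {
  obj <- function(par) {
    w2 <- stats::plogis(par[1])
    l1 <- exp(par[2])
    l2 <- exp(par[3])
    -mixture_loglik(scores, c(1 - w2, w2), c(l1, l2))
  }
  fit <- stats::optim(c(stats::qlogis(omega2), log(lambda1), log(lambda2)),
                      obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  -fit$value
}

# Brute-force interval membership: which fragment row contains pos?
scan_fragment <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, ]
  hit <- which(sub$start <= pos & pos < sub$end)
  stopifnot(length(hit) == 1L)
  sub[hit, ]
}

# Literal motif occurrences by exhaustive scan (overlaps allowed), 0-based.
scan_motif <- function(sequence, motif) {
  n <- nchar(sequence)
  k <- nchar(motif)
  if (n < k) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (substr(sequence, i, i + k - 1L) == motif) starts <- c(starts, i - 1L)
  }
  starts
}

# Power-law distance sampler (inverse CDF), independent of the package's.
rpowerlaw <- function(n, alpha, a, b) {
  u <- stats::runif(n)
  if (abs(alpha + 1) < 1e-12) return(a * (b / a)^u)
  e <- alpha + 1
  (a^e + u * (b^e - a^e))^(1 / e)
}
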