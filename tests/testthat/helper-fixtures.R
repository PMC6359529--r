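# Shared fixtures: controlled-conditioning random SPD matrices and small
# labeled trial sets built in code.

# random SPD with eigenvalues in [lo, hi] (keeps congruence/round-trip checks
# away from ill-conditioned corners the tolerances do not cover)
random_spd <- function(n, lo = 0.5, hi = 2) {
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  lam <- runif(n, lo, hi)
  (Q %*% (lam * t(Q)) + t(Q %*% (lam * t(Q)))) / 2
}

# random symmetric matrix with entries of scale s
random_sym <- function(n, s = 1) {
  S <- matrix(rnorm(n * n, sd = s), n)
  (S + t(S)) / 2
}

# random invertible matrix with moderate conditioning
random_invertible <- function(n) {
  A <- matrix(rnorm(n * n), n)
  A + diag(n) * (0.5 + sqrt(n))
}

# tiny two-class trial set: class 2 has boosted variance on the first
# channel, so even a 2-channel CSP separates it
toy_trials <- function(n_per_class = 10, n_ch = 4, n_samp = 50, boost = 3,
                       sfreq = 100) {
  n <- 2 * n_per_class
  labels <- rep(c(1L, 2L), n_per_class)
  data <- array(rnorm(n * n_ch * n_samp), dim = c(n, n_ch, n_samp))
  for (i in which(labels == 2L)) data[i, 1, ] <- data[i, 1, ] * boost
  trial_set(data, labels = labels, sfreq = sfreq)
}

expect_spd <- function(C, tol = 1e-10) {
  expect_true(is.matrix(C))
  expect_lt(max(abs(C - t(C))), tol * max(abs(C), 1))
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
}
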