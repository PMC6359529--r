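test_that("Gaussian adjacency matches its closed form", {
  m <- electrode_montage(c("a", "b"), rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(gaussian_adjacency(m, 0.5)[1, 2], 1)

  r <- 0.3
  m2 <- electrode_montage(c("a", "b"),
                          rbind(c(0, 0, 0), c(r * sqrt(2 * log(2)), 0, 0)))
  expect_equal(gaussian_adjacency(m2, r)[1, 2], 0.5, tolerance = 1e-12)

  set.seed(31)
  mr <- make_montage(10)
  G <- gaussian_adjacency(mr, 0.4)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(G[i, j],
                 exp(-sum((mr$coords[i, ] - mr$coords[j, ])^2) / (2 * 0.4^2)),
                 tolerance = 1e-12)
  }
  expect_true(all(diag(G) == 1))
  expect_error(gaussian_adjacency(mr, 0), "positive")
})

test_that("Laplacian penalty has zero row sums, is PSD, and matches the double sum", {
  set.seed(32)
  G2 <- matrix(c(1, 0.7, 0.7, 1), 2)
  K2 <- laplacian_penalty(G2)
  expect_equal(unclass(K2), matrix(c(0.7, -0.7, -0.7, 0.7), 2),
               ignore_attr = TRUE)

  w1 <- rep(1, 6)
  for (rep in 1:20) {
    m <- make_montage(6)
    G <- gaussian_adjacency(m, runif(1, 0.1, 1))
    K <- laplacian_penalty(G)
    expect_lt(max(abs(rowSums(K))), 1e-10)
    expect_equal(drop(t(w1) %*% K %*% w1), 0, tolerance = 1e-10)
    w <- rnorm(6)
    brute <- sum(outer(w, w, `-`)^2 * G) / 2
    expect_lt(abs(drop(t(w) %*% K %*% w) - brute), 1e-10 * (1 + brute))
  }
  expect_error(laplacian_penalty(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("penalty is PSD on random montages and has the right r limits", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    K <- spatial_penalty(make_montage(n), runif(1, 0.05, 2))
    ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  m <- make_montage(8)
  # r -> 0: G -> I, K -> 0
  expect_lt(max(abs(unclass(spatial_penalty(m, 1e-4)))), 1e-12)
  # r -> Inf: G -> all-ones, K -> N I - J (complete-graph Laplacian)
  Kinf <- unclass(spatial_penalty(m, 1e4))
  expect_lt(max(abs(Kinf - (8 * diag(8) - matrix(1, 8, 8)))), 1e-4)
})

test_that("CSP solves the generalized eigenproblem", {
  fb <- csp_filters(diag(c(4, 1)), diag(c(1, 4)), k = 1)
  expect_equal(abs(fb$W[1, ]), c(1, 0), tolerance = 1e-12)
  expect_equal(abs(fb$W[2, ]), c(0, 1), tolerance = 1e-12)
  expect_equal(fb$eigenvalues, c(4, 0.25), tolerance = 1e-12)

  # degenerate case: deterministic output
  C <- random_spd(4)
  f1 <- csp_filters(C, C, k = 2)
  f2 <- csp_filters(C, C, k = 2)
  expect_identical(f1$W, f2$W)
  expect_equal(f1$eigenvalues, rep(1, 4), tolerance = 1e-10)

  set.seed(34)
  for (rep in 1:10) {
    C1 <- random_spd(6); C2 <- random_spd(6)
    fb <- csp_filters(C1, C2, k = 2)
    expect_equal(nrow(fb$W), 4)
    for (i in 1:4) {
      w <- fb$W[i, ]
      expect_lt(max(abs(C1 %*% w - fb$eigenvalues[i] * C2 %*% w)), 1e-8)
      expect_equal(sum(w^2), 1, tolerance = 1e-12)
    }
  }
  expect_error(csp_filters(random_spd(4), random_spd(4), k = 3), "2k <= N")
})

test_that("SRCSP with alpha = 0 spans the CSP filters", {
  set.seed(35)
  principal_angle_max <- function(W1, W2) {
    q1 <- qr.Q(qr(t(W1))); q2 <- qr.Q(qr(t(W2)))
    s <- svd(t(q1) %*% q2)$d
    max(acos(pmin(1, s)))
  }
  for (rep in 1:10) {
    C1 <- random_spd(8); C2 <- random_spd(8)
    K <- spatial_penalty(make_montage(8), 0.3)
    fb0 <- srcsp_filters(C1, C2, K, alpha = 0, k = 2)
    fb_csp <- csp_filters(C1, C2, k = 2)
    expect_lt(principal_angle_max(fb0$W, fb_csp$W), 1e-6)
  }
})

test_that("SRCSP filters satisfy the penalized eigen-residual", {
  set.seed(36)
  for (rep in 1:10) {
    C1 <- random_spd(8); C2 <- random_spd(8)
    K <- unclass(spatial_penalty(make_montage(8), 0.3))
    alpha <- 10^runif(1, -4, 0)
    fb <- srcsp_filters(C1, C2, K, alpha = alpha, k = 2)
    for (i in 1:2) {   # M1 block
      w <- fb$W[i, ]; lam <- fb$eigenvalues[i]
      expect_lt(max(abs(C1 %*% w - lam * (C2 + alpha * K) %*% w)), 1e-8)
    }
    for (i in 3:4) {   # M2 block
      w <- fb$W[i, ]; lam <- fb$eigenvalues[i]
      expect_lt(max(abs(C2 %*% w - lam * (C1 + alpha * K) %*% w)), 1e-8)
    }
  }
})

test_that("large alpha drives the leading filter toward the smoothest direction", {
  set.seed(37)
  m <- make_montage(6)
  # complete-graph-like penalty, full rank on the orthocomplement of 1
  K <- spatial_penalty(m, 10)
  C1 <- random_spd(6); C2 <- random_spd(6)
  fb <- srcsp_filters(C1, C2, K, alpha = 1e6, k = 1)
  w <- fb$W[1, ]
  cosine <- abs(sum(w * rep(1 / sqrt(6), 6)))
  expect_gt(cosine, 0.99)
})

test_that("the leading SRCSP filter maximizes the penalized Rayleigh quotient", {
  set.seed(38)
  C1 <- random_spd(6); C2 <- random_spd(6)
  K <- unclass(spatial_penalty(make_montage(6), 0.3))
  alpha <- 0.05
  fb <- srcsp_filters(C1, C2, K, alpha = alpha, k = 1)
  J <- function(w) drop(t(w) %*% C1 %*% w) /
    drop(t(w) %*% C2 %*% w + alpha * t(w) %*% K %*% w)
  best <- J(fb$W[1, ])
  for (rep in 1:1000) {
    w <- rnorm(6); w <- w / sqrt(sum(w^2))
    expect_lte(J(w), best + 1e-10)
  }
})

test_that("identical inputs give identical filter banks", {
  set.seed(39)
  C1 <- random_spd(10); C2 <- random_spd(10)
  K <- spatial_penalty(make_montage(10), 0.2)
  f1 <- srcsp_filters(C1, C2, K, alpha = 0.01, k = 3)
  f2 <- srcsp_filters(C1, C2, K, alpha = 0.01, k = 3)
  expect_identical(f1$W, f2$W)
})

test_that("apply_filters projects trials and carries labels through", {
  set.seed(40)
  ts <- toy_trials(n_per_class = 3, n_ch = 4, n_samp = 20)
  fb <- csp_filters(class_covariance(ts, 1L), class_covariance(ts, 2L), k = 2)
  X <- trial_matrix(ts, 1)
  expect_equal(apply_filters(fb, X), fb$W %*% X)
  zt <- apply_filters(fb, ts)
  expect_equal(dim(zt$data), c(6L, 4L, 20L))
  expect_identical(zt$labels, ts$labels)
  expect_equal(matrix(zt$data[2, , ], 4), fb$W %*% trial_matrix(ts, 2))
  expect_error(apply_filters(fb, matrix(0, 3, 10)), "channels")

  # identity-row bank selects channels
  fb$W <- diag(4)[1:2, ]
  expect_equal(apply_filters(fb, X), X[1:2, ])
})
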