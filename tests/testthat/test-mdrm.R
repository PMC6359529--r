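test_that("MDRM means reduce to the trials in degenerate cases", {
  set.seed(61)
  C1 <- random_spd(3); C2 <- random_spd(3)
  m <- fit_mdrm(list(C1, C2), c(1L, 2L))
  expect_equal(m$class_means[["1"]], (C1 + t(C1)) / 2, tolerance = 1e-10)
  expect_equal(m$class_means[["2"]], (C2 + t(C2)) / 2, tolerance = 1e-10)

  # duplicating the whole training set leaves the means unchanged
  covs <- lapply(1:6, function(i) random_spd(3))
  labs <- rep(c(1L, 2L), 3)
  m1 <- fit_mdrm(covs, labs)
  m2 <- fit_mdrm(c(covs, covs), c(labs, labs))
  expect_equal(m1$class_means, m2$class_means, tolerance = 1e-7)
  expect_error(fit_mdrm(covs, rep(1L, 6)), "2 classes")
})

test_that("MDRM recovers known class centers from noisy SPD samples", {
  set.seed(62)
  n <- 4
  centers <- list(`1` = random_spd(n, lo = 0.8, hi = 1.2),
                  `2` = random_spd(n, lo = 1.5, hi = 2.5))
  draw <- function(center) {
    # tangent-space Gaussian perturbation around the center
    exp_map(center, random_sym(n, 0.05))
  }
  covs <- c(lapply(1:200, function(i) draw(centers[["1"]])),
            lapply(1:200, function(i) draw(centers[["2"]])))
  labs <- rep(c(1L, 2L), each = 200)
  m <- fit_mdrm(covs, labs)
  expect_lt(riemannian_distance(m$class_means[["1"]], centers[["1"]]), 0.1)
  expect_lt(riemannian_distance(m$class_means[["2"]], centers[["2"]]), 0.1)
})

test_that("prediction takes the nearest mean, with deterministic tie-breaking", {
  set.seed(63)
  covs <- lapply(1:10, function(i) random_spd(3))
  labs <- rep(c(1L, 2L), 5)
  m <- fit_mdrm(covs, labs)
  p <- predict_mdrm(m, m$class_means[["2"]])
  expect_equal(p$labels, 2L)
  expect_equal(p$distances[1, "2"], 0, tolerance = 1e-7, ignore_attr = TRUE)

  # brute-force argmin oracle
  tests <- lapply(1:20, function(i) random_spd(3))
  p <- predict_mdrm(m, tests)
  for (i in 1:20) {
    d <- sapply(m$class_means, function(M) riemannian_distance(tests[[i]], M))
    expect_equal(p$labels[i], m$classes[which.min(d)])
    expect_equal(p$distances[i, ], d, tolerance = 1e-10, ignore_attr = TRUE)
  }

  # exact tie: both class means identical
  mt <- m
  mt$class_means[["2"]] <- mt$class_means[["1"]]
  expect_warning(pt <- predict_mdrm(mt, random_spd(3)), "equidistant")
  expect_equal(pt$labels, 1L)
  expect_error(predict_mdrm(m, random_spd(4)), "dimension")
})

test_that("predictions are invariant under a common congruence transform", {
  set.seed(64)
  covs <- lapply(1:20, function(i) random_spd(4))
  labs <- rep(c(1L, 2L), 10)
  tests <- lapply(1:15, function(i) random_spd(4))
  A <- random_invertible(4)
  tr <- function(C) t(A) %*% C %*% A
  p0 <- predict_mdrm(fit_mdrm(covs, labs), tests)
  pA <- predict_mdrm(fit_mdrm(lapply(covs, tr), labs), lapply(tests, tr))
  expect_identical(p0$labels, pA$labels)
})

test_that("fitted means and predictions ignore trial order", {
  set.seed(65)
  covs <- lapply(1:12, function(i) random_spd(3))
  labs <- rep(c(1L, 2L), 6)
  perm <- sample(12)
  m1 <- fit_mdrm(covs, labs)
  m2 <- fit_mdrm(covs[perm], labs[perm])
  expect_equal(m1$class_means[["1"]], m2$class_means[["1"]], tolerance = 1e-8)
  expect_equal(m1$class_means[["2"]], m2$class_means[["2"]], tolerance = 1e-8)
  tests <- lapply(1:10, function(i) random_spd(3))
  expect_identical(predict_mdrm(m1, tests)$labels, predict_mdrm(m2, tests)$labels)
})

test_that("accuracy and kappa match the confusion-count formulas", {
  # all correct, balanced
  ev <- evaluate_predictions(rep(c(1, 2), each = 25), rep(c(1, 2), each = 25))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  expect_equal(unname(ev$counts), c(25, 25, 0, 0))

  # coin flip on balanced labels: a=b=25, c=d=25
  truth <- rep(c(1, 2), each = 50)
  pred <- c(rep(c(1, 2), 25), rep(c(1, 2), 25))
  ev <- evaluate_predictions(pred, truth)
  expect_equal(unname(ev$counts), c(25, 25, 25, 25))
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$kappa, 0)

  # hand-computed example: a=40, b=30, c=10, d=20
  truth <- c(rep(1, 60), rep(2, 40))
  pred <- c(rep(1, 40), rep(2, 20), rep(1, 10), rep(2, 30))
  ev <- evaluate_predictions(pred, truth, positive_class = 1)
  expect_equal(unname(ev$counts), c(40, 30, 10, 20))
  expect_equal(ev$accuracy, 0.7)
  expect_equal(ev$random_accuracy, 0.5)
  expect_equal(ev$kappa, 0.4)

  # degenerate single-outcome case: kappa undefined
  ev <- evaluate_predictions(rep(1, 10), rep(1, 10))
  expect_true(is.na(ev$kappa))
})

test_that("evaluation is invariant to the positive-class designation", {
  set.seed(66)
  truth <- sample(1:2, 80, replace = TRUE)
  pred <- ifelse(runif(80) < 0.8, truth, 3 - truth)
  e1 <- evaluate_predictions(pred, truth, positive_class = 1)
  e2 <- evaluate_predictions(pred, truth, positive_class = 2)
  expect_equal(e1$accuracy, e2$accuracy)
  expect_equal(e1$kappa, e2$kappa)
})
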