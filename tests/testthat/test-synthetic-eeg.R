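test_that("Fibonacci montages are distinct, unit-radius and quasi-uniform", {
  m2 <- make_montage(2)
  expect_equal(unname(sqrt(rowSums(m2$coords^2))), c(1, 1), tolerance = 1e-12)
  expect_gt(sum((m2$coords[1, ] - m2$coords[2, ])^2), 0)
  expect_error(make_montage(1), "at least 2")

  for (n in c(10, 22, 60, 118)) {
    m <- make_montage(n)
    expect_true(all(m$coords[, 3] > 0))                 # upper hemisphere
    D <- as.matrix(dist(m$coords))
    diag(D) <- Inf
    expect_true(all(apply(D, 1, min) > 0))
    nn <- apply(D, 1, min)
    expect_lt(sd(nn) / mean(nn), 0.5)                   # quasi-uniformity
  }
})

test_that("simulation is reproducible and has the requested shape", {
  spec <- simulation_spec(n_channels = 12, sampling_rate = 100,
                          n_trials_per_class = 4, seed = 99)
  s1 <- simulate_trials(spec)
  s2 <- simulate_trials(spec)
  expect_identical(s1$trials$data, s2$trials$data)
  expect_identical(s1$trials$labels, s2$trials$labels)
  expect_equal(dim(s1$trials$data), c(8L, 12L, 300L))
  expect_equal(sort(unique(s1$trials$labels)), c(1L, 2L))
  expect_equal(sum(s1$trials$labels == 1L), 4)

  s3 <- simulate_trials(simulation_spec(n_channels = 12, sampling_rate = 100,
                                        n_trials_per_class = 4, seed = 100))
  expect_false(identical(s1$trials$data, s3$trials$data))
})

test_that("generated trials are band-limited to 7-30 Hz before sensor noise", {
  spec <- simulation_spec(n_channels = 8, sampling_rate = 250,
                          n_trials_per_class = 5, noise_power = 0, seed = 7)
  sim <- simulate_trials(spec)
  band_frac <- function(v, fs) {
    sp <- Mod(fft(v - mean(v)))^2
    f <- (seq_along(v) - 1) / length(v) * fs
    half <- f <= fs / 2
    inband <- half & f >= 7 & f <= 30
    sum(sp[inband]) / sum(sp[half])
  }
  fracs <- apply(sim$trials$data, c(1, 2), band_frac, fs = 250)
  expect_gt(min(fracs), 0.9)   # out-of-band power < 10% of total
})

test_that("the planted class difference lies along the discriminative patterns", {
  spec <- simulation_spec(n_channels = 16, sampling_rate = 100,
                          n_trials_per_class = 60, n_sources = 4,
                          n_discriminative = 1, class_variance_ratio = 100,
                          noise_power = 0, trial_length = 4, seed = 5)
  sim <- simulate_trials(spec)
  ts <- sim$trials
  D <- class_covariance(ts, 1L) - class_covariance(ts, 2L)
  u <- eigen(D, symmetric = TRUE)$vectors[, 1]
  a <- sim$truth$mixing[, sim$truth$discriminative]
  a <- a / sqrt(sum(a^2))
  expect_gte(abs(sum(u * a)), 0.95)
})

test_that("ratio 1 gives distributionally identical classes (chance accuracy)", {
  spec <- simulation_spec(n_channels = 10, sampling_rate = 100,
                          n_trials_per_class = 60, class_variance_ratio = 1,
                          seed = 11)
  sim <- simulate_trials(spec)
  cfg <- pipeline_config(k = 2)
  pp <- preprocess(sim$trials, cfg)
  tr <- subset_trials(pp, 1:40)
  te <- subset_trials(pp, 41:120)
  fp <- fit_srmdrm(tr, sim$montage, alpha = 1e-3, r = 0.1, cfg)
  acc <- evaluate_predictions(predict_srmdrm(fp, te)$labels, te$labels)$accuracy
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

test_that("dataset presets reproduce the benchmark shapes", {
  p <- dataset_preset("iva")
  expect_equal(p$n_channels, 118L)
  expect_equal(p$sampling_rate, 100)
  expect_equal(p$train_trials, 28L)   # subject ay
  expect_equal(p$test_trials, 252L)

  p <- dataset_preset("iva", subject = "aa")
  expect_equal(c(p$train_trials, p$test_trials), c(168L, 112L))

  p <- dataset_preset("iiia")
  expect_equal(p$n_channels, 60L)
  expect_equal(p$sampling_rate, 250)

  p <- dataset_preset("iia", subject = "A03")
  expect_equal(p$n_channels, 22L)
  expect_equal(p$sampling_rate, 250)
  expect_equal(c(p$train_trials, p$test_trials), c(144L, 144L))

  expect_error(dataset_preset("nope"), "iva")
  expect_error(dataset_preset("iva", subject = "zz"), "ay")
})

test_that("simulate_split returns the preset's train/test sizes, stratified", {
  spec <- dataset_preset("iiia", subject = "k6b", seed = 3,
                         n_channels = 12)    # scaled-down channel count
  sp <- simulate_split(spec)
  expect_equal(n_trials(sp$train), 60)
  expect_equal(n_trials(sp$test), 60)
  expect_equal(unname(table(sp$train$labels)), c(30L, 30L), ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$labels)), c(30L, 30L), ignore_attr = TRUE)
})

test_that("downstream accuracy is non-decreasing in the class variance ratio", {
  cfg <- pipeline_config(k = 2)
  mean_acc <- sapply(c(1, 2, 4, 8), function(ratio) {
    accs <- sapply(1:20, function(rep) {
      spec <- simulation_spec(n_channels = 10, sampling_rate = 100,
                              n_trials_per_class = 25,
                              class_variance_ratio = ratio,
                              noise_power = 0.3, seed = 1000 + rep)
      sim <- simulate_trials(spec)
      pp <- preprocess(sim$trials, cfg)
      tr <- subset_trials(pp, 1:30)
      te <- subset_trials(pp, 31:50)
      fp <- fit_srmdrm(tr, sim$montage, alpha = 1e-3, r = 0.1, cfg)
      evaluate_predictions(predict_srmdrm(fp, te)$labels, te$labels)$accuracy
    })
    mean(accs)
  })
  # monotone up to small simulation noise on 20-replicate means
  expect_true(all(diff(mean_acc) > -0.05))
  expect_gt(mean_acc[4], mean_acc[1])
})
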