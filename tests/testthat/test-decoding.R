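# small fixture: 12 states, 18 sensors, 6 epochs/state
make_epochs <- function(noise_sd = 0.5, seed = 1, epochs_per_state = 6,
                        time_ms = seq(0, 300, by = 50)) {
  generate_sensor_epochs(n_states = 12, n_sensors = 18,
                         epochs_per_state = epochs_per_state,
                         time_ms = time_ms, latency_ms = 200,
                         noise_sd = noise_sd, amplitude = 3, seed = seed)
}

test_that("noiseless separable patterns decode perfectly; permuted labels at chance", {
  ep <- make_epochs(noise_sd = 0)
  cl <- train_state_classifiers(ep, latency_ms = 200,
                                penalty_grid = 10^seq(-3, 0, length.out = 4),
                                n_folds = 3, seed = 2)
  expect_equal(max(cl$cv_accuracy$accuracy), 1)
  expect_equal(length(unique(ep$labels)), 12)
  # permuted labels: chance = 1/12
  set.seed(3)
  ep_perm <- ep
  ep_perm$labels <- sample(ep$labels)
  cl_perm <- train_state_classifiers(ep_perm, latency_ms = 200,
                                     penalty_grid = c(0.05, 0.5),
                                     n_folds = 3, seed = 4)
  expect_lt(max(cl_perm$cv_accuracy$accuracy), 1 / 12 + 0.12)
})

test_that("training validates inputs: absent classes, orthogonality, latency", {
  ep <- make_epochs(seed = 5)
  ep_missing <- ep
  keep <- ep$labels != 3
  ep_missing$data <- ep$data[keep, , ]
  ep_missing$labels <- ep$labels[keep]
  expect_error(train_state_classifiers(ep_missing, 200),
               class = "replaykit_data_error")
  expect_error(generate_sensor_epochs(n_states = 12, n_sensors = 6),
               class = "replaykit_config_error")
  expect_error(train_state_classifiers(ep, latency_ms = 123),
               class = "replaykit_config_error")
})

test_that("stronger penalties never increase the number of nonzero weights", {
  ep <- make_epochs(noise_sd = 1, seed = 6)
  X <- ep$data[, , which(ep$time_ms == 200)]
  grid <- 10^seq(-3, 0.5, length.out = 6)
  nz <- vapply(grid, function(lam) {
    m <- replaykit:::fit_ovr(X, ep$labels, 1:12, lam)
    sum(m$weights != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("applied classifiers give per-time probabilities with correct argmax", {
  ep <- make_epochs(noise_sd = 0.3, seed = 7)
  cl <- train_state_classifiers(ep, 200, penalty_grid = c(0.01, 0.1),
                                n_folds = 3, seed = 8)
  # window whose columns are training exemplars of known states
  idx <- vapply(1:12, function(k) which(ep$labels == k)[1], integer(1))
  win <- t(ep$data[idx, , which(ep$time_ms == 200)]) # sensor x time(=state)
  rm <- apply_classifiers(cl, win)
  expect_equal(dim(rm), c(12, 12))
  expect_true(all(rm >= 0 & rm <= 1))
  expect_equal(unname(apply(rm, 1, which.max)), 1:12)
  # zero input reproduces the intercept-implied base rates
  rm0 <- apply_classifiers(cl, matrix(0, 18, 5))
  expect_equal(rm0[1, ], plogis(cl$intercepts), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(apply_classifiers(cl, matrix(0, 5, 5)),
               class = "replaykit_data_error")
})

test_that("temporal generalization localizes a single-latency pattern", {
  ep <- make_epochs(noise_sd = 0.5, seed = 9)
  tg <- temporal_generalization(ep, latencies_ms = c(0, 100, 200, 300),
                                penalty = 0.01, n_folds = 3, seed = 10)
  m <- unclass(tg)
  expect_equal(dim(m), c(4, 4))
  expect_gt(m["200", "200"], 0.8)
  off <- m[rownames(m) != "200", colnames(m) != "200"]
  expect_lt(max(off), 0.25) # chance-level away from the expressed latency
})

test_that("reactivation permutation test separates signal from noise windows", {
  ep <- make_epochs(noise_sd = 0.3, seed = 11)
  # windows expressing true state patterns on alternating samples
  sig <- lapply(1:8, function(i) {
    w <- matrix(rnorm(18 * 10, sd = 0.3), 18, 10)
    w[, seq(1, 9, 2)] <- w[, seq(1, 9, 2)] + ep$patterns[, i]
    w
  })
  res <- reactivation_significance(ep, sig, latency_ms = 200,
                                   penalty = 0.01, n_perms = 100, seed = 12)
  expect_lt(res$p, 0.05)
  expect_equal(res$resolution, 1 / 101)
  expect_warning(
    reactivation_significance(ep, sig, latency_ms = 200, penalty = 0.01,
                              n_perms = 20, seed = 13),
    "resolution")
})
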