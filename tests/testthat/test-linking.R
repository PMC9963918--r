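make_fitted_cohort <- function(n = 4, seed = 900) {
  ds <- sim_cohort(n, w = 1, seed = seed, beta = 2)
  fit <- fit_model(ds, "mb", n_starts = 5, seed = seed + 1)
  list(ds = ds, fit = fit,
       table = build_regressor_table(ds, fit))
}

test_that("the regressor table aligns covariates and reproduces the rarity recurrence", {
  co <- make_fitted_cohort(2)
  tab <- co$table
  expect_equal(nrow(tab), nrow(co$ds))
  # first trial of each world: start-state indicators undefined
  firsts <- dplyr::group_by(co$ds, participant, world)
  firsts <- dplyr::slice_min(firsts, trial, n = 1)
  key <- paste(tab$participant, tab$trial)
  expect_true(all(is.na(tab$different_start[key %in%
                                              paste(firsts$participant,
                                                    firsts$trial)])))
  # rarity column equals the independent closed form
  d1 <- co$ds[co$ds$participant == 1, ]
  for (t in c(3, 50, 144)) {
    ind_other <- as.integer(d1$world[1:t] != d1$world[t])
    expect_equal(tab$rarity_other[tab$participant == 1 & tab$trial == t],
                 1 - rarity_closed_form(ind_other, rate = 0.10),
                 tolerance = 1e-12)
  }
  expect_true(all(tab$rarity_other >= 0 & tab$rarity_other <= 1))
  expect_true(all(tab$mean_value >= 0 & tab$mean_value <= 9))
  # alternating worlds: other world always seen on the previous trial
  alt <- tibble::tibble(participant = 1, trial = 1:20, block = 1,
                        world = rep(1:2, 10),
                        start_state = rep(c(1, 3), 10),
                        choice = 1, path = rep(c(1, 3), 10), reward = 5,
                        stakes = 1, rt = 0.5)
  fit_alt <- fit_model(alt, "mb", n_starts = 5, seed = 3)
  tab_alt <- build_regressor_table(alt, fit_alt)
  expect_true(all(tab_alt$other_not_recent[-1] == 0))
})

test_that("linking regression recovers a coupled injection and rejects an uncoupled one", {
  co <- make_fitted_cohort(4, seed = 950)
  tab <- co$table
  tab$different_start[is.na(tab$different_start)] <- 0L
  plan <- dplyr::mutate(tab, amplitude = 0.3 + 1.5 * different_start)
  inj <- replay_injection(lag_ms = 70, direction = "forward",
                          events_per_trial = 2, fidelity = 0.7)
  re <- simulate_cohort_reactivation(plan, default_spec, inj,
                                     target = "current", seed = 955)
  sc <- trialwise_sequenceness(re, default_spec, 70, subset = "current")
  res <- suppressMessages(
    link_glm(sc, co$table, c("different_start", "rarity_other"),
             direction = "fwd", tost_terms = "rarity_other"))
  tabres <- res$table
  ds_row <- tabres[tabres$term == "different_start", ]
  expect_gt(ds_row$estimate, 0)
  expect_lt(ds_row$p_value, 0.01)
  # the uncoupled regressor's coefficient is null and TOST-supported
  ro_row <- tabres[tabres$term == "rarity_other", ]
  expect_gt(ro_row$p_value, 0.05)
  # other-world scores are blind to the current-world injection
  sc_oth <- trialwise_sequenceness(re, default_spec, 70, subset = "other")
  res_oth <- suppressMessages(
    link_glm(sc_oth, co$table, "different_start", direction = "fwd"))
  expect_gt(res_oth$table$p_value[2], 0.05)
})

test_that("constant regressors are dropped with a message", {
  co <- make_fitted_cohort(2, seed = 990)
  sc <- tibble::tibble(participant = co$table$participant,
                       trial = co$table$trial,
                       fwd = rnorm(nrow(co$table)), bwd = 0)
  tab <- dplyr::mutate(co$table, constant_reg = 1)
  expect_message(
    res <- link_glm(sc, tab, c("reward", "constant_reg"), direction = "fwd"),
    "constant")
  expect_false("constant_reg" %in% res$table$term)
})

test_that("lag profiles have one row per lag and localize a coupled effect", {
  co <- make_fitted_cohort(4, seed = 1100)
  tab <- co$table
  tab$different_start[is.na(tab$different_start)] <- 0L
  plan <- dplyr::mutate(tab, amplitude = 0.3 + 1.5 * different_start)
  inj <- replay_injection(lag_ms = 70, direction = "forward",
                          events_per_trial = 2, fidelity = 0.8)
  re <- simulate_cohort_reactivation(plan, default_spec, inj,
                                     target = "current", seed = 1105)
  lags <- seq(10, 130, 10)
  sc <- dplyr::bind_rows(lapply(lags, function(lg)
    trialwise_sequenceness(re, default_spec, lg, subset = "current")))
  prof <- suppressMessages(lag_profile(sc, co$table, "different_start",
                                       direction = "fwd"))
  expect_equal(nrow(prof), 13)
  expect_equal(prof$lag_ms[which.max(prof$estimate)], 70)
})

test_that("across-participant correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(across_participant_correlation(x, x)$r, 1)
  expect_equal(across_participant_correlation(x, -x)$r, -1)
  degen <- across_participant_correlation(x, rep(1, 4))
  expect_true(degen$flagged)
  expect_true(is.na(degen$r))
  expect_error(across_participant_correlation(1:2, 1:2),
               class = "replaykit_data_error")
  # sampling behavior: mean r over replicates near the generating rho
  set.seed(12)
  rho <- -0.5
  rs <- vapply(1:1000, function(i) {
    a <- rnorm(24)
    b <- rho * a + sqrt(1 - rho^2) * rnorm(24)
    across_participant_correlation(a, b)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("dissociation z test matches normal-theory values", {
  eq <- dissociation_test(0.4, 0.1, 0.4, 0.1)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 0.5)
  se <- sqrt(0.1^2 + 0.1^2)
  d <- dissociation_test(0.4 + 1.96 * se, 0.1, 0.4, 0.1)
  expect_equal(d$p, 0.025, tolerance = 0.001)
  a <- dissociation_test(0.7, 0.1, 0.4, 0.2)
  b <- dissociation_test(0.4, 0.2, 0.7, 0.1)
  expect_equal(a$z, -b$z)
  expect_error(dissociation_test(1, 0, 1, 1), class = "replaykit_param_error")
})

test_that("replay split labels attach to the following world-change trial", {
  co <- make_fitted_cohort(2, seed = 1200)
  sc <- tibble::tibble(participant = co$table$participant,
                       trial = co$table$trial,
                       fwd = 0, bwd = rnorm(nrow(co$table)))
  labs <- replay_split_labels(sc, co$table)
  # labels land on world-change trials only
  d <- derive_trial_covariates(co$ds)
  key <- paste(d$participant, d$trial)
  expect_true(all(d$world_change[match(paste(labs$participant, labs$trial),
                                       key)] == 1L))
  # balanced within participant up to one trial
  cnt <- table(labs$participant, labs$replay_label)
  expect_true(all(abs(cnt[, "high"] - cnt[, "low"]) <= 1))
  # degenerate all-equal scores are flagged
  sc0 <- dplyr::mutate(sc, bwd = 1)
  expect_message(replay_split_labels(sc0, co$table), "Degenerate")
})
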