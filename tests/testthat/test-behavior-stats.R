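test_that("trial covariates reference the previous same-world trial", {
  raw <- tibble::tibble(
    participant = 1, trial = 1:5, block = 1,
    world = c(1, 2, 1, 2, 2), start_state = c(1, 3, 2, 3, 4),
    choice = c(1, 1, 1, 2, 2), path = c(1, 3, 1, 4, 4),
    reward = c(8, 2, 5, 7, 3), stakes = 1, rt = 0.6)
  d <- derive_trial_covariates(raw)
  expect_true(all(is.na(d$stay[1:2])))            # first trial of each world
  expect_equal(d$stay[3], 1L)                      # same path as trial 1
  expect_equal(d$same_start[3], 0L)                # start 2 vs start 1
  expect_equal(d$prev_reward[3], 8)                # trial 1's reward, not 2's
  expect_equal(d$stay[5], 1L)
  expect_equal(d$same_start[5], 0L)
  expect_equal(d$world_change[2], 1L)
  expect_equal(d$world_change_next[1], 1L)
  raw_bad <- raw
  raw_bad$world[2] <- NA
  expect_error(derive_trial_covariates(raw_bad),
               class = "replaykit_data_error")
})

test_that("the number of defined stay trials is trials minus worlds", {
  ds <- sim_cohort(1, w = 1, seed = 70)
  d <- derive_trial_covariates(ds)
  expect_equal(sum(!is.na(d$stay)), 144 - 2)
})

test_that("stay GLM detects the model-free signature and its absence", {
  # model-free agents: reward transfers only within the same start state
  d0 <- derive_trial_covariates(sim_cohort(10, w = 0, seed = 80, beta = 2))
  g0 <- suppressMessages(stay_glm(d0))
  i0 <- g0$table[g0$table$term == "prev_reward_z:same_start", ]
  expect_gt(i0$estimate, 0)
  expect_lt(i0$p_value, 0.01)
  # a pure random chooser shows no effects
  drand <- derive_trial_covariates(sim_cohort(8, w = 1, seed = 90, beta = 0))
  grand <- suppressMessages(stay_glm(drand))
  expect_true(all(abs(grand$table$estimate[-1]) < 0.4))
  expect_s3_class(generics::tidy(grand), "tbl_df")
})

test_that("TOST boundary behavior and monotonicity", {
  expect_lt(tost_equivalence(0, 1e-6, 0.5)$p_equiv, 1e-10)
  expect_gte(tost_equivalence(0.5, 0.1, 0.5)$p_equiv, 0.5) # at the bound
  expect_error(tost_equivalence(0, 0.1, 0), class = "replaykit_param_error")
  expect_error(tost_equivalence(0, -1, 0.5), class = "replaykit_param_error")
  # monotone in |estimate| and antitone in the bound
  ps <- vapply(seq(0, 0.8, 0.1),
               function(e) tost_equivalence(e, 0.2, 0.9)$p_equiv, numeric(1))
  expect_true(all(diff(ps) > 0))
  pb <- vapply(c(0.3, 0.6, 1.2),
               function(b) tost_equivalence(0.1, 0.2, b)$p_equiv, numeric(1))
  expect_true(all(diff(pb) < 0))
  expect_equal(tost_bound_medium(), 0.5 * pi / sqrt(3))
})

test_that("TOST rejection rate at the bound approximates the nominal level", {
  set.seed(5)
  se <- 0.2
  b <- 0.5
  rej <- vapply(1:2000, function(i) {
    est <- rnorm(1, mean = b, sd = se) # true effect exactly at the bound
    tost_equivalence(est, se, b)$p_equiv < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("RT regression recovers an injected start-change slowing", {
  cfg <- task_config()
  ds <- dplyr::bind_rows(lapply(1:8, function(i) {
    sc <- generate_task_schedule(cfg, seed = 500 + i)
    d <- simulate_agent(sc, agent_params(beta = 1), model = "mb",
                        seed = 600 + i, rt_sdlog = 0.05,
                        rt_shift_different_start = 0.05)
    d$participant <- i
    d
  }))
  d <- derive_trial_covariates(ds)
  g <- suppressMessages(rt_glm(d))
  co <- g$table[g$table$term == "different_start", ]
  expect_gt(co$estimate, 0.02)
  expect_lt(co$p_value, 0.01)
  # identical distributions: coefficient near zero
  ds0 <- dplyr::mutate(ds, rt = rlnorm(dplyr::n(), log(0.7), 0.05))
  g0 <- suppressMessages(rt_glm(derive_trial_covariates(ds0)))
  expect_lt(abs(g0$table$estimate[2]), 0.01)
  # single participant falls back to ordinary regression, flagged in engine
  g1 <- suppressMessages(rt_glm(d[d$participant == 1, ]))
  expect_match(g1$engine, "single participant")
})

test_that("memory probes are correct only when all three stages are correct", {
  probes <- tidyr::expand_grid(participant = 1, block = 1, probe = 1:8,
                               stage = 1:3)
  probes$correct <- 1L
  ms <- memory_summary(probes, n_boot = 200)
  expect_equal(ms$overall$pct_correct, 100)
  probes$correct[probes$probe == 3 & probes$stage == 2] <- 0L
  ms2 <- memory_summary(probes, n_boot = 200)
  expect_equal(ms2$per_block$pct_correct, 87.5)
  # missing stage excludes the probe
  probes3 <- probes[!(probes$probe == 1 & probes$stage == 3), ]
  expect_message(ms3 <- memory_summary(probes3, n_boot = 200), "incomplete")
  expect_equal(ms3$n_excluded, 1)
  expect_equal(ms3$overall$n_probes, 7)
})
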