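choice_csv_columns <- c("participant", "trial", "block", "world",
                        "start_state", "choice", "path", "reward",
                        "stakes", "rt")

#' Read and write choice datasets as CSV
#'
#' The on-disk schema has one row per trial with columns participant,
#' trial, block, world, start_state, choice, path, reward, stakes, rt;
#' unknown columns are preserved. Files with shuffled rows are sorted by
#' (participant, trial) with a warning. An optional column `mapping`
#' (named character vector, internal = external) adapts externally
#' deposited tables whose headers differ.
#'
#' @param path File path.
#' @param mapping Optional named character vector mapping internal column
#'   names to the file's column names, e.g.
#'   `c(participant = "subj_id", rt = "reaction_time")`.
#' @return A `ChoiceDataset` tibble.
#' @export
read_choice_csv <- function(path, mapping = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(mapping)) {
    for (internal in names(mapping)) {
      ext <- mapping[[internal]]
      if (!ext %in% names(d)) {
        abort(paste0("Mapped column '", ext, "' not found in file."),
              class = "replaykit_schema_error")
      }
      names(d)[names(d) == ext] <- internal
    }
  }
  missing <- setdiff(choice_csv_columns, names(d))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", "),
                 ". Expected header: ",
                 paste(choice_csv_columns, collapse = ", ")),
          class = "replaykit_schema_error")
  }
  if (is.unsorted(order(d$participant, d$trial))) {
    warn("Rows were not sorted by (participant, trial); sorting.")
    d <- arrange(d, .data$participant, .data$trial)
  }
  as_tibble(d)
}

#' @rdname read_choice_csv
#' @param dataset A `ChoiceDataset` tibble.
#' @export
write_choice_csv <- function(dataset, path) {
  missing <- setdiff(choice_csv_columns, names(dataset))
  if (length(missing) > 0) {
    abort(paste0("Dataset lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "replaykit_schema_error")
  }
  readr::write_csv(dataset, path)
  invisible(path)
}

#' Read and write reactivation series as long-format CSV
#'
#' Serializes a reactivation tibble (participant, trial, optional world,
#' `react` list-column of time-by-state matrices) as plain text with one
#' row per (trial, time sample, state).
#'
#' @param reacts Reactivation tibble.
#' @param path File path.
#' @param sample_ms Grid step recorded in the time column. Default 10.
#' @return `read_reactivation_csv()` returns the reactivation tibble.
#' @export
write_reactivation_csv <- function(reacts, path, sample_ms = 10) {
  rows <- lapply(seq_len(nrow(reacts)), function(i) {
    m <- reacts$react[[i]]
    tibble(participant = reacts$participant[i], trial = reacts$trial[i],
           world = if ("world" %in% names(reacts)) reacts$world[i]
           else NA_integer_,
           time_ms = rep((seq_len(nrow(m)) - 1L) * sample_ms,
                         times = ncol(m)),
           state = rep(seq_len(ncol(m)), each = nrow(m)),
           prob = as.vector(m))
  })
  readr::write_csv(list_rbind(rows), path)
  invisible(path)
}

#' @rdname write_reactivation_csv
#' @export
read_reactivation_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  keys <- distinct(d[, c("participant", "trial", "world")])
  mats <- lapply(seq_len(nrow(keys)), function(i) {
    di <- d[d$participant == keys$participant[i] & d$trial == keys$trial[i], ]
    n_s <- max(di$state)
    n_t <- nrow(di) / n_s
    matrix(di$prob[order(di$state, di$time_ms)], n_t, n_s)
  })
  out <- tibble(participant = keys$participant, trial = keys$trial,
                react = mats)
  if (!all(is.na(keys$world))) out$world <- keys$world
  out
}

#' Default pipeline configuration
#'
#' A nested list with one block per stage, reproducing the task's stated
#' settings: 6 x 24 trials, two worlds, rewards 0-9, stakes 1x/5x, rarity
#' rate 0.10, decoder latency 200 ms, lag grid 10-600 ms with lags of
#' interest 70 ms (forward) and 40 ms (backward). Override any entry via
#' `utils::modifyList()` semantics with `...` given as named blocks, or
#' load a YAML file with [read_pipeline_config()].
#'
#' @param ... Named blocks merged over the defaults (recursively).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  base <- list(
    n_participants = 6L,
    task = list(n_blocks = 6L, trials_per_block = 24L, walk_sd = 2,
                reward_min = 0, reward_max = 9),
    agent = list(model = "mb", alpha = 0.6, beta = 4, w = 1),
    fit = list(model = "mb", n_starts = 5L),
    decoder = list(enabled = FALSE, latency_ms = 200,
                   penalty_grid = 10^seq(-4, 1.5, length.out = 12)),
    sequenceness = list(lags_ms = seq(10, 600, 10), lag_fwd_ms = 70,
                        lag_bwd_ms = 40, n_perms = 100L,
                        planning_window_ms = 2340,
                        feedback_window_ms = 3500),
    injection = list(events_per_trial = 2, fidelity = 0.8,
                     baseline = c(1, 10),
                     planning_coupling = 1.5, feedback_coupling = 2),
    linking = list(rarity_rate = 0.10,
                   planning_regressors = c("different_start", "mean_value"),
                   feedback_regressors = c("rarity_other", "reward"))
  )
  over <- list(...)
  cfg <- utils::modifyList(base, over)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with (a subset of) the configuration blocks.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

validate_pipeline_config <- function(config) {
  need <- c("n_participants", "task", "agent", "fit", "sequenceness",
            "injection", "linking")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort(paste0("Pipeline config is missing block(s): ",
                 paste(missing, collapse = ", ")),
          class = "replaykit_config_error")
  }
  invisible(config)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> fit behavior -> simulate neural -> sequenceness ->
#' link on one configuration: per participant, a task schedule and agent
#' choices are generated; the behavioral model is fitted; planning-period
#' reactivation series receive current-world forward events whose amplitude
#' is larger on different-start trials, and feedback-period series receive
#' other-world backward events whose amplitude tracks the other world's
#' rarity; trial-wise sequenceness at the lags of interest is then linked
#' back to those regressors. Identical config and seed give identical
#' results.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A results bundle (list): `choices`, `fit`, `regressors`,
#'   `planning_scores`, `feedback_scores`, `planning_link`,
#'   `feedback_link`, `manifest` (seed, config hash, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L) {
  validate_pipeline_config(config)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 6L)
  tc <- task_config(n_blocks = config$task$n_blocks,
                    trials_per_block = config$task$trials_per_block,
                    walk_sd = config$task$walk_sd,
                    reward_min = config$task$reward_min,
                    reward_max = config$task$reward_max)
  spec <- transition_spec()
  n_p <- config$n_participants

  # behavior: one schedule + agent per participant
  set.seed(stage_seeds[1])
  sched_seeds <- sample.int(.Machine$integer.max - 1L, n_p)
  choices <- list_rbind(lapply(seq_len(n_p), function(i) {
    sc <- generate_task_schedule(tc, seed = sched_seeds[i])
    ds <- simulate_agent(sc, agent_params(alpha = config$agent$alpha,
                                          beta = config$agent$beta,
                                          w = config$agent$w),
                         model = config$agent$model, seed = sched_seeds[i])
    ds$participant <- i
    ds
  }))
  fit <- fit_model(choices, model = config$fit$model,
                   n_starts = config$fit$n_starts, seed = stage_seeds[2])
  table <- build_regressor_table(choices, fit,
                                 rarity_rate = config$linking$rarity_rate)

  # neural: coupled injections per period
  inj <- config$injection
  plan_trials <- mutate(table,
                        amplitude = 1 + inj$planning_coupling *
                          tidyr::replace_na(.data$different_start, 0))
  fb_trials <- mutate(table,
                      amplitude = 1 + inj$feedback_coupling *
                        (.data$rarity_other - mean(.data$rarity_other)))
  plan_inject <- replay_injection(lag_ms = config$sequenceness$lag_fwd_ms,
                                  direction = "forward",
                                  events_per_trial = inj$events_per_trial,
                                  fidelity = inj$fidelity,
                                  baseline = inj$baseline)
  fb_inject <- replay_injection(lag_ms = config$sequenceness$lag_bwd_ms,
                                direction = "backward",
                                events_per_trial = inj$events_per_trial,
                                fidelity = inj$fidelity,
                                baseline = inj$baseline)
  plan_react <- simulate_cohort_reactivation(
    plan_trials, spec, plan_inject, target = "current",
    window_ms = config$sequenceness$planning_window_ms,
    seed = stage_seeds[3])
  fb_react <- simulate_cohort_reactivation(
    fb_trials, spec, fb_inject, target = "other",
    window_ms = config$sequenceness$feedback_window_ms,
    seed = stage_seeds[4])

  plan_scores <- trialwise_sequenceness(plan_react, spec,
                                        config$sequenceness$lag_fwd_ms,
                                        subset = "current")
  fb_scores <- trialwise_sequenceness(fb_react, spec,
                                      config$sequenceness$lag_bwd_ms,
                                      subset = "other")
  plan_link <- link_glm(plan_scores, table,
                        regressors = config$linking$planning_regressors,
                        direction = "fwd")
  fb_link <- link_glm(fb_scores, table,
                      regressors = config$linking$feedback_regressors,
                      direction = "bwd")
  list(choices = choices, fit = fit, regressors = table,
       planning_scores = plan_scores, feedback_scores = fb_scores,
       planning_link = plan_link, feedback_link = fb_link,
       manifest = list(seed = seed, config_hash = rlang::hash(config),
                       package_version =
                         as.character(utils::packageVersion("replaykit")),
                       timestamp = format(Sys.time(), tz = "UTC")))
}
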