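#' Task configuration for the dual-environment two-step task
#'
#' Describes the structure of a reward-learning task in which each trial
#' starts in one of two equivalent start states of one of two independent
#' environments ("worlds"); each start state offers a choice between two
#' options that lead deterministically to one of the world's two three-state
#' paths, ending in 0-9 reward points that drift across trials and are
#' multiplied by the trial's stakes.
#'
#' @param n_worlds Number of independent environments. Default 2.
#' @param n_paths_per_world Number of paths (and options) per world. Default 2.
#' @param path_length Number of intermediate states per path. Default 3.
#' @param n_start_states_per_world Equivalent start states per world. Default 2.
#' @param n_blocks,trials_per_block Session structure; defaults 6 blocks of 24
#'   trials (144 trials total).
#' @param reward_min,reward_max Bounds of the drifting reward points (0 and 9).
#' @param stakes_levels Multipliers applied to end-of-path points; default
#'   `c(1, 5)`, drawn equiprobably per trial.
#' @param walk_sd Standard deviation, in points per trial, of the Gaussian
#'   reward random walk (reflected at the bounds). Default 2.
#' @param sample_ms Temporal grid step in milliseconds used by all neural
#'   series in the package. Default 10.
#' @param max_world_run Maximum number of consecutive trials in the same
#'   world allowed by the pseudorandom schedule. Default 3.
#'
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$n_blocks * cfg$trials_per_block # 144
#' @export
task_config <- function(n_worlds = 2,
                        n_paths_per_world = 2,
                        path_length = 3,
                        n_start_states_per_world = 2,
                        n_blocks = 6,
                        trials_per_block = 24,
                        reward_min = 0,
                        reward_max = 9,
                        stakes_levels = c(1, 5),
                        walk_sd = 2,
                        sample_ms = 10,
                        max_world_run = 3) {
  if (reward_min >= reward_max) {
    abort("`reward_min` must be strictly below `reward_max`.",
          class = "replaykit_config_error")
  }
  counts <- c(n_worlds = n_worlds, n_paths_per_world = n_paths_per_world,
              path_length = path_length,
              n_start_states_per_world = n_start_states_per_world,
              n_blocks = n_blocks, trials_per_block = trials_per_block)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("Count fields of a task_config must be positive integers.",
          class = "replaykit_config_error")
  }
  if (walk_sd < 0) abort("`walk_sd` must be non-negative.",
                         class = "replaykit_config_error")
  structure(
    list(n_worlds = as.integer(n_worlds),
         n_paths_per_world = as.integer(n_paths_per_world),
         path_length = as.integer(path_length),
         n_start_states_per_world = as.integer(n_start_states_per_world),
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         reward_min = reward_min, reward_max = reward_max,
         stakes_levels = stakes_levels, walk_sd = walk_sd,
         sample_ms = sample_ms, max_world_run = as.integer(max_world_run)),
    class = "task_config")
}

#' Number of distinct path states implied by a task configuration
#' @param config A [task_config()].
#' @return Integer count (12 under the defaults).
#' @export
n_states <- function(config) {
  config$n_worlds * config$n_paths_per_world * config$path_length
}

# Reflect a value into [lo, hi] (repeatedly, for large excursions).
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  for (i in seq_along(x)) {
    while (x[i] < lo || x[i] > hi) {
      if (x[i] < lo) x[i] <- 2 * lo - x[i]
      if (x[i] > hi) x[i] <- 2 * hi - x[i]
    }
  }
  x
}

#' Generate a pseudorandom task schedule
#'
#' Draws a per-trial sequence of worlds (equal marginal probability,
#' constrained to at most `max_world_run` consecutive repeats), start states
#' (uniform within world), stakes (equiprobable), and a latent reward value
#' per path that follows a Gaussian random walk reflected at the reward
#' bounds. Within a world, both start states map onto the same two paths
#' through a fixed option-to-path map, so knowledge of one start state's
#' outcomes generalizes to the other.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; all schedule randomness flows from it and the
#'   seed is recorded in the returned object.
#' @return A `task_schedule`: list with `trials` (tibble: trial, block, world,
#'   start_state, stakes), `latent_rewards` (matrix, trial by path),
#'   `paths` (tibble: path, world, option, and the path's ordered state ids),
#'   `state_of` (matrix, path by position, state ids), `config`, `seed`.
#' @examples
#' sched <- generate_task_schedule(task_config(), seed = 1)
#' nrow(sched$trials) # 144
#' @export
generate_task_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  n_trials <- config$n_blocks * config$trials_per_block
  n_paths <- config$n_worlds * config$n_paths_per_world

  # world sequence: uniform draws, forced switch after max_world_run repeats
  world <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    run_capped <- t > config$max_world_run &&
      length(unique(world[(t - config$max_world_run):(t - 1)])) == 1L
    cand <- seq_len(config$n_worlds)
    if (run_capped) cand <- setdiff(cand, world[t - 1])
    if (length(cand) == 0L) cand <- seq_len(config$n_worlds)
    world[t] <- cand[sample.int(length(cand), 1L)]
  }

  # start states indexed globally: world w owns starts
  # (w-1)*n_start_states_per_world + 1 .. w*n_start_states_per_world
  start_within <- sample.int(config$n_start_states_per_world, n_trials,
                             replace = TRUE)
  start_state <- (world - 1L) * config$n_start_states_per_world + start_within
  stakes <- sample(config$stakes_levels, n_trials, replace = TRUE)

  # reflected Gaussian reward walks, one per path
  latent <- matrix(NA_real_, n_trials, n_paths)
  latent[1, ] <- runif(n_paths, config$reward_min, config$reward_max)
  if (n_trials > 1) {
    for (t in 2:n_trials) {
      step <- latent[t - 1, ] + rnorm(n_paths, 0, config$walk_sd)
      latent[t, ] <- reflect_into(step, config$reward_min, config$reward_max)
    }
  }

  # option -> path map, identical for both start states of a world
  paths <- tidyr::expand_grid(world = seq_len(config$n_worlds),
                              option = seq_len(config$n_paths_per_world))
  paths$path <- (paths$world - 1L) * config$n_paths_per_world + paths$option
  state_of <- matrix(seq_len(n_states(config)), nrow = n_paths,
                     ncol = config$path_length, byrow = TRUE)
  paths$states <- lapply(paths$path, function(p) state_of[p, ])
  paths <- paths[, c("path", "world", "option", "states")]

  trials <- tibble(
    trial = seq_len(n_trials),
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    world = world,
    start_state = start_state,
    stakes = stakes
  )

  structure(list(trials = trials, latent_rewards = latent,
                 paths = as_tibble(paths), state_of = state_of,
                 config = config, seed = seed),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("<task_schedule> ", nrow(x$trials), " trials, ",
      x$config$n_worlds, " worlds, ",
      nrow(x$paths), " paths x ", x$config$path_length,
      " states (seed ", x$seed, ")\n", sep = "")
  print(head(x$trials, 5))
  invisible(x)
}

# path chosen when `option` is taken in `world` (vectorized)
path_for_option <- function(schedule, world, option) {
  (world - 1L) * schedule$config$n_paths_per_world + option
}
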