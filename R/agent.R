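#' Parameters of a Q-learning agent
#'
#' @param alpha Learning rate in \[0, 1\], shared by the model-free (start
#'   state by option) and model-based (path value) stores.
#' @param beta Softmax inverse temperature (>= 0).
#' @param w Model-based weight in \[0, 1\]; the decision value is
#'   `w * V_path + (1 - w) * Q_MF`. Only meaningful for the hybrid model
#'   (the model-free and model-based controllers are its w = 0 / w = 1
#'   boundaries).
#' @param persev Perseveration bonus in log-odds units added to the option
#'   whose path matches the previous same-world path choice. Default 0 (off).
#' @param beta_high,beta_low Inverse temperatures applied on world-change
#'   trials labeled as preceded by high versus low feedback replay
#'   (replay-modulated model only).
#' @return An `agent_params` list.
#' @export
agent_params <- function(alpha = 0.5, beta = 5, w = 1, persev = 0,
                         beta_high = NULL, beta_low = NULL) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].",
                                    class = "replaykit_param_error")
  if (beta < 0) abort("`beta` must be non-negative.",
                      class = "replaykit_param_error")
  if (w < 0 || w > 1) abort("`w` must lie in [0, 1].",
                            class = "replaykit_param_error")
  if (!is.null(beta_high) && beta_high < 0 ||
      !is.null(beta_low) && beta_low < 0) {
    abort("Replay-split inverse temperatures must be non-negative.",
          class = "replaykit_param_error")
  }
  structure(list(alpha = alpha, beta = beta, w = w, persev = persev,
                 beta_high = beta_high, beta_low = beta_low),
            class = "agent_params")
}

#' Initial value stores for an agent
#'
#' Q (start state by option, model-free) and V (per path, model-based) are
#' initialized at the reward midpoint so the first trial carries no optimism
#' or pessimism bias.
#'
#' @param config A [task_config()].
#' @param init Initial value; default the midpoint of the reward range.
#' @return A `value_state` list with matrix `Q` and vector `V`.
#' @export
value_state <- function(config = task_config(),
                        init = (config$reward_min + config$reward_max) / 2) {
  n_starts <- config$n_worlds * config$n_start_states_per_world
  n_paths <- config$n_worlds * config$n_paths_per_world
  structure(list(
    Q = matrix(init, n_starts, config$n_paths_per_world),
    V = rep(init, n_paths)),
    class = "value_state")
}

#' Delta-rule value update after one trial
#'
#' Updates the model-free action value of the chosen option at the visited
#' start state and the model-based value of the chosen path toward the
#' observed reward; all other entries are untouched. With rewards in
#' \[0, 9\] and `alpha` in \[0, 1\] both stores stay inside \[0, 9\].
#'
#' @param state A [value_state()].
#' @param trial A list or one-row data frame with `start_state`, `choice`
#'   (option index), `path`, `reward`.
#' @param alpha Learning rate in \[0, 1\].
#' @return The updated `value_state`.
#' @examples
#' st <- value_state()
#' st <- value_update(st, list(start_state = 1, choice = 1, path = 1, reward = 9),
#'                    alpha = 0.5)
#' st$Q[1, 1] # 6.75
#' @export
value_update <- function(state, trial, alpha) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].",
                                    class = "replaykit_param_error")
  s <- trial$start_state; a <- trial$choice; p <- trial$path; r <- trial$reward
  state$Q[s, a] <- state$Q[s, a] + alpha * (r - state$Q[s, a])
  state$V[p] <- state$V[p] + alpha * (r - state$V[p])
  state
}

# option values for one trial under a named controller; returns length-2
# vector over options 1..2 of the trial's world
option_values <- function(state, world, start_state, params, model,
                          n_paths_per_world = 2L) {
  opts <- seq_len(n_paths_per_world)
  paths <- (world - 1L) * n_paths_per_world + opts
  v_mb <- state$V[paths]
  v_mf <- state$Q[start_state, opts]
  switch(model,
         mf = v_mf,
         mb = v_mb,
         hybrid = ,
         replay_modulated = params$w * v_mb + (1 - params$w) * v_mf,
         abort(paste0("Unknown model '", model, "'."),
               class = "replaykit_model_error"))
}

#' Softmax choice probabilities for one trial
#'
#' Computes the probability of each of the two available options under a
#' named controller: `"mf"` uses start-state action values, `"mb"` looks
#' ahead to the values of the paths the options lead to, `"hybrid"` mixes
#' the two with weight `w`, and `"replay_modulated"` is the hybrid/MB rule
#' with `beta_high`/`beta_low` replacing `beta` on world-change trials
#' carrying a high/low preceding-feedback-replay label.
#'
#' @param state A [value_state()].
#' @param trial List/row with `world`, `start_state`; optionally `prev_path`
#'   (previous same-world chosen path, for perseveration), `world_change`
#'   and `replay_label` (`"high"`/`"low"`) for the replay-modulated model.
#' @param params An [agent_params()].
#' @param model One of `"mf"`, `"mb"`, `"hybrid"`, `"replay_modulated"`.
#' @return Numeric length-2 probability vector summing to 1.
#' @export
choice_probabilities <- function(state, trial, params, model = "hybrid") {
  npw <- ncol(state$Q)
  v <- option_values(state, trial$world, trial$start_state, params, model, npw)
  beta <- params$beta
  if (model == "replay_modulated" && isTRUE(trial$world_change == 1) &&
      !is.null(trial$replay_label) && !is.na(trial$replay_label)) {
    beta <- if (trial$replay_label == "high") params$beta_high else params$beta_low
  }
  bonus <- numeric(npw)
  if (!is.null(trial$prev_path) && !is.na(trial$prev_path) &&
      params$persev != 0) {
    paths <- (trial$world - 1L) * npw + seq_len(npw)
    bonus <- params$persev * (paths == trial$prev_path)
  }
  z <- beta * v + bonus
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Simulate agents performing the task
#'
#' Plays one or more agents through a [generate_task_schedule()] schedule
#' under a named controller, drawing choices from the softmax policy,
#' observing rounded path rewards, and generating synthetic reaction times
#' (log-normal, with an optional additive shift on start-state-change
#' trials). Generative choice probabilities are retained for oracle checks.
#'
#' @param schedule A `task_schedule`.
#' @param params An [agent_params()].
#' @param model Controller name, see [choice_probabilities()].
#' @param n_agents Number of independent agents (participants) to simulate.
#' @param seed Integer seed.
#' @param rt_base Median RT in seconds. Default 0.7.
#' @param rt_sdlog Log-scale RT standard deviation. Default 0.25.
#' @param rt_shift_different_start Additive RT shift (s) on trials whose
#'   start state differs from the previous same-world trial. Default 0.01.
#' @param replay_labels Optional tibble (participant, trial, replay_label)
#'   for the replay-modulated controller.
#' @return A `ChoiceDataset` tibble: participant, trial, block, world,
#'   start_state, choice, path, reward, stakes, rt, p_option1.
#' @export
simulate_agent <- function(schedule, params, model = "hybrid", n_agents = 1L,
                           seed = 1L, rt_base = 0.7, rt_sdlog = 0.25,
                           rt_shift_different_start = 0.01,
                           replay_labels = NULL) {
  stopifnot(inherits(schedule, "task_schedule"))
  if (model == "replay_modulated" &&
      (is.null(params$beta_high) || is.null(params$beta_low))) {
    abort("replay_modulated model requires beta_high and beta_low.",
          class = "replaykit_param_error")
  }
  cfg <- schedule$config
  tr <- schedule$trials
  n_trials <- nrow(tr)
  npw <- cfg$n_paths_per_world
  set.seed(seed)

  out <- vector("list", n_agents)
  for (ag in seq_len(n_agents)) {
    st <- value_state(cfg)
    prev_path_w <- rep(NA_integer_, cfg$n_worlds) # last chosen path per world
    prev_start_w <- rep(NA_integer_, cfg$n_worlds)
    choice <- integer(n_trials); path <- integer(n_trials)
    reward <- numeric(n_trials); p1 <- numeric(n_trials)
    rt <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      w <- tr$world[t]
      lab <- NA_character_
      if (!is.null(replay_labels)) {
        hit <- replay_labels$participant == ag & replay_labels$trial == t
        if (any(hit)) lab <- replay_labels$replay_label[which(hit)[1]]
      }
      trial <- list(world = w, start_state = tr$start_state[t],
                    prev_path = prev_path_w[w],
                    world_change = as.integer(t > 1 && tr$world[t - 1] != w),
                    replay_label = lab)
      pr <- choice_probabilities(st, trial, params, model)
      p1[t] <- pr[1]
      choice[t] <- sample.int(npw, 1L, prob = pr)
      path[t] <- path_for_option(schedule, w, choice[t])
      reward[t] <- round(schedule$latent_rewards[t, path[t]])
      st <- value_update(st, list(start_state = tr$start_state[t],
                                  choice = choice[t], path = path[t],
                                  reward = reward[t]), params$alpha)
      diff_start <- !is.na(prev_start_w[w]) && prev_start_w[w] != tr$start_state[t]
      rt[t] <- rlnorm(1, log(rt_base), rt_sdlog) +
        rt_shift_different_start * diff_start
      prev_path_w[w] <- path[t]
      prev_start_w[w] <- tr$start_state[t]
    }
    out[[ag]] <- tibble(participant = ag, tr,
                        choice = choice, path = path, reward = reward,
                        rt = rt, p_option1 = p1)
  }
  ds <- list_rbind(out)
  ds <- ds[, c("participant", "trial", "block", "world", "start_state",
               "choice", "path", "reward", "stakes", "rt", "p_option1")]
  attr(ds, "seed") <- seed
  attr(ds, "model") <- model
  ds
}
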