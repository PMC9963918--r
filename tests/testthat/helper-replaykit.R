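# Shared fixtures, built in code at test time.

default_spec <- transition_spec()

# Small cohort of agents on independent schedules; returns a ChoiceDataset.
sim_cohort <- function(n_agents, w, seed, alpha = 0.6, beta = 1,
                       config = task_config(), model = "hybrid") {
  dplyr::bind_rows(lapply(seq_len(n_agents), function(i) {
    sc <- generate_task_schedule(config, seed = seed + i)
    d <- simulate_agent(sc, agent_params(alpha = alpha, beta = beta, w = w),
                        model = model, seed = seed + 1000L + i)
    d$participant <- i
    d
  }))
}

# Reactivation sets for several participants with a shared injection.
sim_react_cohort <- function(n_participants, n_trials, inject, seed,
                             window_ms = 2340, spec = default_spec) {
  dplyr::bind_rows(lapply(seq_len(n_participants), function(p) {
    generate_reactivation_series(spec, inject, n_trials = n_trials,
                                 window_ms = window_ms, seed = seed + p,
                                 participant = p)
  }))
}

# Closed-form exponentially weighted frequency, independent of the
# recurrence implementation: F_t = (1-rate)^t F0 + rate * sum (1-rate)^(t-k) I_k
rarity_closed_form <- function(indicators, rate, init = 0.5) {
  t <- length(indicators)
  (1 - rate)^t * init +
    rate * sum((1 - rate)^(t - seq_len(t)) * indicators)
}
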