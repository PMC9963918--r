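#' Specification of injected replay events for synthetic reactivation series
#'
#' Ground-truth description of sequential reactivation events to embed in a
#' synthetic time-by-state probability series: each event reactivates the
#' three states of one path in order (s1, s2, s3 at offsets 0, lag, 2*lag)
#' for forward events, or in reversed order for backward events.
#'
#' @param lag_ms State-to-state lag in ms; must be a multiple of the 10-ms
#'   sampling grid.
#' @param direction `"forward"` or `"backward"`.
#' @param events_per_trial Expected event count per trial; integers give a
#'   fixed count, non-integers a Poisson draw with that mean.
#' @param fidelity Probability bump amplitude in (0, 1\].
#' @param baseline Beta distribution parameters `c(shape1, shape2)` of the
#'   i.i.d. baseline noise (low, positive, bounded classifier probabilities);
#'   `NULL` for a zero baseline. Default `c(1, 10)`.
#' @param affected_paths Integer ids of the paths receiving events.
#' @param sample_ms Sampling grid step. Default 10.
#' @return A `replay_injection` list.
#' @export
replay_injection <- function(lag_ms = 70, direction = c("forward", "backward"),
                             events_per_trial = 3, fidelity = 0.8,
                             baseline = c(1, 10), affected_paths = 1:4,
                             sample_ms = 10) {
  direction <- match.arg(direction)
  if (abs(lag_ms / sample_ms - round(lag_ms / sample_ms)) > 1e-9) {
    abort("`lag_ms` must be a multiple of the sampling grid.",
          class = "replaykit_lag_error")
  }
  if (fidelity <= 0 || fidelity > 1) {
    abort("`fidelity` must lie in (0, 1].", class = "replaykit_param_error")
  }
  if (events_per_trial < 0) {
    abort("`events_per_trial` must be non-negative.",
          class = "replaykit_param_error")
  }
  structure(list(lag_ms = lag_ms, direction = direction,
                 events_per_trial = events_per_trial, fidelity = fidelity,
                 baseline = baseline, affected_paths = affected_paths,
                 sample_ms = sample_ms),
            class = "replay_injection")
}

# add one event for path states `sts` to matrix m starting at sample t0
add_event <- function(m, sts, t0, L, amp, backward = FALSE) {
  if (backward) sts <- rev(sts)
  for (k in seq_along(sts)) {
    idx <- t0 + (k - 1L) * L
    m[idx, sts[k]] <- m[idx, sts[k]] + amp
  }
  m
}

# One trial's [time x state] matrix from the *current* RNG stream.
# Returns list(mat, events tibble).
gen_react_matrix <- function(spec, inject, n_t, amplitude = 1,
                             affected_paths = NULL) {
  n_s <- spec$n_states
  base <- if (is.null(inject) || is.null(inject$baseline)) {
    matrix(0, n_t, n_s)
  } else {
    matrix(stats::rbeta(n_t * n_s, inject$baseline[1], inject$baseline[2]),
           n_t, n_s)
  }
  ev <- list()
  if (!is.null(inject) && inject$events_per_trial > 0) {
    paths_use <- affected_paths %||% inject$affected_paths
    L <- as.integer(inject$lag_ms / inject$sample_ms)
    n_ev <- if (abs(inject$events_per_trial -
                    round(inject$events_per_trial)) < 1e-9) {
      as.integer(round(inject$events_per_trial))
    } else {
      stats::rpois(1, inject$events_per_trial)
    }
    for (e in seq_len(n_ev)) {
      pth <- if (length(paths_use) == 1) paths_use else sample(paths_use, 1)
      t0 <- sample.int(n_t - 2L * L, 1)
      base <- add_event(base, spec$paths[[pth]], t0, L,
                        inject$fidelity * amplitude,
                        backward = inject$direction == "backward")
      ev[[length(ev) + 1]] <- tibble(onset_sample = t0, path = pth,
                                     direction = inject$direction,
                                     amplitude = inject$fidelity * amplitude)
    }
  }
  list(mat = pmin(pmax(base, 0), 1),
       events = if (length(ev) > 0) list_rbind(ev) else NULL)
}

#' Generate synthetic reactivation probability series with injected replay
#'
#' Emulates the time-by-state classifier probability matrices produced by
#' applying state decoders to a trial period: i.i.d. Beta baseline noise per
#' state and sample, plus sequential probability bumps following the path
#' order of a [transition_spec()] at a controlled lag, rate and fidelity
#' (see [replay_injection()]). Values are clipped to \[0, 1\]. The injected
#' events are returned as a ground-truth attribute.
#'
#' @param spec A [transition_spec()].
#' @param inject A [replay_injection()], or `NULL` for pure baseline noise.
#' @param n_trials Number of trials to generate.
#' @param window_ms Window length in ms; must be at least `3 * lag_ms`.
#' @param seed Integer seed (recorded in the output's `seed` attribute).
#' @param amplitudes Optional per-trial multiplier of the event amplitude
#'   (length `n_trials`), e.g. to couple replay strength to a regressor.
#' @param participant Participant id stamped on the rows. Default 1.
#' @param worlds Optional per-trial world labels to attach (for
#'   current/other-world scoring).
#' @return Tibble with columns participant, trial, (world,) and `react`
#'   (list-column of time-by-state matrices). Attributes: `events`
#'   (ground-truth tibble), `seed`.
#' @export
generate_reactivation_series <- function(spec, inject, n_trials = 1L,
                                         window_ms = 2340, seed = 1L,
                                         amplitudes = NULL, participant = 1L,
                                         worlds = NULL) {
  stopifnot(inherits(spec, "transition_spec"))
  sample_ms <- if (is.null(inject)) 10 else inject$sample_ms
  n_t <- as.integer(window_ms / sample_ms)
  if (!is.null(inject) && window_ms < 3 * inject$lag_ms) {
    abort("Window must be at least 3 x lag long.",
          class = "replaykit_lag_error")
  }
  if (is.null(amplitudes)) amplitudes <- rep(1, n_trials)
  stopifnot(length(amplitudes) == n_trials)
  if (!is.null(seed)) set.seed(seed)
  mats <- vector("list", n_trials)
  ev_log <- list()
  for (tr in seq_len(n_trials)) {
    g <- gen_react_matrix(spec, inject, n_t, amplitudes[tr])
    mats[[tr]] <- g$mat
    if (!is.null(g$events)) {
      ev_log[[length(ev_log) + 1]] <- mutate(g$events, trial = tr,
                                             .before = 1)
    }
  }
  out <- tibble(participant = participant, trial = seq_len(n_trials),
                react = mats)
  if (!is.null(worlds)) out$world <- worlds
  attr(out, "events") <- if (length(ev_log) > 0) list_rbind(ev_log) else
    tibble(trial = integer(), onset_sample = integer(), path = integer(),
           direction = character(), amplitude = numeric())
  attr(out, "seed") <- seed
  out
}

#' Simulate a cohort's trial-wise reactivation series with coupled replay
#'
#' Generates one reactivation matrix per trial for a whole cohort, placing
#' injected events on the paths of either the trial's current world or the
#' other world, with a per-trial event amplitude given by a coupling column.
#' This is the generative design for replay-behavior linking analyses:
#' e.g. planning-period forward events on current-world paths whose
#' amplitude grows on different-start trials, or feedback-period backward
#' events on other-world paths whose amplitude tracks rarity.
#'
#' @param trials Tibble with columns `participant`, `trial`, `world` and a
#'   numeric `amplitude` column (per-trial event amplitude multiplier; 0
#'   suppresses events on that trial).
#' @param spec A [transition_spec()].
#' @param inject A [replay_injection()] template (its `affected_paths` is
#'   ignored; paths are chosen per trial by `target`).
#' @param target `"current"` or `"other"`: which world's paths receive the
#'   events on each trial.
#' @param window_ms Window length in ms.
#' @param seed Integer seed.
#' @return Tibble: participant, trial, world, react (list-column), suitable
#'   for [trialwise_sequenceness()] and [sequenceness_curve()].
#' @export
simulate_cohort_reactivation <- function(trials, spec, inject,
                                         target = c("current", "other"),
                                         window_ms = 2340, seed = 1L) {
  target <- match.arg(target)
  need <- c("participant", "trial", "world", "amplitude")
  if (!all(need %in% names(trials))) {
    abort(paste0("`trials` needs columns: ", paste(need, collapse = ", ")),
          class = "replaykit_data_error")
  }
  n_t <- as.integer(window_ms / inject$sample_ms)
  if (window_ms < 3 * inject$lag_ms) {
    abort("Window must be at least 3 x lag long.",
          class = "replaykit_lag_error")
  }
  set.seed(seed)
  mats <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    paths <- if (target == "current") which(spec$world == trials$world[i])
    else which(spec$world != trials$world[i])
    amp <- trials$amplitude[i]
    inj_i <- inject
    if (amp <= 0) inj_i$events_per_trial <- 0
    g <- gen_react_matrix(spec, inj_i, n_t, max(amp, 0), paths)
    mats[[i]] <- g$mat
  }
  out <- tibble(participant = trials$participant, trial = trials$trial,
                world = trials$world, react = mats)
  attr(out, "seed") <- seed
  out
}
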