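#' Exponentially weighted experience frequency and rarity
#'
#' Tracks, for each world, the frequency of recent experience with the same
#' delta rule used for reward values, applied to a binary appearance
#' indicator: `F <- F + rate * (appeared - F)`. Rarity is the inverted
#' frequency `R = 1 - F`. The update rate defaults to 0.10, a deliberately
#' slow rate appropriate for tracking experience over tens of trials.
#'
#' @param n_worlds Number of worlds tracked. Default 2.
#' @param rate Experience learning rate in (0, 1). Default 0.10.
#' @param init Initial frequency per world. Default 0.5.
#' @return A `rarity_trace`: list with `F` (frequency per world), `R`
#'   (rarity per world) and `rate`.
#' @examples
#' tr <- rarity_trace()
#' tr <- update_rarity(tr, c(1, 0)) # world 1 appeared
#' tr$F # 0.55 0.45
#' @export
rarity_trace <- function(n_worlds = 2L, rate = 0.10, init = 0.5) {
  if (rate <= 0 || rate >= 1) abort("`rate` must lie strictly in (0, 1).",
                                    class = "replaykit_param_error")
  if (any(init < 0) || any(init > 1)) abort("`init` must lie in [0, 1].",
                                            class = "replaykit_param_error")
  f <- rep_len(init, n_worlds)
  structure(list(F = f, R = 1 - f, rate = rate), class = "rarity_trace")
}

#' @rdname rarity_trace
#' @param trace A `rarity_trace`.
#' @param appeared Binary indicator vector, one per world (1 = the world
#'   appeared on this trial).
#' @export
update_rarity <- function(trace, appeared) {
  stopifnot(inherits(trace, "rarity_trace"))
  if (length(appeared) != length(trace$F) || !all(appeared %in% c(0, 1))) {
    abort("`appeared` must be a 0/1 vector with one entry per world.",
          class = "replaykit_param_error")
  }
  trace$F <- trace$F + trace$rate * (appeared - trace$F)
  trace$R <- 1 - trace$F
  trace
}

#' Per-trial rarity series for a sequence of world visits
#'
#' Runs [update_rarity()] along a trial sequence and returns the trace
#' *before* each trial's update (the value available at that trial's
#' feedback), plus the updated value.
#'
#' @param worlds Integer vector of the world visited on each trial.
#' @param n_worlds Number of worlds.
#' @param rate,init See [rarity_trace()].
#' @return A tibble: trial, world (the world of column `frequency`),
#'   `frequency`/`rarity` after the trial's update, and
#'   `frequency_pre`/`rarity_pre` before it.
#' @export
rarity_series <- function(worlds, n_worlds = max(worlds), rate = 0.10,
                          init = 0.5) {
  tr <- rarity_trace(n_worlds, rate, init)
  n <- length(worlds)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    pre <- tr$F
    tr <- update_rarity(tr, as.integer(seq_len(n_worlds) == worlds[t]))
    out[[t]] <- tibble(trial = t, world = seq_len(n_worlds),
                       frequency_pre = pre, rarity_pre = 1 - pre,
                       frequency = tr$F, rarity = tr$R)
  }
  list_rbind(out)
}
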