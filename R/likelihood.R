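# Internal: recover the option -> path map of a world from observed trials.
# Within a world both start states lead to the same two paths, so the map is
# a function of (world, option) alone; inconsistency means corrupt data.
derive_option_map <- function(dataset) {
  ok <- !is.na(dataset$choice) & !is.na(dataset$path)
  m <- distinct(dataset[ok, c("world", "choice", "path")])
  if (anyDuplicated(m[, c("world", "choice")]) > 0) {
    abort("Inconsistent option-to-path mapping in dataset.",
          class = "replaykit_data_error")
  }
  m
}

# Internal single-participant negative log-likelihood. `d` must be ordered by
# trial. Missing choices contribute no likelihood term; the value update is
# still applied when a path/reward was observed.
nll_one <- function(d, params, model, opt_map, n_starts_total, npw,
                    reward_mid = 4.5) {
  n <- nrow(d)
  Q <- matrix(reward_mid, n_starts_total, npw)
  V <- rep(reward_mid, max(opt_map$path))
  # path of each option in each world
  pmap_mat <- matrix(NA_integer_, max(d$world), npw)
  pmap_mat[cbind(opt_map$world, opt_map$choice)] <- opt_map$path
  alpha <- params$alpha; w <- params$w; persev <- params$persev %||% 0
  prev_path_w <- rep(NA_integer_, max(d$world))
  has_labels <- model == "replay_modulated" && "replay_label" %in% names(d)
  nll <- 0
  for (t in seq_len(n)) {
    wld <- d$world[t]; ss <- d$start_state[t]
    paths_t <- pmap_mat[wld, ]
    v <- switch(model,
                mf = Q[ss, ],
                mb = V[paths_t],
                hybrid = w * V[paths_t] + (1 - w) * Q[ss, ],
                replay_modulated = w * V[paths_t] + (1 - w) * Q[ss, ])
    beta <- params$beta
    if (has_labels && !is.na(d$replay_label[t])) {
      beta <- if (d$replay_label[t] == "high") params$beta_high else params$beta_low
    }
    z <- beta * v
    if (persev != 0 && !is.na(prev_path_w[wld])) {
      z <- z + persev * (paths_t == prev_path_w[wld])
    }
    z <- z - max(z)
    ch <- d$choice[t]
    if (!is.na(ch)) nll <- nll - (z[ch] - log(sum(exp(z))))
    p <- d$path[t]; r <- d$reward[t]
    if (!is.na(p) && !is.na(r)) {
      if (!is.na(ch)) Q[ss, ch] <- Q[ss, ch] + alpha * (r - Q[ss, ch])
      V[p] <- V[p] + alpha * (r - V[p])
      prev_path_w[wld] <- p
    }
  }
  nll
}

#' Negative log-likelihood of observed choices under a Q-learning controller
#'
#' Values are updated trial by trial (delta rule on both the model-free and
#' model-based stores); the likelihood sums `-log P(chosen option)` over all
#' trials with an observed choice, independently per participant.
#'
#' @param dataset A `ChoiceDataset` tibble (see [simulate_agent()]),
#'   chronologically ordered within participant. May carry a `replay_label`
#'   column for the replay-modulated model.
#' @param params An [agent_params()].
#' @param model `"mf"`, `"mb"`, `"hybrid"` or `"replay_modulated"`.
#' @return Total negative log-likelihood in nats (>= 0).
#' @examples
#' sched <- generate_task_schedule(task_config(), seed = 2)
#' ds <- simulate_agent(sched, agent_params(beta = 0), model = "mb", seed = 3)
#' nll_choices(ds, agent_params(beta = 0), "mb") # = 144 * log(2)
#' @export
nll_choices <- function(dataset, params, model = "hybrid") {
  if (!model %in% c("mf", "mb", "hybrid", "replay_modulated")) {
    abort(paste0("Unknown model '", model, "'."),
          class = "replaykit_model_error")
  }
  opt_map <- derive_option_map(dataset)
  npw <- max(opt_map$choice)
  n_starts_total <- max(dataset$start_state)
  mid <- 4.5
  total <- 0
  for (pid in unique(dataset$participant)) {
    d <- dataset[dataset$participant == pid, ]
    d <- d[order(d$trial), ]
    total <- total + nll_one(d, params, model, opt_map, n_starts_total, npw, mid)
  }
  total
}

# parameter layout per model: names, lower, upper
model_par_spec <- function(model, include_persev = FALSE) {
  base <- switch(model,
    mf = list(names = c("alpha", "beta"), lower = c(1e-3, 1e-2),
              upper = c(1, 50)),
    mb = list(names = c("alpha", "beta"), lower = c(1e-3, 1e-2),
              upper = c(1, 50)),
    hybrid = list(names = c("alpha", "beta", "w"), lower = c(1e-3, 1e-2, 0),
                  upper = c(1, 50, 1)),
    replay_modulated = list(
      names = c("alpha", "beta", "beta_high", "beta_low"),
      lower = c(1e-3, 1e-2, 1e-2, 1e-2), upper = c(1, 50, 50, 50)),
    abort(paste0("Unknown model '", model, "'."),
          class = "replaykit_model_error"))
  if (include_persev) {
    base$names <- c(base$names, "persev")
    base$lower <- c(base$lower, -5)
    base$upper <- c(base$upper, 5)
  }
  base
}

par_vec_to_params <- function(x, names, model) {
  p <- as.list(x)
  names(p) <- names
  p$persev <- p$persev %||% 0
  p$w <- p$w %||% switch(model, mb = 1, mf = 0, replay_modulated = 1, 1)
  structure(p, class = "agent_params")
}

random_start <- function(spec) {
  vapply(seq_along(spec$names), function(i) {
    nm <- spec$names[i]
    if (nm == "alpha") runif(1, 0.05, 0.95)
    else if (nm %in% c("beta", "beta_high", "beta_low")) exp(runif(1, log(0.5), log(20)))
    else if (nm == "w") runif(1, 0.05, 0.95)
    else runif(1, -1, 1)
  }, numeric(1))
}

fit_one_participant <- function(d, model, spec, n_starts, opt_map,
                                n_starts_total, npw) {
  obj <- function(x) {
    nll_one(d, par_vec_to_params(x, spec$names, model), model, opt_map,
            n_starts_total, npw)
  }
  best <- NULL
  start_log <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    x0 <- random_start(spec)
    res <- tryCatch(
      optim(x0, obj, method = "L-BFGS-B", lower = spec$lower,
            upper = spec$upper, control = list(maxit = 200)),
      error = function(e) NULL)
    start_log[[s]] <- tibble(start = s, value = if (is.null(res)) NA_real_
                             else res$value,
                             converged = !is.null(res) && res$convergence == 0)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(list(est = setNames(rep(NA_real_, length(spec$names)), spec$names),
                nll = NA_real_, converged = FALSE,
                starts = list_rbind(start_log)))
  }
  list(est = setNames(best$par, spec$names), nll = best$value,
       converged = best$convergence == 0, starts = list_rbind(start_log))
}

#' Fit a reinforcement-learning model to each participant by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization of [nll_choices()] from
#' multiple random starting points, independently per participant, with
#' AIC/BIC penalized fit scores. Refitting with the same seed reproduces the
#' estimates exactly.
#'
#' @param dataset A `ChoiceDataset` tibble.
#' @param model `"mf"`, `"mb"` or `"hybrid"`.
#' @param n_starts Random restarts per participant (>= 5). Default 10.
#' @param seed Integer seed for the starting points.
#' @param include_persev Add a perseveration parameter. Default `FALSE`.
#' @return An object of class `rk_fit`: list with `fits` (tibble, one row per
#'   participant: estimates, `nll`, `aic`, `bic`, `converged`), `model`,
#'   `n_starts`, `start_log` (per-start objective values for diagnostics).
#' @export
fit_model <- function(dataset, model = "hybrid", n_starts = 10L, seed = 1L,
                      include_persev = FALSE) {
  if (n_starts < 5) abort("`n_starts` must be at least 5.",
                          class = "replaykit_param_error")
  spec <- model_par_spec(model, include_persev)
  opt_map <- derive_option_map(dataset)
  npw <- max(opt_map$choice)
  n_ss <- max(dataset$start_state)
  set.seed(seed)
  pids <- unique(dataset$participant)
  rows <- vector("list", length(pids))
  logs <- vector("list", length(pids))
  k <- length(spec$names)
  for (i in seq_along(pids)) {
    d <- dataset[dataset$participant == pids[i], ]
    d <- d[order(d$trial), ]
    n_obs <- sum(!is.na(d$choice))
    f <- fit_one_participant(d, model, spec, n_starts, opt_map, n_ss, npw)
    rows[[i]] <- tibble(participant = pids[i], !!!as.list(f$est),
                        nll = f$nll, aic = 2 * k + 2 * f$nll,
                        bic = k * log(n_obs) + 2 * f$nll,
                        converged = f$converged)
    logs[[i]] <- mutate(f$starts, participant = pids[i])
  }
  structure(list(fits = list_rbind(rows), model = model,
                 n_starts = as.integer(n_starts), k = k, seed = seed,
                 start_log = list_rbind(logs)),
            class = "rk_fit")
}

#' @export
print.rk_fit <- function(x, ...) {
  cat("<rk_fit> model:", x$model, "|", nrow(x$fits), "participants |",
      x$n_starts, "starts\n")
  print(x$fits)
  invisible(x)
}

#' @rdname fit_model
#' @param x,object An `rk_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rk_fit <- function(x, ...) {
  par_cols <- setdiff(names(x$fits),
                      c("participant", "nll", "aic", "bic", "converged"))
  tidyr::pivot_longer(x$fits[, c("participant", par_cols)],
                      -"participant", names_to = "term",
                      values_to = "estimate")
}

#' @rdname fit_model
#' @exportS3Method generics::glance
glance.rk_fit <- function(x, ...) {
  tibble(model = x$model, n_participants = nrow(x$fits), k = x$k,
         total_nll = sum(x$fits$nll), mean_aic = mean(x$fits$aic),
         mean_bic = mean(x$fits$bic),
         prop_converged = mean(x$fits$converged))
}

#' Fit the replay-modulated choice model
#'
#' Augments the base controller with two additional softmax inverse
#' temperatures that apply only on world-change trials, split by whether the
#' preceding feedback-period backward replay of the upcoming world was high
#' or low (labels from [replay_split_labels()]). Reports a one-tailed
#' Wilcoxon signed-rank test of `beta_high > beta_low` across participants.
#'
#' @param dataset A `ChoiceDataset` tibble.
#' @param replay_labels Tibble (participant, trial, replay_label in
#'   `"high"`/`"low"`), defined only on world-change trials.
#' @param n_starts,seed As in [fit_model()].
#' @param min_labeled Minimum labeled trials per cell below which a
#'   participant's fit is flagged. Default 3.
#' @return An `rk_fit` with extra elements `test` (list: statistic, p_value,
#'   one-tailed) and a `flagged` column in `fits`.
#' @export
fit_replay_modulated <- function(dataset, replay_labels, n_starts = 10L,
                                 seed = 1L, min_labeled = 3L) {
  # world-change indicator from the dataset's own ordering
  ds <- arrange(dataset, .data$participant, .data$trial)
  ds <- mutate(group_by(ds, .data$participant),
               world_change = as.integer(.data$world != lag(.data$world)))
  ds <- ungroup(ds)
  key <- paste(ds$participant, ds$trial)
  lab_key <- paste(replay_labels$participant, replay_labels$trial)
  bad <- lab_key[!lab_key %in% key[ds$world_change %in% 1L]]
  if (length(bad) > 0) {
    abort("Replay labels must be defined only on world-change trials.",
          class = "replaykit_label_error")
  }
  ds$replay_label <- replay_labels$replay_label[match(key, lab_key)]
  fit <- fit_model(ds, model = "replay_modulated", n_starts = n_starts,
                   seed = seed)
  counts <- summarise(group_by(filter(ds, !is.na(.data$replay_label)),
                               .data$participant, .data$replay_label),
                      n = n(), .groups = "drop")
  counts <- tidyr::pivot_wider(counts, names_from = "replay_label",
                               values_from = "n", values_fill = 0L)
  flagged <- counts$participant[pmin(counts$high %||% 0, counts$low %||% 0) <
                                  min_labeled]
  fit$fits$flagged <- fit$fits$participant %in% flagged
  diffs <- fit$fits$beta_high - fit$fits$beta_low
  diffs <- diffs[is.finite(diffs)]
  test <- if (length(diffs) >= 3) {
    wt <- suppressWarnings(wilcox.test(diffs, alternative = "greater"))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         alternative = "beta_high > beta_low (one-tailed)")
  } else {
    list(statistic = NA_real_, p_value = NA_real_,
         alternative = "beta_high > beta_low (one-tailed)")
  }
  fit$test <- test
  fit
}
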