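# Internal: replay the delta-rule value model through one participant's
# trials, recording the option values available at each choice.
value_series <- function(d, params, model, opt_map, n_starts_total, npw,
                         reward_mid = 4.5) {
  n <- nrow(d)
  Q <- matrix(reward_mid, n_starts_total, npw)
  V <- rep(reward_mid, max(opt_map$path))
  pmap_mat <- matrix(NA_integer_, max(d$world), npw)
  pmap_mat[cbind(opt_map$world, opt_map$choice)] <- opt_map$path
  w <- params$w %||% 1
  v1 <- v2 <- v_chosen <- numeric(n)
  for (t in seq_len(n)) {
    wld <- d$world[t]; ss <- d$start_state[t]
    paths_t <- pmap_mat[wld, ]
    v <- switch(model, mf = Q[ss, ], mb = V[paths_t],
                w * V[paths_t] + (1 - w) * Q[ss, ])
    v1[t] <- v[1]; v2[t] <- v[2]
    ch <- d$choice[t]
    v_chosen[t] <- if (is.na(ch)) NA_real_ else v[ch]
    p <- d$path[t]; r <- d$reward[t]
    if (!is.na(p) && !is.na(r)) {
      if (!is.na(ch)) Q[ss, ch] <- Q[ss, ch] + params$alpha * (r - Q[ss, ch])
      V[p] <- V[p] + params$alpha * (r - V[p])
    }
  }
  tibble(trial = d$trial, v_opt1 = v1, v_opt2 = v2,
         v_mean = (v1 + v2) / 2, v_chosen = v_chosen)
}

#' Assemble the per-trial regressor table for replay-behavior linking
#'
#' Aligns, per trial: the start-state generalization indicators (different
#' versus same start as the previous same-world trial), the mean
#' model-predicted state value (average of the two options' values under
#' the fitted controller), the rarity of the current and other world
#' (exponentially weighted experience tracker, including the current
#' trial's appearance), reward, reward prediction error (reward minus the
#' fitted value of the chosen option), trial index, and the world-change
#' indicators used for the replay-modulated choice model.
#'
#' @param dataset A `ChoiceDataset` tibble.
#' @param fit An [fit_model()] `rk_fit` providing per-participant parameter
#'   estimates for the model-predicted values.
#' @param rarity_rate Experience learning rate. Default 0.10.
#' @return A tibble, one row per trial, with the covariates above; rows of
#'   each world's first trial carry `NA` start-state indicators.
#' @export
build_regressor_table <- function(dataset, fit, rarity_rate = 0.10) {
  stopifnot(inherits(fit, "rk_fit"))
  d <- derive_trial_covariates(dataset)
  opt_map <- derive_option_map(dataset)
  npw <- max(opt_map$choice)
  n_ss <- max(dataset$start_state)
  n_worlds <- max(dataset$world)
  out <- vector("list", length(unique(d$participant)))
  pids <- unique(d$participant)
  for (i in seq_along(pids)) {
    di <- filter(d, .data$participant == pids[i])
    di <- arrange(di, .data$trial)
    est <- filter(fit$fits, .data$participant == pids[i])
    if (nrow(est) != 1) {
      abort(paste0("No fit for participant ", pids[i], "."),
            class = "replaykit_data_error")
    }
    params <- list(alpha = est$alpha, beta = est$beta,
                   w = if ("w" %in% names(est)) est$w else NULL)
    vs <- value_series(di, params, fit$model, opt_map, n_ss, npw)
    if (nrow(vs) != nrow(di)) {
      abort("Misaligned trial counts between dataset and value series.",
            class = "replaykit_data_error")
    }
    rs <- rarity_series(di$world, n_worlds = n_worlds, rate = rarity_rate)
    cur <- filter(rs, .data$world == di$world[.data$trial])
    rar_cur <- vapply(seq_len(nrow(di)), function(t)
      rs$rarity[rs$trial == t & rs$world == di$world[t]], numeric(1))
    rar_oth <- vapply(seq_len(nrow(di)), function(t)
      mean(rs$rarity[rs$trial == t & rs$world != di$world[t]]), numeric(1))
    out[[i]] <- tibble(
      participant = pids[i], trial = di$trial, world = di$world,
      different_start = di$different_start, same_start = di$same_start,
      mean_value = vs$v_mean, rarity_other = rar_oth,
      rarity_current = rar_cur, reward = di$reward,
      rpe = di$reward - vs$v_chosen, stakes = di$stakes,
      world_change = di$world_change,
      world_change_next = di$world_change_next,
      other_not_recent = 1L - di$world_change)
  }
  list_rbind(out)
}

#' Multilevel regression linking trial-wise sequenceness to task variables
#'
#' Regresses trial-wise sequenceness scores (z-scored within participant by
#' default) on a set of per-trial regressors with a random intercept and a
#' random slope of the first regressor per participant (falling back to a
#' random-intercept model, then ordinary regression, on non-convergence).
#' TOST equivalence p values are appended for designated terms.
#'
#' @param scores A [trialwise_sequenceness()] tibble.
#' @param table A [build_regressor_table()] tibble.
#' @param regressors Character vector of column names in `table`.
#' @param direction `"fwd"` or `"bwd"`: which score column to model.
#' @param zscore_scores Standardize scores within participant. Default TRUE.
#' @param tost_terms Terms for which to report TOST equivalence p values.
#' @param tost_bound Equivalence bound on the (standardized-score) outcome
#'   scale. Default `0.5 / sqrt(3) * pi / 2` is *not* used; the default is
#'   half the within-participant score SD times d = 0.5, i.e. 0.5 in
#'   standardized units — see [tost_bound_medium()] applied on a linear
#'   scale: bound = 0.5 * sd(score) per unit regressor SD. Supply a number
#'   to override.
#' @param one_tailed_terms Terms whose p values are reported one-tailed
#'   (positive direction), matching analyses with a directional prediction.
#' @return A `replay_glm` whose table has one row per term with estimate,
#'   95% CI, statistic, p, sidedness and (where requested) `tost_p`.
#' @export
link_glm <- function(scores, table, regressors, direction = c("fwd", "bwd"),
                     zscore_scores = TRUE, tost_terms = NULL,
                     tost_bound = NULL, one_tailed_terms = NULL) {
  direction <- match.arg(direction)
  d <- left_join(scores, table, by = c("participant", "trial"))
  d$score <- d[[direction]]
  if (zscore_scores) {
    d <- mutate(group_by(d, .data$participant),
                score = as.numeric(scale(.data$score)))
    d <- ungroup(d)
  }
  keep <- stats::complete.cases(d[, c("score", regressors)])
  d <- d[keep, ]
  # drop all-constant regressors
  const <- vapply(regressors, function(r) var(d[[r]]) == 0, logical(1))
  if (any(const)) {
    inform(paste0("Dropping constant regressor(s): ",
                  paste(regressors[const], collapse = ", ")))
    regressors <- regressors[!const]
  }
  if (length(regressors) == 0) {
    abort("No non-constant regressors left.", class = "replaykit_data_error")
  }
  rhs <- paste(regressors, collapse = " + ")
  multi <- length(unique(d$participant)) > 1
  if (multi) {
    f_slope <- stats::as.formula(paste0(
      "score ~ ", rhs, " + (1 + ", regressors[1], " | participant)"))
    f_int <- stats::as.formula(paste0("score ~ ", rhs, " + (1 | participant)"))
    fits <- list(function() lmerTest::lmer(f_slope, data = d),
                 function() lmerTest::lmer(f_int, data = d))
    labels <- c(paste0("lmer (1 + ", regressors[1], " | participant)"),
                "lmer (1 | participant)")
  } else {
    f_lm <- stats::as.formula(paste0("score ~ ", rhs))
    fits <- list(function() lm(f_lm, data = d))
    labels <- "lm (single participant)"
  }
  f <- fit_with_fallback(fits, labels)
  tab <- fixef_table(f$model, "t")
  if (!is.null(one_tailed_terms)) {
    sel <- tab$term %in% one_tailed_terms
    tab$p_value[sel] <- pnorm(tab$statistic[sel], lower.tail = FALSE)
    tab$sidedness[sel] <- "one-tailed (positive)"
  }
  if (!is.null(tost_terms)) {
    b <- tost_bound %||% 0.5 # standardized-score units per unit regressor
    tab$tost_p <- NA_real_
    for (tm in tost_terms) {
      sel <- tab$term == tm
      if (any(sel)) {
        tab$tost_p[sel] <- tost_equivalence(tab$estimate[sel],
                                            tab$std_error[sel], b)$p_equiv
      }
    }
  }
  new_replay_glm(tab, f$model, f$engine, f$fallback,
                 paste0("sequenceness (", direction, ") linking regression"))
}

#' Regression coefficient of a replay-behavior link as a function of lag
#'
#' Repeats [link_glm()] at every lag present in the scores and extracts one
#' regressor's coefficient, producing the lag profile of an effect (e.g.
#' generalization benefit over 10-130 ms).
#'
#' @param scores_by_lag Trial-wise scores stacked over lags (rows carry a
#'   `lag_ms` column), e.g. several [trialwise_sequenceness()] calls bound
#'   together.
#' @param table A [build_regressor_table()] tibble.
#' @param regressor Single regressor name whose coefficient is profiled.
#' @param direction `"fwd"` or `"bwd"`.
#' @param ... Passed to [link_glm()].
#' @return Tibble of class `lag_profile`: lag_ms, estimate, ci_low, ci_high,
#'   statistic, p_value.
#' @export
lag_profile <- function(scores_by_lag, table, regressor,
                        direction = c("fwd", "bwd"), ...) {
  direction <- match.arg(direction)
  lags <- sort(unique(scores_by_lag$lag_ms))
  rows <- lapply(lags, function(lg) {
    res <- link_glm(filter(scores_by_lag, .data$lag_ms == lg), table,
                    regressors = regressor, direction = direction, ...)
    row <- filter(res$table, .data$term == regressor)
    mutate(select(row, -"term"), lag_ms = lg, .before = 1)
  })
  out <- list_rbind(rows)
  class(out) <- c("lag_profile", class(out))
  attr(out, "regressor") <- regressor
  out
}

#' Across-participant correlation of two per-participant effects
#'
#' @param effect_a,effect_b Paired numeric vectors, one entry per
#'   participant (>= 3).
#' @param alternative Sidedness passed to [cor.test()]. Default two-sided.
#' @return List: `r`, `p`, `n`, `alternative`, `flagged` (TRUE when a
#'   vector has zero variance, in which case r is NA).
#' @export
across_participant_correlation <- function(effect_a, effect_b,
                                           alternative = "two.sided") {
  if (length(effect_a) != length(effect_b) || length(effect_a) < 3) {
    abort("Need paired vectors with at least 3 participants.",
          class = "replaykit_data_error")
  }
  if (sd(effect_a) == 0 || sd(effect_b) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(effect_a),
                alternative = alternative, flagged = TRUE))
  }
  ct <- cor.test(effect_a, effect_b, alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(effect_a),
       alternative = alternative, flagged = FALSE)
}

#' One-tailed z test for a difference between two regression coefficients
#'
#' Independent-variances form: `z = (a - b) / sqrt(se_a^2 + se_b^2)`; used
#' to test whether one period's replay-behavior effect is stronger than the
#' other's.
#'
#' @param coef_a,se_a,coef_b,se_b Coefficients and positive standard errors.
#' @param alternative `"greater"` (a > b, default), `"less"` or
#'   `"two.sided"`.
#' @return List: `z`, `p`, `alternative`.
#' @export
dissociation_test <- function(coef_a, se_a, coef_b, se_b,
                              alternative = c("greater", "less",
                                              "two.sided")) {
  alternative <- match.arg(alternative)
  if (se_a <= 0 || se_b <= 0) {
    abort("Standard errors must be positive.",
          class = "replaykit_param_error")
  }
  z <- (coef_a - coef_b) / sqrt(se_a^2 + se_b^2)
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two.sided = 2 * pnorm(-abs(z)))
  list(z = z, p = p, alternative = alternative)
}

#' High/low labels from preceding feedback replay for world-change trials
#'
#' Implements the split feeding the replay-modulated choice model: on
#' trials that precede a world change, the feedback-period backward
#' sequenceness (of the upcoming world, i.e. the current trial's other
#' world) is median-split within participant; the resulting high/low label
#' is attached to the *following* trial — the world-change choice trial.
#' Ties at the median go to "low". Participants whose eligible scores are
#' all equal are flagged as degenerate.
#'
#' @param scores Trial-wise feedback-period backward scores
#'   ([trialwise_sequenceness()] tibble; the `bwd` column is used).
#' @param table A [build_regressor_table()] tibble (provides
#'   `world_change_next`).
#' @return Tibble: participant, trial (the labeled world-change choice
#'   trial), replay_label ("high"/"low"); attribute `degenerate` lists
#'   flagged participants.
#' @export
replay_split_labels <- function(scores, table) {
  d <- left_join(scores, table[, c("participant", "trial",
                                   "world_change_next")],
                 by = c("participant", "trial"))
  d <- filter(d, .data$world_change_next %in% 1L)
  degenerate <- c()
  out <- vector("list", length(unique(d$participant)))
  pids <- unique(d$participant)
  for (i in seq_along(pids)) {
    di <- filter(d, .data$participant == pids[i])
    med <- median(di$bwd)
    if (all(di$bwd == di$bwd[1])) degenerate <- c(degenerate, pids[i])
    out[[i]] <- tibble(participant = pids[i], trial = di$trial + 1L,
                       replay_label = ifelse(di$bwd > med, "high", "low"))
  }
  res <- list_rbind(out)
  if (length(degenerate) > 0) {
    inform(paste0("Degenerate (all-equal) replay split for participant(s): ",
                  paste(degenerate, collapse = ", ")))
  }
  attr(res, "degenerate") <- degenerate
  res
}
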