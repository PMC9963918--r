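#' Derive trial-wise behavioral covariates
#'
#' Adds, per participant, the covariates behavioral analyses condition on.
#' All "previous" references point to the previous trial *in the same
#' world*, not the previous trial overall: `stay` (chosen path equals the
#' previous same-world path), `same_start` / `different_start` (start-state
#' identity versus the previous same-world trial), `prev_reward` (reward of
#' the previous same-world trial) and its within-participant z-score
#' `prev_reward_z`, plus `world_change` (world differs from the immediately
#' preceding trial) and `world_change_next`. Covariates are `NA` on each
#' world's first trial.
#'
#' @param raw A `ChoiceDataset` tibble (participant, trial, world,
#'   start_state, choice, path, reward, ...).
#' @return The input with covariate columns appended.
#' @export
derive_trial_covariates <- function(raw) {
  if (anyNA(raw$world)) {
    abort("Unknown (NA) world label in dataset.",
          class = "replaykit_data_error")
  }
  d <- arrange(raw, .data$participant, .data$trial)
  d <- mutate(group_by(d, .data$participant),
              world_change = as.integer(.data$world != lag(.data$world)),
              world_change_next = lead(.data$world_change))
  d <- mutate(group_by(d, .data$participant, .data$world),
              prev_path = lag(.data$path),
              prev_start = lag(.data$start_state),
              prev_reward = lag(.data$reward))
  d <- mutate(ungroup(d, "world"),
              stay = as.integer(.data$path == .data$prev_path),
              same_start = as.integer(.data$start_state == .data$prev_start),
              different_start = 1L - .data$same_start,
              prev_reward_z = as.numeric(scale(.data$prev_reward)))
  ungroup(d)
}

# Fit a mixed model with a declared fallback chain; returns list(model,
# engine, fallback). `fits` is a list of functions returning a fitted model.
fit_with_fallback <- function(fits, labels) {
  for (i in seq_along(fits)) {
    ok <- TRUE
    m <- withCallingHandlers(
      tryCatch(fits[[i]](), error = function(e) NULL),
      warning = function(w) {
        if (grepl("converge|Hessian|singular", conditionMessage(w),
                  ignore.case = TRUE)) ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (!is.null(m) && inherits(m, "merMod")) {
      msgs <- m@optinfo$conv$lme4$messages
      if (!is.null(msgs) && length(msgs) > 0) ok <- FALSE
      if (lme4::isSingular(m)) ok <- FALSE
    }
    if (!is.null(m) && (ok || i == length(fits))) {
      if (!ok) inform(paste0("Model '", labels[i],
                             "' did not converge cleanly; using it as the ",
                             "last fallback."))
      if (i > 1) inform(paste0("Falling back to model '", labels[i], "'."))
      return(list(model = m, engine = labels[i], fallback = i > 1))
    }
  }
  abort("All models in the fallback chain failed.",
        class = "replaykit_fit_error")
}

# Wald summary of fixed effects as a tibble
fixef_table <- function(model, stat_label = "z") {
  if (inherits(model, "merMod")) {
    cf <- summary(model)$coefficients
  } else {
    cf <- summary(model)$coefficients
  }
  est <- cf[, 1]; se <- cf[, 2]
  stat <- est / se
  p <- if (stat_label == "z") 2 * pnorm(-abs(stat)) else {
    pcol <- grep("^Pr", colnames(cf))
    if (length(pcol) == 1) cf[, pcol] else 2 * pnorm(-abs(stat))
  }
  tibble(term = rownames(cf), estimate = est, std_error = se,
         ci_low = est - qnorm(0.975) * se, ci_high = est + qnorm(0.975) * se,
         statistic = stat, p_value = as.numeric(p),
         sidedness = "two-sided")
}

new_replay_glm <- function(table, model, engine, fallback, kind) {
  structure(list(table = table, model = model, engine = engine,
                 fallback = fallback, kind = kind),
            class = "replay_glm")
}

#' @export
print.replay_glm <- function(x, ...) {
  cat("<replay_glm> ", x$kind, " (", x$engine,
      if (x$fallback) ", fallback" else "", ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @rdname stay_glm
#' @param x,object A `replay_glm`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.replay_glm <- function(x, ...) x$table

#' @rdname stay_glm
#' @exportS3Method generics::glance
glance.replay_glm <- function(x, ...) {
  tibble(kind = x$kind, engine = x$engine, fallback = x$fallback,
         n_terms = nrow(x$table))
}

#' Multilevel logistic regression of stay choices
#'
#' The model-based generalization test: stay (repeating the previous
#' same-world path) is regressed on the previous same-world reward
#' (z-scored within participant), the same-start indicator, and their
#' interaction, with a random intercept and random reward slope per
#' participant. A purely model-based learner transfers reward across start
#' states, so the interaction is asymptotically zero; a model-free learner
#' produces a positive interaction. On non-convergence the random-slope
#' model falls back to a random-intercept model; with a single participant
#' an ordinary logistic regression is used (flagged via the `engine`).
#'
#' @param data A [derive_trial_covariates()] dataset.
#' @return A `replay_glm` with a coefficient `table` (estimate, Wald 95% CI,
#'   z, p), the fitted model, and the engine used.
#' @export
stay_glm <- function(data) {
  need <- c("stay", "prev_reward_z", "same_start")
  if (!all(need %in% names(data))) {
    abort("Run derive_trial_covariates() first.",
          class = "replaykit_data_error")
  }
  d <- filter(data, !is.na(.data$stay) & !is.na(.data$prev_reward_z) &
                !is.na(.data$same_start))
  multi <- length(unique(d$participant)) > 1
  if (multi) {
    fits <- list(
      function() lme4::glmer(
        stay ~ prev_reward_z * same_start + (1 + prev_reward_z | participant),
        data = d, family = binomial,
        control = lme4::glmerControl(calc.derivs = FALSE)),
      function() lme4::glmer(
        stay ~ prev_reward_z * same_start + (1 | participant),
        data = d, family = binomial,
        control = lme4::glmerControl(calc.derivs = FALSE)))
    labels <- c("glmer (1 + prev_reward_z | participant)",
                "glmer (1 | participant)")
  } else {
    fits <- list(function() glm(stay ~ prev_reward_z * same_start,
                                data = d, family = binomial))
    labels <- "glm (single participant)"
  }
  f <- fit_with_fallback(fits, labels)
  new_replay_glm(fixef_table(f$model, "z"), f$model, f$engine, f$fallback,
                 "stay choice logistic regression")
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Rejects the presence of an effect larger than `bound` in either
#' direction: `p_equiv` is the larger of the two one-sided p values against
#' the bounds `-bound` and `+bound`. A small `p_equiv` supports equivalence
#' (the effect lies inside the bounds).
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param bound Symmetric equivalence bound (> 0). See
#'   [tost_bound_medium()] for the default used for stay-GLM interactions.
#' @return List: `p_equiv`, `p_lower`, `p_upper`, `bound`.
#' @examples
#' tost_equivalence(0.03, 0.05, bound = 0.9)$p_equiv
#' @export
tost_equivalence <- function(estimate, se, bound) {
  if (bound <= 0) abort("`bound` must be positive.",
                        class = "replaykit_param_error")
  if (se <= 0) abort("`se` must be positive.",
                     class = "replaykit_param_error")
  p_lower <- 1 - pnorm((estimate + bound) / se) # H0: effect <= -bound
  p_upper <- pnorm((estimate - bound) / se)     # H0: effect >= +bound
  list(p_equiv = max(p_lower, p_upper), p_lower = p_lower,
       p_upper = p_upper, bound = bound)
}

#' Equivalence bound for a medium standardized effect on the log-odds scale
#'
#' Maps a standardized effect size d to logistic-regression log-odds units
#' via the logistic scale factor pi/sqrt(3), times the regressor's SD.
#' With d = 0.5 and a unit-SD regressor the bound is about 0.907.
#'
#' @param d Standardized effect size. Default 0.5 (medium).
#' @param sd_x Regressor standard deviation. Default 1 (z-scored).
#' @return Numeric bound in log-odds units.
#' @export
tost_bound_medium <- function(d = 0.5, sd_x = 1) d * pi / sqrt(3) * sd_x

#' Multilevel regression of reaction times on start-state change
#'
#' Linear mixed model of RT on the different-start indicator with a random
#' intercept per participant. Nonpositive RTs are dropped with a message;
#' a single participant degrades to ordinary regression (flagged).
#'
#' @param data A [derive_trial_covariates()] dataset with an `rt` column in
#'   seconds.
#' @return A `replay_glm`.
#' @export
rt_glm <- function(data) {
  if (!"different_start" %in% names(data)) {
    abort("Run derive_trial_covariates() first.",
          class = "replaykit_data_error")
  }
  bad <- sum(data$rt <= 0, na.rm = TRUE)
  if (bad > 0) inform(paste0("Dropping ", bad, " nonpositive RT(s)."))
  d <- filter(data, .data$rt > 0 & !is.na(.data$different_start))
  multi <- length(unique(d$participant)) > 1
  if (multi) {
    fits <- list(function() lmerTest::lmer(
      rt ~ different_start + (1 | participant), data = d))
    labels <- "lmer (1 | participant)"
  } else {
    inform("Single participant: using ordinary least squares.")
    fits <- list(function() lm(rt ~ different_start, data = d))
    labels <- "lm (single participant)"
  }
  f <- fit_with_fallback(fits, labels)
  new_replay_glm(fixef_table(f$model, "t"), f$model, f$engine, f$fallback,
                 "reaction time regression")
}

#' Summarize structure-memory probe performance
#'
#' A probe is correct only if the correct stimulus was selected at all three
#' path stages; probes with a missing stage are excluded (with a message).
#' Percent correct is reported per block and overall, with bootstrap
#' percentile CIs over probes, plus mean confidence where available.
#'
#' @param probes Long tibble: participant, block, probe, stage, correct
#'   (0/1), optionally confidence (1-4, constant within probe).
#' @param n_stages Stages per probe. Default 3.
#' @param n_boot Bootstrap draws for the CIs. Default 2000.
#' @param seed Integer seed for the bootstrap.
#' @return List: `per_block` (tibble: block, pct_correct, ci_low, ci_high,
#'   mean_confidence, n_probes), `overall` (one-row tibble),
#'   `n_excluded`.
#' @export
memory_summary <- function(probes, n_stages = 3L, n_boot = 2000L, seed = 1L) {
  by_probe <- summarise(
    group_by(probes, .data$participant, .data$block, .data$probe),
    n_stage = n(), all_correct = as.integer(all(.data$correct == 1)),
    confidence = if ("confidence" %in% names(probes))
      mean(.data$confidence) else NA_real_,
    .groups = "drop")
  incomplete <- by_probe$n_stage < n_stages
  if (any(incomplete)) {
    inform(paste0("Excluding ", sum(incomplete),
                  " incomplete probe(s) (missing stage)."))
  }
  bp <- by_probe[!incomplete, ]
  set.seed(seed)
  boot_ci <- function(x) {
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
    unname(quantile(bm, c(0.025, 0.975)))
  }
  per_block <- summarise(group_by(bp, .data$block),
                         pct_correct = 100 * mean(.data$all_correct),
                         ci_low = 100 * boot_ci(.data$all_correct)[1],
                         ci_high = 100 * boot_ci(.data$all_correct)[2],
                         mean_confidence = mean(.data$confidence),
                         n_probes = n(), .groups = "drop")
  overall <- tibble(pct_correct = 100 * mean(bp$all_correct),
                    ci_low = 100 * boot_ci(bp$all_correct)[1],
                    ci_high = 100 * boot_ci(bp$all_correct)[2],
                    mean_confidence = mean(bp$confidence),
                    n_probes = nrow(bp))
  list(per_block = per_block, overall = overall,
       n_excluded = sum(incomplete))
}
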