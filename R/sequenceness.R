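#' First TDLM stage: empirical lagged state-to-state matrix
#'
#' For one reactivation probability matrix (time by state, on a regular
#' sampling grid), regresses each state's time series on the time courses of
#' all states lagged by `lag_ms`, entered jointly with an intercept. Entry
#' (i, j) of the result is the coefficient with which lagged state i predicts
#' state j.
#'
#' @param react Numeric matrix, time samples by states, values typically
#'   classifier probabilities in \[0, 1\].
#' @param lag_ms Lag in milliseconds; must be a multiple of `sample_ms`.
#' @param sample_ms Sampling step of the series in ms. Default 10.
#' @param zscore Standardize each state's series before the regression.
#'   Default `FALSE`.
#' @return A states-by-states numeric matrix of regression coefficients.
#' @export
stage1_empirical <- function(react, lag_ms, sample_ms = 10, zscore = FALSE) {
  react <- as.matrix(react)
  L <- lag_ms / sample_ms
  if (abs(L - round(L)) > 1e-9 || L < 1) {
    abort("`lag_ms` must be a positive multiple of the sampling step.",
          class = "replaykit_lag_error")
  }
  L <- as.integer(round(L))
  n_t <- nrow(react); n_s <- ncol(react)
  if (n_t < L + 2) {
    abort("Window must be at least lag + 2 samples long.",
          class = "replaykit_lag_error")
  }
  if (zscore) {
    sds <- apply(react, 2, sd)
    mus <- colMeans(react)
    ok <- sds > 0
    react[, ok] <- sweep(sweep(react[, ok, drop = FALSE], 2, mus[ok]),
                         2, sds[ok], "/")
  }
  X <- react[seq_len(n_t - L), , drop = FALSE]
  Y <- react[(L + 1):n_t, , drop = FALSE]
  D <- cbind(1, X)
  XtX <- crossprod(D)
  XtY <- crossprod(D, Y)
  B <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  if (is.null(B)) {
    # rank-deficient design (e.g. constant series): pivoted QR, aliased
    # predictors get coefficient 0
    warn("Rank-deficient lagged design; aliased coefficients set to 0.",
         class = "replaykit_rank_warning")
    qd <- qr(D)
    B <- qr.coef(qd, Y)
    B[is.na(B)] <- 0
  }
  B <- B[-1, , drop = FALSE] # drop intercept row
  dimnames(B) <- list(predictor = NULL, outcome = NULL)
  B
}

#' Second TDLM stage: regression onto structural transition matrices
#'
#' Regresses the vectorized empirical matrix jointly on the vectorized
#' forward, backward, constant and self-transition indicator matrices. The
#' forward/backward coefficients are the sequenceness measures; the constant
#' matrix absorbs background dynamics and the identity absorbs
#' autocorrelation.
#'
#' @param empirical States-by-states matrix from [stage1_empirical()].
#' @param spec A [transition_spec()].
#' @param paths Optional integer subset of paths; restricts `T_F`/`T_B` to
#'   those paths' transitions (controls unchanged), e.g. for current- versus
#'   other-world scoring.
#' @return Named numeric vector `c(fwd, bwd, cons, auto)`.
#' @export
stage2_sequenceness <- function(empirical, spec, paths = NULL) {
  dm <- directional_matrices(spec, paths)
  Z <- cbind(fwd = as.vector(dm$T_F), bwd = as.vector(dm$T_B),
             cons = as.vector(spec$T_cons), auto = as.vector(spec$T_auto))
  y <- as.vector(as.matrix(empirical))
  beta <- solve(crossprod(Z), crossprod(Z, y))
  setNames(as.vector(beta), colnames(Z))
}

# ---- internal: per-participant mean empirical matrices by lag ------------
# reacts: tibble with columns participant, react (list of [time x state]).
# Returns list(lags_kept, emp = list over lags of list over participants of
# mean matrices). Lags longer than a window minus 2 samples are dropped.
empirical_by_lag <- function(reacts, lags_ms, sample_ms = 10, zscore = FALSE) {
  min_t <- min(vapply(reacts$react, nrow, integer(1)))
  n_s <- ncol(reacts$react[[1]])
  # a lag is estimable only if the lagged design (n_s predictors +
  # intercept) has more rows than columns
  keep <- min_t - lags_ms / sample_ms >= n_s + 2
  if (any(!keep)) {
    inform(paste0("Dropping ", sum(!keep),
                  " lag(s) longer than the analysis window allows."))
  }
  lags_ms <- lags_ms[keep]
  pids <- unique(reacts$participant)
  emp <- lapply(lags_ms, function(lg) {
    lapply(pids, function(pid) {
      mats <- reacts$react[reacts$participant == pid]
      ms <- lapply(mats, stage1_empirical, lag_ms = lg,
                   sample_ms = sample_ms, zscore = zscore)
      Reduce(`+`, ms) / length(ms)
    })
  })
  list(lags_ms = lags_ms, participants = pids, emp = emp)
}

#' Sequenceness as a function of state-to-state lag
#'
#' Runs the full two-stage TDLM per participant: stage-1 empirical matrices
#' are computed per trial and averaged within participant, then stage 2 is
#' applied at every lag of the grid. The group curve is the participant mean.
#'
#' @param reacts A tibble with columns `participant`, `trial` and `react`
#'   (list-column of time-by-state matrices), e.g. from
#'   [generate_reactivation_series()].
#' @param spec A [transition_spec()].
#' @param lags_ms Lag grid in ms. Default 10 to 600 by 10 (60 lags).
#' @param sample_ms Sampling step in ms. Default 10.
#' @param zscore Standardize series before stage 1. Default `FALSE`.
#' @return A tibble of class `sequenceness_result`: participant, lag_ms,
#'   fwd, bwd (one row per participant and lag).
#' @seealso [group_curve()], [permutation_threshold()], [autoplot.sequenceness_result()]
#' @export
sequenceness_curve <- function(reacts, spec, lags_ms = seq(10, 600, by = 10),
                               sample_ms = 10, zscore = FALSE) {
  eb <- empirical_by_lag(reacts, lags_ms, sample_ms, zscore)
  rows <- vector("list", length(eb$lags_ms))
  for (i in seq_along(eb$lags_ms)) {
    co <- vapply(eb$emp[[i]],
                 function(m) stage2_sequenceness(m, spec)[c("fwd", "bwd")],
                 numeric(2))
    rows[[i]] <- tibble(participant = eb$participants,
                        lag_ms = eb$lags_ms[i],
                        fwd = co[1, ], bwd = co[2, ])
  }
  out <- arrange(list_rbind(rows), .data$participant, .data$lag_ms)
  class(out) <- c("sequenceness_result", class(out))
  attr(out, "sample_ms") <- sample_ms
  out
}

#' Group-mean sequenceness curve
#'
#' @param result A [sequenceness_curve()] result.
#' @return Tibble: lag_ms, fwd, bwd (participant means), fwd_sem, bwd_sem.
#' @export
group_curve <- function(result) {
  summarise(group_by(as_tibble(result), .data$lag_ms),
            fwd_sem = sd(.data$fwd) / sqrt(n()),
            bwd_sem = sd(.data$bwd) / sqrt(n()),
            fwd = mean(.data$fwd), bwd = mean(.data$bwd),
            .groups = "drop")
}

#' Permutation significance threshold for sequenceness curves
#'
#' Builds the null distribution by re-assigning the 12 states to path
#' positions: for each draw, a random relabeling of states is applied to the
#' forward/backward transition matrices (controls unchanged), stage 2 is
#' recomputed at every lag from the unchanged stage-1 matrices, and the
#' absolute maximum of the group-mean curve across lags is recorded per
#' direction. The threshold is the 95th percentile of these maxima.
#' Relabelings that leave the forward transition matrix unchanged (the
#' identity and whole-path relabelings) are excluded from the null set.
#'
#' @inheritParams sequenceness_curve
#' @param n_perms Number of permutation draws (>= 100 recommended; fewer
#'   triggers a warning). Default 500.
#' @param seed Integer seed for the draws.
#' @param probs Percentile of the null maxima to report. Default 0.95.
#' @return List: `fwd`, `bwd` (across-lag thresholds), `per_lag` (tibble of
#'   per-lag uncorrected thresholds), `draws` (tibble of per-permutation
#'   maxima), `n_perms`, `seed`.
#' @export
permutation_threshold <- function(reacts, spec, n_perms = 500L, seed = 1L,
                                  lags_ms = seq(10, 600, by = 10),
                                  sample_ms = 10, zscore = FALSE,
                                  probs = 0.95) {
  if (n_perms < 100) {
    warn(paste0("Only ", n_perms, " permutations; p resolution is 1/",
                n_perms + 1, "."))
  }
  eb <- empirical_by_lag(reacts, lags_ms, sample_ms, zscore)
  set.seed(seed)
  n_s <- spec$n_states
  perms <- list(); tries <- 0L
  max_tries <- 200L * n_perms
  while (length(perms) < n_perms && tries < max_tries) {
    tries <- tries + 1L
    p <- sample.int(n_s)
    Tp <- permute_states(spec$T_F, p)
    if (identical(Tp, spec$T_F)) next
    key <- paste(p, collapse = ",")
    if (!is.null(perms[[key]])) next
    perms[[key]] <- p
  }
  if (length(perms) < n_perms) {
    inform(paste0("Permutation space exhausted; using ", length(perms),
                  " unique relabelings."))
  }
  n_used <- length(perms)

  Z_cons <- as.vector(spec$T_cons)
  Z_auto <- as.vector(spec$T_auto)
  n_lag <- length(eb$lags_ms)
  # vectorized empirical matrices: per lag a matrix [144 x participants]
  Ymats <- lapply(eb$emp, function(l) vapply(l, as.vector,
                                             numeric(n_s * n_s)))
  draws <- matrix(NA_real_, n_used, 2,
                  dimnames = list(NULL, c("fwd", "bwd")))
  per_lag_draws <- array(NA_real_, c(n_used, n_lag, 2))
  for (k in seq_len(n_used)) {
    p <- perms[[k]]
    dm_f <- as.vector(permute_states(spec$T_F, p))
    dm_b <- as.vector(permute_states(spec$T_B, p))
    Z <- cbind(dm_f, dm_b, Z_cons, Z_auto)
    ZtZi <- solve(crossprod(Z))
    H <- ZtZi %*% t(Z) # 4 x 144
    for (i in seq_len(n_lag)) {
      co <- H %*% Ymats[[i]] # 4 x participants
      per_lag_draws[k, i, 1] <- mean(co[1, ])
      per_lag_draws[k, i, 2] <- mean(co[2, ])
    }
    draws[k, 1] <- max(abs(per_lag_draws[k, , 1]))
    draws[k, 2] <- max(abs(per_lag_draws[k, , 2]))
  }
  per_lag <- tibble(
    lag_ms = eb$lags_ms,
    fwd = apply(abs(per_lag_draws[, , 1, drop = FALSE]), 2, quantile,
                probs = probs),
    bwd = apply(abs(per_lag_draws[, , 2, drop = FALSE]), 2, quantile,
                probs = probs))
  list(fwd = unname(quantile(draws[, "fwd"], probs = probs)),
       bwd = unname(quantile(draws[, "bwd"], probs = probs)),
       per_lag = per_lag,
       draws = as_tibble(draws), perms = unname(perms),
       n_perms = n_used, seed = seed)
}

# Stage 2 with separate directional regressors per path group, so that
# sequence structure on one group cannot leak into the other group's
# coefficient through the shared constant control. Returns the (fwd, bwd)
# pair of the first group.
stage2_subset <- function(empirical, spec, paths_of_interest) {
  other <- setdiff(seq_along(spec$paths), paths_of_interest)
  dm_a <- directional_matrices(spec, paths_of_interest)
  cols <- list(fwd = as.vector(dm_a$T_F), bwd = as.vector(dm_a$T_B))
  if (length(other) > 0) {
    dm_b <- directional_matrices(spec, other)
    cols$fwd_rest <- as.vector(dm_b$T_F)
    cols$bwd_rest <- as.vector(dm_b$T_B)
  }
  cols$cons <- as.vector(spec$T_cons)
  cols$auto <- as.vector(spec$T_auto)
  Z <- do.call(cbind, cols)
  beta <- solve(crossprod(Z), crossprod(Z, as.vector(as.matrix(empirical))))
  setNames(as.vector(beta), names(cols))[c("fwd", "bwd")]
}

#' Trial-wise sequenceness at a fixed lag
#'
#' Scores every trial's reactivation matrix with the two TDLM stages at a
#' single analysis lag. When scoring only the trial's current-world or
#' other-world paths, the directional matrices of *both* path subsets are
#' entered jointly in stage 2 (controls unchanged) and the requested
#' subset's coefficients are reported, so sequences on the unselected paths
#' cannot bleed into the score through the constant control. Degenerate
#' trials (any constant reactivation series makes the lagged design rank
#' deficient, or an all-flat matrix) score 0 and are flagged.
#'
#' @param reacts Tibble with columns `participant`, `trial`, `react`
#'   (list-column of time-by-state matrices) and, unless `subset = "all"`,
#'   `world` (the trial's world).
#' @param spec A [transition_spec()].
#' @param lag_ms Analysis lag in ms (e.g. 70 forward, 40 backward).
#' @param subset `"all"`, `"current"` (the trial's world's paths),
#'   `"other"` (the other world's paths), or an integer vector of path ids.
#' @param sample_ms,zscore As in [sequenceness_curve()].
#' @return Tibble: participant, trial, world_subset, lag_ms, fwd, bwd,
#'   degenerate.
#' @export
trialwise_sequenceness <- function(reacts, spec, lag_ms, subset = "all",
                                   sample_ms = 10, zscore = FALSE) {
  named_subset <- is.character(subset)
  if (named_subset && !subset %in% c("all", "current", "other")) {
    abort("`subset` must be 'all', 'current', 'other' or path ids.",
          class = "replaykit_spec_error")
  }
  if (named_subset && subset != "all" && !"world" %in% names(reacts)) {
    abort("Current/other scoring needs a `world` column.",
          class = "replaykit_spec_error")
  }
  n <- nrow(reacts)
  fwd <- bwd <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    m <- reacts$react[[i]]
    paths <- if (!named_subset) subset
    else switch(subset,
                all = NULL,
                current = which(spec$world == reacts$world[i]),
                other = which(spec$world != reacts$world[i]))
    if (all(apply(m, 2, sd) == 0)) {
      degen[i] <- TRUE
      next
    }
    emp <- withCallingHandlers(
      stage1_empirical(m, lag_ms, sample_ms, zscore),
      replaykit_rank_warning = function(w) {
        degen[i] <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- if (is.null(paths)) stage2_sequenceness(emp, spec)[c("fwd", "bwd")]
    else stage2_subset(emp, spec, paths)
    fwd[i] <- co[["fwd"]]; bwd[i] <- co[["bwd"]]
  }
  tibble(participant = reacts$participant, trial = reacts$trial,
         world_subset = if (named_subset) subset else "custom",
         lag_ms = lag_ms, fwd = fwd, bwd = bwd, degenerate = degen)
}
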