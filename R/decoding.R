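# Internal: stratified fold assignment, seeded upstream.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# Internal: fit the 12 one-vs-rest L1-logistic models at one time sample.
# `penalty` is a single lambda; returns intercepts + weight matrix.
fit_ovr <- function(X, labels, states, penalty) {
  W <- matrix(0, length(states), ncol(X))
  b <- numeric(length(states))
  # descend gradually to the target penalty: warm starts keep the solver
  # stable on (near-)separable data
  lam_path <- penalty * 10^seq(2, 0, length.out = 15)
  for (i in seq_along(states)) {
    y <- as.integer(labels == states[i])
    # small-class and separable fixtures trigger benign glmnet warnings
    fit <- suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                     lambda = lam_path, standardize = FALSE))
    cf <- as.matrix(coef(fit, s = penalty, exact = FALSE))
    b[i] <- cf[1, 1]
    W[i, ] <- cf[-1, 1]
  }
  list(intercepts = b, weights = W)
}

#' Train one-vs-rest L1-penalized logistic state classifiers
#'
#' One lasso-regularized logistic regression model per state, trained on the
#' sensor pattern at a single post-stimulus latency. The penalty is chosen
#' by stratified k-fold cross-validation over a log-spaced grid (shared
#' across states: the grid value with the best mean held-out multiclass
#' accuracy wins).
#'
#' @param epochs An [generate_sensor_epochs()] `epoch_set` (or a compatible
#'   list with `data`, `labels`, `time_ms`).
#' @param latency_ms Training latency in ms. Default 200.
#' @param penalty_grid Lambda grid; default log-spaced over 6 decades.
#' @param n_folds Cross-validation folds. Default 5.
#' @param seed Integer seed for the folds.
#' @return A `classifier_set`: list with `intercepts`, `weights` (state by
#'   sensor), `penalty`, `latency_ms`, `states`, `cv_accuracy` (tibble per
#'   grid value), `seed`.
#' @export
train_state_classifiers <- function(epochs, latency_ms = 200,
                                    penalty_grid = 10^seq(-4, 1.5,
                                                          length.out = 12),
                                    n_folds = 5L, seed = 1L) {
  t_idx <- which(epochs$time_ms == latency_ms)
  if (length(t_idx) != 1) {
    abort("`latency_ms` must match one sample on the epoch time axis.",
          class = "replaykit_config_error")
  }
  X <- epochs$data[, , t_idx]
  labels <- epochs$labels
  states <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(paste0("State(s) ", paste(names(counts)[counts < 2], collapse = ", "),
                 " have fewer than 2 training epochs."),
          class = "replaykit_data_error")
  }
  missing_states <- setdiff(seq_len(max(states)), states)
  if (length(missing_states) > 0) {
    abort(paste0("State(s) absent from training data: ",
                 paste(missing_states, collapse = ", ")),
          class = "replaykit_data_error")
  }
  set.seed(seed)
  fold <- stratified_folds(labels, n_folds)
  acc <- matrix(NA_real_, length(penalty_grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    for (g in seq_along(penalty_grid)) {
      m <- fit_ovr(X[tr, , drop = FALSE], labels[tr], states,
                   penalty_grid[g])
      p <- plogis(sweep(X[!tr, , drop = FALSE] %*% t(m$weights), 2,
                        m$intercepts, `+`))
      pred <- states[max.col(p, ties.method = "first")]
      acc[g, f] <- mean(pred == labels[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)
  final <- fit_ovr(X, labels, states, penalty_grid[best])
  structure(list(intercepts = final$intercepts, weights = final$weights,
                 penalty = penalty_grid[best], latency_ms = latency_ms,
                 states = states,
                 cv_accuracy = tibble(penalty = penalty_grid,
                                      accuracy = mean_acc),
                 seed = seed),
            class = "classifier_set")
}

#' @export
print.classifier_set <- function(x, ...) {
  cat("<classifier_set>", length(x$states), "states,",
      ncol(x$weights), "sensors; lambda =", signif(x$penalty, 3),
      "; CV accuracy", round(max(x$cv_accuracy$accuracy), 3), "\n")
  invisible(x)
}

#' Apply trained state classifiers to a sensor window
#'
#' Produces the time-by-state reactivation probability matrix for one trial
#' period: each classifier's predicted probability at every time sample.
#' One-vs-rest outputs are not renormalized across states.
#'
#' @param classifiers A [train_state_classifiers()] result.
#' @param window Sensor-by-time numeric matrix (same sensors as training).
#' @return Time-by-state matrix of probabilities in \[0, 1\].
#' @export
apply_classifiers <- function(classifiers, window) {
  if (nrow(window) != ncol(classifiers$weights)) {
    abort(paste0("Window has ", nrow(window), " sensors; classifiers expect ",
                 ncol(classifiers$weights), "."),
          class = "replaykit_data_error")
  }
  plogis(sweep(t(window) %*% t(classifiers$weights), 2,
               classifiers$intercepts, `+`))
}

#' Temporal generalization matrix
#'
#' Cross-validated classification accuracy for every pair of training and
#' testing latencies: classifiers trained at one time sample are evaluated
#' at all others on held-out epochs, revealing when the training pattern is
#' expressed.
#'
#' @param epochs An `epoch_set`.
#' @param latencies_ms Latencies to use for both axes; default the full
#'   epoch time axis.
#' @param penalty Single lasso penalty used at every latency. Default 0.01.
#' @param n_folds CV folds. Default 5.
#' @param seed Integer seed.
#' @return A matrix (train latency by test latency) of held-out multiclass
#'   accuracy, with latencies as dimnames; class `temporal_generalization`.
#' @export
temporal_generalization <- function(epochs, latencies_ms = epochs$time_ms,
                                    penalty = 0.01, n_folds = 5L, seed = 1L) {
  labels <- epochs$labels
  states <- sort(unique(labels))
  set.seed(seed)
  fold <- stratified_folds(labels, n_folds)
  t_idx <- match(latencies_ms, epochs$time_ms)
  if (anyNA(t_idx)) abort("All latencies must lie on the epoch time axis.",
                          class = "replaykit_config_error")
  n_lat <- length(t_idx)
  acc <- array(0, c(n_lat, n_lat))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    for (i in seq_len(n_lat)) {
      m <- fit_ovr(epochs$data[tr, , t_idx[i]], labels[tr], states, penalty)
      for (j in seq_len(n_lat)) {
        Xte <- epochs$data[!tr, , t_idx[j]]
        p <- plogis(sweep(Xte %*% t(m$weights), 2, m$intercepts, `+`))
        pred <- states[max.col(p, ties.method = "first")]
        acc[i, j] <- acc[i, j] + mean(pred == labels[!tr]) / n_folds
      }
    }
  }
  dimnames(acc) <- list(train_ms = latencies_ms, test_ms = latencies_ms)
  class(acc) <- c("temporal_generalization", class(acc))
  acc
}

#' Permutation test of overall stimulus reactivation
#'
#' Compares the mean reactivation strength obtained with veridically trained
#' classifiers against a null distribution from classifiers trained on
#' permuted epoch labels. The summary statistic is the mean over windows and
#' time samples of the across-state maximum probability; misaligned
#' (permuted) classifiers assign systematically lower peak probabilities.
#'
#' @param epochs Training `epoch_set`.
#' @param windows List of sensor-by-time matrices (trial periods to score).
#' @param latency_ms Training latency. Default 200.
#' @param penalty Single lasso penalty (no CV inside the permutation loop).
#'   Default 0.01.
#' @param n_perms Number of label permutations; below 100 a warning reports
#'   the coarse p resolution. Default 100.
#' @param seed Integer seed.
#' @return List: `p` (permutation p value), `real_stat`, `null_stats`,
#'   `resolution` (= 1 / (n_perms + 1)).
#' @export
reactivation_significance <- function(epochs, windows, latency_ms = 200,
                                      penalty = 0.01, n_perms = 100L,
                                      seed = 1L) {
  if (n_perms < 100) {
    warn(paste0("Only ", n_perms, " permutations; p resolution is 1/",
                n_perms + 1, "."))
  }
  t_idx <- which(epochs$time_ms == latency_ms)
  X <- epochs$data[, , t_idx]
  states <- sort(unique(epochs$labels))
  stat_for <- function(labels) {
    m <- fit_ovr(X, labels, states, penalty)
    cl <- list(intercepts = m$intercepts, weights = m$weights)
    mean(vapply(windows, function(w) {
      pr <- plogis(sweep(t(w) %*% t(cl$weights), 2, cl$intercepts, `+`))
      mean(apply(pr, 1, max))
    }, numeric(1)))
  }
  real <- stat_for(epochs$labels)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perms),
                       function(i) stat_for(sample(epochs$labels)),
                       numeric(1))
  list(p = (1 + sum(null_stats >= real)) / (n_perms + 1),
       real_stat = real, null_stats = null_stats,
       resolution = 1 / (n_perms + 1))
}
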