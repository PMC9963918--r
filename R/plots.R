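#' Plot a group sequenceness curve
#'
#' Participant-mean forward and backward sequenceness against state-to-state
#' lag, with SEM ribbons and optional permutation-threshold lines.
#'
#' @param object A [sequenceness_curve()] result.
#' @param threshold Optional [permutation_threshold()] result; drawn as
#'   dashed horizontal lines per direction.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sequenceness_result <- function(object, threshold = NULL, ...) {
  g <- group_curve(object)
  long <- tidyr::pivot_longer(g, c("fwd", "bwd"), names_to = "direction",
                              values_to = "sequenceness")
  long$sem <- ifelse(long$direction == "fwd", g$fwd_sem[match(long$lag_ms,
                                                              g$lag_ms)],
                     g$bwd_sem[match(long$lag_ms, g$lag_ms)])
  long$direction <- factor(long$direction, c("fwd", "bwd"),
                           c("forward", "backward"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$lag_ms,
                                          y = .data$sequenceness)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sequenceness - .data$sem,
                                      ymax = .data$sequenceness + .data$sem),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "state-to-state lag (ms)", y = "sequenceness") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    th <- tibble(direction = factor(c("forward", "backward"),
                                    c("forward", "backward")),
                 value = c(threshold$fwd, threshold$bwd))
    p <- p + ggplot2::geom_hline(data = th,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed")
  }
  p
}

#' Plot a temporal generalization matrix
#'
#' @param object A [temporal_generalization()] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.temporal_generalization <- function(object, ...) {
  d <- as_tibble(expand.grid(
    train_ms = as.numeric(rownames(unclass(object))),
    test_ms = as.numeric(colnames(unclass(object)))))
  d$accuracy <- as.vector(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$test_ms, .data$train_ms,
                                  fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "test latency (ms)", y = "train latency (ms)",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a lag profile of a replay-behavior effect
#'
#' @param object A [lag_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lag_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_ms, .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "state-to-state lag (ms)",
                  y = paste0("coefficient (",
                             attr(object, "regressor") %||% "effect", ")")) +
    ggplot2::theme_minimal()
}

#' Stay-probability summary plot
#'
#' Display-parity summary of the model-based signature: stay probability by
#' binarized previous same-world reward (median split: high/low) and start
#' state identity (same/different). A model-based learner shows a reward
#' effect of equal size in both start-state conditions.
#'
#' @param data A [derive_trial_covariates()] dataset.
#' @return A ggplot object.
#' @export
plot_stay_probability <- function(data) {
  d <- filter(data, !is.na(.data$stay) & !is.na(.data$same_start) &
                !is.na(.data$prev_reward))
  d <- mutate(group_by(d, .data$participant),
              reward_level = ifelse(.data$prev_reward >
                                      median(.data$prev_reward),
                                    "high", "low"))
  d <- summarise(group_by(ungroup(d), .data$participant,
                          .data$reward_level, .data$same_start),
                 stay = mean(.data$stay), .groups = "drop")
  d <- summarise(group_by(d, .data$reward_level, .data$same_start),
                 sem = sd(.data$stay) / sqrt(n()), stay = mean(.data$stay),
                 .groups = "drop")
  d$start <- factor(d$same_start, c(1, 0), c("same start", "different start"))
  d$reward_level <- factor(d$reward_level, c("low", "high"))
  ggplot2::ggplot(d, ggplot2::aes(.data$reward_level, .data$stay,
                                  fill = .data$start)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$stay - .data$sem,
                                        ymax = .data$stay + .data$sem),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.2) +
    ggplot2::labs(x = "previous same-world reward", y = "P(stay)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
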