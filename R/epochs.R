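#' Generate labeled synthetic sensor epochs for decoder training
#'
#' Builds an epoch-by-sensor-by-time array in which each state is expressed
#' as a fixed spatial sensor pattern at a nominal latency, embedded in
#' Gaussian sensor noise — the structure a functional localizer provides for
#' training state classifiers. Patterns are orthonormal columns (scaled by
#' `amplitude`) by default, which requires at least as many sensors as
#' states.
#'
#' @param n_states Number of states/classes. Default 12.
#' @param n_sensors Number of sensors. Default 30.
#' @param epochs_per_state Epochs per state. Default 20.
#' @param time_ms Time axis of each epoch, in ms. Default 0-400 by 10.
#' @param latency_ms Latency at which the pattern is expressed. Default 200.
#' @param noise_sd Sensor noise SD. Default 1.
#' @param amplitude Pattern scale. Default 3.
#' @param orthogonal Require orthonormal patterns. Default `TRUE`.
#' @param seed Integer seed (recorded in the output).
#' @return An `epoch_set`: list with `data` (array epoch x sensor x time),
#'   `labels`, `time_ms`, `patterns` (sensor x state), `latency_ms`, `seed`.
#' @export
generate_sensor_epochs <- function(n_states = 12L, n_sensors = 30L,
                                   epochs_per_state = 20L,
                                   time_ms = seq(0, 400, by = 10),
                                   latency_ms = 200, noise_sd = 1,
                                   amplitude = 3, orthogonal = TRUE,
                                   seed = 1L) {
  if (orthogonal && n_sensors < n_states) {
    abort("Orthogonal patterns need at least as many sensors as states.",
          class = "replaykit_config_error")
  }
  if (!latency_ms %in% time_ms) {
    abort("`latency_ms` must be on the epoch time axis.",
          class = "replaykit_config_error")
  }
  set.seed(seed)
  raw <- matrix(rnorm(n_sensors * n_states), n_sensors, n_states)
  patterns <- if (orthogonal) qr.Q(qr(raw)) else raw / sqrt(n_sensors)
  patterns <- patterns * amplitude
  n_ep <- n_states * epochs_per_state
  labels <- rep(seq_len(n_states), each = epochs_per_state)
  data <- array(rnorm(n_ep * n_sensors * length(time_ms), sd = noise_sd),
                dim = c(n_ep, n_sensors, length(time_ms)))
  t_idx <- which(time_ms == latency_ms)
  for (e in seq_len(n_ep)) {
    data[e, , t_idx] <- data[e, , t_idx] + patterns[, labels[e]]
  }
  structure(list(data = data, labels = labels, time_ms = time_ms,
                 patterns = patterns, latency_ms = latency_ms, seed = seed),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", d[1], "epochs x", d[2], "sensors x", d[3],
      "samples;", length(unique(x$labels)), "states\n")
  invisible(x)
}

#' Bin a sensor window onto a coarser regular time grid
#'
#' Averages consecutive samples so that downstream reactivation series live
#' on the analysis lag grid (100 Hz by default).
#'
#' @param window Sensor-by-time numeric matrix.
#' @param time_ms Time axis of the columns, in ms (regular).
#' @param target_ms Target grid step in ms. Default 10.
#' @return List with `window` (binned sensor-by-time matrix) and `time_ms`.
#' @export
downsample_window <- function(window, time_ms, target_ms = 10) {
  step <- diff(time_ms[1:2])
  k <- target_ms / step
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    abort("`target_ms` must be a multiple of the window's sampling step.",
          class = "replaykit_config_error")
  }
  k <- as.integer(round(k))
  if (k == 1L) return(list(window = window, time_ms = time_ms))
  n_bins <- floor(ncol(window) / k)
  idx <- rep(seq_len(n_bins), each = k)
  binned <- vapply(seq_len(n_bins),
                   function(b) rowMeans(window[, idx == b, drop = FALSE]),
                   numeric(nrow(window)))
  list(window = binned,
       time_ms = vapply(seq_len(n_bins),
                        function(b) mean(time_ms[seq_len(n_bins * k)][idx == b]),
                        numeric(1)))
}
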