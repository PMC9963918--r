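#' Structural transition matrices for the task graph
#'
#' Encodes the four three-state paths over the 12 path states as indicator
#' matrices used in the second TDLM stage: `T_F` marks the 8 within-path
#' forward transitions (2 per path), `T_B = t(T_F)` the backward ones,
#' `T_cons` is an all-ones off-diagonal control capturing the average of all
#' transitions (background dynamics), and `T_auto` the identity, modeling
#' self-transitions to control for autocorrelation.
#'
#' @param paths List of ordered integer state vectors, one per path. Default:
#'   the canonical layout of [generate_task_schedule()] (path p occupies
#'   states `3p-2, 3p-1, 3p`).
#' @param world Integer world membership of each path. Default `c(1,1,2,2)`.
#' @param n_states Total number of states. Default 12.
#' @return A `transition_spec`: list with `T_F`, `T_B`, `T_cons`, `T_auto`,
#'   `paths`, `world`, `n_states`.
#' @examples
#' spec <- transition_spec()
#' sum(spec$T_F) # 8
#' @export
transition_spec <- function(paths = lapply(1:4, function(p) (3 * p - 2):(3 * p)),
                            world = c(1L, 1L, 2L, 2L),
                            n_states = 12L) {
  states <- unlist(paths)
  if (anyDuplicated(states) > 0 || any(states > n_states) || any(states < 1)) {
    abort("Paths must be disjoint ordered subsets of 1..n_states.",
          class = "replaykit_spec_error")
  }
  if (length(world) != length(paths)) {
    abort("`world` must give one world per path.",
          class = "replaykit_spec_error")
  }
  T_F <- matrix(0, n_states, n_states)
  for (p in paths) {
    for (k in seq_len(length(p) - 1)) T_F[p[k], p[k + 1]] <- 1
  }
  T_B <- t(T_F)
  if (any(T_F * T_B != 0)) {
    abort("Paths imply symmetric transitions; forward/backward inseparable.",
          class = "replaykit_spec_error")
  }
  T_cons <- matrix(1, n_states, n_states) - diag(n_states)
  structure(list(T_F = T_F, T_B = T_B, T_cons = T_cons,
                 T_auto = diag(n_states), paths = paths,
                 world = as.integer(world), n_states = as.integer(n_states)),
            class = "transition_spec")
}

# Directional indicator matrices restricted to a subset of paths;
# controls are never restricted.
directional_matrices <- function(spec, paths = NULL) {
  if (is.null(paths)) return(list(T_F = spec$T_F, T_B = spec$T_B))
  T_F <- matrix(0, spec$n_states, spec$n_states)
  for (ip in paths) {
    p <- spec$paths[[ip]]
    for (k in seq_len(length(p) - 1)) T_F[p[k], p[k + 1]] <- 1
  }
  list(T_F = T_F, T_B = t(T_F))
}

# Relabel states by a permutation: entry (i, j) of the permuted matrix is
# entry (perm[i], perm[j]) of the original.
permute_states <- function(M, perm) M[perm, perm]

#' @export
print.transition_spec <- function(x, ...) {
  cat("<transition_spec>", length(x$paths), "paths over", x$n_states,
      "states;", sum(x$T_F), "forward transitions\n")
  invisible(x)
}
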