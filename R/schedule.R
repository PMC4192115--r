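#' Constrained pseudo-random side schedule
#'
#' Specification of the per-session schedule of rewarded-stimulus sides used
#' in the single-image training steps and in the PD/PDR tasks: a fixed number
#' of left and right presentations with a cap on how many consecutive trials
#' the rewarded side may repeat.
#'
#' @param n_trials total trials per session.
#' @param n_left,n_right number of left / right presentations;
#'   must sum to `n_trials`.
#' @param max_run maximum allowed run of identical sides (>= 1).
#'
#' @return A list of class `schedule_spec`.
#' @examples
#' schedule_spec()           # the standard 30-trial, 15/15, max-run-3 session
#' schedule_spec(4, 2, 2, 1) # forced alternation
#' @export
schedule_spec <- function(n_trials = 30L, n_left = 15L, n_right = 15L,
                          max_run = 3L) {
  n_trials <- as.integer(n_trials)
  n_left <- as.integer(n_left)
  n_right <- as.integer(n_right)
  max_run <- as.integer(max_run)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (n_left < 0L || n_right < 0L) stop("side counts must be >= 0")
  if (n_left + n_right != n_trials) {
    stop("n_left + n_right must equal n_trials")
  }
  if (max_run < 1L) stop("max_run must be >= 1")
  # a sequence with runs <= m exists iff each side fits between the other's
  # presentations: n_left <= m * (n_right + 1) and vice versa
  if (n_left > max_run * (n_right + 1L) ||
      n_right > max_run * (n_left + 1L)) {
    stop("unsatisfiable schedule constraints: no sequence with ", n_left,
         " left / ", n_right, " right and runs <= ", max_run, " exists")
  }
  structure(list(n_trials = n_trials, n_left = n_left, n_right = n_right,
                 max_run = max_run),
            class = "schedule_spec")
}

#' Longest run of identical elements
#'
#' @param sides a vector (typically of `"left"`/`"right"`).
#' @return Integer length of the longest run.
#' @examples
#' max_side_run(c("left", "left", "right")) # 2
#' @export
max_side_run <- function(sides) {
  if (length(sides) == 0L) return(0L)
  max(rle(as.character(sides))$lengths)
}

#' Generate a constrained pseudo-random side sequence
#'
#' Draws a sequence of rewarded-stimulus sides with exactly `n_left` left and
#' `n_right` right presentations and no run of identical sides longer than
#' `max_run`. Sampling is by rejection: uniformly random permutations of the
#' side multiset are drawn until one satisfies the run constraint, which makes
#' the distribution exactly uniform over the set of valid sequences.
#'
#' @param spec a [schedule_spec()].
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param max_tries rejection-sampling cap (the standard 15/15 max-run-3
#'   session accepts roughly one draw in three, so the cap is never reached
#'   in practice).
#'
#' @return Character vector of `"left"`/`"right"` of length `n_trials`.
#' @examples
#' s <- generate_side_sequence(schedule_spec(), seed = 1)
#' table(s)
#' max_side_run(s) # <= 3
#' @export
generate_side_sequence <- function(spec = schedule_spec(), seed = NULL,
                                   max_tries = 100000L) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (!is.null(seed)) set.seed(seed)
  pool <- c(rep("left", spec$n_left), rep("right", spec$n_right))
  if (spec$n_trials <= 1L) return(pool)
  for (i in seq_len(max_tries)) {
    s <- sample(pool)
    if (max_side_run(s) <= spec$max_run) return(s)
  }
  stop("rejection sampling failed after ", max_tries, " tries")
}
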