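#' Interaction episode
#'
#' An episode is the timestamped log of one play session (real or simulated):
#' each record gives the time at which the child entered a state, the robot
#' action in force when it did, and the state entered. Timestamps are seconds
#' from session start and must be strictly increasing; the session `duration`
#' may extend past the last recorded transition.
#'
#' @param timestamp_s Numeric vector of strictly increasing times (seconds).
#' @param robot_action Character vector over [cri_actions()].
#' @param child_state Character vector over [cri_states()].
#' @param duration Session duration in seconds; defaults to the last
#'   timestamp. Must be >= the last timestamp.
#' @return A data frame of class `cri_episode` with attribute `duration`.
#' @export
episode <- function(timestamp_s, robot_action, child_state,
                    duration = NULL) {
  n <- length(timestamp_s)
  stopifnot(length(robot_action) == n, length(child_state) == n)
  if (n == 0L) stop("episode must contain at least one record", call. = FALSE)
  if (any(diff(timestamp_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  state_index(child_state)
  action_index(robot_action)
  if (is.null(duration)) duration <- timestamp_s[n]
  if (duration < timestamp_s[n]) {
    stop("duration must be at least the last timestamp", call. = FALSE)
  }
  out <- data.frame(timestamp_s = as.numeric(timestamp_s),
                    robot_action = as.character(robot_action),
                    child_state = as.character(child_state),
                    stringsAsFactors = FALSE)
  attr(out, "duration") <- as.numeric(duration)
  class(out) <- c("cri_episode", class(out))
  out
}

#' Episode duration in seconds
#' @param x A `cri_episode`.
#' @export
episode_duration <- function(x) {
  stopifnot(inherits(x, "cri_episode"))
  attr(x, "duration")
}

#' Time-normalized accumulated utility of an episode
#'
#' Sums the per-state utility over every recorded state entry and divides by
#' the episode duration, giving utility per second. Invariant to
#' re-timestamping that preserves the duration and the multiset of entries.
#'
#' @param episode A [episode()].
#' @param utility Per-state utility vector; default [cri_utility()].
#' @return Utility per second (a single number).
#' @export
#' @examples
#' ep <- episode(1:3, c("f", "f", "s"), c("M", "M", "TA"), duration = 3)
#' accumulate_utility(ep)  # (2 + 2 + 1) / 3
accumulate_utility <- function(episode, utility = cri_utility()) {
  stopifnot(inherits(episode, "cri_episode"))
  dur <- episode_duration(episode)
  if (!is.finite(dur) || dur <= 0) stop("episode duration must be positive",
                                        call. = FALSE)
  u <- stats::setNames(as.numeric(utility), cri_states())
  sum(u[episode$child_state]) / dur
}

#' Absolute change in utility rate between two sessions
#'
#' The session-level outcome used to compare a child's first and last
#' sessions: the absolute difference of the two time-normalized accumulated
#' utilities. A large value signals that the robot's effectiveness changed
#' between the sessions (e.g. after switching from the regular to the
#' computed optimal policy).
#'
#' @param episode_first,episode_last Two [episode()]s.
#' @param utility Per-state utility vector; default [cri_utility()].
#' @return Non-negative number; symmetric in its two episode arguments.
#' @export
policy_change_score <- function(episode_first, episode_last,
                                utility = cri_utility()) {
  abs(accumulate_utility(episode_last, utility) -
        accumulate_utility(episode_first, utility))
}
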