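#' Child-robot interaction MDP: states, actions, utilities
#'
#' The interaction during a chasing game is modeled as a four-state Markov
#' decision process. States describe the child's current mode of engagement:
#' \describe{
#'   \item{NL}{not looking at the robot}
#'   \item{L}{looking at the robot but not following it}
#'   \item{TA}{touching the robot, or visibly aroused/excited by it}
#'   \item{M}{moving towards / following the robot}
#' }
#' Actions are the robot's maneuvers: `f` (move forward, towards the child),
#' `s` (stay in place or turn without changing distance), `b` (retreat while
#' facing the child). Reaching `TA` or `M` is a success for the robot, so the
#' default per-state utility vector is `c(NL = 0, L = 0, TA = 1, M = 2)`.
#'
#' @name cri-mdp-space
#' @keywords internal
NULL

#' Canonical state and action symbol sets
#'
#' @return Character vectors of the four child states and three robot actions,
#'   in canonical order. `TA` is the serialized form of the touching/aroused
#'   state.
#' @export
cri_states <- function() c("NL", "L", "TA", "M")

#' @rdname cri_states
#' @export
cri_actions <- function() c("f", "s", "b")

#' Default per-state utility vector
#'
#' Zero utility for the disengaged states (`NL`, `L`), 1 for touching/aroused
#' (`TA`) and 2 for moving/following (`M`).
#'
#' @return Named numeric vector over [cri_states()].
#' @export
cri_utility <- function() c(NL = 0, L = 0, TA = 1, M = 2)

state_index <- function(x) {
  i <- match(x, cri_states())
  if (anyNA(x) || anyNA(i)) {
    bad <- unique(x[is.na(match(x, cri_states()))])
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(cri_states(), collapse = ", "), ")",
         call. = FALSE)
  }
  i
}

action_index <- function(x) {
  i <- match(x, cri_actions())
  if (anyNA(x) || anyNA(i)) {
    bad <- unique(x[is.na(match(x, cri_actions()))])
    stop("unknown action symbol(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(cri_actions(), collapse = ", "), ")",
         call. = FALSE)
  }
  i
}

#' Create an empty transition-count tensor
#'
#' The count tensor `N[state, action, next_state]` is the sufficient statistic
#' for both transition-probability estimators. It starts at zero ("the model is
#' initialized with no transitions") and is incremented online as child
#' responses to robot actions are observed.
#'
#' @return A 4 x 3 x 4 integer array of class `transition_counts`, with
#'   dimnames `(state, action, next_state)`.
#' @export
#' @examples
#' n <- transition_counts()
#' n <- update_counts(n, "L", "s", "TA")
#' sum(n)
transition_counts <- function() {
  n <- array(0L, dim = c(4L, 3L, 4L),
             dimnames = list(state = cri_states(),
                             action = cri_actions(),
                             next_state = cri_states()))
  class(n) <- c("transition_counts", class(n))
  n
}

#' Record one observed child transition
#'
#' Increments exactly one cell of the count tensor: the child was in
#' `from_state`, the robot performed `action`, and the child responded by
#' moving to `to_state`.
#'
#' @param counts A [transition_counts()] tensor.
#' @param from_state,to_state Child state symbols (see [cri_states()]).
#' @param action Robot action symbol (see [cri_actions()]).
#' @return The updated tensor.
#' @export
update_counts <- function(counts, from_state, action, to_state) {
  stopifnot(inherits(counts, "transition_counts"))
  i <- state_index(from_state)
  j <- action_index(action)
  k <- state_index(to_state)
  counts[i, j, k] <- counts[i, j, k] + 1L
  counts
}

#' Accumulate all transitions of an episode into a count tensor
#'
#' Each consecutive pair of records `(state_t, action_{t+1}, state_{t+1})` is
#' one observation: the action logged with a record is the robot maneuver that
#' elicited that record's state. The first record seeds the chain.
#'
#' @param counts A [transition_counts()] tensor.
#' @param episode An [episode()] with at least two records.
#' @return The updated tensor; total increment equals `nrow(episode) - 1`.
#' @export
count_episode <- function(counts, episode) {
  stopifnot(inherits(episode, "cri_episode"))
  st <- episode$child_state
  ac <- episode$robot_action
  if (length(st) < 2L) return(counts)
  for (t in seq_len(length(st) - 1L)) {
    counts <- update_counts(counts, st[t], ac[t + 1L], st[t + 1L])
  }
  counts
}

#' Maximum-likelihood transition probabilities
#'
#' Each `(state, action)` row is the empirical distribution of observed next
#' states: `P[s,a,k] = N[s,a,k] / sum_j N[s,a,j]`. Rows with no observations
#' are *undefined* (all `NA`), deliberately distinct from uniform: an event not
#' yet observed is not necessarily impossible, and planning on ML output is
#' refused until rows are defined (see [estimate_smoothed()]).
#'
#' @param counts A [transition_counts()] tensor.
#' @return A 4 x 3 x 4 probability array with attribute `defined`, a 4 x 3
#'   logical matrix marking rows with at least one observation.
#' @export
#' @examples
#' n <- transition_counts()
#' for (i in 1:4) n <- update_counts(n, "L", "s", "TA")
#' n <- update_counts(n, "L", "s", "M")
#' estimate_ml(n)["L", "s", ]   # 0 0 0.8 0.2
estimate_ml <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  p <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  totals <- apply(counts, c(1, 2), sum)
  for (i in 1:4) for (j in 1:3) {
    if (totals[i, j] > 0) p[i, j, ] <- counts[i, j, ] / totals[i, j]
  }
  attr(p, "defined") <- totals > 0
  attr(p, "estimator") <- "ml"
  p
}

#' Additively smoothed transition probabilities
#'
#' Add-lambda (Laplace/Lidstone) smoothing:
#' `P[s,a,k] = (N[s,a,k] + lambda) / (sum_j N[s,a,j] + lambda * |S|)`.
#' Every entry is strictly positive and every row sums to one, including rows
#' with no observations (which become uniform). This encodes the sparse-data
#' stance that unobserved transitions are improbable, not impossible; as
#' `lambda -> 0` the estimate converges to maximum likelihood on observed rows.
#'
#' @param counts A [transition_counts()] tensor.
#' @param lambda Positive smoothing pseudo-count; default 1 (add-one).
#' @return A 4 x 3 x 4 strictly positive row-stochastic array; attribute
#'   `defined` is all-`TRUE`.
#' @export
#' @examples
#' n <- transition_counts()
#' for (i in 1:4) n <- update_counts(n, "L", "s", "TA")
#' n <- update_counts(n, "L", "s", "M")
#' estimate_smoothed(n, 1)["L", "s", ]   # 1/9 1/9 5/9 2/9
estimate_smoothed <- function(counts, lambda = 1) {
  stopifnot(inherits(counts, "transition_counts"))
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("lambda must be a single positive number", call. = FALSE)
  }
  ns <- dim(counts)[3L]
  p <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  totals <- apply(counts, c(1, 2), sum)
  for (i in 1:4) for (j in 1:3) {
    p[i, j, ] <- (counts[i, j, ] + lambda) / (totals[i, j] + lambda * ns)
  }
  attr(p, "defined") <- matrix(TRUE, 4, 3, dimnames = dimnames(totals))
  attr(p, "estimator") <- "smoothed"
  attr(p, "lambda") <- lambda
  p
}

#' Assemble a child-robot interaction MDP
#'
#' @param transition A 4 x 3 x 4 row-stochastic array over
#'   `(state, action, next_state)`, e.g. from [estimate_smoothed()] or a
#'   ground-truth simulator tensor.
#' @param utility Per-state utility vector; default [cri_utility()].
#' @return An object of class `cri_mdp`.
#' @export
cri_mdp <- function(transition, utility = cri_utility()) {
  stopifnot(is.array(transition), all(dim(transition) == c(4L, 3L, 4L)))
  if (length(utility) != 4L) stop("utility must have one entry per state")
  defined <- attr(transition, "defined")
  if (is.null(defined)) {
    defined <- !apply(is.na(transition), c(1, 2), any)
  }
  rows_ok <- TRUE
  for (i in 1:4) for (j in 1:3) {
    if (defined[i, j]) {
      row <- transition[i, j, ]
      if (any(row < 0) || abs(sum(row) - 1) > 1e-9) rows_ok <- FALSE
    }
  }
  if (!rows_ok) stop("defined transition rows must be non-negative and sum to 1")
  structure(list(states = cri_states(), actions = cri_actions(),
                 transition = transition, utility = stats::setNames(
                   as.numeric(utility), cri_states()),
                 defined = defined),
            class = "cri_mdp")
}

#' @export
print.cri_mdp <- function(x, ...) {
  cat("Child-robot interaction MDP\n")
  cat("  states :", paste(x$states, collapse = " "), "\n")
  cat("  actions:", paste(x$actions, collapse = " "), "\n")
  cat("  utility:", paste(sprintf("%s=%g", x$states, x$utility),
                          collapse = " "), "\n")
  cat("  defined rows:", sum(x$defined), "of", length(x$defined), "\n")
  invisible(x)
}
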