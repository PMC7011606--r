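#' Ground-truth child behavior profile
#'
#' A profile fixes the "true" response model of a simulated child: a
#' row-stochastic tensor `P*[state, action, next_state]` giving how the child
#' reacts to each robot maneuver in each engagement state, plus a mean dwell
#' time between transitions. Two synthetic fixture profiles ship with the
#' package (parameters are invented, calibrated to no real subject):
#' \describe{
#'   \item{"responsive"}{retreating (`b`) while the child is moving strongly
#'     sustains the chase; holding position (`s`) while the child is looking
#'     tends to draw it into touching/excitement; approaching a looking child
#'     (`f`) often startles it back to not-looking. Under this child the
#'     operator heuristic of always approaching a disengaged child is
#'     noticeably suboptimal.}
#'   \item{"distractible"}{every row leaks heavily back to `NL`; engagement is
#'     hard to sustain regardless of maneuver.}
#' }
#'
#' @param name `"responsive"` or `"distractible"`, or `NULL` when passing
#'   `transition` directly.
#' @param transition Optional 4 x 3 x 4 row-stochastic tensor overriding the
#'   named fixture.
#' @param dwell Mean time between child transitions, seconds (default 2).
#' @param drift Optional per-session multiplicative perturbation factor of the
#'   tensor (default `NULL`, none).
#' @return Object of class `child_profile`.
#' @export
child_profile <- function(name = "responsive", transition = NULL,
                          dwell = 2.0, drift = NULL) {
  if (dwell <= 0) stop("dwell must be positive", call. = FALSE)
  if (is.null(transition)) {
    name <- match.arg(name, c("responsive", "distractible"))
    transition <- fixture_tensor(name)
  } else {
    name <- name %||% "custom"
  }
  stopifnot(all(dim(transition) == c(4L, 3L, 4L)))
  rs <- apply(transition, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-9) || any(transition < 0)) {
    stop("profile transition rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  dimnames(transition) <- list(state = cri_states(), action = cri_actions(),
                               next_state = cri_states())
  structure(list(name = name, transition = transition, dwell = dwell,
                 drift = drift),
            class = "child_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic fixture tensors. Rows are (next-state) distributions in the
# canonical order NL, L, TA, M.
fixture_tensor <- function(name) {
  p <- array(NA_real_, c(4, 3, 4))
  if (name == "responsive") {
    # action f: approach. Gets attention from NL, but startles a looking or
    # engaged child back towards NL.
    p[1, 1, ] <- c(0.35, 0.50, 0.10, 0.05)  # NL,f
    p[2, 1, ] <- c(0.50, 0.30, 0.10, 0.10)  # L,f
    p[3, 1, ] <- c(0.30, 0.40, 0.25, 0.05)  # TA,f
    p[4, 1, ] <- c(0.25, 0.35, 0.15, 0.25)  # M,f
    # action s: hold/turn. Draws a looking child into touching/excitement.
    p[1, 2, ] <- c(0.70, 0.20, 0.05, 0.05)  # NL,s
    p[2, 2, ] <- c(0.05, 0.15, 0.60, 0.20)  # L,s
    p[3, 2, ] <- c(0.10, 0.20, 0.55, 0.15)  # TA,s
    p[4, 2, ] <- c(0.10, 0.25, 0.20, 0.45)  # M,s
    # action b: retreat facing the child. Sustains a chase strongly.
    p[1, 3, ] <- c(0.80, 0.15, 0.02, 0.03)  # NL,b
    p[2, 3, ] <- c(0.15, 0.35, 0.10, 0.40)  # L,b
    p[3, 3, ] <- c(0.10, 0.15, 0.25, 0.50)  # TA,b
    p[4, 3, ] <- c(0.03, 0.07, 0.05, 0.85)  # M,b
  } else {
    # distractible: heavy leak to NL in every row.
    for (j in 1:3) {
      p[1, j, ] <- c(0.80, 0.15, 0.03, 0.02)
      p[2, j, ] <- c(0.60, 0.25, 0.10, 0.05)
      p[3, j, ] <- c(0.55, 0.25, 0.15, 0.05)
      p[4, j, ] <- c(0.55, 0.20, 0.05, 0.20)
    }
  }
  p
}

#' Simulate one interaction episode
#'
#' Alternates robot action (chosen by the policy at the child's current
#' state) and child response (sampled from the profile's true tensor), with
#' exponentially distributed inter-transition times of mean `dwell`. The
#' session starts in `NL` at time 0 and runs until `duration_s`.
#'
#' @param profile A [child_profile()].
#' @param policy A [cri_policy()].
#' @param duration_s Session length in seconds.
#' @param seed Integer seed; the episode is reproducible from it.
#' @param start_state Initial child state (default `"NL"`).
#' @return A [episode()] whose records are the child's transitions.
#' @export
simulate_episode <- function(profile, policy, duration_s, seed,
                             start_state = "NL") {
  stopifnot(inherits(profile, "child_profile"),
            inherits(policy, "cri_policy"))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  state <- state_index(start_state)
  t_now <- 0
  ts <- numeric(0); ac <- character(0); st <- character(0)
  repeat {
    t_now <- t_now + stats::rexp(1L, rate = 1 / profile$dwell)
    if (t_now > duration_s) break
    a <- unname(policy[cri_states()[state]])
    nxt <- sample.int(4L, 1L, prob = profile$transition[state,
                                                        action_index(a), ])
    ts <- c(ts, t_now); ac <- c(ac, a); st <- c(st, cri_states()[nxt])
    state <- nxt
  }
  if (length(ts) == 0L) {
    # no transition fell inside the window; log the initial state at the end
    # so the episode is non-empty and carries zero-ish utility honestly
    ts <- duration_s; ac <- unname(policy[start_state]); st <- start_state
  }
  episode(ts, ac, st, duration = duration_s)
}

# Save/restore .Random.seed around seeded simulation so package functions do
# not disturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Uniform-exploration transition-recovery experiment
#'
#' Simulates `n_transitions` child responses under a robot that picks each
#' maneuver uniformly at random (guaranteeing coverage of all state-action
#' rows as n grows), fits the chosen estimator to the resulting counts, and
#' reports the per-row total-variation distance to the profile's true tensor.
#'
#' @param profile A [child_profile()].
#' @param n_transitions Number of observed transitions to simulate.
#' @param estimator `"ml"` or `"smoothed"`.
#' @param lambda Smoothing pseudo-count (used when `estimator = "smoothed"`).
#' @param seed Integer seed.
#' @return Data frame with one row per `(state, action)`: observation count
#'   `n_obs`, whether the estimated row is `defined`, and `tv`, the
#'   total-variation distance `0.5 * sum |Phat - Pstar|` (`NA` for undefined
#'   rows).
#' @export
recovery_experiment <- function(profile, n_transitions, estimator = c("ml",
                                "smoothed"), lambda = 1, seed = 1) {
  stopifnot(inherits(profile, "child_profile"), n_transitions >= 1)
  estimator <- match.arg(estimator)
  rng <- local_rng(seed)
  on.exit(rng())
  counts <- transition_counts()
  state <- 1L
  for (t in seq_len(n_transitions)) {
    a <- sample.int(3L, 1L)
    nxt <- sample.int(4L, 1L, prob = profile$transition[state, a, ])
    counts[state, a, nxt] <- counts[state, a, nxt] + 1L
    state <- nxt
  }
  p_hat <- if (estimator == "ml") estimate_ml(counts) else {
    estimate_smoothed(counts, lambda)
  }
  defined <- attr(p_hat, "defined")
  grid <- expand.grid(state = cri_states(), action = cri_actions(),
                      stringsAsFactors = FALSE)
  grid$n_obs <- as.integer(apply(counts, c(1, 2), sum))
  grid$defined <- as.logical(defined)
  grid$tv <- NA_real_
  for (r in seq_len(nrow(grid))) {
    i <- state_index(grid$state[r]); j <- action_index(grid$action[r])
    if (defined[i, j]) {
      grid$tv[r] <- 0.5 * sum(abs(p_hat[i, j, ] - profile$transition[i, j, ]))
    }
  }
  attr(grid, "counts") <- counts
  grid
}

#' Compare two robot policies on a simulated child
#'
#' Runs `n_reps` seeded episodes under each policy and scores each with
#' [accumulate_utility()]. The two arms of replicate `r` share one derived
#' seed (common random numbers), so comparisons are paired and the
#' Monte-Carlo variance of the difference is reduced.
#'
#' @param profile A [child_profile()].
#' @param policy_a,policy_b Two [cri_policy()] objects; the reported
#'   difference is `b - a` (e.g. `a` = regular baseline, `b` = optimal).
#' @param duration_s Episode length in seconds (default 180, one 3-minute
#'   free-play trial).
#' @param n_reps Number of replicates per policy.
#' @param seed Integer base seed.
#' @return List with per-replicate `rates_a`, `rates_b`, `diff`
#'   (`rates_b - rates_a`), `mean_diff`, `sd_diff`, and `frac_b_ge_a`, the
#'   fraction of replicates where policy b scored at least policy a.
#' @export
compare_policies <- function(profile, policy_a, policy_b, duration_s = 180,
                             n_reps = 100, seed = 1) {
  rates_a <- numeric(n_reps); rates_b <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- (seed * 10007L + r) %% .Machine$integer.max
    rates_a[r] <- accumulate_utility(
      simulate_episode(profile, policy_a, duration_s, seed = s))
    rates_b[r] <- accumulate_utility(
      simulate_episode(profile, policy_b, duration_s, seed = s))
  }
  d <- rates_b - rates_a
  list(rates_a = rates_a, rates_b = rates_b, diff = d,
       mean_diff = mean(d), sd_diff = stats::sd(d),
       frac_b_ge_a = mean(d >= 0))
}
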