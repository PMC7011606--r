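#' Deterministic stationary policy
#'
#' A policy maps every child state to one robot action.
#'
#' @param mapping Named character vector, one action per state in
#'   [cri_states()].
#' @param provenance One of `"regular"`, `"optimal"`, `"custom"`.
#' @return Object of class `cri_policy` (named character vector).
#' @export
cri_policy <- function(mapping, provenance = "custom") {
  mapping <- mapping[cri_states()]
  if (anyNA(mapping) || length(mapping) != 4L) {
    stop("policy must define an action for every state ",
         paste(cri_states(), collapse = ", "), call. = FALSE)
  }
  action_index(unname(mapping))
  provenance <- match.arg(provenance, c("regular", "optimal", "custom"))
  structure(stats::setNames(unname(mapping), cri_states()),
            provenance = provenance, class = "cri_policy")
}

#' The operator's heuristic "regular" policy
#'
#' Encodes the human tele-operation strategy used as the baseline: close the
#' distance when the child is not engaging in the desired activity (approach
#' from `NL` and `L`), hold position when the child is touching/aroused, and
#' retreat when the child starts chasing, to steer it along. The state-action
#' mapping is an interpretation of that narrative strategy, not a published
#' table; it is fixed here so experiments are reproducible.
#'
#' @return A `cri_policy`: NL -> f, L -> f, TA -> s, M -> b.
#' @export
regular_policy <- function() {
  cri_policy(c(NL = "f", L = "f", TA = "s", M = "b"), provenance = "regular")
}

#' Optimal policy by value iteration
#'
#' Solves the infinite-horizon discounted MDP with reward collected on
#' entering a state: acting `a` in `s`, the robot receives `u(s')` for the
#' child's response `s'`. Bellman backups
#' `V(s) <- max_a sum_k P[s,a,k] (u(k) + gamma V(k))`
#' iterate until the sup-norm change drops below `tol`; the greedy policy is
#' extracted from the final value function.
#'
#' @param mdp A [cri_mdp()] whose transition rows are all defined (use
#'   [estimate_smoothed()]; maximum-likelihood output with unobserved rows is
#'   refused).
#' @param gamma Discount factor in `[0, 1)`; default 0.95.
#' @param tol Sup-norm convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap (safety valve).
#' @return List with `policy` (a `cri_policy` with provenance `"optimal"`),
#'   `value` (named numeric vector), `iterations`, and `q` (the 4 x 3
#'   state-action value matrix).
#' @export
value_iteration <- function(mdp, gamma = 0.95, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(mdp, "cri_mdp"))
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  if (!all(mdp$defined)) {
    stop("transition rows with no observations are undefined; ",
         "estimate the model with estimate_smoothed() before planning",
         call. = FALSE)
  }
  p <- mdp$transition
  u <- mdp$utility
  v <- stats::setNames(numeric(4L), mdp$states)
  q <- matrix(0, 4L, 3L, dimnames = list(mdp$states, mdp$actions))
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in 1:3) q[, j] <- p[, j, ] %*% (u + gamma * v)
    v_new <- apply(q, 1L, max)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol || it >= max_iter) break
  }
  greedy <- mdp$actions[apply(q, 1L, which.max)]
  list(policy = cri_policy(stats::setNames(greedy, mdp$states),
                           provenance = "optimal"),
       value = v, iterations = it, q = q)
}

#' Exact value of a fixed policy
#'
#' Solves the linear policy-evaluation system
#' `V = P_pi (u + gamma V)` directly, i.e.
#' `(I - gamma P_pi) V = P_pi u`. Used both for reporting and as the basis of
#' exhaustive policy enumeration.
#'
#' @inheritParams value_iteration
#' @param policy A [cri_policy()].
#' @return Named numeric value vector over states.
#' @export
evaluate_policy <- function(mdp, policy, gamma = 0.95) {
  stopifnot(inherits(mdp, "cri_mdp"), inherits(policy, "cri_policy"))
  if (!all(mdp$defined)) stop("transition rows must all be defined")
  ai <- action_index(unname(policy[mdp$states]))
  p_pi <- t(vapply(1:4, function(i) mdp$transition[i, ai[i], ],
                   numeric(4L)))
  r_pi <- as.numeric(p_pi %*% mdp$utility)
  v <- solve(diag(4L) - gamma * p_pi, r_pi)
  stats::setNames(v, mdp$states)
}

#' Enumerate all deterministic stationary policies
#'
#' With 4 states and 3 actions there are `3^4 = 81` deterministic stationary
#' policies; each is evaluated exactly with [evaluate_policy()]. This serves
#' as a brute-force optimality check for [value_iteration()] on a space small
#' enough to enumerate.
#'
#' @inheritParams value_iteration
#' @return List with `best` (the enumeration-optimal `cri_policy`), `values`
#'   (81 x 4 matrix of state values), and `policies` (81 x 4 character matrix).
#' @export
enumerate_policies <- function(mdp, gamma = 0.95) {
  acts <- mdp$actions
  grid <- expand.grid(NL = acts, L = acts, TA = acts, M = acts,
                      stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow(grid), 4L,
                 dimnames = list(NULL, mdp$states))
  for (r in seq_len(nrow(grid))) {
    pol <- cri_policy(stats::setNames(as.character(grid[r, ]), mdp$states))
    vals[r, ] <- evaluate_policy(mdp, pol, gamma)
  }
  best_row <- which.max(rowSums(vals))
  list(best = cri_policy(stats::setNames(as.character(grid[best_row, ]),
                                         mdp$states), provenance = "optimal"),
       values = vals, policies = as.matrix(grid))
}
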