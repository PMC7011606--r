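test_that("a deterministic child follows the hand-rolled chain", {
  # every (state, action) row is a unit vector: NL->L->TA->M->M under the
  # regular policy's actions
  p <- array(0, c(4, 3, 4))
  p[1, 1, 2] <- 1   # NL, f -> L
  p[2, 1, 3] <- 1   # L, f -> TA
  p[3, 2, 4] <- 1   # TA, s -> M
  p[4, 3, 4] <- 1   # M, b -> M
  for (i in 1:4) for (j in 1:3) if (sum(p[i, j, ]) == 0) p[i, j, i] <- 1
  prof <- child_profile(transition = p, dwell = 1)
  ep <- simulate_episode(prof, regular_policy(), duration_s = 60, seed = 5)
  expect_identical(ep$child_state[1:4], c("L", "TA", "M", "M"))
  expect_true(all(ep$child_state[-(1:3)] == "M"))
})

test_that("simulation frequencies converge to the true tensor", {
  prof <- child_profile("responsive", dwell = 1)
  # long episode under a fixed policy; compare conditional frequencies
  ep <- simulate_episode(prof, regular_policy(), duration_s = 12000,
                         seed = 21)
  expect_gt(nrow(ep), 10000)
  n <- count_episode(transition_counts(), ep)
  p_hat <- estimate_ml(n)
  pol <- regular_policy()
  for (s in cri_states()) {
    a <- unname(pol[s])
    row_n <- sum(n[s, a, ])
    if (row_n > 1000) {
      expect_lt(max(abs(p_hat[s, a, ] - prof$transition[s, a, ])), 0.02)
    }
  }
})

test_that("episodes are reproducible from the seed", {
  prof <- child_profile("responsive")
  e1 <- simulate_episode(prof, regular_policy(), 300, seed = 4)
  e2 <- simulate_episode(prof, regular_policy(), 300, seed = 4)
  expect_identical(e1, e2)
})

test_that("ML recovery error is small at 10,000 transitions", {
  prof <- child_profile("responsive")
  rec <- recovery_experiment(prof, 10000, estimator = "ml", seed = 2)
  expect_true(all(rec$defined))
  expect_lt(mean(rec$tv), 0.05)
})

test_that("at n = 30 smoothing defines all rows while ML leaves gaps", {
  prof <- child_profile("responsive")
  rec_ml <- recovery_experiment(prof, 30, estimator = "ml", seed = 7)
  rec_sm <- recovery_experiment(prof, 30, estimator = "smoothed", seed = 7)
  expect_true(any(!rec_ml$defined))
  expect_true(all(rec_sm$defined))
  expect_true(all(is.na(rec_ml$tv[!rec_ml$defined])))
})

test_that("identical policies score identically up to Monte-Carlo error", {
  prof <- child_profile("responsive")
  cmp <- compare_policies(prof, regular_policy(), regular_policy(),
                          duration_s = 120, n_reps = 40, seed = 3)
  expect_lt(abs(cmp$mean_diff), 3 * cmp$sd_diff / sqrt(40) + 0.05)
})

test_that("utility rate is insensitive to episode length", {
  prof <- child_profile("responsive")
  r1 <- mean(sapply(1:20, function(s) accumulate_utility(
    simulate_episode(prof, regular_policy(), 120, seed = s))))
  r2 <- mean(sapply(1:20, function(s) accumulate_utility(
    simulate_episode(prof, regular_policy(), 240, seed = 100 + s))))
  expect_lt(abs(r1 - r2), 0.12)
})

test_that("the true-model optimal policy dominates every fixed policy", {
  prof <- child_profile("responsive")
  mdp <- cri_mdp(prof$transition)
  vi <- value_iteration(mdp, gamma = 0.95, tol = 1e-10)
  en <- enumerate_policies(mdp, gamma = 0.95)
  v_opt <- evaluate_policy(mdp, vi$policy, gamma = 0.95)
  expect_true(all(v_opt >= apply(en$values, 2, max) - 1e-6))
})
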