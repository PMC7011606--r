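worked_counts <- function() {
  n <- transition_counts()
  for (i in 1:4) n <- update_counts(n, "L", "s", "TA")
  update_counts(n, "L", "s", "M")
}

test_that("update_counts increments exactly one cell", {
  n0 <- transition_counts()
  n1 <- update_counts(n0, "L", "s", "TA")
  expect_identical(sum(n1), 1L)
  expect_identical(n1["L", "s", "TA"], 1L)
  expect_error(update_counts(n0, "L", "x", "TA"), "x")
  expect_error(update_counts(n0, "Z", "s", "TA"), "Z")
})

test_that("the five-observation sequence from L under s gives counts 4 and 1", {
  n <- worked_counts()
  expect_identical(n["L", "s", "TA"], 4L)
  expect_identical(n["L", "s", "M"], 1L)
  expect_identical(sum(n), 5L)
})

test_that("replaying an episode adds one count per recorded transition", {
  ep <- episode(1:6, c("f", "s", "s", "b", "f", "s"),
                c("NL", "L", "TA", "M", "NL", "L"))
  n <- count_episode(transition_counts(), ep)
  expect_identical(sum(n), nrow(ep) - 1L)
})

test_that("maximum likelihood reproduces the worked 0.8 / 0.2 row", {
  p <- estimate_ml(worked_counts())
  expect_equal(unname(p["L", "s", ]), c(0, 0, 0.8, 0.2))
})

test_that("ML marks unobserved rows undefined, not uniform", {
  p <- estimate_ml(transition_counts())
  expect_true(all(is.na(p)))
  expect_true(all(!attr(p, "defined")))
  p2 <- estimate_ml(worked_counts())
  expect_identical(sum(attr(p2, "defined")), 1L)
  # defined rows sum to 1 and give exact zeros to unobserved next states
  expect_equal(sum(p2["L", "s", ]), 1)
  expect_identical(unname(p2["L", "s", c("NL", "L")]), c(0, 0))
})

test_that("add-one smoothing gives the hand-computed 1/9 1/9 5/9 2/9 row", {
  p <- estimate_smoothed(worked_counts(), lambda = 1)
  expect_equal(unname(p["L", "s", ]), c(1, 1, 5, 2) / 9, tolerance = 1e-12)
})

test_that("smoothing of empty counts is uniform; lambda must be positive", {
  p <- estimate_smoothed(transition_counts(), lambda = 2.5)
  expect_true(all(abs(p - 0.25) < 1e-12))
  expect_error(estimate_smoothed(transition_counts(), 0), "lambda")
  expect_error(estimate_smoothed(transition_counts(), -1), "lambda")
})

test_that("smoothed rows are strictly positive and row-stochastic", {
  set.seed(8)
  for (rep in 1:5) {
    n <- transition_counts()
    for (k in seq_len(sample(0:40, 1))) {
      n <- update_counts(n, sample(cri_states(), 1),
                         sample(cri_actions(), 1), sample(cri_states(), 1))
    }
    p <- estimate_smoothed(n, lambda = runif(1, 0.1, 3))
    expect_true(all(p > 0))
    expect_equal(unname(apply(p, c(1, 2), sum)),
                 matrix(1, 4, 3), tolerance = 1e-9)
  }
})

test_that("smoothing converges to ML as lambda tends to zero", {
  n <- worked_counts()
  ml <- estimate_ml(n)["L", "s", ]
  sm <- estimate_smoothed(n, lambda = 1e-8)["L", "s", ]
  expect_lt(max(abs(sm - ml)), 1e-6)
})
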