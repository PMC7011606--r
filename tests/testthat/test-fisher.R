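# Small synthetic descriptor samples (two well-separated clouds).
two_clouds <- function(n = 120, d = 6, sep = 10, seed = 3) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(rep(sep, 2), rep(0, d - 2)))
  x <- matrix(rnorm(n * d, sd = 0.5), n, d)
  half <- seq_len(n / 2)
  x[half, ] <- sweep(x[half, ], 2, centers[1, ], `+`)
  x[-half, ] <- sweep(x[-half, ], 2, centers[2, ], `+`)
  list(x = x, centers = centers)
}

test_that("codebook on two separated clouds recovers the cloud centers", {
  tc <- two_clouds()
  cb <- fit_codebook(tc$x, K = 2, projected_dim = 3, seed = 1)
  # compare in the projected space
  proj <- sweep(tc$centers, 2, cb$center) %*% cb$rotation
  d <- as.matrix(dist(rbind(proj, t(cb$means))))[1:2, 3:4]
  expect_lt(min(d[1, ]), 0.5)
  expect_lt(min(d[2, ]), 0.5)
  expect_gt(max(d), 5)   # the two components are not on the same cloud
})

test_that("codebook fitting is deterministic given the seed", {
  tc <- two_clouds()
  cb1 <- fit_codebook(tc$x, K = 2, seed = 7)
  cb2 <- fit_codebook(tc$x, K = 2, seed = 7)
  expect_identical(cb1, cb2)
})

test_that("mixture weights are positive and sum to one", {
  tc <- two_clouds()
  cb <- fit_codebook(tc$x, K = 3, seed = 2)
  expect_true(all(cb$weights > 0))
  expect_equal(sum(cb$weights), 1, tolerance = 1e-9)
  expect_true(all(cb$variances > 0))
})

test_that("K is reduced with a warning when descriptors are too few", {
  x <- matrix(rep(c(0, 1, 5), each = 4), 3, 4, byrow = TRUE)
  expect_warning(cb <- fit_codebook(rbind(x, x), K = 8, seed = 1),
                 "reducing K")
  expect_lte(cb$K, 3L)
})

test_that("a descriptor at a component mean has a zero first-order block", {
  tc <- two_clouds()
  cb <- fit_codebook(tc$x, K = 2, projected_dim = 3, seed = 1)
  # raw-space point whose projection is exactly component 1's mean
  x_at_mean <- cb$center + as.numeric(cb$rotation %*% cb$means[, 1])
  v <- encode_fisher(matrix(x_at_mean, 1), cb)
  dp <- cb$projected_dim
  expect_lt(max(abs(as.numeric(v)[seq_len(dp)])), 1e-6)
})

test_that("embeddings are unit-norm and duplication-invariant", {
  tc <- two_clouds()
  cb <- fit_codebook(tc$x, K = 2, seed = 1)
  d <- tc$x[1:10, ]
  v1 <- encode_fisher(d, cb)
  v2 <- encode_fisher(rbind(d, d), cb)
  expect_equal(sum(as.numeric(v1)^2), 1, tolerance = 1e-9)
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-9)
  expect_length(as.numeric(v1), 2L * cb$K * cb$projected_dim)
})

test_that("an empty descriptor set encodes to a flagged zero vector", {
  tc <- two_clouds()
  cb <- fit_codebook(tc$x, K = 2, seed = 1)
  v <- encode_fisher(matrix(numeric(0), 0, ncol(tc$x)), cb)
  expect_true(attr(v, "empty"))
  expect_true(all(as.numeric(v) == 0))
})

test_that("the clip-to-embedding pipeline is deterministic", {
  clip <- translating_clip()
  trs <- extract_trajectories(clip)
  d <- compute_descriptors(trs, clip)
  cb <- fit_codebook(d, K = 2, seed = 5)
  e1 <- encode_clip(clip, cb)
  e2 <- encode_clip(clip, cb)
  expect_identical(e1, e2)
  expect_equal(sum(as.numeric(e1)^2), 1, tolerance = 1e-9)
})
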