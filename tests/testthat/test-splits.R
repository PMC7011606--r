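test_that("the printed class counts reproduce 840/208 instances per split", {
  bags <- make_feature_bags(c(166, 228, 406, 248), dim = 4,
                            occlusion_rate = 0, seed = 1)
  expect_length(bags, 1048L)
  sp <- make_splits(bags, n_splits = 5, train_frac = 0.8, seed = 0)
  for (s in sp$splits) {
    expect_length(s$train, 840L)
    expect_length(s$test, 208L)
    # at 5 views per instance this is 4200 training / 1040 testing videos
    expect_identical(5L * length(s$train), 4200L)
    expect_identical(5L * length(s$test), 1040L)
  }
})

test_that("splits are disjoint, complete and per-class ceiling-stratified", {
  counts <- c(13, 27, 40, 21)
  bags <- make_feature_bags(counts, dim = 4, seed = 2)
  labels <- sapply(bags, function(b) b$label)
  ids <- sapply(bags, function(b) b$instance_id)
  sp <- make_splits(bags, n_splits = 3, train_frac = 0.8, seed = 4)
  for (s in sp$splits) {
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), ids)
    for (ci in seq_along(counts)) {
      cl_ids <- ids[labels == action_classes()[ci]]
      expect_identical(sum(s$train %in% cl_ids),
                       as.integer(ceiling(0.8 * counts[ci])))
    }
  }
})

test_that("two balanced classes of 10 give a 16/4 split", {
  bags <- make_feature_bags(c(10, 10, 2, 2), dim = 4, seed = 1)
  bags <- bags[sapply(bags, function(b) b$label) %in%
                 c("crawling", "sitting")]
  sp <- make_splits(bags, n_splits = 1, train_frac = 0.8, seed = 1)
  expect_length(sp$splits[[1]]$train, 16L)
  expect_length(sp$splits[[1]]$test, 4L)
  labels <- sapply(bags, function(b) b$label)
  ids <- sapply(bags, function(b) b$instance_id)
  for (cl in c("crawling", "sitting")) {
    expect_identical(sum(sp$splits[[1]]$train %in% ids[labels == cl]), 8L)
  }
})

test_that("split plans are reproducible from the seed", {
  bags <- make_feature_bags(c(5, 5, 5, 5), dim = 4, seed = 1)
  expect_identical(make_splits(bags, seed = 9), make_splits(bags, seed = 9))
  expect_false(identical(make_splits(bags, seed = 9)$splits,
                         make_splits(bags, seed = 10)$splits))
})

test_that("a class with fewer than two instances cannot be stratified", {
  bags <- make_feature_bags(c(5, 5, 5, 1), dim = 4, seed = 1)
  expect_error(make_splits(bags), "fewer than 2")
})

test_that("degenerate train fractions are rejected", {
  bags <- make_feature_bags(c(3, 3, 3, 3), dim = 4, seed = 1)
  expect_error(make_splits(bags, train_frac = 0), "train_frac")
  expect_error(make_splits(bags, train_frac = 1), "train_frac")
})
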