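# Bags with exactly one informative view; the generator records which.
single_witness_bags <- function(n_per_class = 12, dim = 10, sep = 4,
                                n_views = 5, seed = 1) {
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(dim * 4), dim, 4)))
  bags <- list()
  k <- 0
  for (ci in 1:4) for (b in seq_len(n_per_class)) {
    k <- k + 1
    emb <- matrix(rnorm(n_views * dim), n_views, dim)
    wit <- sample.int(n_views, 1)
    emb[wit, ] <- emb[wit, ] + sep * basis[, ci]
    info <- rep(FALSE, n_views); info[wit] <- TRUE
    bags[[k]] <- mv_instance(sprintf("b%03d", k), emb,
                             label = action_classes()[ci],
                             informative_views = info)
  }
  bags
}

test_that("witness alternation recovers the informative views", {
  bags <- single_witness_bags(seed = 11)
  model <- train_mi_svm(bags)
  labels <- sapply(bags, function(b) b$label)
  hits <- 0; total <- 0
  for (cl in action_classes()) {
    pos <- bags[labels == cl]
    wit <- model$witnesses[[cl]]
    truth <- sapply(pos, function(b) which(b$informative_views))
    hits <- hits + sum(wit == truth)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.9)
})

test_that("iteration 0 starts from label transfer", {
  bags <- single_witness_bags(n_per_class = 5, seed = 2)
  model <- train_mi_svm(bags)
  # every positive bag contributes all of its 5 views at initialization
  expect_identical(unname(model$init_positive_rows),
                   rep(5L * 5L, 4L))
})

test_that("identical views make the witness choice vacuous", {
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(8 * 4), 8, 4)))
  bags <- list()
  k <- 0
  for (ci in 1:4) for (b in 1:6) {
    k <- k + 1
    v <- rnorm(8) + 3 * basis[, ci]
    emb <- matrix(rep(v, each = 5), 5, 8)
    bags[[k]] <- mv_instance(sprintf("b%03d", k), emb,
                             label = action_classes()[ci])
  }
  m1 <- train_mi_svm(bags)
  m2 <- train_mi_svm(bags)
  expect_identical(m1$W, m2$W)
  expect_true(all(m1$converged))
  # bag score = any view's score, so prediction equals single-view argmax
  for (b in bags[c(1, 7, 13, 19)]) {
    s <- crilearn:::ovr_scores(m1, b$embeddings[1, , drop = FALSE])
    expect_identical(predict_mi(m1, b), action_classes()[which.max(s)])
  }
})

test_that("bag scores match an exhaustive per-view oracle", {
  bags <- single_witness_bags(n_per_class = 6, seed = 3)
  model <- train_mi_svm(bags)
  for (b in bags[seq(1, 24, by = 5)]) {
    s <- crilearn:::ovr_scores(model, b$embeddings)
    oracle <- model$classes[which.max(apply(s, 2, max))]
    expect_identical(predict_mi(model, b), oracle)
  }
})

test_that("exact score ties break by fixed class order", {
  model <- manual_model(matrix(0, 4, 4), approach = "mi-svm")
  bag <- onehot_bag(c("walking", "sitting"))
  expect_identical(predict_mi(model, bag), "crawling")
})

test_that("the hinge objective is non-increasing across alternations", {
  bags <- single_witness_bags(n_per_class = 10, sep = 2.5, seed = 9)
  model <- train_mi_svm(bags)
  for (cl in action_classes()) {
    obj <- model$objective[[cl]]
    if (length(obj) >= 2) {
      expect_true(all(diff(obj) <= 1e-6 + 1e-6 * abs(obj[-length(obj)])))
    }
  }
})

test_that("hitting the alternation cap warns and flags non-convergence", {
  bags <- single_witness_bags(n_per_class = 8, sep = 1.0, seed = 13)
  expect_warning(model <- train_mi_svm(bags, max_alternations = 1L),
                 "did not converge")
  expect_false(all(model$converged))
})
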