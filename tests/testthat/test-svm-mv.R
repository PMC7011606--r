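test_that("label transfer unrolls each 5-view bag into 5 labeled rows", {
  bags <- make_feature_bags(c(3, 3, 3, 3), dim = 6, occlusion_rate = 0,
                            seed = 1)
  u <- crilearn:::unroll_bags(bags)
  expect_identical(nrow(u$x), 5L * length(bags))
  for (i in seq_along(bags)) {
    expect_identical(unique(u$label[u$bag == i]), bags[[i]]$label)
    expect_identical(sum(u$bag == i), 5L)
  }
})

test_that("separable per-view features give 100% training-view accuracy", {
  bags <- make_feature_bags(c(6, 6, 6, 6), dim = 8, occlusion_rate = 0,
                            class_separation = 6, seed = 2)
  model <- train_svm_mv(bags)
  u <- crilearn:::unroll_bags(bags)
  s <- crilearn:::ovr_scores(model, u$x)
  pred <- action_classes()[apply(s, 1, which.max)]
  expect_identical(mean(pred == u$label), 1)
})

test_that("training is deterministic", {
  bags <- make_feature_bags(c(5, 5, 5, 5), dim = 6, seed = 3)
  m1 <- train_svm_mv(bags, seed = 1)
  m2 <- train_svm_mv(bags, seed = 1)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
})

test_that("a class missing from training is an error", {
  bags <- make_feature_bags(c(4, 4, 4, 4), dim = 6, seed = 1)
  bags <- bags[sapply(bags, function(b) b$label) != "walking"]
  expect_error(train_svm_mv(bags), "walking")
})

test_that("strict majority wins the vote", {
  model <- manual_model(diag(4))
  bag <- onehot_bag(c("walking", "walking", "walking", "sitting",
                      "standing"))
  expect_identical(predict_mv(model, bag), "walking")
})

test_that("vote ties break by the larger summed decision score", {
  model <- manual_model(diag(4))
  # 2 sitting votes (gain 1), 2 standing votes (gain 1.2), 1 walking vote:
  # tied on votes; standing has the larger summed score
  emb <- rbind(c(0, 1.0, 0, 0), c(0, 1.0, 0, 0),
               c(0, 0, 1.2, 0), c(0, 0, 1.2, 0),
               c(0, 0, 0, 0.5))
  bag <- mv_instance("t", emb)
  expect_identical(predict_mv(model, bag), "standing")
  # brute-force oracle: per-class summed scores among tied classes
  s <- crilearn:::ovr_scores(model, emb)
  votes <- tabulate(apply(s, 1, which.max), 4)
  tied <- which(votes == max(votes))
  oracle <- action_classes()[tied[which.max(colSums(s)[tied])]]
  expect_identical(predict_mv(model, bag), oracle)
})

test_that("a single-view bag returns that view's prediction", {
  model <- manual_model(diag(4))
  bag <- onehot_bag("crawling")
  expect_identical(predict_mv(model, bag), "crawling")
})

test_that("when all views agree the fused label is the per-view label", {
  bags <- make_feature_bags(c(4, 4, 4, 4), dim = 6, occlusion_rate = 0,
                            class_separation = 6, seed = 5)
  model <- train_svm_mv(bags)
  for (b in bags[c(1, 6, 11, 16)]) {
    s <- crilearn:::ovr_scores(model, b$embeddings)
    per_view <- action_classes()[apply(s, 1, which.max)]
    if (length(unique(per_view)) == 1L) {
      expect_identical(predict_mv(model, b), per_view[1])
    }
  }
})

test_that("predicting with the wrong approach is an error", {
  bags <- make_feature_bags(c(3, 3, 3, 3), dim = 6, seed = 1)
  model <- train_svm_mv(bags)
  expect_error(predict_mi(model, bags[[1]]), "MI-SVM")
})
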