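two_segment_script <- function(...) {
  scene_script(data.frame(action = c("walking", "sitting"),
                          duration_frames = c(18, 18)), ...)
}

test_that("zero occlusion renders every view visible", {
  rs <- render_session(two_segment_script(n_views = 3, occlusion_rate = 0,
                                          seed = 1))
  vis <- as.matrix(rs$annotations[, grep("visible_view",
                                         names(rs$annotations))])
  expect_true(all(vis))
  expect_true(all(!rs$occluded))
})

test_that("occlusion draws match the requested rate", {
  set.seed(123)
  occ <- crilearn:::draw_occlusions(1000, 5, 0.4)
  expect_lt(abs(mean(occ) - 0.4), 0.03)
})

test_that("the default configuration matches the five-camera 15 fps rig", {
  sc <- scene_script(data.frame(action = "walking", duration_frames = 15))
  expect_identical(sc$n_views, 5L)
  expect_identical(sc$fps, 15)
  rs <- render_session(sc, width = 32, height = 24)
  expect_length(rs$clips, 5L)
  expect_true(all(sapply(rs$clips, function(cl) cl$fps) == 15))
})

test_that("annotations match the archetype driving each frame", {
  rs <- render_session(two_segment_script(n_views = 2, seed = 3))
  expect_identical(rs$annotations$label,
                   rep(c("walking", "sitting"), each = 18))
  expect_identical(rs$annotations$frame, 0:35)
})

test_that("segments shorter than the trajectory length are rejected", {
  sc <- scene_script(data.frame(action = "walking", duration_frames = 10))
  expect_error(render_session(sc, L = 15), "at least L")
})

test_that("rendering is reproducible from the script seed", {
  rs1 <- render_session(two_segment_script(n_views = 2, occlusion_rate = 0.3,
                                           n_distractors = 1, seed = 9))
  rs2 <- render_session(two_segment_script(n_views = 2, occlusion_rate = 0.3,
                                           n_distractors = 1, seed = 9))
  expect_identical(rs1$clips[[1]]$frames, rs2$clips[[1]]$frames)
  expect_identical(rs1$occluded, rs2$occluded)
})

test_that("feature bags reproduce the study's instance and video counts", {
  bags <- make_feature_bags(c(166, 228, 406, 248), dim = 4, seed = 1)
  expect_length(bags, 1048L)
  expect_identical(sum(sapply(bags, function(b) nrow(b$embeddings))), 5240L)
  tab <- table(sapply(bags, function(b) b$label))
  expect_identical(as.integer(tab[action_classes()]),
                   c(166L, 228L, 406L, 248L))
})

test_that("clean well-separated bags are perfectly classifiable", {
  bags <- make_feature_bags(c(10, 10, 10, 10), dim = 8, occlusion_rate = 0,
                            class_separation = 6, seed = 2)
  sp <- make_splits(bags, n_splits = 1, seed = 1)
  expect_equal(evaluate("svm-mv", bags, sp)$mean_accuracy, 100)
})

test_that("bag metadata marks exactly the occluded views", {
  bags <- make_feature_bags(c(20, 20, 20, 20), dim = 8,
                            occlusion_rate = 0.4, seed = 5)
  info <- unlist(lapply(bags, function(b) b$informative_views))
  expect_lt(abs(mean(!info) - 0.4), 0.08)
  # uninformative views come from the background distribution: their mean
  # norm is clearly below the informative views' (separated) norm
  norms <- unlist(lapply(bags, function(b) sqrt(rowSums(b$embeddings^2))))
  expect_gt(mean(norms[info]), mean(norms[!info]))
})
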