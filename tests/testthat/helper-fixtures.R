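# Shared fixtures, all built in code.

# Textured Gaussian blob centred at (cx, cy); the texture translates with the
# blob so optical flow on it is a rigid translation.
blob_frame <- function(cx, cy = 24, w = 64, h = 48, radius = 8) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  mask <- exp(-2 * (((xs - cx) / radius)^2 + ((ys - cy) / radius)^2))
  0.1 + 0.8 * mask * (0.5 + 0.5 * sin(0.9 * (xs - cx)) * cos(1.1 * (ys - cy)))
}

translating_clip <- function(n_frames = 16, dx = 1, x0 = 20) {
  video_clip(lapply(seq_len(n_frames) - 1, function(t) blob_frame(x0 + dx * t)),
             fps = 15)
}

static_clip <- function(n_frames = 16) {
  video_clip(rep(list(blob_frame(20)), n_frames), fps = 15)
}

constant_clip <- function(n_frames = 16, value = 0.5) {
  video_clip(rep(list(matrix(value, 48, 64)), n_frames), fps = 15)
}

# Hand-built straight-line trajectory (for descriptor tests that bypass
# extraction).
straight_trajectory <- function(x0 = 20, y0 = 24, dx = 1, dy = 0, L = 15,
                                start_frame = 0) {
  pts <- cbind(x0 + dx * (seq_len(L) - 1), y0 + dy * (seq_len(L) - 1))
  list(points = pts, start_frame = start_frame)
}

# Random seeded row-stochastic 4x3x4 transition tensor.
random_tensor <- function(seed) {
  set.seed(seed)
  p <- array(stats::rgamma(48, 1), c(4, 3, 4))
  sweep(p, c(1, 2), apply(p, c(1, 2), sum), "/")
}

# A cri_svm model with hand-set weights, for fusion/tie-break tests.
manual_model <- function(W, b = rep(0, 4), approach = "svm-mv") {
  structure(list(approach = approach, classes = action_classes(),
                 W = W, b = stats::setNames(b, action_classes()), C = 1,
                 seed = 0),
            class = "cri_svm")
}

# Bag whose views are one-hot rows: view v votes for class class_of_view[v]
# when scored against the identity weight matrix.
onehot_bag <- function(class_of_view, gain = 1) {
  emb <- matrix(0, length(class_of_view), 4)
  for (v in seq_along(class_of_view)) {
    emb[v, match(class_of_view[v], action_classes())] <- gain[
      ((v - 1) %% length(gain)) + 1]
  }
  mv_instance("bag1", emb)
}
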