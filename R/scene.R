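#' Synthetic scene script
#'
#' Describes a multi-view session to render: a sequence of action segments
#' (one motion archetype each), the camera count, frame rate, per-view
#' occlusion probability and number of distractor agents. The four motion
#' archetypes emulate the gross-motor classes:
#' \describe{
#'   \item{crawling}{low, wide agent oscillating horizontally at crawl pace}
#'   \item{sitting}{low, wide agent, essentially static with a slight rock}
#'   \item{standing}{tall, narrow agent, essentially static with a slight
#'     sway}
#'   \item{walking}{tall agent translating horizontally with a vertical gait
#'     bounce}
#' }
#' Sitting and standing deliberately differ mainly in agent geometry, not
#' motion, so that — as with real data — motion-based features struggle to
#' separate them.
#'
#' @param segments Data frame with columns `action` (from
#'   [action_classes()]) and `duration_frames`.
#' @param n_views Number of synchronized camera views (default 5).
#' @param fps Frames per second (default 15).
#' @param occlusion_rate Probability that a given view is occluded for a
#'   given segment (default 0).
#' @param n_distractors Independently moving non-child agents (default 0);
#'   distractors reuse the archetype motions, genuinely confounding
#'   scene-level features.
#' @param seed Integer seed.
#' @return Object of class `scene_script`.
#' @export
scene_script <- function(segments, n_views = 5L, fps = 15, occlusion_rate = 0,
                         n_distractors = 0L, seed = 1) {
  stopifnot(is.data.frame(segments),
            all(c("action", "duration_frames") %in% names(segments)))
  if (!all(segments$action %in% action_classes())) {
    stop("unknown action(s) in script: ",
         paste(setdiff(segments$action, action_classes()), collapse = ", "),
         call. = FALSE)
  }
  if (occlusion_rate < 0 || occlusion_rate >= 1) {
    stop("occlusion_rate must lie in [0, 1)", call. = FALSE)
  }
  if (n_views < 1L) stop("n_views must be >= 1", call. = FALSE)
  structure(list(segments = segments, n_views = as.integer(n_views),
                 fps = fps, occlusion_rate = occlusion_rate,
                 n_distractors = as.integer(n_distractors), seed = seed),
            class = "scene_script")
}

# Per-(segment, view) occlusion draws; caller controls the RNG state.
draw_occlusions <- function(n_segments, n_views, occlusion_rate) {
  matrix(stats::runif(n_segments * n_views) < occlusion_rate,
         n_segments, n_views)
}

# Archetype kinematics: center position and body half-sizes at time t
# (seconds). Amplitudes/speeds are synthetic fixtures chosen so classes are
# distinguishable but overlapping (sitting vs standing differ mainly in
# geometry).
archetype_state <- function(action, t, cx, ground_y, phase = 0) {
  switch(action,
    crawling = list(x = cx + 10 * sin(2 * pi * 0.35 * t + phase),
                    y = ground_y - 4, hw = 7, hh = 3.5),
    sitting = list(x = cx + 1.2 * sin(2 * pi * 0.6 * t + phase),
                   y = ground_y - 5, hw = 6, hh = 4),
    standing = list(x = cx + 1.2 * sin(2 * pi * 0.25 * t + phase),
                    y = ground_y - 9 + 0.8 * sin(2 * pi * 0.5 * t + phase),
                    hw = 3, hh = 9),
    walking = list(x = cx + 12 * sin(2 * pi * 0.25 * t + phase),
                   y = ground_y - 9 + 1.5 * abs(sin(2 * pi * 1.2 * t +
                                                      phase)),
                   hw = 3.5, hh = 9),
    stop("unknown archetype: ", action))
}

# Paint a textured soft-edged agent into a frame; the texture translates
# with the agent so tracked points on it move rigidly.
paint_agent <- function(frame, st, freq = c(0.9, 1.1), amp = 0.8) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- (xs - st$x) / st$hw
  dy <- (ys - st$y) / st$hh
  mask <- exp(-2 * (dx^2 + dy^2))
  tex <- 0.5 + 0.5 * sin(freq[1L] * (xs - st$x)) *
    cos(freq[2L] * (ys - st$y))
  frame + amp * mask * tex
}

#' Render a synthetic multi-view session
#'
#' Produces one frame-synchronized [video_clip()] per camera view plus the
#' matching per-frame annotation table. The child agent follows the
#' archetype of the current segment; each view sees the scene with a
#' per-view horizontal parallax shift (2-D orthographic rendering, no 3-D
#' camera model). For each (view, segment) pair, with probability
#' `occlusion_rate` the child is hidden behind a static occluder mask in
#' that view and the corresponding visibility flags are `FALSE`. Distractor
#' agents (visible in every view) follow their own archetype motions.
#'
#' @param script A [scene_script()].
#' @param width,height Frame size in pixels (default 64 x 48).
#' @param L Minimum segment length in frames (trajectory length; segments
#'   shorter than `L` are an error).
#' @return List with `clips` (list of `n_views` clips), `annotations` (an
#'   `annotation_table` with per-view visibility flags), and `occluded`
#'   (segments x views logical matrix).
#' @export
render_session <- function(script, width = 64L, height = 48L, L = 15L) {
  stopifnot(inherits(script, "scene_script"))
  seg <- script$segments
  if (any(seg$duration_frames < L)) {
    stop("every segment must last at least L = ", L, " frames",
         call. = FALSE)
  }
  rng <- local_rng(script$seed)
  on.exit(rng())
  n_views <- script$n_views
  nf_total <- sum(seg$duration_frames)
  occluded <- draw_occlusions(nrow(seg), n_views, script$occlusion_rate)
  view_shift <- round(seq(-6, 6, length.out = n_views))
  ground_y <- height - 6
  cx0 <- width / 2
  # distractor setup: archetype, location, phase (shared across views)
  distr <- replicate(script$n_distractors, list(
    action = sample(action_classes(), 1L),
    cx = stats::runif(1L, width * 0.15, width * 0.85),
    phase = stats::runif(1L, 0, 2 * pi),
    freq = stats::runif(2L, 0.6, 1.3)), simplify = FALSE)
  frames_per_view <- lapply(seq_len(n_views), function(v) {
    vector("list", nf_total)
  })
  ann <- data.frame(frame = seq_len(nf_total) - 1L,
                    label = rep(seg$action, seg$duration_frames),
                    stringsAsFactors = FALSE)
  vis <- matrix(TRUE, nf_total, n_views)
  child_phase <- stats::runif(1L, 0, 2 * pi)
  child_freq <- stats::runif(2L, 0.7, 1.2)
  f_global <- 0L
  for (s in seq_len(nrow(seg))) {
    for (f in seq_len(seg$duration_frames[s])) {
      f_global <- f_global + 1L
      t_sec <- (f - 1L) / script$fps
      for (v in seq_len(n_views)) {
        fr <- matrix(0.1, height, width)
        for (dd in distr) {
          st_d <- archetype_state(dd$action, t_sec, dd$cx + view_shift[v],
                                  ground_y, dd$phase)
          fr <- paint_agent(fr, st_d, freq = dd$freq, amp = 0.5)
        }
        if (occluded[s, v]) {
          # static occluder panel where the child would be
          fr[seq(ground_y - 16, ground_y),
             seq(max(1, cx0 - 16 + view_shift[v]),
                 min(width, cx0 + 16 + view_shift[v]))] <- 0.6
          vis[f_global, v] <- FALSE
        } else {
          st_c <- archetype_state(seg$action[s], t_sec,
                                  cx0 + view_shift[v], ground_y,
                                  child_phase)
          fr <- paint_agent(fr, st_c, freq = child_freq, amp = 0.8)
        }
        frames_per_view[[v]][[f_global]] <- pmin(fr, 1)
      }
    }
  }
  for (v in seq_len(n_views)) {
    ann[[sprintf("visible_view_%d", v - 1L)]] <- vis[, v]
  }
  clips <- lapply(seq_len(n_views), function(v) {
    video_clip(frames_per_view[[v]], fps = script$fps, view_id = v - 1L)
  })
  list(clips = clips, annotations = annotation_table(ann, fps = script$fps),
       occluded = occluded)
}
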