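#' Extract short dense trajectories from a clip
#'
#' Tracks densely seeded points for `L` consecutive frames (one second at the
#' default `L = 15` and 15 fps). Each frame, new tracks are seeded on a
#' regular pixel grid of the given stride wherever no active track is nearby;
#' active points are advected by iterative Lucas-Kanade flow, median-filtered
#' over neighbouring tracked points. A track that reaches `L` points is
#' finalized; tracks whose total displacement is below `min_displacement`
#' (static points) are discarded, as are tracks that leave the frame.
#'
#' Camera-motion compensation is deliberately omitted: the camera rig is
#' static, so all image motion is scene motion.
#'
#' @param clip A [video_clip()].
#' @param sampling_stride Seeding grid stride in pixels (default 5).
#' @param L Trajectory length in frames (default 15).
#' @param min_displacement Minimum total displacement in pixels for a track
#'   to survive (default 1).
#' @param min_eigen Structure-tensor threshold for seeding: grid points whose
#'   local gradient structure tensor has a smaller minimum eigenvalue are in
#'   homogeneous areas, cannot be tracked reliably, and are not seeded
#'   (default 0.05).
#' @return List of trajectories, each a list with `points` (an `L x 2` matrix
#'   of `(x, y)` image coordinates) and `start_frame` (0-based index within
#'   the clip). A clip shorter than `L` frames yields an empty list with a
#'   warning.
#' @export
extract_trajectories <- function(clip, sampling_stride = 5L, L = 15L,
                                 min_displacement = 1, min_eigen = 0.05) {
  stopifnot(inherits(clip, "video_clip"))
  nf <- n_frames(clip)
  if (nf < L) {
    warning(sprintf("clip has %d frames, fewer than L = %d; no trajectories",
                    nf, L), call. = FALSE)
    return(list())
  }
  w <- frame_width(clip); h <- frame_height(clip)
  margin <- 5
  gx <- seq(margin, w - margin, by = sampling_stride)
  gy <- seq(margin, h - margin, by = sampling_stride)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  near2 <- (sampling_stride / 2)^2

  active <- list()   # each: list(points = growing matrix, start = frame idx)
  done <- list()

  seed_tracks <- function(active, start_frame) {
    if (length(active)) {
      cur <- do.call(rbind, lapply(active, function(tr) {
        tr$points[nrow(tr$points), , drop = FALSE]
      }))
      free <- vapply(seq_len(nrow(grid)), function(g) {
        min((cur[, 1L] - grid[g, 1L])^2 + (cur[, 2L] - grid[g, 2L])^2) > near2
      }, logical(1L))
    } else {
      free <- rep(TRUE, nrow(grid))
    }
    cand <- which(free)
    if (length(cand)) {
      textured <- structure_min_eigen(clip$frames[[start_frame]],
                                      grid[cand, , drop = FALSE]) >= min_eigen
      cand <- cand[textured]
    }
    for (g in cand) {
      active[[length(active) + 1L]] <- list(
        points = grid[g, , drop = FALSE], start = start_frame)
    }
    active
  }

  active <- seed_tracks(active, 1L)
  for (t in seq_len(nf - 1L)) {
    if (!length(active)) {
      if (t < nf - 1L) active <- seed_tracks(active, t + 1L)
      next
    }
    pts <- do.call(rbind, lapply(active, function(tr) {
      tr$points[nrow(tr$points), , drop = FALSE]
    }))
    fl <- lk_flow_points(clip$frames[[t]], clip$frames[[t + 1L]], pts)
    fl <- median_filter_point_flow(pts, fl, radius = 2 * sampling_stride)
    new_pts <- pts + fl
    keep <- new_pts[, 1L] >= 1 & new_pts[, 1L] <= w &
      new_pts[, 2L] >= 1 & new_pts[, 2L] <= h
    nxt <- list()
    for (i in seq_along(active)) {
      if (!keep[i]) next
      tr <- active[[i]]
      tr$points <- rbind(tr$points, new_pts[i, , drop = FALSE])
      if (nrow(tr$points) == L) {
        disp <- diff(tr$points)
        if (sum(sqrt(rowSums(disp^2))) >= min_displacement) {
          done[[length(done) + 1L]] <- list(
            points = unname(tr$points), start_frame = tr$start - 1L)
        }
      } else {
        nxt[[length(nxt) + 1L]] <- tr
      }
    }
    active <- nxt
    if (t < nf - 1L) active <- seed_tracks(active, t + 1L)
  }
  done
}
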