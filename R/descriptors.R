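#' Per-trajectory shape / motion / appearance descriptors
#'
#' Associates a fixed-dimension descriptor with every trajectory:
#' \describe{
#'   \item{shape (`2(L-1)` dims)}{the sequence of frame-to-frame
#'     displacements, L1-normalized by the total displacement magnitude, so
#'     the magnitudes of the normalized displacements sum to one.}
#'   \item{motion (`8 x 2 x 2 x 3` dims)}{orientation histograms of dense
#'     optical flow over a spatio-temporal tube that follows the trajectory:
#'     a `tube_size x tube_size` pixel patch split into 2 x 2 spatial cells
#'     and 3 temporal segments, 8 angular bins weighted by flow magnitude,
#'     L1-normalized over the block.}
#'   \item{appearance (`8 x 2 x 2 x 3` dims)}{gradient-orientation histograms
#'     over the same tube, L1-normalized; invariant to additive brightness
#'     shifts by construction.}
#' }
#' Tube patches extending past the image are clamped to the border. With the
#' default `L = 15` the total dimension is `28 + 96 + 96 = 220`.
#'
#' @param trajectories Output of [extract_trajectories()] on the same clip.
#' @param clip The [video_clip()] the trajectories came from.
#' @param tube_size Side of the square tube cross-section in pixels
#'   (default 12; split into 2 x 2 cells).
#' @param n_bins Angular bins per histogram (default 8).
#' @return Numeric matrix, one row per trajectory, with attribute `blocks`
#'   giving the column ranges of the shape/motion/appearance blocks.
#' @export
compute_descriptors <- function(trajectories, clip, tube_size = 12L,
                                n_bins = 8L) {
  stopifnot(inherits(clip, "video_clip"))
  if (!length(trajectories)) {
    d <- descriptor_dim(nrow_points = 15L, n_bins = n_bins)
    return(structure(matrix(numeric(0), 0L, d$total),
                     blocks = d$blocks))
  }
  L <- nrow(trajectories[[1L]]$points)
  d <- descriptor_dim(L, n_bins)
  # dense flow fields once per frame pair actually needed
  used <- sort(unique(unlist(lapply(trajectories, function(tr) {
    tr$start_frame + seq_len(L - 1L)   # 1-based frame-pair indices
  }))))
  fields <- vector("list", n_frames(clip) - 1L)
  for (t in used) {
    fields[[t]] <- lk_flow_field(clip$frames[[t]], clip$frames[[t + 1L]])
  }
  grads <- vector("list", n_frames(clip))
  out <- matrix(0, length(trajectories), d$total)
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    stopifnot(nrow(tr$points) == L)
    disp <- diff(tr$points)
    total <- sum(sqrt(rowSums(disp^2)))
    shape <- if (total > 0) as.vector(t(disp)) / total else numeric(2L *
                                                                    (L - 1L))
    seg_of <- cut(seq_len(L - 1L), 3L, labels = FALSE)
    motion <- numeric(d$hist_block)
    appear <- numeric(d$hist_block)
    for (s in seq_len(L - 1L)) {
      t_idx <- tr$start_frame + s       # frame-pair index (1-based)
      fl <- fields[[t_idx]]
      if (is.null(grads[[t_idx]])) {
        grads[[t_idx]] <- image_gradients(clip$frames[[t_idx]])
      }
      gr <- grads[[t_idx]]
      cells <- tube_cells(tr$points[s, ], tube_size,
                          frame_width(clip), frame_height(clip))
      seg <- seg_of[s]
      for (ci in seq_along(cells)) {
        idx <- cells[[ci]]
        off <- ((seg - 1L) * 4L + (ci - 1L)) * n_bins
        motion[off + seq_len(n_bins)] <- motion[off + seq_len(n_bins)] +
          orientation_hist(fl$u[idx], fl$v[idx], n_bins)
        appear[off + seq_len(n_bins)] <- appear[off + seq_len(n_bins)] +
          orientation_hist(gr$gx[idx], gr$gy[idx], n_bins)
      }
    }
    if (sum(motion) > 0) motion <- motion / sum(motion)
    if (sum(appear) > 0) appear <- appear / sum(appear)
    out[i, ] <- c(shape, motion, appear)
  }
  structure(out, blocks = d$blocks)
}

descriptor_dim <- function(nrow_points, n_bins = 8L) {
  shape <- 2L * (nrow_points - 1L)
  hist_block <- n_bins * 4L * 3L
  list(total = shape + 2L * hist_block, hist_block = hist_block,
       blocks = list(shape = seq_len(shape),
                     motion = shape + seq_len(hist_block),
                     appearance = shape + hist_block + seq_len(hist_block)))
}

# 2x2 spatial cells of the tube cross-section centred at (x, y); returns a
# list of 4 index matrices (cbind(row, col)), clamped to the image border.
tube_cells <- function(center, tube_size, w, h) {
  halfc <- tube_size / 4          # half-side of one cell
  cell_centers <- list(c(-halfc, -halfc), c(halfc, -halfc),
                       c(-halfc, halfc), c(halfc, halfc))
  lapply(cell_centers, function(cc) {
    xs <- round(center[1L] + cc[1L] + seq(-halfc, halfc - 1L))
    ys <- round(center[2L] + cc[2L] + seq(-halfc, halfc - 1L))
    xs <- pmin(pmax(xs, 1L), w)
    ys <- pmin(pmax(ys, 1L), h)
    as.matrix(expand.grid(row = ys, col = xs))
  })
}

# Magnitude-weighted orientation histogram of 2-D vectors; bin 1 starts at
# angle -pi (atan2 convention), so rightward motion (angle 0) falls in bin
# n_bins/2 + 1.
orientation_hist <- function(vx, vy, n_bins) {
  mag <- sqrt(vx^2 + vy^2)
  keep <- mag > 1e-9
  hist <- numeric(n_bins)
  if (!any(keep)) return(hist)
  ang <- atan2(vy[keep], vx[keep])
  bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  for (b in seq_along(bin)) hist[bin[b]] <- hist[bin[b]] + mag[keep][b]
  hist
}
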