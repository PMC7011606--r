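# Optical flow primitives shared by trajectory extraction and descriptor
# computation. Two flavours are provided: an accurate iterative Lucas-Kanade
# estimate at a sparse set of tracked points (used for point advection), and
# a one-shot dense field over the whole frame (used for the motion
# histograms of the spatio-temporal tube, where only the flow orientation
# matters).

# Bilinear sample of an image at continuous (x, y) = (col, row) coordinates,
# clamped to the image border.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1L)]
  i10 <- img[cbind(y0 + 1L, x0)]
  i11 <- img[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Iterative (Newton-refined) Lucas-Kanade flow at a set of points.
# points: n x 2 matrix of (x, y). Returns n x 2 matrix of (dx, dy).
lk_flow_points <- function(f1, f2, points, half = 4L, n_iter = 3L,
                           min_det = 1e-6) {
  n <- nrow(points)
  flow <- matrix(0, n, 2L)
  if (n == 0L) return(flow)
  offs <- seq(-half, half)
  # dy varies fastest so that matrix(patch, nrow) has rows = y, cols = x
  og <- expand.grid(dy = offs, dx = offs)
  for (p in seq_len(n)) {
    cx <- points[p, 1L]; cy <- points[p, 2L]
    xs <- cx + og$dx; ys <- cy + og$dy
    patch1 <- matrix(bilinear_sample(f1, xs, ys), 2L * half + 1L)
    # spatial gradients of the template patch (central differences)
    gx <- (patch1[, -(1:2)] - patch1[, 1:(ncol(patch1) - 2L)]) / 2
    gx <- gx[2:(nrow(patch1) - 1L), ]
    gy <- (patch1[-(1:2), ] - patch1[1:(nrow(patch1) - 2L), ]) / 2
    gy <- gy[, 2:(ncol(patch1) - 1L)]
    gxx <- sum(gx * gx); gyy <- sum(gy * gy); gxy <- sum(gx * gy)
    det <- gxx * gyy - gxy * gxy
    if (det < min_det) next
    d <- c(0, 0)
    inner <- which(abs(og$dx) <= half - 1L & abs(og$dy) <= half - 1L)
    p1_inner <- matrix(patch1, ncol = 1L)[inner]
    for (it in seq_len(n_iter)) {
      p2 <- bilinear_sample(f2, xs[inner] + d[1L], ys[inner] + d[2L])
      di <- p1_inner - p2
      bx <- sum(gx * di); by <- sum(gy * di)
      d <- d + c(gyy * bx - gxy * by, gxx * by - gxy * bx) / det
    }
    flow[p, ] <- d
  }
  flow
}

# Median-filter point flows over spatial neighbourhoods of tracked points:
# each point's flow is replaced by the component-wise median of the flows of
# all points within `radius`, suppressing isolated bad matches.
median_filter_point_flow <- function(points, flow, radius) {
  n <- nrow(points)
  if (n <= 1L) return(flow)
  d2 <- as.matrix(stats::dist(points))^2
  r2 <- radius^2
  out <- flow
  for (p in seq_len(n)) {
    nb <- which(d2[p, ] <= r2)
    if (length(nb) > 1L) {
      out[p, 1L] <- stats::median(flow[nb, 1L])
      out[p, 2L] <- stats::median(flow[nb, 2L])
    }
  }
  out
}

# Minimum eigenvalue of the gradient structure tensor in a window around
# each point; the classic "good features to track" criterion used to reject
# seeding in homogeneous (untrackable) areas.
structure_min_eigen <- function(frame, points, half = 4L) {
  g <- image_gradients(frame)
  gxx <- box_sum(g$gx * g$gx, half)
  gyy <- box_sum(g$gy * g$gy, half)
  gxy <- box_sum(g$gx * g$gy, half)
  h <- nrow(frame); w <- ncol(frame)
  ij <- cbind(pmin(pmax(round(points[, 2L]), 1L), h),
              pmin(pmax(round(points[, 1L]), 1L), w))
  a <- gxx[ij]; b <- gyy[ij]; c2 <- gxy[ij]
  0.5 * ((a + b) - sqrt((a - b)^2 + 4 * c2^2))
}

# Sliding box sum with border clamping, via integral images.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  cs <- cbind(0, t(apply(cs, 1L, cumsum)))
  i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
  cs[i2 + 1L, j2 + 1L] - cs[i1, j2 + 1L] - cs[i2 + 1L, j1] + cs[i1, j1]
}

# Image gradients by central differences (replicated borders).
image_gradients <- function(f) {
  h <- nrow(f); w <- ncol(f)
  gx <- (f[, c(2:w, w)] - f[, c(1, 1:(w - 1L))]) / 2
  gy <- (f[c(2:h, h), ] - f[c(1, 1:(h - 1L)), ]) / 2
  list(gx = gx, gy = gy)
}

# One-shot dense Lucas-Kanade flow field between two frames.
# Returns list(u, v): per-pixel horizontal and vertical flow matrices.
lk_flow_field <- function(f1, f2, r = 3L, min_det = 1e-6) {
  g <- image_gradients(f1)
  it <- f2 - f1
  sxx <- box_sum(g$gx * g$gx, r)
  syy <- box_sum(g$gy * g$gy, r)
  sxy <- box_sum(g$gx * g$gy, r)
  sxt <- box_sum(g$gx * it, r)
  syt <- box_sum(g$gy * it, r)
  det <- sxx * syy - sxy * sxy
  ok <- det > min_det
  u <- matrix(0, nrow(f1), ncol(f1))
  v <- matrix(0, nrow(f1), ncol(f1))
  u[ok] <- (-syy[ok] * sxt[ok] + sxy[ok] * syt[ok]) / det[ok]
  v[ok] <- (-sxx[ok] * syt[ok] + sxy[ok] * sxt[ok]) / det[ok]
  list(u = u, v = v)
}
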