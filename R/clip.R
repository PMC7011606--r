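#' Video clip container
#'
#' A clip is an ordered sequence of frames from one camera view. Frames are
#' grayscale matrices (rows = image y, columns = image x, values in `[0, 1]`);
#' RGB arrays are converted by luminance averaging.
#'
#' @param frames List of numeric matrices of identical dimensions (or
#'   `h x w x 3` arrays).
#' @param fps Frames per second; default 15, the recording rate of the
#'   five-camera rig.
#' @param view_id Camera index 0-4.
#' @param frame_offset Index of the first frame in session time (0-based).
#' @return Object of class `video_clip`.
#' @export
video_clip <- function(frames, fps = 15, view_id = 0L, frame_offset = 0L) {
  if (!length(frames)) stop("a clip needs at least one frame", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive",
                                         call. = FALSE)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- apply(f, c(1, 2), mean)
    as.matrix(f)
  })
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  structure(list(frames = frames, fps = fps, view_id = as.integer(view_id),
                 frame_offset = as.integer(frame_offset)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("video_clip: %d frames of %dx%d @ %g fps (view %d)\n",
              length(x$frames), d[1L], d[2L], x$fps, x$view_id))
  invisible(x)
}

n_frames <- function(clip) length(clip$frames)
frame_width <- function(clip) ncol(clip$frames[[1L]])
frame_height <- function(clip) nrow(clip$frames[[1L]])

#' Read a clip from a directory of numbered image frames
#'
#' Frames are PNG files whose lexicographic order is the temporal order
#' (0-based numbering recommended).
#'
#' @param dir Directory of `.png` frames.
#' @inheritParams video_clip
#' @return A [video_clip()].
#' @export
read_clip_dir <- function(dir, fps = 15, view_id = 0L, frame_offset = 0L) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG frames requires the 'png' package", call. = FALSE)
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no .png frames in ", dir, call. = FALSE)
  video_clip(lapply(files, function(f) png::readPNG(f)), fps = fps,
             view_id = view_id, frame_offset = frame_offset)
}

#' Write a clip as numbered PNG frames
#'
#' @param clip A [video_clip()].
#' @param dir Output directory (created if needed).
#' @export
write_clip_dir <- function(clip, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG frames requires the 'png' package", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_frames(clip))) {
    f <- pmin(pmax(clip$frames[[i]], 0), 1)
    png::writePNG(f, file.path(dir, sprintf("frame_%05d.png", i - 1L)))
  }
  invisible(dir)
}
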