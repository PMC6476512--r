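#' Construct a video stack
#'
#' A video stack is the in-memory surrogate of a high-speed videoendoscopy
#' recording: an 8-bit grayscale image sequence with a known frame rate.
#' Intensities are stored as a `height x width x frames` integer array.
#'
#' @param px Integer array of dimension `height x width x frames` with values
#'   in `[0, 255]`.
#' @param fps Frame rate in frames per second.
#' @return An object of class `video_stack` with elements `px` and `fps`.
#' @export
video_stack <- function(px, fps) {
  if (length(dim(px)) != 3L) {
    stop("`px` must be a height x width x frames array", call. = FALSE)
  }
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  storage.mode(px) <- "integer"
  structure(list(px = px, fps = fps), class = "video_stack")
}

#' @export
dim.video_stack <- function(x) dim(x$px)

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$px)
  cat(sprintf("<video_stack> %d x %d px, %d frames @ %g fps\n",
              d[1], d[2], d[3], x$fps))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based with half-open extents, so a ROI with `top = 0`,
#' `height = 4` covers pixel rows 0..3 (R rows 1..4).
#'
#' @param top,left 0-based offsets of the upper-left corner.
#' @param height,width Extents in pixels, both positive.
#' @return An object of class `roi`.
#' @export
roi <- function(top, left, height, width) {
  v <- c(top = top, left = left, height = height, width = width)
  if (anyNA(v) || any(v != round(v))) stop("roi fields must be integers", call. = FALSE)
  if (top < 0 || left < 0) stop("roi origin must be non-negative", call. = FALSE)
  if (height <= 0 || width <= 0) stop("roi extents must be positive", call. = FALSE)
  structure(as.list(v), class = "roi")
}

check_roi_inside <- function(r, h, w) {
  if (r$top + r$height > h || r$left + r$width > w) {
    stop(sprintf("roi (%d,%d,%d,%d) lies outside the %d x %d frame",
                 r$top, r$left, r$height, r$width, h, w), call. = FALSE)
  }
  invisible(r)
}

#' Scale a ROI between resolutions of a triad
#'
#' Divides all four ROI fields by `factor`, so that a ROI selected on the
#' original resolution maps onto the matching subsection of a block-averaged
#' reduction. All fields must be divisible by `factor`.
#'
#' @param r A [roi()].
#' @param factor Integer reduction factor (2 or 4); 1 returns `r` unchanged.
#' @export
scale_roi <- function(r, factor) {
  if (factor == 1) return(r)
  v <- c(r$top, r$left, r$height, r$width)
  if (any(v %% factor != 0)) {
    stop("roi coordinates must be divisible by the reduction factor", call. = FALSE)
  }
  roi(r$top / factor, r$left / factor, r$height / factor, r$width / factor)
}

#' Reduce spatial resolution by block averaging
#'
#' Each output pixel is the arithmetic mean of a `factor x factor` block of
#' source pixels, rounded to the nearest integer with halves rounded away
#' from zero. The frame rate is unchanged. This emulates recording the same
#' scene with a camera of half or quarter the linear resolution.
#'
#' @param video A [video_stack()].
#' @param factor Block edge length, 2 or 4. Frame height and width must be
#'   divisible by `factor`; padding or cropping is the caller's responsibility.
#' @return A [video_stack()] with dimensions divided by `factor`.
#' @export
block_downsample <- function(video, factor) {
  stopifnot(inherits(video, "video_stack"))
  if (!factor %in% c(2L, 4L)) stop("`factor` must be 2 or 4", call. = FALSE)
  d <- dim(video$px)
  if (d[1] %% factor != 0 || d[2] %% factor != 0) {
    stop("frame dimensions must be divisible by `factor`", call. = FALSE)
  }
  h2 <- d[1] %/% factor
  w2 <- d[2] %/% factor
  acc <- array(0, c(h2, w2, d[3]))
  for (i in seq_len(factor)) {
    for (j in seq_len(factor)) {
      acc <- acc + video$px[seq(i, d[1], by = factor),
                            seq(j, d[2], by = factor), , drop = FALSE]
    }
  }
  out <- round_half_away(acc / factor^2)
  video_stack(out, video$fps)
}

#' Build a resolution triad
#'
#' Returns the original recording together with its 2x2 and 4x4
#' block-averaged reductions. Both reductions are computed directly from the
#' original, so rounding to integer intensities is applied exactly once per
#' reduction (iterated 2x2 averaging can differ from direct 4x4 averaging in
#' the rounding step).
#'
#' @param video A [video_stack()] whose frame dimensions are divisible by 4.
#' @return A list with elements `sr1`, `sr2`, `sr3`.
#' @export
make_triad <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  d <- dim(video$px)
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0) {
    stop("frame dimensions must be divisible by 4 to build a triad", call. = FALSE)
  }
  list(sr1 = video,
       sr2 = block_downsample(video, 2L),
       sr3 = block_downsample(video, 4L))
}

#' Crop a video stack to a region of interest
#'
#' @param video A [video_stack()].
#' @param r A [roi()] lying fully inside the frame.
#' @return The cropped [video_stack()].
#' @export
crop_video <- function(video, r) {
  stopifnot(inherits(video, "video_stack"), inherits(r, "roi"))
  d <- dim(video$px)
  check_roi_inside(r, d[1], d[2])
  px <- video$px[(r$top + 1):(r$top + r$height),
                 (r$left + 1):(r$left + r$width), , drop = FALSE]
  video_stack(px, video$fps)
}
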