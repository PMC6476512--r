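#' Regular seed-point grid for region growing
#'
#' Seed points are laid out as a regular lattice over a region of interest.
#' Using a grid instead of hand-placed points keeps the segmentation
#' objective, and a close-meshed grid makes sure no dark area inside the
#' glottis is missed.
#'
#' @param r A [roi()] (0-based, half-open) the grid should cover.
#' @param spacing Lattice spacing in pixels, at least 1. A spacing larger
#'   than the ROI leaves a single point at the ROI origin.
#' @return An object of class `seed_grid` with a `points` matrix (0-based
#'   `row`, `col` positions), the `spacing` and the generating `roi`.
#' @export
make_seed_grid <- function(r, spacing) {
  stopifnot(inherits(r, "roi"))
  if (spacing < 1) stop("`spacing` must be at least 1", call. = FALSE)
  rows <- r$top + seq(0, r$height - 1, by = spacing)
  cols <- r$left + seq(0, r$width - 1, by = spacing)
  pts <- cbind(row = rep(rows, times = length(cols)),
               col = rep(cols, each = length(rows)))
  structure(list(points = pts, spacing = spacing, roi = r),
            class = "seed_grid")
}

#' Condense a seed grid for a higher resolution
#'
#' A grid drawn on the lowest-resolution member of a triad is condensed by
#' the resolution factor for the higher-resolution members: the covered ROI
#' scales by `factor` while the lattice spacing in pixels stays the same, so
#' the point count multiplies by `factor^2` and the mesh keeps the same
#' density relative to the glottis.
#'
#' @param grid A [make_seed_grid()] result.
#' @param factor Integer condensation factor (2 or 4); 1 returns the grid
#'   unchanged.
#' @export
condense_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "seed_grid"))
  if (factor == 1) return(grid)
  if (!factor %in% c(2L, 4L)) stop("`factor` must be 1, 2 or 4", call. = FALSE)
  r <- grid$roi
  big <- roi(r$top * factor, r$left * factor,
             r$height * factor, r$width * factor)
  make_seed_grid(big, grid$spacing)
}

#' Segmentation settings
#'
#' @param threshold Brightness threshold in `[0, 255]`; pixels strictly
#'   darker than this can join the glottal area. Thresholds are chosen by the
#'   operator (or taken from the rendering configuration for synthetic data),
#'   not estimated automatically.
#' @param connectivity `"4"` (default) or `"8"` neighborhood.
#' @param spacing Seed-grid spacing in pixels on the lowest resolution.
#' @export
segmentation_settings <- function(threshold, connectivity = c("4", "8"),
                                  spacing = 2L) {
  connectivity <- match.arg(connectivity)
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  }
  structure(list(threshold = threshold, connectivity = connectivity,
                 spacing = as.integer(spacing)),
            class = "segmentation_settings")
}

#' Seeded region growing on a single frame
#'
#' Grows the glottal area from every seed point: a pixel joins if it is
#' strictly darker than the brightness threshold and 4- (or 8-) connected to
#' a seed or to an already added pixel. Seeds sitting on pixels at or above
#' the threshold contribute nothing; an empty mask is a valid result.
#'
#' @param frame Integer intensity matrix.
#' @param grid A [make_seed_grid()] result (0-based coordinates).
#' @param threshold Brightness threshold.
#' @param connectivity `"4"` or `"8"`.
#' @return An object of class `glottis_mask`: logical matrix `mask` plus the
#'   pixel `area`.
#' @export
region_grow <- function(frame, grid, threshold, connectivity = c("4", "8")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.matrix(frame), inherits(grid, "seed_grid"))
  storage.mode(frame) <- "integer"
  mask <- region_grow_cpp(frame,
                          grid$points[, "row"] + 1L,
                          grid$points[, "col"] + 1L,
                          threshold,
                          connectivity == "8")
  structure(list(mask = mask, area = sum(mask)), class = "glottis_mask")
}

# Boundary pixels of a mask: true pixels with at least one 4-neighbour
# outside the mask (frame edges count as outside).
mask_boundary <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  which(mask & !interior, arr.ind = TRUE)
}

#' Anterior-posterior midline of a glottis mask
#'
#' The midline is the straight chord between the two contour points at
#' maximal mutual distance (the anterior and posterior ends of the glottis),
#' computed on a reference frame -- by convention the frame of maximal area --
#' and held fixed for the whole sequence. Its length is the glottal length.
#'
#' The anterior endpoint is the lexicographically smaller of the pair (by
#' row, then column), which fixes the orientation of the left/right split
#' deterministically.
#'
#' @param mask A `glottis_mask` (or plain logical matrix) with nonzero extent.
#' @return A list with `anterior`, `posterior` (pixel-center `(row, col)`
#'   coordinates) and `length` in pixels.
#' @export
compute_midline <- function(mask) {
  m <- if (inherits(mask, "glottis_mask")) mask$mask else mask
  if (!any(m)) stop("no glottis found: empty mask", call. = FALSE)
  b <- mask_boundary(m)
  pts <- unique(b)
  if (nrow(pts) > 3) {
    hull <- chull(pts[, 2], pts[, 1])
    pts <- pts[hull, , drop = FALSE]
  }
  dmat <- as.matrix(stats::dist(pts))
  dmax <- max(dmat)
  if (dmax <= 0) stop("no glottis extent: mask has a single point", call. = FALSE)
  idx <- which(dmat == dmax, arr.ind = TRUE)[1, ]
  p <- pts[idx[1], ]
  q <- pts[idx[2], ]
  ord <- order(c(p[1], q[1]), c(p[2], q[2]))
  ends <- rbind(p, q)[ord, , drop = FALSE]
  list(anterior = c(row = ends[1, 1], col = ends[1, 2]),
       posterior = c(row = ends[2, 1], col = ends[2, 2]),
       length = dmax)
}

# Per-pixel left-side weight for a midline: 1 strictly left, 0 strictly
# right, 0.5 exactly on the line. "Left" is the side with negative signed
# cross product relative to the posterior -> anterior direction.
midline_left_weights <- function(h, w, midline) {
  dr <- midline$anterior["row"] - midline$posterior["row"]
  dc <- midline$anterior["col"] - midline$posterior["col"]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  cross <- dr * (cols - midline$posterior["col"]) -
    dc * (rows - midline$posterior["row"])
  wl <- matrix(0, h, w)
  wl[cross < 0] <- 1
  wl[cross == 0] <- 0.5
  wl
}

#' Split a mask into left and right partial areas
#'
#' Pixels are assigned to a side by the sign of their cross product relative
#' to the posterior-to-anterior midline direction; pixels exactly on the line
#' count half to each side, so left + right always equals the total area.
#'
#' @param mask A `glottis_mask` or logical matrix.
#' @param midline A [compute_midline()] result.
#' @return Named numeric vector with elements `left` and `right` in pixels.
#' @export
partial_areas <- function(mask, midline) {
  m <- if (inherits(mask, "glottis_mask")) mask$mask else mask
  if (midline$length <= 0) stop("midline has zero length", call. = FALSE)
  if (!any(m)) return(c(left = 0, right = 0))
  wl <- midline_left_weights(nrow(m), ncol(m), midline)
  left <- sum(wl[m])
  c(left = left, right = sum(m) - left)
}

#' Segment a whole video stack into glottal area waveforms
#'
#' Runs seeded region growing on every frame with a fixed seed grid and
#' threshold, computes the midline on the frame of maximal area, and splits
#' each frame's area into left and right halves. Frames where nothing grows
#' yield an area of exactly 0 pixels (the "true closed phase").
#'
#' @param video A [video_stack()] (typically cropped to the glottal ROI).
#' @param settings A [segmentation_settings()].
#' @param grid A [make_seed_grid()] result matching the video's resolution.
#' @return A [gaw_triple()]; the midline is attached as attribute
#'   `"midline"`.
#' @export
segment_sequence <- function(video, settings, grid) {
  stopifnot(inherits(video, "video_stack"),
            inherits(settings, "segmentation_settings"),
            inherits(grid, "seed_grid"))
  d <- dim(video$px)
  conn8 <- settings$connectivity == "8"
  srow <- grid$points[, "row"] + 1L
  scol <- grid$points[, "col"] + 1L
  zero_w <- matrix(0, d[1], d[2])

  pass1 <- segment_stack_cpp(video$px, d[1], d[2], d[3], srow, scol,
                             settings$threshold, conn8, zero_w)
  totals <- pass1[, 1]
  if (all(totals == 0)) {
    out <- gaw_triple(totals, totals, totals, video$fps, NA_real_)
    attr(out, "midline") <- NULL
    return(out)
  }
  ref <- which.max(totals)
  ref_mask <- region_grow(video$px[, , ref], grid, settings$threshold,
                          settings$connectivity)
  midline <- compute_midline(ref_mask)
  wl <- midline_left_weights(d[1], d[2], midline)
  pass2 <- segment_stack_cpp(video$px, d[1], d[2], d[3], srow, scol,
                             settings$threshold, conn8, wl)
  total <- pass2[, 1]
  left <- pass2[, 2]
  out <- gaw_triple(total, left, total - left, video$fps, midline$length)
  attr(out, "midline") <- midline
  out
}
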