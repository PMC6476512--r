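# Strict local maxima of a series, plateau-aware: a run of equal values is a
# maximum if the neighbouring runs on both sides are lower; the boundary is
# the first frame of the plateau. Runs touching the ends of the series are
# not maxima.
local_maxima <- function(x) {
  r <- rle(x)
  n_runs <- length(r$values)
  if (n_runs < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-n_runs]))
  inner <- 2:(n_runs - 1)
  is_max <- r$values[inner] > r$values[inner - 1] &
    r$values[inner] > r$values[inner + 1]
  starts[inner][is_max]
}

# Topographic prominence of each peak: height above the higher of the two
# key saddles (minima towards the nearest strictly higher ground on each
# side, or towards the series end where no higher ground exists). Peaks of
# exactly equal height do not count as higher ground, so every summit of a
# periodic signal keeps its full prominence.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    hp <- x[p]
    left <- if (p > 1) x[1:(p - 1)] else numeric(0)
    higher <- which(left > hp)
    lmin <- if (length(higher)) min(left[(max(higher) + 1):length(left)])
            else if (length(left)) min(left) else hp
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    higher <- which(right > hp)
    rmin <- if (length(higher)) min(right[1:(min(higher) - 1)])
            else if (length(right)) min(right) else hp
    hp - max(lmin, rmin)
  }, numeric(1))
}

#' Maximum-based cycle detection on a glottal area waveform
#'
#' Each oscillation cycle starts at a sufficiently distinct local maximum and
#' ends one frame before the next such maximum. "Sufficiently distinct" is
#' operationalized as a topographic prominence of at least `prominence_frac`
#' times the global dynamic range of the series, with a minimum distance
#' between retained maxima of `max(4, 0.5 * median gap)` frames (peaks are
#' retained greedily by height). Ties on plateau maxima resolve to the first
#' frame of the plateau.
#'
#' @param gaw Numeric series (glottal area in pixels per frame) or a
#'   [gaw_triple()] (its total waveform is used).
#' @param fps Frame rate; taken from the triple if omitted.
#' @param prominence_frac Fraction of the global dynamic range a maximum must
#'   rise above its surroundings.
#' @param min_boundaries Minimum number of detected maxima required; the
#'   default of 23 guarantees that 20 consecutive cycles starting at the
#'   third are available downstream.
#' @return An object of class `cycle_set` with the boundary frames (1-based
#'   indices of the cycle start maxima) and the frame rate.
#' @export
detect_cycles <- function(gaw, fps = NULL, prominence_frac = 0.25,
                          min_boundaries = 23L) {
  if (inherits(gaw, "gaw_triple")) {
    if (is.null(fps)) fps <- gaw$fps
    gaw <- gaw$total
  }
  if (is.null(fps)) stop("`fps` must be supplied", call. = FALSE)
  if (length(gaw) < 3) stop("series too short for cycle detection", call. = FALSE)
  rng <- max(gaw) - min(gaw)
  peaks <- local_maxima(gaw)
  if (rng > 0 && length(peaks)) {
    prom <- peak_prominence(gaw, peaks)
    peaks <- peaks[prom >= prominence_frac * rng]
  } else {
    peaks <- integer(0)
  }
  if (length(peaks) > 2) {
    min_period <- max(4, floor(0.5 * median(diff(peaks))))
    keep <- logical(length(peaks))
    for (i in order(gaw[peaks], peaks, decreasing = c(TRUE, FALSE), method = "radix")) {
      if (!any(keep & abs(peaks - peaks[i]) < min_period)) keep[i] <- TRUE
    }
    peaks <- sort(peaks[keep])
  }
  if (length(peaks) < min_boundaries) {
    stop(sprintf(paste0("only %d cycle maxima detected; at least %d are needed ",
                        "to select 20 cycles starting at the third"),
                 length(peaks), min_boundaries), call. = FALSE)
  }
  structure(list(boundaries = peaks, fps = fps, selected = NULL,
                 primitives = NULL),
            class = "cycle_set")
}

#' Select the analysis cycles
#'
#' Starting with the third complete cycle, 20 consecutive cycles are
#' retained for parameter computation.
#'
#' @param cycles A [detect_cycles()] result.
#' @param n_select Number of consecutive cycles to keep.
#' @param skip Number of leading cycles to discard.
#' @return The `cycle_set` with `selected` set to the retained cycle start
#'   boundaries (a vector of `n_select + 1` frames).
#' @export
select_cycles <- function(cycles, n_select = 20L, skip = 2L) {
  stopifnot(inherits(cycles, "cycle_set"))
  n_complete <- length(cycles$boundaries) - 1L
  if (n_complete < skip + n_select) {
    stop(sprintf("only %d complete cycles available, %d are required",
                 n_complete, skip + n_select), call. = FALSE)
  }
  cycles$selected <- cycles$boundaries[(skip + 1L):(skip + n_select + 1L)]
  cycles
}

#' Per-cycle primitives of the selected cycles
#'
#' For every selected cycle (frames from one boundary up to, and excluding,
#' the next) the primitives feeding the parameter catalogue are computed:
#'
#' * `T`: period in frames (boundary gap),
#' * `A_max`, `A_min`, `D = A_max - A_min`: extrema and dynamic range (px),
#' * `E`: cycle energy, the sum of squared sample values (px^2 frames),
#' * `O`: open time, the number of frames with area strictly above 0,
#' * `c`: closing time, frames from the cycle start maximum to the first
#'   zero (or to the position of the cycle minimum when the glottis never
#'   fully closes),
#' * `o`: opening time, frames from the last zero (or the minimum position)
#'   to the cycle end,
#' * `p`: plateau time, the number of frames at or above
#'   `plateau_frac * A_max`.
#'
#' @param gaw Numeric series or [gaw_triple()] the boundaries refer to.
#' @param cycles A [select_cycles()] result.
#' @param plateau_frac Fraction of the cycle maximum defining the plateau
#'   band.
#' @return The `cycle_set` with a `primitives` data frame (one row per
#'   selected cycle).
#' @export
cycle_primitives <- function(gaw, cycles, plateau_frac = 0.95) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (inherits(gaw, "gaw_triple")) gaw <- gaw$total
  b <- cycles$selected
  if (is.null(b)) stop("cycles must be selected first (select_cycles)", call. = FALSE)
  n <- length(b) - 1L
  prim <- data.frame(T = diff(b), A_max = NA_real_, A_min = NA_real_,
                     D = NA_real_, E = NA_real_, O = NA_integer_,
                     c = NA_integer_, o = NA_integer_, p = NA_integer_,
                     start = b[-length(b)])
  for (i in seq_len(n)) {
    a <- gaw[b[i]:(b[i + 1] - 1L)]
    Ti <- length(a)
    amax <- max(a)
    amin <- min(a)
    zeros <- which(a == 0)
    if (length(zeros)) {
      cl <- zeros[1] - 1L
      op <- (Ti - 1L) - zeros[length(zeros)] + 1L
    } else {
      at_min <- which.min(a)
      cl <- at_min - 1L
      op <- Ti - at_min
    }
    prim$A_max[i] <- amax
    prim$A_min[i] <- amin
    prim$D[i] <- amax - amin
    prim$E[i] <- sum(a^2)
    prim$O[i] <- sum(a > 0)
    prim$c[i] <- cl
    prim$o[i] <- op
    prim$p[i] <- sum(a >= plateau_frac * amax)
  }
  cycles$primitives <- prim
  cycles
}
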