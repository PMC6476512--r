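#' Configuration of a synthetic phonation recording
#'
#' Describes one simulated subject: a dark, lens-shaped glottis oscillating on
#' brighter tissue, sampled at a high-speed-camera frame rate. Per-cycle
#' period and amplitude perturbation, the open quotient, left-right amplitude
#' and phase asymmetry, additive sensor noise and the glottis pixel scale are
#' all controllable, which gives downstream parameter computations a known
#' ground truth to recover.
#'
#' Sex-specific defaults place the fundamental frequency and the maximal
#' glottal pixel area in ranges typical of sustained phonation recorded at
#' 4000 fps and 512x256 px (female F0 around 180-250 Hz with maximal areas of
#' roughly 1000-2000 px; male F0 around 110-150 Hz with maximal areas of
#' roughly 750-3200 px).
#'
#' @param sex `"female"` or `"male"`; selects defaults for `f0`,
#'   `max_area_px` and `glottis_length_px` when these are not given.
#' @param f0 Fundamental frequency in Hz.
#' @param fps Frame rate in frames per second.
#' @param n_frames Number of frames to generate.
#' @param frame_height,frame_width Frame dimensions in pixels.
#' @param period_jitter Relative standard deviation of per-cycle period
#'   (multiplicative Gaussian factors, truncated at 3 s.d.).
#' @param amp_jitter Relative standard deviation of per-cycle amplitude.
#' @param open_quotient Open fraction of each cycle, in (0, 1].
#' @param asym_amplitude Right/left amplitude ratio, in (0, 1]; 1 means
#'   symmetric folds.
#' @param asym_phase Lag of the right fold behind the left, as a fraction of
#'   the cycle; must satisfy `open_quotient + asym_phase < 1` so that the
#'   delayed right pulse still fits inside the cycle.
#' @param max_area_px Nominal maximal total glottal area in pixels.
#' @param glottis_length_px Anterior-posterior glottal length in pixels.
#' @param noise_sd Standard deviation of additive per-pixel Gaussian noise in
#'   intensity units.
#' @param background_level,glottis_level Tissue and glottis intensities in
#'   `[0, 255]`; the glottis must be darker than the tissue.
#' @param rng_seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return An object of class `subject_config`.
#' @export
subject_config <- function(sex = c("female", "male"),
                           f0 = NULL,
                           fps = 4000,
                           n_frames = 1000,
                           frame_height = 256,
                           frame_width = 512,
                           period_jitter = 0.01,
                           amp_jitter = 0.03,
                           open_quotient = 0.6,
                           asym_amplitude = 1,
                           asym_phase = 0,
                           max_area_px = NULL,
                           glottis_length_px = NULL,
                           noise_sd = 8,
                           background_level = 180,
                           glottis_level = 60,
                           rng_seed = 1L) {
  sex <- match.arg(sex)
  if (is.null(f0)) f0 <- if (sex == "female") 220 else 125
  if (is.null(max_area_px)) max_area_px <- if (sex == "female") 1400 else 1800
  if (is.null(glottis_length_px)) glottis_length_px <- if (sex == "female") 130 else 175
  cfg <- structure(list(
    sex = sex, f0 = f0, fps = fps, n_frames = n_frames,
    frame_height = frame_height, frame_width = frame_width,
    period_jitter = period_jitter, amp_jitter = amp_jitter,
    open_quotient = open_quotient,
    asym_amplitude = asym_amplitude, asym_phase = asym_phase,
    max_area_px = max_area_px, glottis_length_px = glottis_length_px,
    noise_sd = noise_sd,
    background_level = background_level, glottis_level = glottis_level,
    rng_seed = as.integer(rng_seed)
  ), class = "subject_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(constraint) {
    stop(sprintf("invalid subject_config: %s", constraint), call. = FALSE)
  }
  if (cfg$f0 <= 0) fail("f0 > 0")
  if (cfg$fps / cfg$f0 < 6) fail("fps/f0 >= 6 (at least 6 samples per cycle)")
  if (cfg$n_frames * cfg$f0 / cfg$fps < 25) {
    fail("n_frames*f0/fps >= 25 (enough cycles to select 20 starting at the third)")
  }
  if (cfg$glottis_level >= cfg$background_level) {
    fail("glottis_level < background_level (glottis darker than tissue)")
  }
  if (cfg$open_quotient <= 0 || cfg$open_quotient > 1) fail("open_quotient in (0, 1]")
  if (cfg$asym_amplitude <= 0 || cfg$asym_amplitude > 1) fail("asym_amplitude in (0, 1]")
  if (cfg$asym_phase < 0 || cfg$open_quotient + cfg$asym_phase >= 1) {
    fail("open_quotient + asym_phase < 1")
  }
  if (cfg$period_jitter < 0 || cfg$period_jitter > 0.3) fail("period_jitter in [0, 0.3]")
  if (cfg$amp_jitter < 0 || cfg$amp_jitter > 0.3) fail("amp_jitter in [0, 0.3]")
  if (cfg$max_area_px <= 0) fail("max_area_px > 0")
  if (cfg$glottis_length_px < 8) fail("glottis_length_px >= 8")
  if (cfg$noise_sd < 0) fail("noise_sd >= 0")
  invisible(cfg)
}

#' Generate a synthetic glottal area waveform with ground truth
#'
#' Builds the total, left and right glottal area waveforms of one simulated
#' subject. Each cycle is a raised sine-squared pulse over the open phase
#' followed by an exactly-zero closed phase; per-cycle periods and amplitudes
#' carry multiplicative Gaussian perturbation factors (truncated at 3 s.d.).
#' The total waveform equals left + right at every frame by construction.
#' When `asym_phase = 0` the closed phase of each cycle spans
#' `(1 - open_quotient)` of the period at exactly 0 px; a nonzero lag of the
#' right fold shortens the jointly-closed window by the lag.
#'
#' @param config A [subject_config()].
#' @return A list with `gaw` (a [gaw_triple()]) and `truth` (per-cycle ground
#'   truth: realized integer periods, realized total/left/right peak
#'   amplitudes, realized open fractions, and the cycle start frames).
#' @export
generate_gaw <- function(config) {
  validate_config(config)
  with_seed(config$rng_seed, generate_gaw_impl(config))
}

generate_gaw_impl <- function(cfg) {
  nominal <- cfg$fps / cfg$f0
  lo <- max(1 - 3 * cfg$period_jitter, 0.5)
  n_gen <- ceiling(cfg$n_frames / (nominal * lo)) + 3L

  pf <- rnorm_trunc(n_gen, 1, cfg$period_jitter)
  af <- rnorm_trunc(n_gen, 1, cfg$amp_jitter)

  bounds <- round(cumsum(c(0, nominal * pf)))   # integer cycle boundaries
  periods <- diff(bounds)
  stopifnot(all(periods >= 4))

  n <- cfg$n_frames
  left <- numeric(n)
  right <- numeric(n)
  r <- cfg$asym_amplitude
  lam_l <- 1 / (1 + r)
  lam_r <- r / (1 + r)

  for (i in seq_along(periods)) {
    s <- bounds[i]
    if (s >= n) break
    Ti <- periods[i]
    Oi <- max(1L, round(cfg$open_quotient * Ti))
    di <- round(cfg$asym_phase * Ti)
    env <- sin(pi * ((seq_len(Oi) - 0.5) / Oi))^2
    amp <- cfg$max_area_px * af[i]
    il <- s + seq_len(Oi)            # 1-based frame indices s+1 .. s+Oi
    ok <- il <= n
    left[il[ok]] <- lam_l * amp * env[ok]
    ir <- s + di + seq_len(Oi)
    ok <- ir >= 1 & ir <= n
    right[ir[ok]] <- lam_r * amp * env[ok]
  }

  complete <- which(bounds[-1] <= n)   # cycles fully inside the series
  total <- left + right
  truth <- list(
    start_frame = bounds[complete],    # 0-based cycle start frames
    periods = periods[complete],
    amplitudes = vapply(complete, function(i) {
      max(total[(bounds[i] + 1):bounds[i + 1]])
    }, numeric(1)),
    amp_left = vapply(complete, function(i) {
      max(left[(bounds[i] + 1):bounds[i + 1]])
    }, numeric(1)),
    amp_right = vapply(complete, function(i) {
      max(right[(bounds[i] + 1):bounds[i + 1]])
    }, numeric(1)),
    open_fraction = vapply(complete, function(i) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      mean(total[idx] > 0)
    }, numeric(1))
  )
  truth$n_cycles <- length(complete)
  class(truth) <- "gaw_ground_truth"

  list(gaw = gaw_triple(total, left, right, cfg$fps, cfg$glottis_length_px),
       truth = truth)
}

#' Total, left and right glottal area waveforms
#'
#' @param total,left,right Glottal areas in pixels per frame; `left + right`
#'   must match `total` within 2% of the per-frame total (midline
#'   discretization tolerance).
#' @param fps Frame rate in frames per second.
#' @param glottal_length Anterior-posterior glottal length in pixels at
#'   maximal opening (used by length-normalized measures).
#' @return An object of class `gaw_triple`.
#' @export
gaw_triple <- function(total, left, right, fps, glottal_length = NA_real_) {
  n <- length(total)
  if (length(left) != n || length(right) != n) {
    stop("total, left and right series must have equal length", call. = FALSE)
  }
  if (any(total < 0) || any(left < 0) || any(right < 0)) {
    stop("glottal areas must be non-negative", call. = FALSE)
  }
  mism <- abs(left + right - total) > pmax(0.02 * total, 1e-8)
  if (any(mism)) {
    stop(sprintf("left + right deviates from total by more than 2%% on %d frame(s)",
                 sum(mism)), call. = FALSE)
  }
  structure(list(total = total, left = left, right = right,
                 fps = fps, glottal_length = glottal_length),
            class = "gaw_triple")
}

#' @export
print.gaw_triple <- function(x, ...) {
  cat(sprintf("<gaw_triple> %d frames @ %g fps, max area %g px\n",
              length(x$total), x$fps, max(x$total)))
  invisible(x)
}

# Area of a circular segment with chord length L and sagitta s.
segment_area <- function(L, s) {
  R <- ((L / 2)^2 + s^2) / (2 * s)
  R^2 * acos(1 - s / R) - (L / 2) * (R - s)
}

# Sagittas achieving the requested segment areas for chord L, by inverse
# interpolation of the monotone area(s) relation.
sagitta_for_area <- function(L, areas) {
  smax <- L / 2
  sg <- seq(smax / 512, smax, length.out = 512)
  ag <- segment_area(L, sg)
  if (max(areas) > max(ag)) {
    stop("requested glottal area exceeds what a lens of this length can hold",
         call. = FALSE)
  }
  out <- approx(c(0, ag), c(0, sg), xout = areas, rule = 2)$y
  out
}

#' Render a synthetic glottis video stack
#'
#' Draws, for every frame, a dark lens-shaped glottis (two mirrored
#' circular-arc halves about a straight anterior-posterior axis) on a brighter
#' tissue background, with the left and right half-widths following the
#' left/right partial waveforms of [generate_gaw()]. Additive Gaussian pixel
#' noise is applied last and intensities are clipped to `[0, 255]`.
#'
#' The anterior-posterior axis runs horizontally through the centers of one
#' pixel row, so the rendered region splits cleanly into a left half (rows
#' above the axis), a right half (rows below) and the axis row itself, which
#' counts half to each side. The exact rendered pixel areas per frame are
#' returned as ground truth.
#'
#' @param config A [subject_config()].
#' @return A list with `video` (a [video_stack()]), `truth` (the
#'   [generate_gaw()] ground truth extended with per-frame rendered areas
#'   `area_total`, `area_left`, `area_right` and the axis row), and `gaw`
#'   (the underlying analytic [gaw_triple()]).
#' @export
render_video <- function(config) {
  validate_config(config)
  g <- generate_gaw(config)
  h <- config$frame_height
  w <- config$frame_width
  L <- config$glottis_length_px
  if (L > w - 4) stop("glottis longer than the frame width", call. = FALSE)

  # sagitta per frame for each side
  sL <- sagitta_for_area(L, g$gaw$left)
  sR <- sagitta_for_area(L, g$gaw$right)
  need <- max(sL, sR)
  r0 <- ceiling(h / 2)                       # axis row
  if (r0 - ceiling(need) < 1 || r0 + ceiling(need) > h) {
    stop("glottis larger than the frame height", call. = FALSE)
  }
  x0 <- floor((w - L) / 2)                   # 0-based column offset
  u <- (seq_len(L) - 0.5) - L / 2            # column centers about the middle

  arc_halfwidth <- function(s) {
    if (s <= 0) return(numeric(L))
    R <- ((L / 2)^2 + s^2) / (2 * s)
    y <- sqrt(pmax(R^2 - u^2, 0)) - (R - s)
    pmax(y, 0)
  }

  px <- array(as.integer(config$background_level), c(h, w, config$n_frames))
  area_left <- numeric(config$n_frames)
  area_right <- numeric(config$n_frames)
  cols <- x0 + seq_len(L)
  glev <- as.integer(config$glottis_level)

  for (f in seq_len(config$n_frames)) {
    if (g$gaw$total[f] <= 0) next
    yl <- arc_halfwidth(sL[f])
    yr <- arc_halfwidth(sR[f])
    span <- yl >= 0.5 | yr >= 0.5            # columns where the glottis is open
    if (!any(span)) next
    cl <- floor(yl)                          # rows above the axis per column
    cr <- floor(yr)
    px[r0, cols[span], f] <- glev            # axis row
    mcl <- max(cl)
    if (mcl > 0) {
      rows <- r0 - seq_len(mcl)
      m <- px[rows, cols, f, drop = FALSE]
      dim(m) <- c(mcl, L)
      m[outer(seq_len(mcl), cl, "<=")] <- glev
      px[rows, cols, f] <- m
    }
    mcr <- max(cr)
    if (mcr > 0) {
      rows <- r0 + seq_len(mcr)
      m <- px[rows, cols, f, drop = FALSE]
      dim(m) <- c(mcr, L)
      m[outer(seq_len(mcr), cr, "<=")] <- glev
      px[rows, cols, f] <- m
    }
    area_left[f] <- sum(cl[span]) + 0.5 * sum(span)
    area_right[f] <- sum(cr[span]) + 0.5 * sum(span)
  }

  if (config$noise_sd > 0) {
    px <- with_seed(config$rng_seed + 1L,
                    add_noise_clip_cpp(px, config$noise_sd))
  }

  truth <- g$truth
  truth$area_total <- area_left + area_right
  truth$area_left <- area_left
  truth$area_right <- area_right
  truth$axis_row <- r0

  list(video = video_stack(px, config$fps), truth = truth, gaw = g$gaw)
}

#' Generate a cohort of synthetic subjects
#'
#' Samples per-subject fundamental frequency, maximal glottal area and glottal
#' length from sex-specific ranges (female F0 180-250 Hz, maximal areas
#' 1150-1750 px; male F0 110-150 Hz, maximal areas 900-2700 px, so that
#' realized maxima stay inside the ranges observed clinically), derives one
#' RNG seed per subject deterministically from `rng_seed`, and optionally
#' renders the video stacks.
#'
#' @param n_per_sex Number of subjects per sex, at least 1.
#' @param rng_seed Integer master seed.
#' @param render If `TRUE` (default) each subject carries a rendered
#'   [video_stack()]; with `FALSE` only configurations and analytic ground
#'   truth are returned, which keeps large cohorts cheap (videos can then be
#'   rendered one at a time, e.g. by [run_triads()]).
#' @param ... Overrides passed to every [subject_config()] (e.g. `n_frames`,
#'   `frame_height`, `frame_width`, `noise_sd`, perturbation settings).
#' @return A list of subjects, each a list with `id`, `sex`, `config`, and,
#'   when rendered, `video` and `truth`.
#' @export
generate_cohort <- function(n_per_sex, rng_seed = 1L, render = TRUE, ...) {
  if (!is.numeric(n_per_sex) || n_per_sex < 1) {
    stop("`n_per_sex` must be at least 1", call. = FALSE)
  }
  n_per_sex <- as.integer(n_per_sex)
  draws <- with_seed(as.integer(rng_seed), {
    list(seeds = sample.int(2^30, 2L * n_per_sex),
         u = matrix(runif(6L * n_per_sex), ncol = 3L))
  })
  ranges <- list(
    female = list(f0 = c(180, 250), area = c(1150, 1750), len = c(110, 150)),
    male   = list(f0 = c(110, 150), area = c(900, 2700),  len = c(150, 200))
  )
  subjects <- vector("list", 2L * n_per_sex)
  k <- 0L
  for (sex in c("female", "male")) {
    rg <- ranges[[sex]]
    for (i in seq_len(n_per_sex)) {
      k <- k + 1L
      uu <- draws$u[k, ]
      cfg <- subject_config(
        sex = sex,
        f0 = rg$f0[1] + uu[1] * diff(rg$f0),
        max_area_px = rg$area[1] + uu[2] * diff(rg$area),
        glottis_length_px = round(rg$len[1] + uu[3] * diff(rg$len)),
        rng_seed = draws$seeds[k],
        ...
      )
      subj <- list(id = sprintf("%s_%02d", sex, i), sex = sex, config = cfg)
      if (render) {
        rv <- render_video(cfg)
        subj$video <- rv$video
        subj$truth <- rv$truth
      }
      subjects[[k]] <- subj
    }
  }
  subjects
}
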