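# Centered perturbation quotient with window k on a per-cycle quantity x:
# 100 * mean over fully contained windows of |x_i - window mean| / mean(x).
perturbation_quotient <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  idx <- (half + 1L):(n - half)
  devs <- vapply(idx, function(i) {
    abs(x[i] - mean(x[(i - half):(i + half)]))
  }, numeric(1))
  100 * mean(devs) / mean(x)
}

#' Fundamental period measures
#'
#' `F0 = fps / mean(T)` in Hz and the mean cycle duration
#' `MCD = 1000 * mean(T) / fps` in ms; the two are exact reciprocals
#' (`F0 * MCD = 1000`), which is why MCD carries an exclusion flag.
#'
#' @param cycles A [cycle_primitives()] result.
#' @return Named list with `F0` and `MCD`.
#' @export
compute_fpm <- function(cycles) {
  tbar <- mean(cycles$primitives$T)
  list(F0 = cycles$fps / tbar, MCD = 1000 * tbar / cycles$fps)
}

#' Period perturbation measures
#'
#' Cycle-to-cycle perturbation of the period sequence `t_i` (in ms). `TP`
#' (time periodicity, ratio of the smaller to the larger of consecutive
#' periods, averaged) reaches 1 for a perfectly periodic signal; all other
#' measures reach 0. `MJit` is the mean absolute consecutive difference,
#' `PPQ3/5/11` are centered perturbation quotients, and `PVI` is the scaled
#' relative period variance, which is invariant under reordering of the
#' cycles. The six excluded measures are direct rescalings of `MJit`
#' (`Jit(%)`, `JitFac`, `JitRat`, `PPF`) or of `PPQ3` (`RAPB`, `RAPK`).
#'
#' @param cycles A [cycle_primitives()] result with at least 12 cycles.
#' @return Named list of the 12 PPM values.
#' @export
compute_ppm <- function(cycles) {
  t <- 1000 * cycles$primitives$T / cycles$fps
  if (any(t <= 0)) stop("non-positive cycle period", call. = FALSE)
  n <- length(t)
  if (n < 12) stop("at least 12 cycles are needed for PPQ11", call. = FALSE)
  tbar <- mean(t)
  dt <- abs(diff(t))
  f <- 1000 / t
  ppq3 <- perturbation_quotient(t, 3L)
  list(
    TP = mean(pmin(t[-n], t[-1]) / pmax(t[-n], t[-1])),
    MJit = mean(dt),
    PPQ3 = ppq3,
    PPQ5 = perturbation_quotient(t, 5L),
    PPQ11 = perturbation_quotient(t, 11L),
    PVI = 1000 * (sum((t - tbar)^2) / n) / tbar^2,
    `Jit(%)` = 100 * mean(dt) / tbar,
    JitFac = 100 * mean(abs(diff(f))) / mean(f),
    JitRat = 1000 * mean(dt) / tbar,
    PPF = 100 * mean(dt / t[-n]),
    RAPB = ppq3,
    RAPK = ppq3 * (n - 1) / (n - 2)
  )
}

#' Amplitude perturbation measures
#'
#' Perturbation of the per-cycle dynamic range `D_i` (maximal minus minimal
#' area within one cycle). `AP` (amplitude periodicity) reaches 1 at zero
#' perturbation; the shimmer measures reach 0. `AVI` is the decibel-scaled
#' relative variance of `D`, invariant under reordering. `APF` is excluded:
#' for small perturbations it is almost exactly `100 * ln(10) / 20 = 11.51`
#' times `MShim`.
#'
#' @param cycles A [cycle_primitives()] result with all `D_i > 0`.
#' @return Named list of the 8 APM values.
#' @export
compute_apm <- function(cycles) {
  D <- cycles$primitives$D
  bad <- which(D == 0)
  if (length(bad)) {
    stop(sprintf("zero dynamic range in cycle %d", bad[1]), call. = FALSE)
  }
  n <- length(D)
  dbar <- mean(D)
  mshim <- mean(abs(20 * log10(D[-1] / D[-n])))
  list(
    AP = mean(pmin(D[-n], D[-1]) / pmax(D[-n], D[-1])),
    MShim = mshim,
    `Shim(%)` = 100 * mshim / (20 * log10(dbar)),
    APQ3 = perturbation_quotient(D, 3L),
    APQ5 = perturbation_quotient(D, 5L),
    APQ11 = perturbation_quotient(D, 11L),
    AVI = 10 * log10(1000 * (sum((D - dbar)^2) / n) / dbar^2),
    APF = 100 * mean(abs(diff(D))) / dbar
  )
}

#' Energy perturbation measures
#'
#' Perturbation of the per-cycle energy `E_i` (sum of squared area samples
#' within the cycle). Because every sample of a cycle contributes, these are
#' less noise-sensitive counterparts of the amplitude measures. All are
#' scale-invariant: multiplying the waveform by a constant leaves them
#' unchanged.
#'
#' @param cycles A [cycle_primitives()] result with all `E_i > 0`.
#' @return Named list with `EPQ3`, `EPQ5`, `EPQ11`, `EPF`.
#' @export
compute_epm <- function(cycles) {
  E <- cycles$primitives$E
  if (any(E <= 0)) stop("non-positive cycle energy", call. = FALSE)
  list(
    EPQ3 = perturbation_quotient(E, 3L),
    EPQ5 = perturbation_quotient(E, 5L),
    EPQ11 = perturbation_quotient(E, 11L),
    EPF = 100 * mean(abs(diff(E))) / mean(E)
  )
}

#' Left-right symmetry measures
#'
#' Quantify how similar the left vocal fold's vibration is to the right
#' one's, from the two partial waveforms evaluated over the selected cycles
#' (cycle windows taken from the total waveform's boundaries):
#'
#' * `AmSI`: mean per-cycle ratio of the smaller to the larger side maximum;
#'   `AmS`: the same ratio on the cycle-averaged maxima.
#' * `WaSI`: zero-lag normalized cross-correlation of the mean-removed
#'   partial waveforms (waveform shape symmetry).
#' * `PhAI`: mean signed left-minus-right peak position difference per cycle,
#'   as a fraction of the period; `PhA`: the signed global
#'   cross-correlation-peak lag divided by the mean period.
#' * `SpSI`: mean signed relative difference of the per-cycle maximal closing
#'   slopes; `SpS`: the same on the selection-global maximal slopes.
#' * `DyRSI`, `DyRS`: as `AmSI`/`AmS` on per-cycle dynamic ranges (excluded:
#'   near-duplicates of the amplitude versions).
#'
#' @param left,right Partial waveform series.
#' @param cycles A [cycle_primitives()] result carrying the shared cycle
#'   boundaries.
#' @return Named list of the 9 SM values.
#' @export
compute_sym <- function(left, right, cycles) {
  b <- cycles$selected
  n <- length(b) - 1L
  fps <- cycles$fps
  ml <- mr <- dl <- dr <- tl <- tr <- slp_l <- slp_r <- numeric(n)
  for (i in seq_len(n)) {
    idx <- b[i]:(b[i + 1] - 1L)
    al <- left[idx]
    ar <- right[idx]
    ml[i] <- max(al); mr[i] <- max(ar)
    dl[i] <- ml[i] - min(al); dr[i] <- mr[i] - min(ar)
    tl[i] <- which.max(al); tr[i] <- which.max(ar)
    slp_l[i] <- max(-diff(al)) * fps
    slp_r[i] <- max(-diff(ar)) * fps
  }
  if (any(pmax(ml, mr) == 0) || any(pmax(dl, dr) == 0)) {
    stop("a partial waveform is flat within a cycle", call. = FALSE)
  }
  if (any(slp_l + slp_r == 0)) {
    stop("zero closing slope on both sides within a cycle", call. = FALSE)
  }
  sel <- b[1]:(b[n + 1] - 1L)
  lw <- left[sel]
  rw <- right[sel]
  tbar <- mean(cycles$primitives$T)

  # global cross-correlation peak lag: shift applied to the right waveform
  K <- floor(tbar / 2)
  lags <- -K:K
  cors <- vapply(lags, function(k) {
    i1 <- sel
    i2 <- sel - k
    ok <- i2 >= 1 & i2 <= length(right)
    if (sum(ok) < 3) return(-Inf)
    suppressWarnings(cor(left[i1[ok]], right[i2[ok]]))
  }, numeric(1))
  cors[is.na(cors)] <- -Inf
  best <- lags[cors == max(cors)]
  k_best <- best[order(abs(best), best)][1]

  gsl <- max(-diff(lw)) * fps
  gsr <- max(-diff(rw)) * fps
  if (gsl + gsr == 0) stop("zero global closing slope", call. = FALSE)

  list(
    AmSI = mean(pmin(ml, mr) / pmax(ml, mr)),
    AmS = min(mean(ml), mean(mr)) / max(mean(ml), mean(mr)),
    WaSI = suppressWarnings(cor(lw, rw)),
    PhAI = mean((tl - tr) / cycles$primitives$T),
    PhA = k_best / tbar,
    SpSI = mean((slp_l - slp_r) / (slp_l + slp_r)),
    SpS = (gsl - gsr) / (gsl + gsr),
    DyRSI = mean(pmin(dl, dr) / pmax(dl, dr)),
    DyRS = min(mean(dl), mean(dr)) / max(mean(dl), mean(dr))
  )
}

#' Glottal dynamic characteristics
#'
#' Phase-structure quotients of the glottal cycle: open quotient
#' `OQ = mean(O/T)`, closing quotient `CQ = mean(c/T)`, plateau quotient
#' `PQ = mean(p/T)`, glottal area index `GAI = mean(D/A_max)` and the glottal
#' gap index `GGI`, the ratio of the selection-global minimal to maximal
#' area (0 whenever full closure occurs anywhere in the selection). The
#' excluded `SQ`, `SI`, `RQ`, `AQ` are recombinations of the same per-cycle
#' phase durations; cycles with zero closing time are skipped in `SQ` (their
#' count is attached as attribute `"sq_skipped"`).
#'
#' @param cycles A [cycle_primitives()] result.
#' @param gaw The series the cycles refer to (for the global extrema of
#'   `GGI`); a [gaw_triple()] is accepted.
#' @return Named list of the 9 GDC values.
#' @export
compute_gdc <- function(cycles, gaw) {
  if (inherits(gaw, "gaw_triple")) gaw <- gaw$total
  pr <- cycles$primitives
  if (any(pr$O == 0)) stop("cycle without open phase", call. = FALSE)
  b <- cycles$selected
  sel <- gaw[b[1]:(b[length(b)] - 1L)]
  nonzero_c <- pr$c > 0
  sq <- mean(pr$o[nonzero_c] / pr$c[nonzero_c])
  out <- list(
    OQ = mean(pr$O / pr$T),
    CQ = mean(pr$c / pr$T),
    PQ = mean(pr$p / pr$T),
    GAI = mean(pr$D / pr$A_max),
    GGI = min(sel) / max(sel),
    SQ = sq,
    SI = mean((pr$o - pr$c) / (pr$o + pr$c)),
    RQ = mean((pr$T - pr$O) / pr$O),
    AQ = mean(pr$o / pr$T)
  )
  attr(out, "sq_skipped") <- sum(!nonzero_c)
  out
}

#' Mechanical measures
#'
#' Slope-based measures on the per-frame area derivative
#' `v(t) = (a(t+1) - a(t)) * fps` (px/s) over the selected cycles:
#'
#' * `MADR`: maximum area declination rate, the per-cycle maximal decrease,
#'   averaged over cycles, reported in Mpx/s.
#' * `PCV`: the selection-global maximal decrease, in Mpx/s.
#' * `AmQ = mean(D) / MADR` (seconds; MADR in px/s): amplitude-normalized
#'   declination.
#' * `Stiff`: mean per-cycle maximal absolute slope divided by the mean
#'   dynamic range (1/s).
#' * `ALR = mean(D) / glottal length`: dynamic range per unit glottal length.
#' * `PA` (excluded, near-linear in PCV): maximal absolute second derivative
#'   `|v(t+1) - v(t)| * fps` (px/s^2).
#'
#' @param gaw Series or [gaw_triple()].
#' @param cycles A [cycle_primitives()] result.
#' @param glottal_length Glottal length in px; taken from the triple if
#'   omitted.
#' @return Named list of the 6 MM values.
#' @export
compute_mm <- function(gaw, cycles, glottal_length = NULL) {
  if (inherits(gaw, "gaw_triple")) {
    if (is.null(glottal_length)) glottal_length <- gaw$glottal_length
    gaw <- gaw$total
  }
  if (is.null(glottal_length) || !is.finite(glottal_length) || glottal_length <= 0) {
    stop("`glottal_length` must be a positive number", call. = FALSE)
  }
  pr <- cycles$primitives
  b <- cycles$selected
  n <- length(b) - 1L
  madr_i <- stiff_i <- numeric(n)
  for (i in seq_len(n)) {
    idx <- b[i]:(b[i + 1] - 1L)
    v <- diff(gaw[b[i]:b[i + 1]]) * cycles$fps  # slopes within cycle i
    madr_i[i] <- max(-v)
    stiff_i[i] <- max(abs(v))
  }
  sel <- gaw[b[1]:b[n + 1]]
  v_all <- diff(sel) * cycles$fps
  madr <- mean(madr_i)
  if (madr <= 0) stop("zero maximum area declination rate; AmQ undefined", call. = FALSE)
  dbar <- mean(pr$D)
  list(
    MADR = madr / 1e6,
    AmQ = dbar / madr,
    Stiff = mean(stiff_i) / dbar,
    PCV = max(-v_all) / 1e6,
    ALR = dbar / glottal_length,
    PA = max(abs(diff(v_all))) * cycles$fps
  )
}

#' Compute the full 50-measure parameter set
#'
#' Runs maximum-based cycle detection and selection on the total waveform,
#' reuses the boundaries for the partial waveforms, computes all seven
#' measure families and assembles them against the catalogue.
#'
#' @param triple A [gaw_triple()].
#' @param prominence_frac,plateau_frac Tuning constants passed to
#'   [detect_cycles()] and [cycle_primitives()].
#' @param n_select,skip Cycle selection, see [select_cycles()].
#' @return An object of class `parameter_set`: a data frame with columns
#'   `name`, `group`, `value`, `units`, `excluded` (one row per catalogue
#'   entry, 50 in total). The underlying `cycle_set` is attached as
#'   attribute `"cycles"`.
#' @export
compute_all <- function(triple, prominence_frac = 0.25, plateau_frac = 0.95,
                        n_select = 20L, skip = 2L) {
  stopifnot(inherits(triple, "gaw_triple"))
  cyc <- detect_cycles(triple$total, triple$fps,
                       prominence_frac = prominence_frac,
                       min_boundaries = skip + n_select + 1L)
  cyc <- select_cycles(cyc, n_select = n_select, skip = skip)
  cyc <- cycle_primitives(triple$total, cyc, plateau_frac = plateau_frac)

  vals <- c(
    compute_fpm(cyc),
    compute_ppm(cyc),
    compute_apm(cyc),
    compute_epm(cyc),
    compute_sym(triple$left, triple$right, cyc),
    compute_gdc(cyc, triple$total),
    compute_mm(triple$total, cyc, triple$glottal_length)
  )
  cat <- parameter_catalogue()
  stopifnot(setequal(names(vals), cat$name))
  cat$value <- unlist(vals[cat$name], use.names = FALSE)
  out <- cat[, c("name", "group", "value", "units", "excluded")]
  class(out) <- c("parameter_set", "data.frame")
  attr(out, "cycles") <- cyc
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d measures (%d relevant, %d excluded)\n",
              nrow(x), sum(!x$excluded), sum(x$excluded)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
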