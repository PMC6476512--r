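# Brute-force flood fill from seeds over pixels strictly below a threshold:
# the independent oracle for the region-growing implementation.
flood_fill_oracle <- function(img, seeds, threshold, conn8 = FALSE) {
  nr <- nrow(img)
  nc <- ncol(img)
  mask <- matrix(FALSE, nr, nc)
  nb <- if (conn8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (s in seq_len(nrow(seeds))) {
    r <- seeds[s, 1]
    c <- seeds[s, 2]
    if (mask[r, c] || img[r, c] >= threshold) next
    queue <- list(c(r, c))
    mask[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]
        c2 <- p[2] + nb[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!mask[r2, c2] && img[r2, c2] < threshold) {
          mask[r2, c2] <- TRUE
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  mask
}

# Cycle set built directly from per-cycle quantities, for testing the
# parameter formulas in isolation.
fake_cycle_set <- function(T = NULL, D = NULL, E = NULL, fps = 4000) {
  n <- max(length(T), length(D), length(E))
  if (is.null(T)) T <- rep(20L, n)
  if (is.null(D)) D <- rep(1, n)
  if (is.null(E)) E <- rep(1, n)
  prim <- data.frame(T = T, A_max = D, A_min = 0, D = D, E = E,
                     O = T, c = 0L, o = 0L, p = 1L,
                     start = cumsum(c(1L, T[-length(T)])))
  structure(list(boundaries = cumsum(c(1L, T)), fps = fps,
                 selected = cumsum(c(1L, T)), primitives = prim),
            class = "cycle_set")
}

# Cycle set plus series built from explicit per-cycle sample vectors.
cycles_from_samples <- function(samples_list, fps = 4000) {
  series <- unlist(samples_list)
  lens <- vapply(samples_list, length, integer(1))
  b <- cumsum(c(1L, lens))
  cs <- structure(list(boundaries = b, fps = fps, selected = b,
                       primitives = NULL),
                  class = "cycle_set")
  list(cycles = cycle_primitives(series, cs), series = series)
}

# A filled lens-shaped mask (two mirrored circular arcs about an axis through
# the origin at angle `theta`), drawn directly on a pixel grid.
lens_mask <- function(nr, nc, center, half_length, sagitta, theta = 0) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  xr <- (cols - center[2]) * cos(theta) + (rows - center[1]) * sin(theta)
  yr <- -(cols - center[2]) * sin(theta) + (rows - center[1]) * cos(theta)
  R <- (half_length^2 + sagitta^2) / (2 * sagitta)
  halfwidth <- sqrt(pmax(R^2 - xr^2, 0)) - (R - sagitta)
  abs(xr) <= half_length & abs(yr) <= pmax(halfwidth, 0)
}

# Sine-squared pulse train mimicking a noise-free glottal area waveform.
pulse_train <- function(n_cycles, period, open_frames, amp = 100,
                        delay = 0, n_frames = n_cycles * period) {
  x <- numeric(n_frames)
  for (i in seq_len(n_cycles)) {
    s <- (i - 1L) * period + delay
    idx <- s + seq_len(open_frames)
    ok <- idx >= 1 & idx <= n_frames
    env <- sin(pi * ((seq_len(open_frames) - 0.5) / open_frames))^2
    x[idx[ok]] <- amp * env[ok]
  }
  x
}
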