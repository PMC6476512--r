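test_that("the catalogue has the fixed group structure", {
  cat <- parameter_catalogue()
  expect_equal(nrow(cat), 50)
  expect_equal(sum(cat$group != "SM"), 41)
  expect_equal(sum(cat$excluded), 15)
  rel <- table(cat$group[!cat$excluded])
  expect_equal(as.integer(rel[c("FPM", "PPM", "APM", "EPM", "SM", "GDC", "MM")]),
               c(1, 6, 7, 4, 7, 5, 5))
  expect_false(any(duplicated(cat$name)))
})

test_that("fundamental period measures are exact reciprocals", {
  cyc <- fake_cycle_set(T = rep(20L, 20))
  f <- compute_fpm(cyc)
  expect_equal(f$F0, 200)
  expect_equal(f$MCD, 5)

  cyc2 <- fake_cycle_set(T = rep(c(19L, 21L), 10))
  f2 <- compute_fpm(cyc2)
  expect_equal(f2$F0, 200)             # mean period 20 frames
  expect_equal(f2$F0 * f2$MCD, 1000)   # dependency relation
})

test_that("constant periods give the optimum of every period measure", {
  p <- compute_ppm(fake_cycle_set(T = rep(20L, 20)))
  expect_equal(p$TP, 1)
  for (nm in c("MJit", "PPQ3", "PPQ5", "PPQ11", "PVI", "Jit(%)", "JitFac",
               "JitRat", "PPF", "RAPB", "RAPK")) {
    expect_equal(p[[nm]], 0, info = nm)
  }
})

test_that("alternating periods order the PPQ family as proved", {
  p <- compute_ppm(fake_cycle_set(T = rep(c(19L, 21L), 10)))
  expect_gt(p$PPQ3, p$PPQ5)
  expect_gt(p$PPQ11, p$PPQ5)
  # MJit: every consecutive difference is 2 frames = 0.5 ms at 4000 fps
  expect_equal(p$MJit, 0.5)
  expect_equal(p$`Jit(%)`, 100 * 0.5 / 5)
  expect_equal(p$RAPK / p$RAPB, 19 / 18)   # (N-1)/(N-2) with N = 20
})

test_that("PVI is order-invariant but MJit and TP are not", {
  set.seed(123)
  T <- 18 + sample(0:4, 20, replace = TRUE)
  base <- compute_ppm(fake_cycle_set(T = T))
  srt <- compute_ppm(fake_cycle_set(T = sort(T)))
  expect_equal(base$PVI, srt$PVI, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(base$MJit, srt$MJit)))
  expect_false(isTRUE(all.equal(base$TP, srt$TP)))
})

test_that("constant amplitudes give the optimum of every amplitude measure", {
  a <- compute_apm(fake_cycle_set(D = rep(50, 20)))
  expect_equal(a$AP, 1)
  for (nm in c("MShim", "APQ3", "APQ5", "APQ11", "APF")) {
    expect_equal(a[[nm]], 0, info = nm)
  }
})

test_that("APF approaches 11.51 times MShim for small perturbations", {
  a <- compute_apm(fake_cycle_set(D = rep(c(0.99, 1.01), 10)))
  expect_equal(a$APF / a$MShim, 100 * log(10) / 20, tolerance = 1e-3)
})

test_that("AVI is order-invariant and a zero dynamic range is named", {
  set.seed(77)
  D <- runif(20, 40, 60)
  base <- compute_apm(fake_cycle_set(D = D))
  perm <- compute_apm(fake_cycle_set(D = sample(D)))
  expect_equal(base$AVI, perm$AVI, tolerance = 1e-12)

  Dz <- D
  Dz[7] <- 0
  expect_error(compute_apm(fake_cycle_set(D = Dz)), "cycle 7")
})

test_that("energy measures vanish for identical cycles and ignore scale", {
  e <- compute_epm(fake_cycle_set(E = rep(1000, 20)))
  expect_equal(unlist(e), c(EPQ3 = 0, EPQ5 = 0, EPQ11 = 0, EPF = 0))

  set.seed(31)
  E <- runif(20, 500, 1500)
  e1 <- compute_epm(fake_cycle_set(E = E))
  e2 <- compute_epm(fake_cycle_set(E = 16 * E))  # waveform scaled by 4
  expect_equal(e1, e2)

  # brute-force window recomputation oracle for the quotient family
  for (k in c(3, 5, 11)) {
    half <- (k - 1) / 2
    devs <- vapply((half + 1):(20 - half), function(i) {
      abs(E[i] - mean(E[(i - half):(i + half)]))
    }, numeric(1))
    expect_equal(e1[[paste0("EPQ", k)]], 100 * mean(devs) / mean(E))
  }
})

test_that("identical partial waveforms are perfectly symmetric", {
  x <- pulse_train(25, period = 20, open_frames = 12)
  cs <- detect_cycles(2 * x, fps = 4000)
  cs <- select_cycles(cs)
  cs <- cycle_primitives(2 * x, cs)
  s <- compute_sym(x, x, cs)
  expect_equal(s$AmSI, 1)
  expect_equal(s$AmS, 1)
  expect_equal(s$WaSI, 1)
  expect_equal(s$PhAI, 0)
  expect_equal(s$PhA, 0)
  expect_equal(s$SpSI, 0)
  expect_equal(s$SpS, 0)
  expect_equal(s$DyRSI, 1)
})

test_that("pure amplitude asymmetry only rescales the symmetry indices", {
  x <- pulse_train(25, period = 20, open_frames = 12)
  total <- x + 0.5 * x
  cs <- cycle_primitives(total, select_cycles(detect_cycles(total, 4000)))
  s <- compute_sym(x, 0.5 * x, cs)
  expect_equal(s$AmSI, 0.5)
  expect_equal(s$WaSI, 1)
  expect_equal(s$PhAI, 0)
})

test_that("a delayed right fold gives the signed phase asymmetry", {
  left <- pulse_train(30, period = 20, open_frames = 12)
  right <- pulse_train(30, period = 20, open_frames = 12, delay = 2)
  total <- left + right
  cs <- cycle_primitives(total, select_cycles(detect_cycles(total, 4000)))
  s <- compute_sym(left, right, cs)
  expect_equal(s$PhA, -2 / 20)   # right lags left by 2 of 20 frames
  expect_lt(s$PhAI, 0)
})

test_that("glottal dynamic characteristics follow the phase structure", {
  # 15 open frames out of 20
  cyc <- c(9, 7, 5, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1, 0.2, 0.5, 1, 4,
           0, 0, 0, 0, 0)
  res <- cycles_from_samples(rep(list(cyc), 3))
  g <- compute_gdc(res$cycles, res$series)
  expect_equal(g$OQ, 15 / 20)
  expect_equal(g$GGI, 0)       # full closure in the selection

  # symmetric triangle: equal closing and opening branches, no zeros
  tri <- c(9, 7, 5, 3, 1, 3, 5, 7, 9)
  rt <- cycles_from_samples(rep(list(tri), 3))
  gt <- compute_gdc(rt$cycles, rt$series)
  expect_equal(gt$SI, 0)
  expect_equal(gt$SQ, 1)
  expect_gt(gt$GGI, 0)
})

test_that("mechanical measures match direct arithmetic and scaling laws", {
  # sawtooth: rises 25/frame for 4 frames, drops 100 px in one frame
  saw <- rep(c(0, 25, 50, 75, 100), 25)[1:120]
  cs <- structure(list(boundaries = seq(1, 116, by = 5), fps = 4000,
                       selected = seq(1, 116, by = 5), primitives = NULL),
                  class = "cycle_set")
  cs <- cycle_primitives(saw, cs)
  m <- compute_mm(saw, cs, glottal_length = 50)
  expect_equal(m$MADR, 100 * 4000 / 1e6)   # 0.4 Mpx/s
  expect_equal(m$PCV, 100 * 4000 / 1e6)
  expect_equal(m$ALR, 100 / 50)

  # area scaled by 4, length by 2
  cs4 <- cycle_primitives(4 * saw, cs)
  m4 <- compute_mm(4 * saw, cs4, glottal_length = 100)
  expect_equal(m4$MADR, 4 * m$MADR)
  expect_equal(m4$PCV, 4 * m$PCV)
  expect_equal(m4$ALR, 2 * m$ALR)
  expect_equal(m4$AmQ, m$AmQ)
  expect_equal(m4$Stiff, m$Stiff)
})

test_that("MADR and PCV equal brute-force derivative scans on random series", {
  set.seed(17)
  x <- abs(rnorm(120, 50, 20))
  b <- seq(1, 111, by = 10)
  cs <- structure(list(boundaries = b, fps = 4000, selected = b,
                       primitives = NULL), class = "cycle_set")
  cs <- cycle_primitives(x, cs)
  m <- compute_mm(x, cs, glottal_length = 40)

  drops <- vapply(seq_len(length(b) - 1), function(i) {
    seg <- x[b[i]:b[i + 1]]
    max(-(diff(seg))) * 4000
  }, numeric(1))
  expect_equal(m$MADR, mean(drops) / 1e6)
  expect_equal(m$PCV, max(-(diff(x[b[1]:b[11]]))) * 4000 / 1e6)
})

test_that("compute_all fills the whole catalogue and hits every optimum at zero perturbation", {
  cfg <- subject_config("female", f0 = 200, period_jitter = 0, amp_jitter = 0,
                        open_quotient = 0.7, rng_seed = 23)
  g <- generate_gaw(cfg)
  ps <- compute_all(g$gaw)
  expect_s3_class(ps, "parameter_set")
  expect_equal(nrow(ps), 50)
  expect_equal(sum(ps$group != "SM"), 41)
  expect_equal(sum(ps$excluded), 15)

  val <- function(nm) ps$value[ps$name == nm]
  expect_equal(val("TP"), 1)
  expect_equal(val("AP"), 1)
  expect_equal(val("AmSI"), 1)
  expect_equal(val("AmS"), 1)
  expect_equal(val("WaSI"), 1)
  for (nm in c("MJit", "MShim", "PVI", "APF", "PPQ3", "PPQ5", "PPQ11",
               "APQ3", "APQ5", "APQ11", "EPQ3", "EPQ5", "EPQ11", "EPF",
               "PhAI", "PhA", "SpSI", "SpS")) {
    expect_equal(val(nm), 0, info = nm)
  }
  # open quotient recovered exactly: 0.7 * 20 frames is integral
  expect_equal(val("OQ"), 0.7)
  expect_equal(val("GGI"), 0)
  expect_equal(val("F0"), 200)
})
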