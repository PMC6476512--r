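# One-way repeated-measures ANOVA (k conditions, n subjects) with
# Greenhouse-Geisser correction. Textbook decomposition; the GG epsilon is
# computed from the double-centered condition covariance matrix. Sphericity
# is assessed with Mauchly's test on the multivariate fit; the correction is
# applied when the test rejects at `alpha`.
rm_anova <- function(Y, alpha = 0.05) {
  n <- nrow(Y)
  k <- ncol(Y)
  grand <- mean(Y)
  col_m <- colMeans(Y)
  row_m <- rowMeans(Y)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fstat <- (ss_cond / df1) / (ss_err / df2)

  S <- stats::cov(Y)
  Sc <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k, byrow = TRUE) +
    mean(S)
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))

  mauchly_p <- tryCatch(suppressWarnings({
    fit <- stats::lm(Y ~ 1)
    id <- data.frame(cond = factor(seq_len(k)))
    stats::mauchly.test(fit, M = ~cond, X = ~1, idata = id)$p.value
  }), error = function(e) 0)
  # degenerate/singular covariance: maximally non-spherical, correct
  if (!is.finite(mauchly_p)) mauchly_p <- 0

  corrected <- mauchly_p <= alpha
  e <- if (corrected) eps else 1
  p <- stats::pf(Fstat, e * df1, e * df2, lower.tail = FALSE)
  list(statistic = Fstat, p.value = p, gg_epsilon = eps,
       gg_applied = corrected, mauchly_p = mauchly_p)
}

#' Omnibus test across the three resolutions
#'
#' Compares one parameter's values across the SR1/SR2/SR3 conditions with a
#' paired design: a one-way repeated-measures analysis of variance
#' (Greenhouse-Geisser-corrected when Mauchly's test rejects sphericity at
#' 0.05) when every condition passes a Shapiro-Wilk normality check at 0.05,
#' and the Friedman rank test otherwise. `mode` can force either branch.
#' Data that are constant within every subject across conditions yield
#' `p = 1` by convention.
#'
#' @param values Numeric `n x 3` matrix, one row per subject, columns SR1,
#'   SR2, SR3; `n >= 5`, no missing cells.
#' @param mode `"auto"`, `"parametric"` or `"nonparametric"`.
#' @return A list with `test` (name), `statistic`, `p.value` and `branch`.
#' @export
omnibus_test <- function(values, mode = c("auto", "parametric", "nonparametric")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (ncol(values) != 3L) stop("`values` must have three columns", call. = FALSE)
  if (nrow(values) < 5L) stop("at least 5 subjects are required", call. = FALSE)
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)

  if (all(values[, 1] == values[, 2] & values[, 2] == values[, 3])) {
    return(list(test = "constant", statistic = NA_real_, p.value = 1,
                branch = "none"))
  }
  branch <- switch(mode,
    parametric = "parametric",
    nonparametric = "nonparametric",
    auto = {
      normal <- vapply(seq_len(3), function(j) {
        tryCatch(stats::shapiro.test(values[, j])$p.value > 0.05,
                 error = function(e) FALSE)
      }, logical(1))
      if (all(normal)) "parametric" else "nonparametric"
    })
  if (branch == "parametric") {
    r <- rm_anova(values)
    list(test = if (r$gg_applied) "rm-anova (GG)" else "rm-anova",
         statistic = r$statistic, p.value = r$p.value, branch = branch)
  } else {
    ft <- stats::friedman.test(values)
    list(test = "friedman", statistic = unname(ft$statistic),
         p.value = ft$p.value, branch = branch)
  }
}

#' Bonferroni-corrected post-hoc pairwise comparisons
#'
#' Paired t-tests (parametric branch) or Wilcoxon signed-rank tests
#' (nonparametric branch) for the three resolution pairs SR1-SR2, SR1-SR3,
#' SR2-SR3; raw p-values are multiplied by 3 and capped at 1. Pairs with all
#' differences zero yield `p = 1`.
#'
#' @param values Numeric `n x 3` matrix as in [omnibus_test()].
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param bonferroni Correction factor (number of pairwise comparisons).
#' @return Named numeric vector `sr1_sr2`, `sr1_sr3`, `sr2_sr3` of corrected
#'   p-values.
#' @export
posthoc_tests <- function(values, branch = c("parametric", "nonparametric"),
                          bonferroni = 3) {
  branch <- match.arg(branch)
  values <- as.matrix(values)
  pairs <- list(sr1_sr2 = c(1, 2), sr1_sr3 = c(1, 3), sr2_sr3 = c(2, 3))
  raw <- vapply(pairs, function(pr) {
    x <- values[, pr[1]]
    y <- values[, pr[2]]
    if (all(x == y)) return(1)
    if (branch == "parametric") {
      stats::t.test(x, y, paired = TRUE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    }
  }, numeric(1))
  pmin(raw * bonferroni, 1)
}

#' Run the triad experiment on a cohort
#'
#' For every subject: build the SR1/SR2/SR3 triad by block averaging, select
#' a rectangular ROI containing the whole glottal area (from the temporal
#' minimum-intensity projection, padded and snapped so the ROI maps exactly
#' onto the reduced resolutions), segment all three members with a seed grid
#' drawn on the lowest resolution and condensed for the higher ones, and
#' compute the full parameter set on each extracted waveform triple.
#' Subjects whose segmentation or cycle analysis fails are dropped with a
#' message.
#'
#' @param cohort List of subjects as produced by [generate_cohort()] (each
#'   needs `$config`; `$video` is rendered on the fly when absent, which
#'   keeps memory flat for large cohorts).
#' @param settings A [segmentation_settings()]; when `NULL`, the threshold is
#'   placed midway between each subject's glottis and background levels.
#' @param margin ROI padding in SR1 pixels.
#' @param ... Passed to [compute_all()].
#' @return A list of triad results, each with `id`, `sex`, `params` (a list
#'   of three `parameter_set`s named sr1, sr2, sr3) and `gaws`.
#' @export
run_triads <- function(cohort, settings = NULL, margin = 8L, ...) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    res <- tryCatch(
      run_one_triad(subj, settings, margin, ...),
      error = function(e) {
        message(sprintf("subject %s dropped: %s",
                        if (!is.null(subj$id)) subj$id else i,
                        conditionMessage(e)))
        NULL
      })
    out[[i]] <- res
  }
  out[!vapply(out, is.null, logical(1))]
}

run_one_triad <- function(subj, settings, margin, ...) {
  video <- subj$video
  if (is.null(video)) video <- render_video(subj$config)$video
  if (is.null(settings)) {
    # half an intensity step above the midpoint: with the strict darker-than
    # rule this segments blocks that average to exactly the midpoint, i.e.
    # half-covered pixels of a reduced resolution, keeping block-averaged
    # areas unbiased
    cfg <- subj$config
    thr <- (cfg$glottis_level + cfg$background_level) / 2 + 0.5
    settings <- segmentation_settings(threshold = thr)
  }
  triad <- make_triad(video)

  # ROI from the temporal minimum projection of the original resolution
  d <- dim(video$px)
  proj <- video$px[, , 1]
  for (f in 2:d[3]) proj <- pmin(proj, video$px[, , f])
  dark <- which(proj < settings$threshold, arr.ind = TRUE)
  if (!nrow(dark)) stop("no glottis darker than the threshold found")
  top <- max(0L, 4L * ((min(dark[, 1]) - 1L - margin) %/% 4L))
  left <- max(0L, 4L * ((min(dark[, 2]) - 1L - margin) %/% 4L))
  bot <- min(d[1], 4L * as.integer(ceiling((max(dark[, 1]) + margin) / 4)))
  right <- min(d[2], 4L * as.integer(ceiling((max(dark[, 2]) + margin) / 4)))
  r1 <- roi(top, left, bot - top, right - left)

  crops <- list(sr1 = crop_video(triad$sr1, r1),
                sr2 = crop_video(triad$sr2, scale_roi(r1, 2)),
                sr3 = crop_video(triad$sr3, scale_roi(r1, 4)))
  d3 <- dim(crops$sr3$px)
  grid3 <- make_seed_grid(roi(0, 0, d3[1], d3[2]), settings$spacing)
  grids <- list(sr1 = condense_grid(grid3, 4L),
                sr2 = condense_grid(grid3, 2L),
                sr3 = grid3)

  gaws <- lapply(c(sr1 = "sr1", sr2 = "sr2", sr3 = "sr3"), function(sr) {
    segment_sequence(crops[[sr]], settings, grids[[sr]])
  })
  params <- lapply(gaws, compute_all, ...)
  list(id = subj$id, sex = subj$sex, params = params, gaws = gaws, roi = r1)
}

#' Per-subject relative deviations of one parameter
#'
#' Divides a parameter's value at the reduced resolutions by its value at
#' the original resolution, per subject. Subjects whose SR1 value is zero or
#' negative are flagged instead of divided (a zero crossing would produce an
#' infinite or sign-flipping relative change; this affects the measures that
#' can reach zero or negative values, such as AVI, PhAI, PhA, SpSI, SpS and
#' GGI).
#'
#' @param triads A [run_triads()] result.
#' @param parameter Catalogue name of the measure.
#' @return Data frame with `id`, `sex`, `sr1`, `ratio_sr2`, `ratio_sr3`,
#'   `computed`.
#' @export
relative_deviation <- function(triads, parameter) {
  rows <- lapply(triads, function(tr) {
    v <- vapply(tr$params, function(p) p$value[p$name == parameter], numeric(1))
    ok <- is.finite(v[1]) && v[1] > 0
    data.frame(id = tr$id, sex = tr$sex, sr1 = v[1],
               ratio_sr2 = if (ok) v[2] / v[1] else NA_real_,
               ratio_sr3 = if (ok) v[3] / v[1] else NA_real_,
               computed = ok)
  })
  do.call(rbind, rows)
}

#' Statistical comparison of all parameters across resolutions
#'
#' Runs the omnibus test (and, where it rejects, the Bonferroni-corrected
#' post-hoc pairs) for every catalogue parameter, separately per sex.
#'
#' @param triads A [run_triads()] result.
#' @param mode Branch selection passed to [omnibus_test()].
#' @param alpha Significance level.
#' @param bonferroni Post-hoc correction factor.
#' @return An object of class `study_report`: a data frame with one row per
#'   parameter and sex (test name, p-value, corrected pairwise p-values,
#'   significance flag, exclusion flag).
#' @export
study_statistics <- function(triads, mode = "auto", alpha = 0.05,
                             bonferroni = 3) {
  cat <- parameter_catalogue()
  sexes <- unique(vapply(triads, function(tr) tr$sex, character(1)))
  rows <- list()
  for (sex in sexes) {
    sub <- triads[vapply(triads, function(tr) tr$sex == sex, logical(1))]
    for (j in seq_len(nrow(cat))) {
      pname <- cat$name[j]
      vals <- t(vapply(sub, function(tr) {
        vapply(tr$params, function(p) p$value[p$name == pname], numeric(1))
      }, numeric(3)))
      res <- omnibus_test(vals, mode = mode)
      sig <- res$p.value <= alpha
      ph <- c(sr1_sr2 = NA_real_, sr1_sr3 = NA_real_, sr2_sr3 = NA_real_)
      if (sig && res$branch != "none") {
        ph <- posthoc_tests(vals, branch = res$branch, bonferroni = bonferroni)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pname, group = cat$group[j], excluded = cat$excluded[j],
        sex = sex, n = nrow(vals), test = res$test, p = res$p.value,
        p_sr1_sr2 = ph[["sr1_sr2"]], p_sr1_sr3 = ph[["sr1_sr3"]],
        p_sr2_sr3 = ph[["sr2_sr3"]], significant = sig)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_report", "data.frame")
  out
}

#' Per-group summary of significant parameters
#'
#' Condenses a [study_statistics()] report into the per-group overview grid:
#' relevant measure count, the significantly changing relevant parameters
#' for females, for males, and for both, plus a totals row.
#'
#' @param report A `study_report`.
#' @param alpha Significance level.
#' @return Data frame with columns `group`, `n_measures`, `sig_female`,
#'   `sig_male`, `sig_both` and the corresponding counts.
#' @export
summarize_study <- function(report, alpha = 0.05) {
  rel <- report[!report$excluded, ]
  groups <- c("FPM", "PPM", "APM", "EPM", "SM", "GDC", "MM")
  sig_names <- function(g, sex) {
    r <- rel[rel$group == g & rel$sex == sex & rel$p <= alpha, ]
    unique(r$parameter)
  }
  rows <- lapply(groups, function(g) {
    f <- sig_names(g, "female")
    m <- sig_names(g, "male")
    b <- intersect(f, m)
    data.frame(group = g,
               n_measures = length(unique(rel$parameter[rel$group == g])),
               sig_female = paste(f, collapse = ", "),
               sig_male = paste(m, collapse = ", "),
               sig_both = paste(b, collapse = ", "),
               n_female = length(f), n_male = length(m), n_both = length(b))
  })
  out <- do.call(rbind, rows)
  totals <- data.frame(group = "Total",
                       n_measures = sum(out$n_measures),
                       sig_female = "", sig_male = "", sig_both = "",
                       n_female = sum(out$n_female),
                       n_male = sum(out$n_male),
                       n_both = sum(out$n_both))
  rbind(out, totals)
}

#' Minimal relative-deviation plot for one measure group
#'
#' Draws per-subject SR2/SR1 and SR3/SR1 ratios for the relevant parameters
#' of one group (requires ggplot2).
#'
#' @param triads A [run_triads()] result.
#' @param group Group label (`"FPM"`, `"PPM"`, ...).
#' @return A ggplot object.
#' @export
plot_relative_deviation <- function(triads, group) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  cat <- parameter_catalogue()
  pnames <- cat$name[cat$group == group & !cat$excluded]
  dfs <- lapply(pnames, function(p) {
    d <- relative_deviation(triads, p)
    d$parameter <- p
    d
  })
  df <- do.call(rbind, dfs)
  df <- df[df$computed, ]
  long <- rbind(
    data.frame(parameter = df$parameter, sex = df$sex,
               reduction = "SR2/SR1", ratio = df$ratio_sr2),
    data.frame(parameter = df$parameter, sex = df$sex,
               reduction = "SR3/SR1", ratio = df$ratio_sr3))
  ggplot2::ggplot(long, ggplot2::aes(x = parameter, y = ratio,
                                     colour = reduction)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = NULL, y = "relative deviation vs SR1",
                  title = sprintf("%s relative deviations", group))
}
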