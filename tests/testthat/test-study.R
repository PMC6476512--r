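test_that("identical conditions are never significant", {
  set.seed(1)
  x <- rnorm(10, 5, 1)
  res <- omnibus_test(cbind(x, x, x))
  expect_equal(res$p.value, 1)
  expect_equal(res$test, "constant")
})

test_that("the Friedman branch equals the exhaustive rank statistic on a toy", {
  set.seed(2)
  Y <- matrix(rnorm(18), 6, 3)      # continuous, no ties
  res <- omnibus_test(Y, mode = "nonparametric")
  expect_equal(res$test, "friedman")

  # brute-force rank computation: chi^2 = 12/(n k (k+1)) sum Rj^2 - 3 n (k+1)
  R <- t(apply(Y, 1, rank))
  n <- nrow(Y)
  k <- ncol(Y)
  chi2 <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, chi2)
  expect_equal(res$p.value, stats::pchisq(chi2, k - 1, lower.tail = FALSE))
})

test_that("the parametric branch agrees with the aov error-stratum oracle", {
  set.seed(3)
  Y <- matrix(rnorm(45, 10, 2), 15, 3)
  Y[, 3] <- Y[, 3] + 1
  res <- omnibus_test(Y, mode = "parametric")

  df <- data.frame(y = as.vector(Y),
                   cond = factor(rep(1:3, each = 15)),
                   subj = factor(rep(1:15, times = 3)))
  a <- summary(stats::aov(y ~ cond + Error(subj/cond), data = df))
  tab <- a[["Error: subj:cond"]][[1]]
  expect_equal(res$statistic, tab["cond", "F value"], tolerance = 1e-10)
  if (res$test == "rm-anova") {   # no sphericity correction applied
    expect_equal(res$p.value, tab["cond", "Pr(>F)"], tolerance = 1e-10)
  } else {                        # corrected p can only be larger
    expect_gte(res$p.value, tab["cond", "Pr(>F)"])
  }
})

test_that("a strong shift in one condition is detected in both branches", {
  set.seed(4)
  base <- rnorm(20, 10, 0.5)
  Y <- cbind(base, base + rnorm(20, 0, 0.5), base + 10)
  expect_lte(omnibus_test(Y, mode = "parametric")$p.value, 0.05)
  expect_lte(omnibus_test(Y, mode = "nonparametric")$p.value, 0.05)
  # auto mode picks a branch and still rejects
  expect_lte(omnibus_test(Y)$p.value, 0.05)
})

test_that("post-hoc p-values are Bonferroni-corrected and capped", {
  set.seed(5)
  x <- rnorm(12, 10, 1)
  Y <- cbind(x, x + rnorm(12, 0.8, 0.3), x + rnorm(12, 0, 2))
  ph <- posthoc_tests(Y, "parametric")
  raw12 <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)$p.value
  expect_equal(ph[["sr1_sr2"]], min(3 * raw12, 1))
  expect_true(all(ph <= 1))
  # corrected p never falls below raw p
  raw <- c(stats::t.test(Y[, 1], Y[, 2], paired = TRUE)$p.value,
           stats::t.test(Y[, 1], Y[, 3], paired = TRUE)$p.value,
           stats::t.test(Y[, 2], Y[, 3], paired = TRUE)$p.value)
  expect_true(all(ph >= raw))
})

test_that("the Wilcoxon post-hoc matches the exact sign-assignment oracle", {
  set.seed(6)
  x <- c(10.3, 11.7, 9.2, 12.5, 10.9, 11.1, 9.8, 12.0)
  y <- x + c(0.4, -0.2, 0.7, 0.3, -0.5, 0.6, 0.25, 0.9)  # no zeros, no ties
  ph <- posthoc_tests(cbind(x, y, y), "nonparametric")

  # exhaustive oracle: distribution of W+ over all 2^n sign assignments
  d <- y - x
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- signs %*% r
  p_exact <- min(1, 2 * min(mean(Wall >= W), mean(Wall <= W)))
  expect_equal(ph[["sr1_sr2"]], min(3 * p_exact, 1))
})

test_that("a self-triad cohort yields zero significant parameters", {
  set.seed(7)
  cohort <- generate_cohort(3, rng_seed = 70, render = FALSE)
  triads <- lapply(cohort, function(subj) {
    ps <- compute_all(generate_gaw(subj$config)$gaw)
    list(id = subj$id, sex = subj$sex,
         params = list(sr1 = ps, sr2 = ps, sr3 = ps))
  })
  # pad to n >= 5 per sex by reusing configurations with new seeds
  more <- generate_cohort(3, rng_seed = 71, render = FALSE)
  triads <- c(triads, lapply(more, function(subj) {
    ps <- compute_all(generate_gaw(subj$config)$gaw)
    list(id = paste0(subj$id, "b"), sex = subj$sex,
         params = list(sr1 = ps, sr2 = ps, sr3 = ps))
  }))
  rep <- study_statistics(triads)
  expect_false(any(rep$significant))
  expect_true(all(rep$p == 1))

  tab <- summarize_study(rep)
  expect_equal(tab$n_measures[match(c("FPM", "PPM", "APM", "EPM", "SM",
                                      "GDC", "MM"), tab$group)],
               c(1, 6, 7, 4, 7, 5, 5))
  expect_equal(tab$n_measures[tab$group == "Total"], 35)
  expect_true(all(tab$n_female == 0))
})

test_that("relative deviations divide by the original resolution", {
  ps <- function(v) {
    cat <- parameter_catalogue()
    cat$value <- v
    class(cat) <- c("parameter_set", "data.frame")
    cat
  }
  mk <- function(v1, v2, v3) {
    list(id = "s", sex = "female",
         params = list(sr1 = ps(v1), sr2 = ps(v2), sr3 = ps(v3)))
  }
  same <- relative_deviation(list(mk(rep(4, 50), rep(4, 50), rep(4, 50))), "OQ")
  expect_equal(same$ratio_sr2, 1)

  halved <- relative_deviation(list(mk(rep(4, 50), rep(2, 50), rep(1, 50))), "OQ")
  expect_equal(halved$ratio_sr2, 0.5)
  expect_equal(halved$ratio_sr3, 0.25)

  zero <- relative_deviation(list(mk(rep(0, 50), rep(2, 50), rep(1, 50))), "OQ")
  expect_false(zero$computed)
  expect_true(is.na(zero$ratio_sr2))
})

test_that("omnibus input validation rejects unusable matrices", {
  expect_error(omnibus_test(matrix(1, 3, 3)), "at least 5")
  expect_error(omnibus_test(matrix(1, 6, 2)), "three columns")
  m <- matrix(rnorm(18), 6, 3)
  m[2, 2] <- NA
  expect_error(omnibus_test(m), "missing")
})
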