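test_that("sweep tables compute change and percentage change correctly", {
  tab <- sweep_table(c(0, 30), c(48.8, 44.0), "horizontal")
  expect_equal(tab$delta, c(0, -4.8))
  expect_equal(tab$pct_change[2], 100 * (44.0 - 48.8) / 48.8, tolerance = 1e-9)
  expect_equal(round(tab$pct_change[2], 2), -9.84)

  # single-angle sweep: structurally trivial
  m <- noiseless_pelvis(n_points = 100)
  single <- pi_sweep(m, "vertical", angles = 0)
  expect_equal(nrow(single), 1L)
  expect_equal(single$delta, 0)
  expect_equal(single$pct_change, 0)

  expect_error(sweep_table(c(5, 10), c(48, 49), "vertical"),
               class = "pelvir_parameter_error")
  expect_error(pi_sweep(m, "vertical", angles = c(5, 10)),
               class = "pelvir_parameter_error")
})

test_that("a model sweep equals the closed-form oracle per angle", {
  m <- noiseless_pelvis(40, 8.8, n_points = 200)
  for (ax in c("vertical", "horizontal")) {
    sw <- pi_sweep(m, ax)
    expect_equal(sw$pi, closed_form_pi(40, 8.8, ax, sw$angle),
                 tolerance = 1e-6)
    expect_equal(sw$angle, seq(0, 40, 5))
    expect_equal(sw$delta[sw$angle == 0], 0)
  }
})

test_that("the 6-degree criterion reproduces published thresholds", {
  vert <- sweep_table(sweep_angles, published_vertical_means, "vertical")
  expect_equal(acceptable_threshold(vert), 30)
  # the printed horizontal means also give 30 (|48.8 - 42.2| = 6.6 at 35)
  horiz <- sweep_table(sweep_angles, published_horizontal_means, "horizontal")
  expect_equal(acceptable_threshold(horiz), 30)
  # inclusive comparison: |delta| exactly 6 passes
  edge <- sweep_table(c(0, 5, 10), c(50, 56, 57), "vertical")
  expect_equal(acceptable_threshold(edge), 5)
  # all deltas zero: the largest tabulated angle
  flat <- sweep_table(sweep_angles, rep(48.8, 9), "vertical")
  expect_equal(acceptable_threshold(flat), 40)
  # even the smallest non-zero angle failing gives 0
  steep <- sweep_table(c(0, 5, 10), c(50, 57, 58), "vertical")
  expect_equal(acceptable_threshold(steep), 0)
})

test_that("acceptable_threshold is monotone in the tolerance", {
  set.seed(4)
  for (i in 1:10) {
    pis <- 48.8 + cumsum(c(0, runif(8, -2, 3)))
    tab <- sweep_table(sweep_angles, pis, "vertical")
    tols <- c(1, 2, 4, 6, 8, 12)
    thr <- vapply(tols, function(tl) acceptable_threshold(tab, tl), numeric(1))
    expect_true(all(diff(thr) >= 0))
  }
})

test_that("cohort sweeps aggregate member sweeps", {
  base <- noiseless_params(n_points = 100)
  m <- generate_pelvis(base, seed = 5)
  # cohort of identical members equals the single-member sweep
  summ <- cohort_sweep(list(m, m, m), "vertical")
  sw <- pi_sweep(m, "vertical")
  expect_equal(summ$mean_pi, sw$pi, tolerance = 1e-12)
  expect_equal(summ$mean_pct_change, sw$pct_change, tolerance = 1e-12)
  expect_equal(summ$n, rep(3L, 9))

  # permutation invariance of the member order
  coh <- generate_cohort(n = 6, pi_sd = 10, base = base, seed = 10)
  s1 <- cohort_sweep(coh, "horizontal")
  s2 <- cohort_sweep(rev(coh), "horizontal")
  expect_equal(s1$mean_pi, s2$mean_pi, tolerance = 1e-12)

  # zero-spread noiseless cohort: mean PI at 0 deg is exactly the target
  coh0 <- generate_cohort(n = 5, pi_mean = 48.8, pi_sd = 0, base = base, seed = 2)
  s0 <- cohort_sweep(coh0, "vertical")
  expect_equal(s0$mean_pi[s0$angle == 0], 48.8, tolerance = 1e-6)

  # seeded noiseless cohort: horizontal mean PI strictly decreasing
  expect_true(all(diff(s1$mean_pi) < 0))
})

test_that("ICC(3,1) matches an independent two-way ANOVA oracle", {
  # worked example small enough to audit by hand
  mat <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3)
  expect_equal(icc(mat)$icc, icc31_anova_oracle(mat), tolerance = 1e-12)

  # random 5 x 3 matrices
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(rnorm(15, mean = 50, sd = 8), nrow = 5)
    res <- icc(m)
    expect_equal(res$icc, icc31_anova_oracle(m), tolerance = 1e-9)
    expect_lte(res$icc, 1)
  }

  # perfect agreement between raters
  subj <- c(40, 50, 60, 45)
  expect_equal(icc(cbind(subj, subj))$icc, 1)

  # shifting one rater's column by a constant leaves the consistency ICC
  # unchanged (the rater main effect absorbs the shift)
  m <- matrix(rnorm(12, 50, 5), nrow = 4)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 7
  expect_equal(icc(shifted)$icc, icc(m)$icc, tolerance = 1e-9)
  expect_equal(icc31_anova_oracle(shifted), icc(shifted)$icc, tolerance = 1e-9)

  expect_error(icc(matrix(1:2, 1, 2)), class = "pelvir_statistics_error")
  expect_error(icc(matrix(5, 3, 2)), class = "pelvir_statistics_error")
  expect_error(icc(matrix(c(1, 2, NA, 4), 2, 2)),
               class = "pelvir_statistics_error")
  expect_error(icc(mat, form = "2,1"), class = "pelvir_parameter_error")
})

test_that("simulated repeated ratings of a cohort give high reliability", {
  base <- noiseless_params(n_points = 100)
  coh <- generate_cohort(n = 30, pi_mean = 48.8, pi_sd = 5, base = base,
                         seed = 30)
  ratings <- simulate_ratings(coh, n_raters = 2, rater_sd = 0.5, seed = 31)
  expect_equal(dim(ratings), c(30L, 2L))
  res <- icc(ratings)
  # subject sd 5 vs rater sd 0.5: expected ICC ~ 25/25.25 ~ 0.99
  expect_gt(res$icc, 0.9)
  expect_equal(res$label, "excellent")
  # determinism
  expect_identical(ratings,
                   simulate_ratings(coh, n_raters = 2, rater_sd = 0.5, seed = 31))
})

test_that("reliability classification uses inclusive upper bins", {
  expect_equal(classify_icc(c(0.39, 0.40, 0.5, 0.749, 0.75, 0.97)),
               c("poor", "fair to good", "fair to good", "fair to good",
                 "excellent", "excellent"))
})

test_that("glance and autoplot summarise sweeps", {
  m <- noiseless_pelvis(n_points = 100)
  sw <- pi_sweep(m, "vertical")
  g <- glance(sw)
  expect_equal(g$pi_0, 48.8, tolerance = 1e-6)
  expect_equal(g$threshold, acceptable_threshold(sw))
  p <- ggplot2::autoplot(sw)
  expect_s3_class(p, "ggplot")
  summ <- cohort_sweep(list(m, m), "horizontal")
  expect_s3_class(ggplot2::autoplot(summ), "ggplot")
  expect_equal(glance(summ)$n, 2L)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
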