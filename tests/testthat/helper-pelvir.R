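# Shared fixtures and independent oracles for the test suite.

noiseless_params <- function(ss = 40, pt = 8.8, n_points = 500, ...) {
  pelvis_params(ss_frame = ss, pt_frame = pt, noise_sd = 0,
                n_points = n_points, ...)
}

noiseless_pelvis <- function(ss = 40, pt = 8.8, seed = 1, n_points = 500, ...) {
  generate_pelvis(noiseless_params(ss, pt, n_points = n_points, ...),
                  seed = seed)
}

# random proper rotation (det +1) + translation
random_rigid_transform <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  list(r = r, t = rnorm(3, sd = 50))
}

apply_rigid <- function(pts, tf) {
  sweep(as.matrix(pts) %*% t(tf$r), 2, tf$t, "+")
}

transform_model <- function(model, tf) {
  pts <- apply_rigid(cbind(model$points$x, model$points$y, model$points$z), tf)
  model$points$x <- pts[, 1]
  model$points$y <- pts[, 2]
  model$points$z <- pts[, 3]
  model
}

# Independent ICC(3,1) oracle: two-way ANOVA mean squares from base-R lm().
icc31_anova_oracle <- function(mat) {
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  # suppress the F-test warning lm emits on perfect-agreement matrices;
  # only the mean squares are used
  tab <- suppressWarnings(anova(lm(y ~ subject + rater, data = df)))
  bms <- tab["subject", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  k <- ncol(mat)
  (bms - ems) / (bms + (k - 1) * ems)
}

# Published per-angle cohort means for the two rotation axes (projected PI,
# degrees, at 0..40 deg in 5-deg steps).
published_horizontal_means <- c(48.8, 48.7, 48.3, 47.8, 46.9, 45.6, 44.0, 42.2, 39.9)
published_vertical_means <- c(48.8, 49.0, 49.5, 50.2, 51.3, 52.7, 54.4, 56.6, 59.4)
sweep_angles <- seq(0, 40, 5)

vnorm_test <- function(v) sqrt(sum(v^2))
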