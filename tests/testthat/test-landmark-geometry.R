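test_that("three-point circle fitting recovers constructed circles", {
  # symmetric triple on the unit circle
  fit <- fit_circle_three_points(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_equal(abs(fit$plane_normal), c(0, 0, 1), tolerance = 1e-12)

  # construct-then-fit round trip in a random plane
  set.seed(5)
  for (rep in 1:5) {
    tf <- random_rigid_transform(rep)
    centre <- c(3, 4, 5)
    radius <- 7
    angs <- c(0, 90, 200) * pi / 180
    pts <- t(vapply(angs, function(a) {
      centre + radius * (cos(a) * tf$r[, 1] + sin(a) * tf$r[, 2])
    }, numeric(3)))
    fit <- fit_circle_three_points(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(fit$center, centre, tolerance = 1e-9)
    expect_equal(fit$radius, radius, tolerance = 1e-9)
    # fitted circle passes through all three points
    expect_equal(sqrt(rowSums(sweep(pts, 2, fit$center)^2)),
                 rep(radius, 3), tolerance = 1e-9)
    # normal orthogonal to the circle plane, unit length
    expect_equal(sum(fit$plane_normal^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(fit$plane_normal * (pts[2, ] - pts[1, ]))), 1e-9)
  }

  expect_error(fit_circle_three_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "pelvir_degenerate_geometry")
  expect_error(fit_circle_three_points(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "pelvir_degenerate_geometry")
})

test_that("least-squares sphere fitting is exact on spherical data", {
  # regular tetrahedron on the unit sphere
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  fit <- fit_sphere(tet)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-12)

  # 100 noiseless points, centre (0, 90, 0), radius 23
  set.seed(8)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(23 * dirs, 2, c(0, 90, 0), "+")
  fit <- fit_sphere(pts)
  expect_lt(sqrt(sum((fit$center - c(0, 90, 0))^2)), 1e-9)
  expect_equal(fit$radius, 23, tolerance = 1e-9)

  expect_error(fit_sphere(pts[1:3, ]), class = "pelvir_degenerate_geometry")
  # coplanar circle: sphere underdetermined
  th <- seq(0, 2 * pi, length.out = 20)
  expect_error(fit_sphere(cbind(cos(th), sin(th), 0)),
               class = "pelvir_degenerate_geometry")
})

test_that("endplate fitting recovers plane, centre and AP direction", {
  m <- noiseless_pelvis(40, 8.8)
  ep <- m$points[m$points$label == "endplate", ]
  fit <- fit_endplate(ep)
  s <- 40 * pi / 180
  expect_equal(fit$ap_direction, c(cos(s), 0, -sin(s)), tolerance = 1e-9)
  expect_equal(fit$plane_normal, c(sin(s), 0, cos(s)), tolerance = 1e-9)
  expect_lt(abs(sum(fit$ap_direction * fit$plane_normal)), 1e-12)
  pt <- 8.8 * pi / 180
  expect_equal(fit$center, 95 * c(-sin(pt), 0, cos(pt)), tolerance = 1e-9)
  expect_lte(fit$extent_ap, 45)
  expect_gt(fit$extent_ap, 35)  # major axis is anteroposterior

  # axis-aligned flat patch
  set.seed(2)
  flat <- cbind(runif(100, -1, 1), runif(100, -0.1, 0.1), 0)
  ffit <- fit_endplate(flat)
  expect_equal(ffit$plane_normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(abs(ffit$ap_direction[1]), 1, tolerance = 1e-3)

  expect_error(fit_endplate(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               class = "pelvir_degenerate_geometry")
})

test_that("derive_landmarks assembles the 3D sketch correctly", {
  m <- noiseless_pelvis()
  lm <- derive_landmarks(m)
  expect_equal(lm$hip_axis_midpoint, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(lm$hip_axis_midpoint,
               (lm$left_center + lm$right_center) / 2, tolerance = 1e-12)
  expect_equal(lm$sacro_femoral_midpoint,
               (lm$endplate$center + lm$hip_axis_midpoint) / 2,
               tolerance = 1e-12)

  # both head estimators agree exactly on noiseless data
  lm3 <- derive_landmarks(m, head_method = "three_point")
  expect_equal(lm3$left_center, lm$left_center, tolerance = 1e-6)
  expect_equal(lm3$right_center, lm$right_center, tolerance = 1e-6)

  # extent-midpoint endplate centre stays on the AP line through the centroid
  lme <- derive_landmarks(m, endplate_center = "extent_midpoint")
  offset <- lme$endplate$center - lm$endplate$center
  expect_lt(vnorm_test(offset - sum(offset * lm$endplate$ap_direction) *
                         lm$endplate$ap_direction), 1e-9)

  broken <- m
  broken$points <- broken$points[broken$points$label != "left_head", ]
  expect_error(derive_landmarks(broken), class = "pelvir_input_error")
  expect_error(derive_landmarks(broken), "left_head")
})

test_that("fits are rigid-motion and scale equivariant", {
  m <- noiseless_pelvis(n_points = 200)
  pts <- as.matrix(m$points[m$points$label == "left_head", c("x", "y", "z")])
  ep <- as.matrix(m$points[m$points$label == "endplate", c("x", "y", "z")])
  for (seed in 1:3) {
    tf <- random_rigid_transform(seed)
    f0 <- fit_sphere(pts)
    f1 <- fit_sphere(apply_rigid(pts, tf))
    expect_equal(f1$center, as.numeric(tf$r %*% f0$center + tf$t),
                 tolerance = 1e-6)
    expect_equal(f1$radius, f0$radius, tolerance = 1e-9)

    e0 <- fit_endplate(ep)
    e1 <- fit_endplate(apply_rigid(ep, tf))
    expect_equal(e1$center, as.numeric(tf$r %*% e0$center + tf$t),
                 tolerance = 1e-6)
    # directions transform up to the documented sign convention
    expect_lt(min(vnorm_test(e1$ap_direction - as.numeric(tf$r %*% e0$ap_direction)),
                  vnorm_test(e1$ap_direction + as.numeric(tf$r %*% e0$ap_direction))),
              1e-6)
  }
  # scale equivariance
  s <- 2.5
  f0 <- fit_sphere(pts)
  fs <- fit_sphere(pts * s)
  expect_equal(fs$center, f0$center * s, tolerance = 1e-9)
  expect_equal(fs$radius, f0$radius * s, tolerance = 1e-9)
  e0 <- fit_endplate(ep)
  es <- fit_endplate(ep * s)
  expect_equal(es$center, e0$center * s, tolerance = 1e-9)
  expect_equal(es$ap_direction, e0$ap_direction, tolerance = 1e-9)
})

test_that("tidy() flattens a landmark set to named rows", {
  lm <- derive_landmarks(noiseless_pelvis(n_points = 100))
  td <- tidy(lm)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$kind, c("point", "direction"))
  expect_equal(td$x[td$name == "hip_axis_midpoint"], 0, tolerance = 1e-9)
})
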