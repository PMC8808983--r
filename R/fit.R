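# Landmark geometry: recover the 3D sketch primitives (head circles/spheres
# and centres, hip axis, endplate line) from labeled point clouds.

# First sufficiently non-zero component among `prefer` decides the sign.
fix_sign <- function(v, prefer, tol = 1e-9) {
  for (i in prefer) {
    if (abs(v[i]) > tol) {
      if (v[i] < 0) v <- -v
      return(v)
    }
  }
  if (sum(v) < 0) -v else v
}

#' Circle through three points in 3D
#'
#' Fits the unique circle passing through three pairwise-distinct,
#' non-collinear 3D points (the three-point method used to draw circles along
#' the segmented femoral heads). The circle plane normal is the normalized
#' cross product of `p2 - p1` and `p3 - p1`, with its sign fixed to have a
#' positive y component (tie: positive z).
#'
#' @param p1,p2,p3 Numeric 3-vectors, mm.
#' @return A `circle_fit`: list with `center` (3D point), `radius` and
#'   `plane_normal` (unit 3-vector).
#' @examples
#' fit_circle_three_points(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
#' @export
fit_circle_three_points <- function(p1, p2, p3) {
  p1 <- as_point3(p1, "p1"); p2 <- as_point3(p2, "p2"); p3 <- as_point3(p3, "p3")
  v1 <- p2 - p1
  v2 <- p3 - p1
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  scale <- max(vnorm(v1), vnorm(v2))
  if (scale < 1e-12 || vnorm(nrm) < 1e-12 * scale^2) {
    rlang::abort("The three points are collinear or not distinct; no unique circle.",
                 class = "pelvir_degenerate_geometry")
  }
  # centre = p1 + a*v1 + b*v2 with (c-p1).v1 = |v1|^2/2, (c-p1).v2 = |v2|^2/2
  g <- matrix(c(sum(v1 * v1), sum(v1 * v2), sum(v1 * v2), sum(v2 * v2)), 2, 2)
  ab <- solve(g, c(sum(v1 * v1) / 2, sum(v2 * v2) / 2))
  center <- p1 + ab[1] * v1 + ab[2] * v2
  structure(
    list(center = center,
         radius = vnorm(center - p1),
         plane_normal = fix_sign(unitize(nrm, "circle normal"), c(2L, 3L))),
    class = "circle_fit"
  )
}

#' Least-squares sphere fit
#'
#' Algebraic least-squares sphere through a point cloud, via the linearized
#' normal equations in (centre, radius): exact on noiseless spherical data.
#' This is the default femoral-head centre estimator; unlike the manual
#' three-point circle it uses every segmented surface point.
#'
#' @param points An n x 3 numeric matrix or a data frame with columns
#'   `x, y, z`, in mm; at least 4 points in general position.
#' @return A `sphere_fit`: list with `center`, `radius` and `rms_residual`
#'   (root-mean-square radial residual, mm).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 10)
#' pts <- cbind(cos(th), sin(th), 0)
#' pts <- rbind(pts, c(0, 0, 1), c(0, 0, -1))
#' fit_sphere(pts)
#' @export
fit_sphere <- function(points) {
  pts <- as_points_matrix(points)
  if (nrow(pts) < 4L) {
    rlang::abort("Sphere fitting needs at least 4 points.",
                 class = "pelvir_degenerate_geometry")
  }
  a <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qrd <- qr(a)
  if (qrd$rank < 4L) {
    rlang::abort("Points are degenerate (coplanar circle or worse); sphere underdetermined.",
                 class = "pelvir_degenerate_geometry")
  }
  sol <- qr.coef(qrd, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) {
    rlang::abort("Sphere fit collapsed to non-positive radius.",
                 class = "pelvir_degenerate_geometry")
  }
  radius <- sqrt(r2)
  resid <- sqrt(rowSums(sweep(pts, 2, center)^2)) - radius
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean(resid^2))),
    class = "sphere_fit"
  )
}

#' Principal-axis fit of the S1 endplate patch
#'
#' Fits the endplate as a plane through the point centroid using principal
#' component analysis: the plane normal is the least-variance direction
#' (sign: positive z, tie positive x) and the in-plane anteroposterior
#' direction is the greatest-variance direction (sign: positive x, tie
#' positive z). The endplate "line" of a sagittal view is the trace of this
#' patch along `ap_direction`.
#'
#' @param points An n x 3 matrix or data frame with columns `x, y, z`; at
#'   least 3 non-collinear points.
#' @return An `endplate_fit`: list with `center` (centroid), `ap_direction`,
#'   `plane_normal` (orthonormal unit 3-vectors) and `extent_ap` (range of
#'   projections along `ap_direction`, mm).
#' @examples
#' pts <- cbind(runif(50, -1, 1), runif(50, -0.1, 0.1), 0)
#' fit_endplate(pts)
#' @export
fit_endplate <- function(points) {
  pts <- as_points_matrix(points)
  if (nrow(pts) < 3L) {
    rlang::abort("Endplate fitting needs at least 3 points.",
                 class = "pelvir_degenerate_geometry")
  }
  center <- colMeans(pts)
  centered <- sweep(pts, 2, center)
  sv <- svd(centered)
  scale <- sv$d[1]
  if (scale < 1e-12 || sv$d[2] < 1e-9 * scale) {
    rlang::abort("Endplate points are collinear or coincident; plane underdetermined.",
                 class = "pelvir_degenerate_geometry")
  }
  ap <- fix_sign(sv$v[, 1], c(1L, 3L))
  nrm <- fix_sign(sv$v[, 3], c(3L, 1L))
  proj <- centered %*% ap
  structure(
    list(center = unname(center),
         ap_direction = unname(ap),
         plane_normal = unname(nrm),
         extent_ap = diff(range(proj))),
    class = "endplate_fit"
  )
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    missing_cols <- setdiff(c("x", "y", "z"), names(points))
    if (length(missing_cols)) {
      rlang::abort(sprintf("Point data frame lacks column(s): %s.",
                           paste(missing_cols, collapse = ", ")),
                   class = "pelvir_input_error")
    }
    points <- cbind(points$x, points$y, points$z)
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 3L || any(!is.finite(pts))) {
    rlang::abort("Points must be a finite n x 3 matrix.",
                 class = "pelvir_input_error")
  }
  storage.mode(pts) <- "double"
  unname(pts)
}

# Deterministic surrogate for the manual three-point circle: the lowest
# decile of points by z approximates the equatorial segmentation rim; three
# of them are taken at the 10/50/90% quantile positions of their azimuth
# ordering about the rim centroid.
three_point_head_center <- function(pts) {
  ord <- order(pts[, 3], pts[, 1], pts[, 2])
  k <- max(3L, ceiling(0.1 * nrow(pts)))
  rim <- pts[ord[seq_len(k)], , drop = FALSE]
  ctr <- colMeans(rim)
  az <- atan2(rim[, 2] - ctr[2], rim[, 1] - ctr[1])
  rim <- rim[order(az), , drop = FALSE]
  idx <- pmax(1L, pmin(k, round(c(0.1, 0.5, 0.9) * k)))
  if (length(unique(idx)) < 3L) idx <- seq_len(3L)
  fit_circle_three_points(rim[idx[1], ], rim[idx[2], ], rim[idx[3], ])$center
}

#' Derive the full landmark set from a pelvis model
#'
#' Recovers the complete 3D sketch: both femoral head centres, the
#' bicoxofemoral (hip) axis midpoint, the fitted endplate with its centre and
#' anteroposterior direction, and the sacro-femoral midpoint (midpoint of the
#' segment joining the endplate centre to the hip-axis midpoint).
#'
#' @param model A `pelvis_model` from [generate_pelvis()] or [read_pelvis()].
#' @param head_method `"sphere_lsq"` (default, least-squares sphere on all
#'   points) or `"three_point"` (deterministic surrogate of the manual
#'   three-point circle: three points at fixed quantile positions along the
#'   equatorial rim).
#' @param endplate_center `"centroid"` (default) or `"extent_midpoint"`
#'   (midpoint of the projection range along the anteroposterior direction).
#' @return A `landmark_set`: list with `left_center`, `right_center`,
#'   `hip_axis_midpoint`, `endplate` (an `endplate_fit`) and
#'   `sacro_femoral_midpoint`.
#' @examples
#' m <- generate_pelvis(pelvis_params(ss_frame = 40, noise_sd = 0), seed = 1)
#' derive_landmarks(m)
#' @export
derive_landmarks <- function(model,
                             head_method = c("sphere_lsq", "three_point"),
                             endplate_center = c("centroid", "extent_midpoint")) {
  head_method <- match.arg(head_method)
  endplate_center <- match.arg(endplate_center)
  if (!inherits(model, "pelvis_model")) {
    rlang::abort("`model` must be a pelvis_model.", class = "pelvir_input_error")
  }
  structures <- c("left_head", "right_head", "endplate")
  missing_structs <- setdiff(structures, unique(model$points$label))
  if (length(missing_structs)) {
    rlang::abort(sprintf("Model is missing labeled structure(s): %s.",
                         paste(missing_structs, collapse = ", ")),
                 class = "pelvir_input_error")
  }
  get_pts <- function(lab) {
    as_points_matrix(dplyr::filter(model$points, .data$label == lab))
  }
  estimator <- switch(head_method,
    sphere_lsq = function(p) fit_sphere(p)$center,
    three_point = three_point_head_center
  )
  left <- estimator(get_pts("left_head"))
  right <- estimator(get_pts("right_head"))
  hip_mid <- (left + right) / 2

  ep <- fit_endplate(get_pts("endplate"))
  if (endplate_center == "extent_midpoint") {
    proj <- (sweep(get_pts("endplate"), 2, ep$center) %*% ep$ap_direction)
    ep$center <- ep$center + mean(range(proj)) * ep$ap_direction
  }

  structure(
    list(left_center = left,
         right_center = right,
         hip_axis_midpoint = hip_mid,
         endplate = ep,
         sacro_femoral_midpoint = (ep$center + hip_mid) / 2,
         head_method = head_method),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  fmt <- function(p) sprintf("(%.2f, %.2f, %.2f)", p[1], p[2], p[3])
  cat("<landmark_set> (", x$head_method, ")\n", sep = "")
  cat("  head centres L", fmt(x$left_center), " R", fmt(x$right_center), "\n")
  cat("  hip-axis midpoint ", fmt(x$hip_axis_midpoint), "\n")
  cat("  endplate centre ", fmt(x$endplate$center),
      " ap ", fmt(x$endplate$ap_direction), "\n")
  invisible(x)
}
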