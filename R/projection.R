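# Rotated sagittal viewing planes and orthographic projection.
# The unrotated image plane is the sagittal x-z plane: u1 = x (anterior,
# image-right), u2 = z (superior, image-up), normal = y (left).
# "Vertical" rotation tilts the view about the superoinferior z axis (axial
# pelvic rotation); "horizontal" rotation about the anteroposterior x axis
# (coronal obliquity). In-plane rotation about the mediolateral axis cannot
# change a projected angle and is deliberately not offered.

#' Specify a pelvic rotation
#'
#' @param axis_kind `"vertical"` (about the superoinferior axis) or
#'   `"horizontal"` (about the anteroposterior axis).
#' @param angle Rotation angle in degrees, within \[-90, 90\].
#' @return A `rotation_spec` list with `axis_kind` and `angle`.
#' @examples
#' rotation_spec("vertical", 30)
#' @export
rotation_spec <- function(axis_kind = c("vertical", "horizontal"), angle = 0) {
  axis_kind <- match.arg(axis_kind)
  check_number(angle, "angle", lower = -90, upper = 90)
  structure(list(axis_kind = axis_kind, angle = angle), class = "rotation_spec")
}

rotation_axis <- function(axis_kind) switch(axis_kind, vertical = "z", horizontal = "x")

#' Image plane induced by a pelvic rotation
#'
#' Rotates the canonical sagittal viewing basis by the specified angle about
#' the vertical (z) or horizontal (x) reference axis, using a proper rotation
#' (det = +1). Rotating the viewing plane by `+angle` is exactly equivalent
#' to rotating the pelvis by `-angle` (see [rotate_pelvis()]).
#'
#' @param rot A [rotation_spec()].
#' @return An `image_plane`: list with orthonormal in-plane basis vectors
#'   `u1`, `u2` and `normal = u1 x u2`.
#' @examples
#' image_plane_for(rotation_spec("vertical", 40))
#' @export
image_plane_for <- function(rot) {
  if (!inherits(rot, "rotation_spec")) {
    rlang::abort("`rot` must be a rotation_spec.", class = "pelvir_parameter_error")
  }
  r <- rotation_matrix_axis(rotation_axis(rot$axis_kind), rot$angle)
  u1 <- as.numeric(r %*% c(1, 0, 0))
  u2 <- as.numeric(r %*% c(0, 0, 1))
  # normal = u2 x u1: the unit normal lies on the +y (left, viewer) side of
  # the unrotated lateral view, i.e. (0, 1, 0) at 0 degrees
  nrm <- c(u2[2] * u1[3] - u2[3] * u1[2],
           u2[3] * u1[1] - u2[1] * u1[3],
           u2[1] * u1[2] - u2[2] * u1[1])
  structure(list(u1 = u1, u2 = u2, normal = nrm), class = "image_plane")
}

#' Orthographic projection onto an image plane
#'
#' Projects 3D points onto the image plane by parallel (orthographic)
#' projection, matching a CAD screen capture: the image coordinates are the
#' dot products with the in-plane basis. Linear, idempotent on in-plane
#' points, and independent of position along the plane normal.
#'
#' @param points A 3-vector, an n x 3 matrix, or a data frame with columns
#'   `x, y, z`.
#' @param plane An `image_plane` from [image_plane_for()].
#' @return An n x 2 matrix of image coordinates (columns `u`, `v`), or a
#'   length-2 vector for a single point.
#' @examples
#' project(c(1, 2, 3), image_plane_for(rotation_spec("vertical", 0)))
#' @export
project <- function(points, plane) {
  if (!inherits(plane, "image_plane")) {
    rlang::abort("`plane` must be an image_plane.", class = "pelvir_parameter_error")
  }
  single <- is.numeric(points) && is.null(dim(points)) && length(points) == 3L
  pts <- if (single) matrix(points, 1, 3) else as_points_matrix(points)
  out <- cbind(u = pts %*% plane$u1, v = pts %*% plane$u2)
  colnames(out) <- c("u", "v")
  if (single) drop(out) else out
}

#' Project a landmark set into image coordinates
#'
#' Projects the endplate centre, the hip-axis midpoint, both head centres and
#' the endplate anteroposterior direction (renormalized in the image) onto
#' the viewing plane. An endplate viewed end-on (its AP direction parallel to
#' the plane normal) has no image direction and raises a degenerate
#' projection error.
#'
#' @param lm A `landmark_set` from [derive_landmarks()].
#' @param plane An `image_plane`.
#' @return A `projected_landmarks` list with 2D points `endplate_center`,
#'   `hip_axis_midpoint`, `left_center`, `right_center`, a 2D unit vector
#'   `ap_direction`, and the generating `plane`.
#' @export
project_landmarks <- function(lm, plane) {
  if (!inherits(lm, "landmark_set")) {
    rlang::abort("`lm` must be a landmark_set.", class = "pelvir_input_error")
  }
  ap2 <- project(lm$endplate$ap_direction, plane)
  if (vnorm(ap2) < 1e-9) {
    rlang::abort("Endplate is viewed end-on: projected AP direction has zero length.",
                 class = "pelvir_degenerate_projection")
  }
  structure(
    list(endplate_center = project(lm$endplate$center, plane),
         hip_axis_midpoint = project(lm$hip_axis_midpoint, plane),
         left_center = project(lm$left_center, plane),
         right_center = project(lm$right_center, plane),
         ap_direction = ap2 / vnorm(ap2),
         endplate_ap3 = lm$endplate$ap_direction,
         endplate_center3 = lm$endplate$center,
         hip_axis_midpoint3 = lm$hip_axis_midpoint,
         plane = plane),
    class = "projected_landmarks"
  )
}

#' Rigidly rotate a pelvis model
#'
#' Applies the rotation of a [rotation_spec()] to every point of the model
#' (about the canonical axis through the origin). Rotating the pelvis by
#' `-angle` and viewing at 0 deg reproduces viewing the unrotated pelvis on
#' the `+angle` plane exactly; both routes are exposed so either convention
#' can be used.
#'
#' @param model A `pelvis_model`.
#' @param rot A [rotation_spec()].
#' @return The rotated `pelvis_model`.
#' @export
rotate_pelvis <- function(model, rot) {
  if (!inherits(model, "pelvis_model")) {
    rlang::abort("`model` must be a pelvis_model.", class = "pelvir_input_error")
  }
  if (!inherits(rot, "rotation_spec")) {
    rlang::abort("`rot` must be a rotation_spec.", class = "pelvir_parameter_error")
  }
  r <- rotation_matrix_axis(rotation_axis(rot$axis_kind), rot$angle)
  pts <- as_points_matrix(model$points) %*% t(r)
  model$points$x <- pts[, 1]
  model$points$y <- pts[, 2]
  model$points$z <- pts[, 3]
  model
}
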