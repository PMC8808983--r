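# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a landmark set
#'
#' @param x A `landmark_set`.
#' @param ... Unused.
#' @return A tibble with one row per named point or direction and columns
#'   `name`, `kind` (`point` or `direction`), `x`, `y`, `z`.
#' @method tidy landmark_set
#' @export
tidy.landmark_set <- function(x, ...) {
  rows <- list(
    left_center = c("point", x$left_center),
    right_center = c("point", x$right_center),
    hip_axis_midpoint = c("point", x$hip_axis_midpoint),
    endplate_center = c("point", x$endplate$center),
    sacro_femoral_midpoint = c("point", x$sacro_femoral_midpoint),
    endplate_ap_direction = c("direction", x$endplate$ap_direction),
    endplate_plane_normal = c("direction", x$endplate$plane_normal)
  )
  tibble::tibble(
    name = names(rows),
    kind = vapply(rows, `[`, character(1), 1),
    x = as.numeric(vapply(rows, `[`, character(1), 2)),
    y = as.numeric(vapply(rows, `[`, character(1), 3)),
    z = as.numeric(vapply(rows, `[`, character(1), 4))
  )
}

#' Tidy an ICC result
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @return A one-row tibble with `form`, `icc`, `label`, `n_subjects`,
#'   `n_raters` and the ANOVA mean squares.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(form = x$form, icc = x$icc, label = x$label,
                 n_subjects = x$n_subjects, n_raters = x$n_raters,
                 bms = x$bms, jms = x$jms, ems = x$ems)
}

#' @rdname tidy.icc_result
#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, label = x$label,
                 n_subjects = x$n_subjects, n_raters = x$n_raters)
}

#' One-row summary of a sweep
#'
#' @param x A `pi_sweep` or `cohort_summary`.
#' @param tol Acceptability tolerance in degrees, default 6.
#' @param ... Unused.
#' @return A one-row tibble with the 0-degree PI, the PI and delta at the
#'   largest swept angle, and the acceptability threshold.
#' @method glance pi_sweep
#' @export
glance.pi_sweep <- function(x, tol = 6, ...) {
  pi_col <- x$pi
  amax <- max(x$angle)
  tibble::tibble(
    axis_kind = x$axis_kind[1],
    pi_0 = pi_col[x$angle == 0],
    angle_max = amax,
    pi_at_max = pi_col[x$angle == amax],
    delta_at_max = x$delta[x$angle == amax],
    threshold = acceptable_threshold(x, tol)
  )
}

#' @rdname glance.pi_sweep
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, tol = 6, ...) {
  amax <- max(x$angle)
  tibble::tibble(
    axis_kind = x$axis_kind[1],
    n = x$n[1],
    pi_0 = x$mean_pi[x$angle == 0],
    angle_max = amax,
    pi_at_max = x$mean_pi[x$angle == amax],
    delta_at_max = x$delta[x$angle == amax],
    threshold = acceptable_threshold(x, tol)
  )
}

sweep_autoplot <- function(df, pi_col, tol, title) {
  pi0 <- df[[pi_col]][df$angle == 0]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data[[pi_col]])) +
    ggplot2::annotate("ribbon", x = range(df$angle),
                      ymin = pi0 - tol, ymax = pi0 + tol,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = pi0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "Pelvic rotation (degrees)",
                  y = "Projected pelvic incidence (degrees)",
                  title = title,
                  subtitle = sprintf("Shaded band: |error| <= %g degrees", tol)) +
    ggplot2::theme_minimal()
}

#' Plot projected PI against rotation angle
#'
#' Line plot of projected PI over the sweep, with the 0-degree reference and
#' the acceptability band shaded.
#'
#' @param object A `pi_sweep` or `cohort_summary`.
#' @param tol Band half-width in degrees, default 6.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pi_sweep
#' @export
autoplot.pi_sweep <- function(object, tol = 6, ...) {
  sweep_autoplot(object, "pi", tol,
                 sprintf("Projected PI under %s pelvic rotation",
                         object$axis_kind[1]))
}

#' @rdname autoplot.pi_sweep
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, tol = 6, ...) {
  sweep_autoplot(object, "mean_pi", tol,
                 sprintf("Mean projected PI under %s pelvic rotation (n = %d)",
                         object$axis_kind[1], object$n[1]))
}

#' Plot a pelvis point cloud in the sagittal view
#'
#' Orthographic projection of the labeled point cloud onto the (possibly
#' rotated) viewing plane, coloured by structure.
#'
#' @param object A `pelvis_model`.
#' @param rot A [rotation_spec()]; default the unrotated sagittal view.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pelvis_model
#' @export
autoplot.pelvis_model <- function(object, rot = rotation_spec("vertical", 0),
                                  ...) {
  plane <- image_plane_for(rot)
  uv <- project(object$points, plane)
  df <- tibble::tibble(u = uv[, 1], v = uv[, 2], label = object$points$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Image u (mm)", y = "Image v (mm)",
                  colour = "Structure",
                  title = sprintf("%s rotation, %g degrees",
                                  rot$axis_kind, rot$angle)) +
    ggplot2::theme_minimal()
}
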