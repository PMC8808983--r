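# Rotation sweeps: projected PI across a grid of rotation angles, change from
# the unrotated view, percentage change, and the acceptability criterion.

#' Build a sweep table from PI values
#'
#' Assembles the per-angle sweep table from already-measured PI values:
#' change from the 0-degree value and percentage change, both computed from
#' the unrounded inputs. Used internally by [pi_sweep()] and directly when
#' applying the acceptability criterion to published per-angle means.
#'
#' @param angles Rotation angles in degrees; must contain 0.
#' @param pi_values Projected PI at each angle, degrees.
#' @param axis_kind `"vertical"` or `"horizontal"`.
#' @return A tibble of class `pi_sweep` with columns `axis_kind`, `angle`,
#'   `pi`, `delta` (degrees from the 0-degree value) and `pct_change`.
#' @examples
#' sweep_table(seq(0, 40, 5),
#'             c(48.8, 49.0, 49.5, 50.2, 51.3, 52.7, 54.4, 56.6, 59.4),
#'             "vertical")
#' @export
sweep_table <- function(angles, pi_values,
                        axis_kind = c("vertical", "horizontal")) {
  axis_kind <- match.arg(axis_kind)
  if (length(angles) != length(pi_values) || !length(angles)) {
    rlang::abort("`angles` and `pi_values` must be non-empty and equal length.",
                 class = "pelvir_parameter_error")
  }
  if (!any(angles == 0)) {
    rlang::abort("`angles` must include 0 (the reference view).",
                 class = "pelvir_parameter_error")
  }
  ord <- order(angles)
  angles <- angles[ord]
  pi_values <- pi_values[ord]
  pi0 <- pi_values[angles == 0][1]
  out <- tibble::tibble(
    axis_kind = axis_kind,
    angle = angles,
    pi = pi_values,
    delta = pi_values - pi0,
    pct_change = 100 * (pi_values - pi0) / pi0
  )
  class(out) <- c("pi_sweep", class(out))
  out
}

#' Sweep projected PI over rotation angles
#'
#' Runs the full projection-and-measurement pipeline on one pelvis (or
#' pre-fitted landmark set) at each rotation angle about the chosen axis and
#' tabulates projected PI, its change from the unrotated value, and the
#' percentage change.
#'
#' @param x A `pelvis_model` or `landmark_set`.
#' @param axis_kind `"vertical"` or `"horizontal"`.
#' @param angles Degrees; default `seq(0, 40, 5)`, the 5-degree grid from 0
#'   to 40. Must include 0.
#' @param mode,head_method Passed to [measure_pi()].
#' @return A `pi_sweep` tibble (see [sweep_table()]).
#' @examples
#' m <- generate_pelvis(pelvis_params(ss_frame = 40, noise_sd = 0), seed = 1)
#' pi_sweep(m, "vertical")
#' @export
pi_sweep <- function(x, axis_kind = c("vertical", "horizontal"),
                     angles = seq(0, 40, 5),
                     mode = c("in_image_perpendicular",
                              "projected_3d_perpendicular"),
                     head_method = c("sphere_lsq", "three_point")) {
  axis_kind <- match.arg(axis_kind)
  mode <- match.arg(mode)
  head_method <- match.arg(head_method)
  if (!any(angles == 0)) {
    rlang::abort("`angles` must include 0 (the reference view).",
                 class = "pelvir_parameter_error")
  }
  lm <- if (inherits(x, "pelvis_model")) {
    derive_landmarks(x, head_method = head_method)
  } else {
    x
  }
  pis <- vapply(angles, function(a) {
    tryCatch(
      measure_pi(lm, rotation_spec(axis_kind, a), mode = mode),
      pelvir_degenerate_projection = function(e) {
        rlang::abort(sprintf("Degenerate projection at %g deg %s rotation.",
                             a, axis_kind),
                     class = "pelvir_degenerate_projection", parent = e)
      }
    )
  }, numeric(1))
  sweep_table(angles, pis, axis_kind)
}

#' Largest rotation with acceptable PI error
#'
#' Applies the acceptability criterion: the largest angle in the table such
#' that the absolute change from the 0-degree PI stays within `tol` at that
#' angle and at every smaller angle (a prefix rule; the comparison is
#' inclusive, so a change of exactly `tol` passes). The default tolerance of
#' 6 degrees is the published variability bound for satisfactory
#' reproducibility of repeated angle measurements.
#'
#' @param table A `pi_sweep` or cohort summary tibble with `angle` and
#'   `delta` (for a cohort summary, `delta` of the mean PI).
#' @param tol Acceptable absolute error, degrees. Default 6.
#' @return The threshold angle in degrees (0 if even the smallest non-zero
#'   angle exceeds `tol`).
#' @examples
#' tab <- sweep_table(seq(0, 40, 5),
#'                    c(48.8, 49.0, 49.5, 50.2, 51.3, 52.7, 54.4, 56.6, 59.4),
#'                    "vertical")
#' acceptable_threshold(tab)   # 30
#' @export
acceptable_threshold <- function(table, tol = 6) {
  check_number(tol, "tol", lower = 0)
  if (!all(c("angle", "delta") %in% names(table))) {
    rlang::abort("`table` must have columns `angle` and `delta`.",
                 class = "pelvir_input_error")
  }
  ord <- order(table$angle)
  ang <- table$angle[ord]
  dlt <- table$delta[ord]
  ok <- abs(dlt) <= tol
  bad <- which(!ok)
  if (!length(bad)) return(max(ang))
  if (bad[1] == 1L) return(0)
  ang[bad[1] - 1L]
}

#' Sweep a cohort and aggregate
#'
#' Runs [pi_sweep()] on every cohort member and reports the per-angle mean
#' projected PI and the per-angle mean percentage change, the latter averaged
#' over unrounded per-member values. The `delta` column is the change of the
#' mean PI from its 0-degree value, so [acceptable_threshold()] applies
#' directly to the summary.
#'
#' @param cohort A `pelvis_cohort` (or plain list of `pelvis_model`s).
#' @param axis_kind,angles,mode,head_method As in [pi_sweep()].
#' @return A `cohort_summary` tibble with columns `axis_kind`, `angle`,
#'   `mean_pi`, `delta`, `mean_pct_change`, `n`; the per-member sweeps are
#'   attached as attribute `"members"`.
#' @export
cohort_sweep <- function(cohort, axis_kind = c("vertical", "horizontal"),
                         angles = seq(0, 40, 5),
                         mode = c("in_image_perpendicular",
                                  "projected_3d_perpendicular"),
                         head_method = c("sphere_lsq", "three_point")) {
  axis_kind <- match.arg(axis_kind)
  if (!length(cohort)) {
    rlang::abort("`cohort` must be non-empty.", class = "pelvir_input_error")
  }
  members <- purrr::imap(cohort, function(m, i) {
    tryCatch(
      dplyr::mutate(pi_sweep(m, axis_kind, angles, mode, head_method),
                    member = i, .before = 1),
      error = function(e) {
        rlang::abort(sprintf("Sweep failed for cohort member %d.", i),
                     parent = e)
      }
    )
  })
  all_members <- dplyr::bind_rows(members)
  out <- all_members |>
    dplyr::group_by(.data$axis_kind, .data$angle) |>
    dplyr::summarise(mean_pi = mean(.data$pi),
                     mean_pct_change = mean(.data$pct_change),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$angle) |>
    dplyr::mutate(delta = .data$mean_pi - .data$mean_pi[.data$angle == 0],
                  .after = "mean_pi")
  class(out) <- c("cohort_summary", class(out))
  attr(out, "members") <- all_members
  out
}
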