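#' Pelvis generator parameters
#'
#' Bundles the anatomical and scan-frame parameters that define one synthetic
#' pelvis. The anatomical pelvic incidence is split into a scan-frame sacral
#' slope (`ss_frame`, inclination of the S1 endplate from the transverse plane
#' of the scan frame) and a scan-frame tilt (`pt_frame`, tilt of the
#' endplate-centre-to-hip-axis line from the scan-frame vertical), with the
#' construction identity `pi_anat = ss_frame + pt_frame`. Projected PI under
#' rotation depends on this split, not only on PI itself, which is why it is
#' an explicit parameter.
#'
#' Exactly two of `pi_anat`, `ss_frame`, `pt_frame` determine the third;
#' supply either (`ss_frame`, `pt_frame`) or (`pi_anat`, `pt_frame`).
#'
#' @param pi_anat Anatomical pelvic incidence, degrees. Defaults to
#'   `ss_frame + pt_frame` when both are given.
#' @param ss_frame Scan-frame sacral slope, degrees, in (0, 90).
#' @param pt_frame Scan-frame tilt, degrees, in \[0, 90). Default 8.8.
#' @param head_radius Femoral head radius, mm. Default 23.
#' @param head_separation Distance between femoral head centres along the
#'   mediolateral axis, mm. Default 180.
#' @param sacrum_distance Distance from the endplate centre to the hip-axis
#'   midpoint, mm. Default 95.
#' @param endplate_ap_width Anteroposterior extent of the S1 endplate patch,
#'   mm. Default 45 (the AP axis is the major axis so that the
#'   maximal-variance in-plane direction recovered by [fit_endplate()] is
#'   anteroposterior).
#' @param endplate_ml_width Mediolateral extent of the endplate patch, mm.
#'   Default 35.
#' @param n_points Points sampled per structure. Default 500.
#' @param noise_sd Isotropic Gaussian noise per coordinate, mm. Default 0.5.
#' @param asymmetry List of optional asymmetry offsets, mm:
#'   `endplate_ml` (mediolateral offset of the endplate centre, scalar) and
#'   `left_head` / `right_head` (3-vector perturbations of the head centres).
#'
#' @return An object of class `pelvis_params` (a named list).
#' @examples
#' p <- pelvis_params(ss_frame = 40, pt_frame = 8.8)
#' true_pi(p)
#' @export
pelvis_params <- function(pi_anat = NULL,
                          ss_frame = NULL,
                          pt_frame = 8.8,
                          head_radius = 23,
                          head_separation = 180,
                          sacrum_distance = 95,
                          endplate_ap_width = 45,
                          endplate_ml_width = 35,
                          n_points = 500,
                          noise_sd = 0.5,
                          asymmetry = list()) {
  check_number(pt_frame, "pt_frame", lower = 0, upper = 90, strict_upper = TRUE)
  if (is.null(ss_frame)) {
    if (is.null(pi_anat)) {
      rlang::abort("Supply `ss_frame` or `pi_anat` (with `pt_frame`).",
                   class = "pelvir_parameter_error")
    }
    ss_frame <- pi_anat - pt_frame
  }
  check_number(ss_frame, "ss_frame", lower = 0, upper = 90,
               strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(pi_anat)) pi_anat <- ss_frame + pt_frame
  if (abs(pi_anat - (ss_frame + pt_frame)) > 1e-9) {
    rlang::abort(
      sprintf("pi_anat (%g) must equal ss_frame + pt_frame (%g).",
              pi_anat, ss_frame + pt_frame),
      class = "pelvir_parameter_error"
    )
  }
  check_number(head_radius, "head_radius", lower = 0, strict_lower = TRUE)
  check_number(head_separation, "head_separation", lower = 0, strict_lower = TRUE)
  check_number(sacrum_distance, "sacrum_distance", lower = 0, strict_lower = TRUE)
  check_number(endplate_ap_width, "endplate_ap_width", lower = 0, strict_lower = TRUE)
  check_number(endplate_ml_width, "endplate_ml_width", lower = 0, strict_lower = TRUE)
  check_number(n_points, "n_points", lower = 50)
  check_number(noise_sd, "noise_sd", lower = 0)

  asym <- list(endplate_ml = 0, left_head = c(0, 0, 0), right_head = c(0, 0, 0))
  if (length(asymmetry)) {
    unknown <- setdiff(names(asymmetry), names(asym))
    if (length(unknown)) {
      rlang::abort(sprintf("Unknown asymmetry field(s): %s.",
                           paste(unknown, collapse = ", ")),
                   class = "pelvir_parameter_error")
    }
    if (!is.null(asymmetry$endplate_ml)) {
      check_number(asymmetry$endplate_ml, "asymmetry$endplate_ml")
      asym$endplate_ml <- asymmetry$endplate_ml
    }
    if (!is.null(asymmetry$left_head)) {
      asym$left_head <- as_point3(asymmetry$left_head, "asymmetry$left_head")
    }
    if (!is.null(asymmetry$right_head)) {
      asym$right_head <- as_point3(asymmetry$right_head, "asymmetry$right_head")
    }
  }

  structure(
    list(
      pi_anat = pi_anat, ss_frame = ss_frame, pt_frame = pt_frame,
      head_radius = head_radius, head_separation = head_separation,
      sacrum_distance = sacrum_distance,
      endplate_ap_width = endplate_ap_width,
      endplate_ml_width = endplate_ml_width,
      n_points = as.integer(n_points), noise_sd = noise_sd,
      asymmetry = asym
    ),
    class = "pelvis_params"
  )
}

#' @export
print.pelvis_params <- function(x, ...) {
  cat("<pelvis_params>\n")
  cat(sprintf("  anatomical PI: %.2f deg  (ss_frame %.2f + pt_frame %.2f)\n",
              x$pi_anat, x$ss_frame, x$pt_frame))
  cat(sprintf("  head radius %.1f mm, separation %.1f mm, sacrum distance %.1f mm\n",
              x$head_radius, x$head_separation, x$sacrum_distance))
  cat(sprintf("  endplate %.0f x %.0f mm (AP x ML), %d points/structure, noise sd %.2f mm\n",
              x$endplate_ap_width, x$endplate_ml_width, x$n_points, x$noise_sd))
  invisible(x)
}

#' Ground-truth anatomical pelvic incidence
#'
#' Returns the anatomical PI encoded in a parameter set: the angle between the
#' perpendicular to the sacral endplate at its midpoint and the line from that
#' midpoint to the bicoxofemoral axis midpoint. By construction this equals
#' `ss_frame + pt_frame` and is the ground truth against which projected
#' measurements are compared.
#'
#' @param params A [pelvis_params()] object (or a `pelvis_model`, whose
#'   params are used).
#' @return Anatomical PI in degrees.
#' @examples
#' true_pi(pelvis_params(ss_frame = 40, pt_frame = 8.8))
#' @export
true_pi <- function(params) {
  if (inherits(params, "pelvis_model")) params <- params$params
  if (!inherits(params, "pelvis_params")) {
    rlang::abort("`params` must be a pelvis_params or pelvis_model object.",
                 class = "pelvir_parameter_error")
  }
  params$ss_frame + params$pt_frame
}
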