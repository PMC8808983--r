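# Synthetic pelvis generation: stand-in for CT-segmented femoral heads and
# S1 endplate. Canonical frame: origin at the hip-axis midpoint, x anterior,
# y left, z superior, units mm, angles degrees.

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Points on the closed upper hemisphere of a head. A fixed 20% of the points
# sit exactly on the equatorial rim at deterministic uniform azimuths,
# emulating the planar segmentation cut of the half-head; the rest are drawn
# uniformly on the open cap. Returned relative to the centre.
sample_hemisphere <- function(n, radius) {
  n_rim <- max(3L, ceiling(0.2 * n))
  n_cap <- n - n_rim
  phi_rim <- 2 * pi * (seq_len(n_rim) - 1L) / n_rim
  rim <- cbind(radius * cos(phi_rim), radius * sin(phi_rim), 0)
  w <- stats::runif(n_cap)          # cos(polar) uniform on (0,1]: uniform cap
  phi <- stats::runif(n_cap, 0, 2 * pi)
  rho <- radius * sqrt(1 - w^2)
  cap <- cbind(rho * cos(phi), rho * sin(phi), radius * w)
  rbind(rim, cap)
}

#' Generate one synthetic pelvis
#'
#' Builds labeled 3D point clouds for the left and right femoral heads
#' (closed upper hemispheres, including the equatorial rim left by the
#' segmentation cut) and the S1 endplate (a planar elliptical patch), posed in
#' the canonical frame with a known anatomical pelvic incidence. The right
#' head is the exact mirror image of the left across the sagittal (x-z)
#' plane before asymmetry offsets and noise are applied, so noiseless
#' zero-asymmetry models are perfectly symmetric.
#'
#' Geometry, in the canonical frame (origin at the hip-axis midpoint,
#' x anterior, y left, z superior):
#' head centres at `(0, +/- head_separation/2, 0)`; endplate centre at
#' `sacrum_distance * (-sin(pt_frame), 0, cos(pt_frame))` (posterior and
#' superior to the hip axis); endplate plane spanned by the mediolateral axis
#' and the anteroposterior direction `(cos(ss_frame), 0, -sin(ss_frame))`.
#'
#' @param params A [pelvis_params()] object.
#' @param seed Integer seed; the model is bitwise-reproducible for a fixed
#'   `(params, seed)` pair. The caller's RNG state is preserved.
#' @return A `pelvis_model`: a list with `points` (tibble with columns
#'   `x, y, z, label`; label in `left_head`, `right_head`, `endplate`),
#'   `params` and `seed`.
#' @examples
#' m <- generate_pelvis(pelvis_params(ss_frame = 40, pt_frame = 8.8,
#'                                    noise_sd = 0), seed = 1)
#' dplyr::count(m$points, label)
#' @export
generate_pelvis <- function(params, seed = 1L) {
  if (!inherits(params, "pelvis_params")) {
    rlang::abort("`params` must be created by pelvis_params().",
                 class = "pelvir_parameter_error")
  }
  check_number(seed, "seed")
  seed <- as.integer(seed)
  n <- params$n_points
  r <- params$head_radius
  half_sep <- params$head_separation / 2
  ss <- deg2rad(params$ss_frame)
  pt <- deg2rad(params$pt_frame)

  pts <- with_preserved_rng(seed, {
    hemi <- sample_hemisphere(n, r)
    left <- sweep(hemi, 2, c(0, half_sep, 0) + params$asymmetry$left_head, "+")
    right <- sweep(hemi %*% diag(c(1, -1, 1)), 2,
                   c(0, -half_sep, 0) + params$asymmetry$right_head, "+")

    centre_ep <- params$sacrum_distance * c(-sin(pt), 0, cos(pt)) +
      c(0, params$asymmetry$endplate_ml, 0)
    ap_dir <- c(cos(ss), 0, -sin(ss))
    ml_dir <- c(0, 1, 0)
    # Reflection-symmetric patch sampling: each first-quadrant draw is
    # emitted at (+/-u, +/-v) and again mirrored across the quadrant
    # diagonal. The centroid then sits exactly at the endplate centre, the
    # in-plane covariance is exactly diagonal in the (AP, ML) axes, and the
    # AP/ML sample-variance ratio is exactly (ap_width/ml_width)^2 > 1 --
    # so the noiseless pipeline recovers the generating geometry to machine
    # precision and the fitted AP axis can never flip to the mediolateral
    # direction at small point counts. Leftover points go to the centre.
    q <- n %/% 8L
    rho <- sqrt(stats::runif(q))
    phi <- stats::runif(q, 0, pi / 2)
    uq <- c(rho * cos(phi), rho * sin(phi))
    vq <- c(rho * sin(phi), rho * cos(phi))
    signs <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
    u <- (params$endplate_ap_width / 2) *
      c(as.vector(outer(signs[, 1], uq)), rep(0, n - 8L * q))
    v <- (params$endplate_ml_width / 2) *
      c(as.vector(outer(signs[, 2], vq)), rep(0, n - 8L * q))
    endplate <- sweep(outer(u, ap_dir) + outer(v, ml_dir), 2, centre_ep, "+")

    all_pts <- rbind(left, right, endplate)
    if (params$noise_sd > 0) {
      all_pts <- all_pts + stats::rnorm(length(all_pts), sd = params$noise_sd)
    }
    all_pts
  })

  structure(
    list(
      points = tibble::tibble(
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        label = rep(c("left_head", "right_head", "endplate"), each = n)
      ),
      params = params,
      seed = seed
    ),
    class = "pelvis_model"
  )
}

#' @export
print.pelvis_model <- function(x, ...) {
  cat("<pelvis_model>\n")
  cat(sprintf("  %d points (%d per structure), seed %d\n",
              nrow(x$points), x$params$n_points, x$seed))
  cat(sprintf("  anatomical PI %.2f deg (ss_frame %.2f / pt_frame %.2f), noise sd %.2f mm\n",
              x$params$pi_anat, x$params$ss_frame, x$params$pt_frame,
              x$params$noise_sd))
  invisible(x)
}

#' Generate a cohort of synthetic pelves
#'
#' Draws `n` pelves whose anatomical PI follows a Normal distribution
#' truncated to \[30, 85\] degrees and whose scan-frame tilt `pt_frame` is
#' uniform on `pt_frame_range`; `ss_frame = pi_anat - pt_frame`, so with the
#' default range \[0, 15\] the frame sacral slope always exceeds the frame
#' tilt. Per-member generator seeds are derived deterministically from
#' `seed`.
#'
#' @param n Number of pelves (default 30, the cohort size the measurement
#'   protocol was developed on).
#' @param pi_mean,pi_sd Mean and SD of the anatomical PI distribution,
#'   degrees. Defaults 48.8 and 10.
#' @param pt_frame_range Length-2 numeric range for `pt_frame`, degrees,
#'   within \[0, 20\]. Default `c(0, 15)`.
#' @param base A [pelvis_params()] object supplying all non-angular
#'   parameters (geometry, point count, noise, asymmetry).
#' @param seed Integer seed for the cohort draw and all member seeds.
#' @return A list of `pelvis_model` objects with class `pelvis_cohort`.
#' @examples
#' coh <- generate_cohort(n = 3, pi_sd = 0, seed = 7,
#'                        base = pelvis_params(ss_frame = 40, noise_sd = 0))
#' vapply(coh, function(m) true_pi(m$params), numeric(1))
#' @export
generate_cohort <- function(n = 30L,
                            pi_mean = 48.8,
                            pi_sd = 10,
                            pt_frame_range = c(0, 15),
                            base = pelvis_params(ss_frame = 40, pt_frame = 8.8),
                            seed = 1L) {
  check_number(n, "n", lower = 1)
  check_number(pi_sd, "pi_sd", lower = 0)
  if (length(pt_frame_range) != 2L || any(!is.finite(pt_frame_range)) ||
      pt_frame_range[1] > pt_frame_range[2] ||
      pt_frame_range[1] < 0 || pt_frame_range[2] > 20) {
    rlang::abort("`pt_frame_range` must be an increasing range within [0, 20] degrees.",
                 class = "pelvir_parameter_error")
  }
  if (!inherits(base, "pelvis_params")) {
    rlang::abort("`base` must be created by pelvis_params().",
                 class = "pelvir_parameter_error")
  }
  n <- as.integer(n)

  draws <- with_preserved_rng(as.integer(seed), {
    pi_anat <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        val <- stats::rnorm(1, pi_mean, pi_sd)
        if (val >= 30 && val <= 85) break
      }
      pi_anat[i] <- val
    }
    list(
      pi_anat = pi_anat,
      pt_frame = stats::runif(n, pt_frame_range[1], pt_frame_range[2]),
      member_seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })

  members <- purrr::pmap(draws, function(pi_anat, pt_frame, member_seeds) {
    p <- base
    p$pi_anat <- pi_anat
    p$pt_frame <- pt_frame
    p$ss_frame <- pi_anat - pt_frame
    generate_pelvis(p, seed = member_seeds)
  })
  structure(members, class = "pelvis_cohort")
}

#' @export
print.pelvis_cohort <- function(x, ...) {
  pis <- vapply(x, function(m) m$params$pi_anat, numeric(1))
  cat(sprintf("<pelvis_cohort> %d members, anatomical PI %.1f-%.1f deg (mean %.1f)\n",
              length(x), min(pis), max(pis), mean(pis)))
  invisible(x)
}
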