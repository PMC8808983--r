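# Internal geometry helpers. All public angles are degrees; radians stay internal.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# acos guarded against |x| > 1 from roundoff
acos_safe <- function(x) acos(pmin(1, pmax(-1, x)))

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) {
    rlang::abort(
      sprintf("Cannot normalize a zero-length %s.", what),
      class = "pelvir_degenerate_geometry"
    )
  }
  v / n
}

# proper rotation matrix about a canonical axis ("x" or "z"), angle in degrees
rotation_matrix_axis <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),
    rlang::abort(sprintf("Unknown axis '%s'.", axis), class = "pelvir_parameter_error")
  )
}

# unsigned angle between two 2D or 3D vectors, in degrees
angle_between <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) {
    rlang::abort("Angle undefined for zero-length vector.",
                 class = "pelvir_degenerate_geometry")
  }
  rad2deg(acos_safe(sum(u * v) / (nu * nv)))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name),
                 class = "pelvir_parameter_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    rlang::abort(
      sprintf("`%s` = %g violates the bound %s%g, %g%s.",
              name, x,
              if (strict_lower) "(" else "[", lower, upper,
              if (strict_upper) ")" else "]"),
      class = "pelvir_parameter_error"
    )
  }
  invisible(x)
}

as_point3 <- function(x, name = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    rlang::abort(sprintf("`%s` must be a finite 3D point.", name),
                 class = "pelvir_parameter_error")
  }
  x
}
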