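# File round-tripping: point clouds as ASCII PLY or CSV with a structure
# label, YAML metadata sidecars carrying generator params and seed, landmark
# and sweep CSVs, and the plain-text report.

STRUCTURE_LABELS <- c("left_head", "right_head", "endplate")

meta_path_for <- function(path) paste0(path, ".meta.yaml")

#' Write a pelvis model to disk
#'
#' Writes the labeled point cloud as CSV (columns `x,y,z,label`) or ASCII
#' PLY (one vertex element per structure), plus a YAML metadata sidecar
#' (`<path>.meta.yaml`) recording the generator parameters and seed so a run
#' is reproducible from its outputs.
#'
#' @param model A `pelvis_model`.
#' @param path Output file; extension `.csv` or `.ply` selects the format.
#' @param sidecar Write the metadata sidecar? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_pelvis <- function(model, path, sidecar = TRUE) {
  if (!inherits(model, "pelvis_model")) {
    rlang::abort("`model` must be a pelvis_model.", class = "pelvir_input_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(model$points, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "ply") {
    write_pelvis_ply(model$points, path)
  } else {
    rlang::abort(sprintf("Unsupported point-cloud format '.%s' (use .csv or .ply).", ext),
                 class = "pelvir_io_error")
  }
  if (sidecar && !is.null(model$params)) {
    meta <- unclass(model$params)
    meta$seed <- model$seed
    yaml::write_yaml(meta, meta_path_for(path))
  }
  invisible(path)
}

write_pelvis_ply <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c("ply", "format ascii 1.0",
              "comment synthetic pelvis landmark point cloud")
  chunks <- list()
  for (lab in STRUCTURE_LABELS) {
    pts <- points[points$label == lab, c("x", "y", "z"), drop = FALSE]
    header <- c(header,
                sprintf("element %s %d", lab, nrow(pts)),
                "property double x", "property double y", "property double z")
    chunks[[lab]] <- pts
  }
  writeLines(c(header, "end_header"), con)
  for (pts in chunks) {
    writeLines(sprintf("%.17g %.17g %.17g", pts$x, pts$y, pts$z), con)
  }
  invisible(path)
}

read_pelvis_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply") {
    rlang::abort(sprintf("%s: not a PLY file.", path), class = "pelvir_io_error")
  }
  end_hdr <- match("end_header", lines)
  if (is.na(end_hdr)) {
    rlang::abort(sprintf("%s: PLY header not terminated.", path),
                 class = "pelvir_io_error")
  }
  hdr <- lines[seq_len(end_hdr)]
  elems <- hdr[startsWith(hdr, "element ")]
  parsed <- strsplit(elems, "\\s+")
  labels <- vapply(parsed, `[`, character(1), 2)
  counts <- as.integer(vapply(parsed, `[`, character(1), 3))
  body <- lines[(end_hdr + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) != sum(counts)) {
    rlang::abort(sprintf("%s: expected %d data rows, found %d (line %d).",
                         path, sum(counts), length(body), end_hdr + length(body) + 1L),
                 class = "pelvir_parse_error")
  }
  vals <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(vals) != 3L)
  if (length(bad)) {
    rlang::abort(sprintf("%s: malformed point on line %d.",
                         path, end_hdr + bad[1]),
                 class = "pelvir_parse_error")
  }
  m <- matrix(as.numeric(unlist(vals)), ncol = 3, byrow = TRUE)
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                 label = rep(labels, counts))
}

#' Read a pelvis model from disk
#'
#' Reads a labeled point cloud written by [write_pelvis()] (CSV or ASCII
#' PLY). If the YAML metadata sidecar is present the generator parameters
#' and seed are restored; otherwise they are `NULL`/`NA` (landmark fitting
#' and sweeps do not need them).
#'
#' @param path Point-cloud file.
#' @return A `pelvis_model`.
#' @export
read_pelvis <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("No such file: %s", path), class = "pelvir_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  points <- if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("x", "y", "z", "label")
    if (!all(need %in% names(df))) {
      rlang::abort(sprintf("%s: CSV must have columns x,y,z,label.", path),
                   class = "pelvir_parse_error")
    }
    if (any(!is.finite(as.matrix(df[c("x", "y", "z")])))) {
      bad <- which(!stats::complete.cases(df[c("x", "y", "z")]))[1]
      rlang::abort(sprintf("%s: non-numeric coordinate on data line %d.", path, bad),
                   class = "pelvir_parse_error")
    }
    tibble::as_tibble(df[need])
  } else if (ext == "ply") {
    read_pelvis_ply(path)
  } else {
    rlang::abort(sprintf("Unsupported point-cloud format '.%s'.", ext),
                 class = "pelvir_io_error")
  }
  params <- NULL
  seed <- NA_integer_
  mp <- meta_path_for(path)
  if (file.exists(mp)) {
    meta <- yaml::read_yaml(mp)
    seed <- meta$seed
    meta$seed <- NULL
    params <- try_restore_params(meta)
  }
  structure(list(points = points, params = params, seed = seed),
            class = "pelvis_model")
}

try_restore_params <- function(meta) {
  tryCatch(
    pelvis_params(
      pi_anat = meta$pi_anat, ss_frame = meta$ss_frame,
      pt_frame = meta$pt_frame, head_radius = meta$head_radius,
      head_separation = meta$head_separation,
      sacrum_distance = meta$sacrum_distance,
      endplate_ap_width = meta$endplate_ap_width,
      endplate_ml_width = meta$endplate_ml_width,
      n_points = meta$n_points, noise_sd = meta$noise_sd,
      asymmetry = lapply(meta$asymmetry, unlist)
    ),
    error = function(e) NULL
  )
}

#' Write a landmark set as a flat CSV
#'
#' One row per named point or direction, columns `name,x,y,z`.
#'
#' @param lm A `landmark_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  if (!inherits(lm, "landmark_set")) {
    rlang::abort("`lm` must be a landmark_set.", class = "pelvir_input_error")
  }
  rows <- rbind(
    left_center = lm$left_center,
    right_center = lm$right_center,
    hip_axis_midpoint = lm$hip_axis_midpoint,
    endplate_center = lm$endplate$center,
    endplate_ap_direction = lm$endplate$ap_direction,
    endplate_plane_normal = lm$endplate$plane_normal,
    sacro_femoral_midpoint = lm$sacro_femoral_midpoint
  )
  df <- data.frame(name = rownames(rows), x = rows[, 1], y = rows[, 2],
                   z = rows[, 3], row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subjects-by-raters measurement matrix
#'
#' CSV with a header row naming the raters; rows are subjects. All cells
#' must be numeric and present.
#'
#' @param path CSV path.
#' @return A numeric matrix.
#' @export
read_icc_matrix <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("No such file: %s", path), class = "pelvir_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    rlang::abort(sprintf("%s: measurement matrix has missing or non-numeric cells.",
                         path),
                 class = "pelvir_statistics_error")
  }
  mat
}

#' Format a sweep as a plain-text report table
#'
#' Mirrors the published table layout: an angle row, a PI row rounded to one
#' decimal, and a percentage-change row rounded to two decimals, followed by
#' the acceptability threshold for the given tolerance.
#'
#' @param x A `pi_sweep` or `cohort_summary`.
#' @param tol Acceptability tolerance in degrees, default 6.
#' @return A character vector of report lines.
#' @export
format_sweep_report <- function(x, tol = 6) {
  is_cohort <- inherits(x, "cohort_summary")
  pi_col <- if (is_cohort) x$mean_pi else x$pi
  pct_col <- if (is_cohort) x$mean_pct_change else x$pct_change
  axis <- x$axis_kind[1]
  n_line <- if (is_cohort) sprintf(" (n = %d, mean values)", x$n[1]) else ""
  w <- 9L
  fmt_row <- function(label, cells) {
    paste0(formatC(label, width = 22, flag = "-"),
           paste(formatC(cells, width = w), collapse = ""))
  }
  pct_cells <- ifelse(
    x$angle == 0, "-",
    sprintf("%+.2f", round(pct_col, 2))
  )
  c(
    sprintf("Effect of %s pelvic rotation on PI%s", axis, n_line),
    fmt_row("Rotation (deg)", sprintf("%g", x$angle)),
    fmt_row("Pelvic incidence", sprintf("%.1f", round(pi_col, 1))),
    fmt_row("Change (%)", pct_cells),
    sprintf("Acceptable (|error| <= %g deg) up to: %g deg %s rotation",
            tol, acceptable_threshold(x, tol), axis)
  )
}
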