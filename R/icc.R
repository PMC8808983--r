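# Interobserver reliability: single-measure, consistency-form intraclass
# correlation from the two-way mixed-effects model, ICC(3,1).

#' Intraclass correlation coefficient, ICC(3,1)
#'
#' Computes the single-measure, two-way mixed-effects, consistency-form
#' intraclass correlation from a complete subjects-by-raters measurement
#' matrix, via the two-way ANOVA decomposition:
#' \deqn{ICC(3,1) = \frac{BMS - EMS}{BMS + (k - 1)\,EMS}}
#' where BMS is the between-subjects mean square, EMS the residual mean
#' square, and k the number of raters.
#'
#' @param mat A numeric matrix or data frame, rows = subjects, columns =
#'   raters; at least 2 of each, no missing cells.
#' @param form Only `"3,1"` is implemented.
#' @return An `icc_result`: list with `icc`, `n_subjects`, `n_raters`,
#'   `form = "ICC(3,1)"`, the mean squares `bms`, `jms`, `ems`, and `label`
#'   (reliability classification, see [classify_icc()]).
#' @examples
#' ratings <- cbind(r1 = c(40, 50, 60, 45), r2 = c(41, 49, 61, 46))
#' icc(ratings)
#' @export
icc <- function(mat, form = "3,1") {
  if (!identical(form, "3,1")) {
    rlang::abort("Only ICC form \"3,1\" is implemented.",
                 class = "pelvir_parameter_error")
  }
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) {
    rlang::abort("ICC needs at least 2 subjects and 2 raters.",
                 class = "pelvir_statistics_error")
  }
  if (any(!is.finite(mat))) {
    rlang::abort("Measurement matrix has missing or non-finite cells.",
                 class = "pelvir_statistics_error")
  }
  grand <- mean(mat)
  if (all(abs(mat - grand) < 1e-12)) {
    rlang::abort("All measurements are identical: ICC is undefined (zero variance).",
                 class = "pelvir_statistics_error")
  }
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  jms <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- mat - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  val <- (bms - ems) / (bms + (k - 1) * ems)
  structure(
    list(icc = val, n_subjects = n, n_raters = k, form = "ICC(3,1)",
         bms = bms, jms = jms, ems = ems, label = classify_icc(val)),
    class = "icc_result"
  )
}

#' Classify a reliability coefficient
#'
#' Reliability bins on the 0-1 scale: at least 0.75 is "excellent", 0.40 up
#' to (but excluding) 0.75 is "fair to good", below 0.40 is "poor". The
#' boundary values 0.40 and 0.75 belong to the upper bin.
#'
#' @param x ICC value(s).
#' @return Character vector of labels.
#' @examples
#' classify_icc(c(0.39, 0.40, 0.75, 0.97))
#' @export
classify_icc <- function(x) {
  dplyr::case_when(
    x >= 0.75 ~ "excellent",
    x >= 0.40 ~ "fair to good",
    .default = "poor"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.3f (%s); %d subjects x %d raters\n",
              x$form, x$icc, x$label, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Simulate repeated PI ratings of a cohort
#'
#' Emulates a reliability study: each rater independently re-measures the
#' projected PI of every cohort member, with rater error modeled as
#' independent Gaussian noise (sd `rater_sd`) on top of the pipeline
#' measurement. Returns the subjects-by-raters matrix that [icc()] consumes.
#'
#' @param cohort A `pelvis_cohort` or list of `pelvis_model`s.
#' @param n_raters Number of raters; default 2, as in a two-observer study.
#' @param rater_sd Rater measurement error sd, degrees; default 0.5.
#' @param rot Rotation at which the measurements are taken; default the
#'   unrotated sagittal view.
#' @param seed Integer seed for the rater noise.
#' @return Numeric matrix, rows = subjects, columns = raters.
#' @export
simulate_ratings <- function(cohort, n_raters = 2L, rater_sd = 0.5,
                             rot = rotation_spec("vertical", 0), seed = 1L) {
  check_number(n_raters, "n_raters", lower = 2)
  check_number(rater_sd, "rater_sd", lower = 0)
  truth <- vapply(cohort, measure_pi, numeric(1), rot = rot)
  with_preserved_rng(as.integer(seed), {
    noise <- matrix(stats::rnorm(length(truth) * n_raters, sd = rater_sd),
                    nrow = length(truth))
    out <- truth + noise
    colnames(out) <- paste0("rater", seq_len(n_raters))
    out
  })
}
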