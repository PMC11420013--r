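# Collective alignment statistics on axial orientations: the per-image
# median-centred deviations, their coefficient of variation, and the radial
# (rose-plot) histogram in which each cell contributes a diameter.

#' Coefficient of variation of median-centred orientation deviations
#'
#' The deviations, which live in `(-90, 90]` with axial median 0, are
#' shifted by +90 degrees onto `(0, 180]`; the CV is the sample standard
#' deviation (n-1 denominator) of the shifted values divided by their mean.
#' For median-centred deviations the mean is close to 90, so the CV is
#' approximately SD/90: orientations uniform on the axial range give
#' `1/sqrt(3) ~ 0.577`, perfectly aligned cells give 0, and the statistic
#' shrinks monotonically as alignment strengthens.
#'
#' @param deviations numeric vector of signed deviations in degrees (each in
#'   `(-90, 90]`), at least 2 values.
#' @return the coefficient of variation (dimensionless, >= 0).
#' @export
#' @examples
#' alignment_cv(c(-45, 45))                 # ~0.707
#' alignment_cv(rep(0, 10))                 # 0
alignment_cv <- function(deviations) {
  if (length(deviations) < 2L) {
    stop("alignment_cv() needs at least 2 deviations")
  }
  stopifnot(all(is.finite(deviations)),
            all(deviations > -90 - 1e-9), all(deviations <= 90 + 1e-9))
  shifted <- deviations + 90
  sd(shifted) / mean(shifted)
}

#' Radial histogram of orientation deviations (rose-plot bins)
#'
#' Each deviation contributes two counts, one at `d mod 360` and one at
#' `(d + 180) mod 360`, so every cell is drawn as a diameter and the
#' histogram is point-symmetric. Bins partition `[0, 360)` starting at 0.
#'
#' @param deviations numeric vector of deviations in degrees.
#' @param n_bins number of bins; must divide 360. Default 36 (10-degree bins).
#' @return data frame with `bin_start_deg` and `count`; counts sum to
#'   `2 * length(deviations)`.
#' @export
#' @examples
#' radial_histogram(c(0, -30))
radial_histogram <- function(deviations, n_bins = 36) {
  if (n_bins <= 0 || 360 %% n_bins != 0) {
    stop("n_bins must be a positive divisor of 360")
  }
  width <- 360 / n_bins
  ang <- c(deviations %% 360, (deviations + 180) %% 360)
  idx <- floor(ang / width) %% n_bins  # guard the 360-boundary
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(bin_start_deg = (seq_len(n_bins) - 1L) * width, count = counts)
}

#' Alignment summary for one set of orientations
#'
#' Bundles the axial median, signed deviations, coefficient of variation and
#' radial histogram for the orientations of one image (or of cells pooled
#' across the images of a condition, in which case deviations should already
#' be median-centred per image and passed via `deviations`).
#'
#' @param orientations numeric vector of cell orientations in degrees; used
#'   to compute the median and deviations when `deviations` is NULL.
#' @param deviations optional pre-computed deviations (e.g. pooled across
#'   images); when given, `orientations` may be NULL and the median is NA.
#' @param scope label describing what the summary covers.
#' @param n_bins radial bins, as in [radial_histogram()].
#' @return list of class `alignment_summary`: `scope`, `n_cells`,
#'   `median_orientation_deg`, `deviations_deg`, `cv`, `radial_bins`.
#' @export
alignment_summary <- function(orientations = NULL, deviations = NULL,
                              scope = "image", n_bins = 36) {
  if (is.null(deviations)) {
    if (is.null(orientations) || length(orientations) == 0L) {
      stop("alignment_summary() needs orientations or deviations")
    }
    med <- axial_median(orientations)
    deviations <- axial_difference(orientations, med)
  } else {
    med <- if (is.null(orientations)) NA_real_ else axial_median(orientations)
  }
  out <- list(
    scope = scope, n_cells = length(deviations),
    median_orientation_deg = med, deviations_deg = deviations,
    cv = if (length(deviations) >= 2) alignment_cv(deviations) else NA_real_,
    radial_bins = radial_histogram(deviations, n_bins))
  class(out) <- "alignment_summary"
  out
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf(
    "alignment_summary '%s': %d cells, median orientation %.2f deg, CV %.3f\n",
    x$scope, x$n_cells, x$median_orientation_deg, x$cv))
  invisible(x)
}
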