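# Axial (180-degree periodic) angle arithmetic. Major-axis orientations are
# undirected, so all angle work happens modulo 180 with the representative
# range (-90, 90]; -90 itself maps to +90.

#' Wrap an angle onto the axial range (-90, 90]
#'
#' Major-axis orientations are axial: theta and theta + 180 describe the same
#' axis. This maps any finite angle to its representative in `(-90, 90]`.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each value in `(-90, 90]`.
#' @export
#' @examples
#' wrap_axial(c(90, -90, 170, 359))
wrap_axial <- function(x) {
  stopifnot(is.numeric(x))
  w <- ((x + 90) %% 180) - 90
  w[w <= -90] <- w[w <= -90] + 180  # -90 is identified with +90
  w
}

#' Signed axial difference between two orientations
#'
#' Returns `a - b` wrapped the short way around the axial (period-180) circle,
#' so the result always lies in `(-90, 90]`.
#'
#' @param a,b angles in degrees (recycled to common length).
#' @return signed difference in degrees, in `(-90, 90]`.
#' @export
#' @examples
#' axial_difference(30, 10)   # 20
#' axial_difference(85, -85)  # -10: the short way around
axial_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), all(is.finite(a)), all(is.finite(b)))
  wrap_axial(a - b)
}

#' Axial median orientation
#'
#' The data value minimising the summed absolute axial distance to all
#' observations (the circular analogue of the sample median, restricted to
#' observed values). Ties are broken by the smallest representative angle in
#' `(-90, 90]`.
#'
#' @param orientations numeric vector of orientations in degrees, non-empty.
#' @return a single angle in degrees, in `(-90, 90]`.
#' @export
#' @examples
#' axial_median(c(10, 20, 30))   # 20
#' axial_median(c(-80, 80, 90))  # 90
axial_median <- function(orientations) {
  if (length(orientations) == 0L) {
    stop("axial_median() requires at least one orientation")
  }
  stopifnot(is.numeric(orientations), all(is.finite(orientations)))
  cand <- wrap_axial(orientations)
  # cost of each observed value as the centre; O(n^2) but n is per-image
  cost <- vapply(cand, function(m) sum(abs(axial_difference(cand, m))), 0)
  best <- which(cost <= min(cost) + 1e-9)
  min(cand[best])
}

#' Per-cell deviations from the axial median orientation
#'
#' Each orientation minus the axial median of the set, wrapped into
#' `(-90, 90]`, so the median orientation itself maps to 0.
#'
#' @param orientations numeric vector of orientations in degrees, non-empty.
#' @return numeric vector of signed deviations in degrees.
#' @export
#' @examples
#' deviations_from_median(c(10, 20, 30))  # -10 0 10
deviations_from_median <- function(orientations) {
  m <- axial_median(orientations)
  axial_difference(orientations, m)
}

#' Axial mean orientation
#'
#' Mean direction of the doubled angles, halved back to the axial range.
#' Used to check recovery of an imposed flow direction.
#'
#' @param orientations numeric vector of orientations in degrees, non-empty.
#' @return a single angle in degrees, in `(-90, 90]`.
#' @export
axial_mean <- function(orientations) {
  stopifnot(length(orientations) > 0, all(is.finite(orientations)))
  d <- orientations * pi / 90  # doubled angle in radians
  wrap_axial(atan2(mean(sin(d)), mean(cos(d))) * 90 / pi)
}
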