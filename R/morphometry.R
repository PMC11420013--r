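# Per-cell morphometry from pixel moments. Conventions:
#  * moments use pixel centres with no per-pixel variance correction, so a
#    solid w x h rectangle has variances (w^2-1)/12 and (h^2-1)/12 exactly;
#  * the image row axis points down, so the vertical coordinate is y = -row:
#    positive orientation is then counter-clockwise from the horizontal,
#    i.e. "the angle of the major axis from the x-axis".

#' Orientation of the major axis from central second moments
#'
#' Computes `0.5 * atan2(2 * mu11, mu20 - mu02)` in degrees, mapped to the
#' axial range `(-90, 90]`. `mu11` must follow the y-up sign convention. The
#' fully isotropic case (`mu11 == 0`, `mu20 == mu02`) returns 0 by convention.
#'
#' @param mu20,mu11,mu02 normalised central second moments (pixel^2).
#' @return orientation in degrees, in `(-90, 90]`.
#' @export
#' @examples
#' orientation_from_moments(2, 0, 2/3)  # 0: wider than tall
#' orientation_from_moments(2/3, 0, 2)  # 90: taller than wide
#' orientation_from_moments(1, 0.5, 1)  # 45
orientation_from_moments <- function(mu20, mu11, mu02) {
  stopifnot(all(mu20 >= 0), all(mu02 >= 0),
            all(mu20 * mu02 - mu11^2 >= -1e-9))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta[mu11 == 0 & mu20 == mu02] <- 0
  wrap_axial(theta)
}

#' Equivalent-ellipse axis lengths from covariance eigenvalues
#'
#' The ellipse with the same normalised second central moments as the region
#' has full axis lengths `4 * sqrt(lambda)`.
#'
#' @param lambda1,lambda2 eigenvalues of the pixel covariance matrix,
#'   `lambda1 >= lambda2 >= 0`.
#' @return list with `major_len` and `minor_len` (pixels).
#' @export
#' @examples
#' equivalent_ellipse_axes(2, 2/3)  # 4*sqrt(2), 4*sqrt(2/3)
equivalent_ellipse_axes <- function(lambda1, lambda2) {
  if (any(lambda2 < 0) || any(lambda1 < lambda2)) {
    stop("require lambda1 >= lambda2 >= 0")
  }
  list(major_len = 4 * sqrt(lambda1), minor_len = 4 * sqrt(lambda2))
}

#' Measure every cell in a label mask
#'
#' Computes, per distinct positive label: pixel area, centroid, normalised
#' central second moments, major-axis orientation, equivalent-ellipse axis
#' lengths, elongation factor (major/minor, the covariance-eigenvalue ratio
#' `sqrt(lambda1/lambda2)`), and whether the cell touches the image border.
#'
#' Degenerate cases follow documented conventions: a single-pixel cell has
#' elongation factor 1 and orientation 0; a perfectly collinear cell
#' (`lambda2 = 0`, `lambda1 > 0`) gets an `Inf` elongation factor and is
#' expected to be removed by the aspect-ratio QC filter. A label whose pixels
#' are not connected is still measured as one region, with a warning.
#'
#' @param mask a [label_mask()] or integer matrix.
#' @param warn_disconnected warn when a label is not 8-connected (default
#'   TRUE; the check adds a connected-components pass).
#' @return data frame with one row per label: `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, `mu20`, `mu11`, `mu02`,
#'   `orientation_deg`, `major_len`, `minor_len`, `elongation_factor`,
#'   `touches_border`. Empty (zero-row) for a mask without positive labels.
#' @export
measure_cells <- function(mask, warn_disconnected = TRUE) {
  px <- if (inherits(mask, "label_mask")) mask$pixels else mask
  stopifnot(is.matrix(px))
  sel <- which(px > 0L)
  empty <- data.frame(
    label = integer(0), area_px = numeric(0), centroid_row = numeric(0),
    centroid_col = numeric(0), mu20 = numeric(0), mu11 = numeric(0),
    mu02 = numeric(0), orientation_deg = numeric(0), major_len = numeric(0),
    minor_len = numeric(0), elongation_factor = numeric(0),
    touches_border = logical(0))
  if (length(sel) == 0L) return(empty)

  lab <- px[sel]
  r <- ((sel - 1L) %% nrow(px)) + 1L
  cc <- ((sel - 1L) %/% nrow(px)) + 1L
  g <- factor(lab)
  n <- as.vector(rowsum(rep(1, length(sel)), g))
  sr <- as.vector(rowsum(as.numeric(r), g))
  sc <- as.vector(rowsum(as.numeric(cc), g))
  srr <- as.vector(rowsum(as.numeric(r) * r, g))
  scc <- as.vector(rowsum(as.numeric(cc) * cc, g))
  src <- as.vector(rowsum(as.numeric(r) * cc, g))
  mr <- sr / n
  mc <- sc / n
  # x = col, y = -row: mu11 flips sign relative to the row/col covariance
  mu20 <- pmax(scc / n - mc^2, 0)
  mu02 <- pmax(srr / n - mr^2, 0)
  mu11 <- -(src / n - mr * mc)

  half_tr <- (mu20 + mu02) / 2
  half_d <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  lambda1 <- half_tr + half_d
  lambda2 <- pmax(half_tr - half_d, 0)

  axes <- equivalent_ellipse_axes(lambda1, lambda2)
  ef <- ifelse(lambda1 == 0, 1, ifelse(lambda2 == 0, Inf,
                                       sqrt(lambda1 / lambda2)))
  border <- as.vector(rowsum(
    as.numeric(r == 1L | r == nrow(px) | cc == 1L | cc == ncol(px)), g)) > 0

  if (warn_disconnected) {
    labs <- as.integer(levels(g))
    for (i in seq_along(labs)) {
      if (n[i] > 1L && !label_is_connected(px, labs[i])) {
        warning("label ", labs[i], " is not a single 8-connected component; ",
                "measured as one region")
      }
    }
  }

  data.frame(
    label = as.integer(levels(g)), area_px = n, centroid_row = mr,
    centroid_col = mc, mu20 = mu20, mu11 = mu11, mu02 = mu02,
    orientation_deg = orientation_from_moments(mu20, mu11, mu02),
    major_len = axes$major_len, minor_len = axes$minor_len,
    elongation_factor = ef, touches_border = border)
}

#' Elongation factor of one measured cell set
#'
#' Convenience summary of the elongation-factor distribution: the ratio of
#' equivalent-ellipse major to minor axis per cell, with mean, SD and median.
#'
#' @param values numeric vector of elongation factors (each >= 1).
#' @param scope label describing what the values cover (image or condition).
#' @return data frame with `scope`, `n_cells`, `mean`, `sd`, `median`.
#' @export
elongation_summary <- function(values, scope = "all") {
  stopifnot(all(values >= 1 | !is.finite(values)))
  data.frame(scope = scope, n_cells = length(values),
             mean = mean(values), sd = if (length(values) > 1) sd(values) else NA_real_,
             median = median(values))
}

# TRUE iff all pixels of `value` in `px` form one 8-connected component.
label_is_connected <- function(px, value) {
  idx <- which(px == value, arr.ind = TRUE)
  comp <- connected_components_8(idx, nrow(px), ncol(px))
  max(comp) == 1L
}

# 8-connected component labels for a pixel set given as (row, col) index
# matrix; returns an integer vector over the rows of `idx` with components
# numbered from 1. Iterative minimum-label propagation on the bounding box.
connected_components_8 <- function(idx, nr, nc) {
  if (nrow(idx) == 0L) return(integer(0))
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  h <- max(idx[, 1]) - r0 + 1L
  w <- max(idx[, 2]) - c0 + 1L
  m <- matrix(Inf, h + 2L, w + 2L)  # padded; Inf = outside the set
  ri <- idx[, 1] - r0 + 2L
  ci <- idx[, 2] - c0 + 2L
  lin <- (ci - 1L) * (h + 2L) + ri
  m[lin] <- seq_len(nrow(idx))
  core_r <- 2:(h + 1L); core_c <- 2:(w + 1L)
  sub <- function(dr, dc) as.vector(m[core_r + dr, core_c + dc, drop = FALSE])
  inset <- is.finite(sub(0L, 0L))
  repeat {
    nb <- pmin(sub(-1L, -1L), sub(-1L, 0L), sub(-1L, 1L), sub(0L, -1L),
               sub(0L, 1L), sub(1L, -1L), sub(1L, 0L), sub(1L, 1L))
    cur <- sub(0L, 0L)
    upd <- pmin(cur, nb)
    upd[!inset] <- Inf  # labels never cross pixels outside the set
    if (identical(upd, cur)) break
    m[core_r, core_c] <- upd
  }
  comp <- m[lin]
  as.integer(factor(comp))
}
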