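# Moment-based morphometry against an independent brute-force oracle.

test_that("solid rectangles match the closed-form pixel-moment values", {
  m <- matrix(0L, 9, 11); m[4:6, 4:8] <- 1L   # 5 cols x 3 rows
  cs <- measure_cells(m)
  expect_equal(cs$area_px, 15)
  expect_equal(cs$mu20, 2)          # variance of 5 consecutive integers
  expect_equal(cs$mu02, 2 / 3)
  expect_equal(cs$mu11, 0)
  expect_equal(cs$orientation_deg, 0)
  expect_equal(cs$major_len, 4 * sqrt(2))
  expect_equal(cs$minor_len, 4 * sqrt(2 / 3))
  expect_equal(cs$elongation_factor, sqrt(3))
  expect_false(cs$touches_border)
  # transposed rectangle: orientation 90, elongation unchanged
  mt <- matrix(0L, 11, 9); mt[4:8, 4:6] <- 1L  # 3 cols x 5 rows
  ct <- measure_cells(mt)
  expect_equal(ct$orientation_deg, 90)
  expect_equal(ct$elongation_factor, sqrt(3))
})

test_that("degenerate cells follow the documented conventions", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  c1 <- measure_cells(one)
  expect_equal(c1$area_px, 1)
  expect_equal(c1$elongation_factor, 1)
  expect_equal(c1$orientation_deg, 0)
  # collinear pixels: minor axis 0, Inf sentinel
  lin <- matrix(0L, 5, 9); lin[3, 2:8] <- 1L
  cl <- measure_cells(lin)
  expect_equal(cl$minor_len, 0)
  expect_equal(cl$elongation_factor, Inf)
  # empty mask: empty frame, not an error
  expect_equal(nrow(measure_cells(matrix(0L, 4, 4))), 0)
  # disconnected label is measured with a warning
  dm <- matrix(0L, 9, 9); dm[2:3, 2:3] <- 1L; dm[7:8, 7:8] <- 1L
  expect_warning(measure_cells(dm), "8-connected")
})

test_that("orientation_from_moments covers the axis-aligned and 45-degree cases", {
  expect_equal(orientation_from_moments(2, 0, 1), 0)
  expect_equal(orientation_from_moments(1, 0, 2), 90)
  expect_equal(orientation_from_moments(1, 0.5, 1), 45)
  expect_equal(orientation_from_moments(1, -0.5, 1), -45)
  expect_equal(orientation_from_moments(1, 0, 1), 0)  # isotropic convention
  expect_error(equivalent_ellipse_axes(1, -0.1), "lambda")
  expect_equal(equivalent_ellipse_axes(0, 0), list(major_len = 0, minor_len = 0))
  expect_equal(equivalent_ellipse_axes(1, 1), list(major_len = 4, minor_len = 4))
})

test_that("production morphometry equals the brute-force oracle on random blobs", {
  set.seed(42)
  fields <- c("area_px", "centroid_row", "centroid_col", "mu20", "mu11",
              "mu02", "major_len", "minor_len")
  for (k in 1:100) {
    kind <- k %% 3
    px <- if (kind == 0) {
      random_ellipse_blob(26, 26, runif(1, 3, 9), runif(1, 2, 7),
                          runif(1, -90, 90))
    } else if (kind == 1) {
      random_grown_blob(24, 24, sample(20:120, 1))
    } else {
      m <- matrix(0L, 20, 20)
      m[sample(3:17, 1):sample(17:19, 1), sample(3:17, 1):sample(17:19, 1)] <- 1L
      m
    }
    if (sum(px) < 2) next
    got <- measure_cells(px, warn_disconnected = FALSE)
    want <- oracle_measure(px, 1L)
    expect_equal(got$area_px, want$area, tolerance = 1e-9)
    expect_equal(got$centroid_row, want$centroid_row, tolerance = 1e-9)
    expect_equal(got$mu20, want$mu20, tolerance = 1e-9)
    expect_equal(got$mu11, want$mu11, tolerance = 1e-9)
    expect_equal(got$mu02, want$mu02, tolerance = 1e-9)
    expect_equal(got$major_len, want$major_len, tolerance = 1e-9)
    expect_equal(got$minor_len, want$minor_len, tolerance = 1e-9)
    expect_equal(got$touches_border, want$touches_border)
    if (is.finite(want$elongation)) {
      expect_equal(got$elongation_factor, want$elongation, tolerance = 1e-9)
    }
    if (want$lambda1 - want$lambda2 > 1e-6) {
      expect_lt(abs(axial_difference(got$orientation_deg, want$orientation)),
                1e-6)
    }
  }
})

test_that("measurements are invariant to translation", {
  set.seed(43)
  px <- random_ellipse_blob(30, 30, 8, 4, 25)
  base <- measure_cells(px)
  for (off in list(c(3, 5), c(-2, 7), c(6, -1))) {
    shifted <- matrix(0L, 50, 50)
    idx <- which(px == 1L, arr.ind = TRUE)
    shifted[cbind(idx[, 1] + 10 + off[1], idx[, 2] + 10 + off[2])] <- 1L
    got <- measure_cells(shifted)
    expect_equal(got$area_px, base$area_px)
    expect_equal(got$mu20, base$mu20, tolerance = 1e-9)
    expect_equal(got$mu11, base$mu11, tolerance = 1e-9)
    expect_equal(got$mu02, base$mu02, tolerance = 1e-9)
    expect_equal(got$orientation_deg, base$orientation_deg, tolerance = 1e-9)
    expect_equal(got$elongation_factor, base$elongation_factor,
                 tolerance = 1e-9)
  }
})

test_that("90-degree grid rotation preserves elongation and shifts orientation", {
  set.seed(44)
  for (ang in c(10, 40, 75, -30)) {
    px <- random_ellipse_blob(40, 40, 12, 5, ang)
    base <- measure_cells(px)
    rot <- t(px)[ncol(px):1, ]   # 90-degree counter-clockwise grid rotation
    got <- measure_cells(rot)
    expect_equal(got$elongation_factor, base$elongation_factor,
                 tolerance = 1e-9)
    expect_lt(abs(axial_difference(got$orientation_deg,
                                   base$orientation_deg + 90)), 1e-9)
  }
})

test_that("arbitrary-angle re-rasterisation changes elongation by at most 5%", {
  for (ang in c(17, 37, 58, 81)) {
    base <- measure_cells(raster_ellipse(60, 60, 18, 8, 0))
    rot <- measure_cells(raster_ellipse(60, 60, 18, 8, ang))
    expect_gte(base$area_px, 200)
    expect_lt(abs(rot$elongation_factor - base$elongation_factor) /
                base$elongation_factor, 0.05)
    expect_lt(abs(axial_difference(rot$orientation_deg, ang)), 2)
  }
})
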