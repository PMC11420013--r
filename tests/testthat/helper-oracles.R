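# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracle deliberately uses explicit double loops and
# eigen() so it shares no code path with the package internals.

# Brute-force region properties for one label value in an integer matrix.
oracle_measure <- function(px, value) {
  n <- 0; sr <- 0; sc <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (px[i, j] == value) { n <- n + 1; sr <- sr + i; sc <- sc + j }
  }
  stopifnot(n > 0)
  mr <- sr / n; mc <- sc / n
  sxx <- 0; syy <- 0; sxy <- 0
  border <- FALSE
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (px[i, j] == value) {
      x <- j - mc; y <- -(i - mr)       # y-up
      sxx <- sxx + x * x; syy <- syy + y * y; sxy <- sxy + x * y
      if (i == 1 || i == nrow(px) || j == 1 || j == ncol(px)) border <- TRUE
    }
  }
  mu20 <- sxx / n; mu02 <- syy / n; mu11 <- sxy / n
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- max(ev$values[2], 0)
  # orientation from the major eigenvector (independent of the atan2 formula)
  if (l1 - l2 < 1e-12) {
    theta <- 0
  } else {
    v <- ev$vectors[, 1]
    theta <- atan2(v[2], v[1]) * 180 / pi
    theta <- ((theta + 90) %% 180) - 90
    if (theta <= -90) theta <- theta + 180
  }
  list(area = n, centroid_row = mr, centroid_col = mc,
       mu20 = mu20, mu11 = mu11, mu02 = mu02,
       lambda1 = l1, lambda2 = l2,
       major_len = 4 * sqrt(l1), minor_len = 4 * sqrt(l2),
       elongation = if (l1 == 0) 1 else if (l2 == 0) Inf else sqrt(l1 / l2),
       orientation = theta, touches_border = border)
}

# Random connected-ish blob: filled ellipse with given semi-axes at angle, plus
# optional pixel dropout away from the centre. Returns an integer matrix.
random_ellipse_blob <- function(nr, nc, a, b, angle_deg, cr = NULL, cc0 = NULL) {
  if (is.null(cr)) cr <- nr / 2
  if (is.null(cc0)) cc0 <- nc / 2
  th <- angle_deg * pi / 180
  px <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    x <- j - cc0; y <- -(i - cr)
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    if ((u / a)^2 + (v / b)^2 <= 1) px[i, j] <- 1L
  }
  px
}

# Rasterise an ellipse membership test at arbitrary angle (vectorised).
raster_ellipse <- function(nr, nc, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  jj <- rep(seq_len(nc), each = nr)
  ii <- rep(seq_len(nr), times = nc)
  x <- jj - (nc + 1) / 2
  y <- -(ii - (nr + 1) / 2)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), nr, nc)
}

# Irregular random blob grown from a seed pixel (4-connected growth).
random_grown_blob <- function(nr, nc, target_area) {
  px <- matrix(0L, nr, nc)
  cur <- matrix(c(nr %/% 2, nc %/% 2), 1, 2)
  px[cur] <- 1L
  area <- 1L
  frontier <- cur
  while (area < target_area && nrow(frontier) > 0) {
    k <- sample(nrow(frontier), 1)
    p <- frontier[k, ]
    d <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    d <- d[sample(4), , drop = FALSE]
    grown <- FALSE
    for (q in seq_len(4)) {
      np <- p + d[q, ]
      if (np[1] >= 1 && np[1] <= nr && np[2] >= 1 && np[2] <= nc &&
          px[np[1], np[2]] == 0L) {
        px[np[1], np[2]] <- 1L
        frontier <- rbind(frontier, np)
        area <- area + 1L
        grown <- TRUE
        break
      }
    }
    if (!grown) frontier <- frontier[-k, , drop = FALSE]
  }
  px
}

# Build a CellShape-like data frame row for QC tests without a mask.
fake_cell <- function(label, area, ef = 2, border = FALSE) {
  data.frame(label = label, area_px = area, centroid_row = 0, centroid_col = 0,
             mu20 = 1, mu11 = 0, mu02 = 1, orientation_deg = 0,
             major_len = 4, minor_len = 4, elongation_factor = ef,
             touches_border = border)
}

# Write a small synthetic study (masks + manifest) into `dir`; returns the
# manifest path. Two conditions ("static", "flow") with `reps` images each.
write_synthetic_study <- function(dir, reps = 2, n_cells = 24,
                                  size = c(96, 96), seed0 = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0
  for (cond in c("static", "flow")) {
    stretch <- if (cond == "flow") 3 else 1
    kappa <- if (cond == "flow") 8 else 0
    for (r in seq_len(reps)) {
      k <- k + 1
      sim <- generate_monolayer(
        synthetic_spec(size, n_cells, stretch = stretch, kappa = kappa,
                       rng_seed = seed0 + k),
        image_id = sprintf("%s_%d", cond, r), condition = cond,
        replicate = as.character(r))
      f <- sprintf("%s_%d.tif", cond, r)
      write_label_mask(sim$mask, file.path(dir, f))
      rows[[k]] <- data.frame(mask_path = f, condition = cond,
                              replicate = as.character(r), flow_angle_deg = 0)
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE,
            quote = FALSE)
  manifest_path
}
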