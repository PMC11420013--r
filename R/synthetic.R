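# Synthetic confluent monolayers via anisotropic Voronoi tessellation.
# Each seed carries its own orientation (axial von Mises around the flow
# direction, concentration kappa) and anisotropy (stretch), so the generated
# tissue has known per-cell ground truth: elongated, individually oriented
# cells that tile the frame with no background, like a confluent endothelial
# monolayer.

#' Parameters of a synthetic monolayer
#'
#' @param image_size integer (rows, cols) of the generated mask. Default
#'   `c(256, 256)`.
#' @param n_cells number of cells, >= 4. Default 100, the typical per-image
#'   cell count analysed per condition in flow-alignment experiments.
#' @param stretch target anisotropy (>= 1) of cells along their own major
#'   axis; 1 gives isotropic polygonal cells (static-like), values around
#'   3-4 give elongated flow-like cells. Default 1.
#' @param kappa von Mises concentration (>= 0) of cell orientations on the
#'   doubled-angle circle; 0 = unaligned (static-like), larger values align
#'   cells to `flow_angle_deg`. Default 0.
#' @param flow_angle_deg flow direction in degrees, in `(-90, 90]`. Default 0.
#' @param seed_jitter jitter of the seed lattice, as a fraction of the
#'   lattice spacing. Default 0.35.
#' @param rng_seed integer seed governing seed placement, orientations and
#'   rendering noise. Default 1.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(256, 256), n_cells = 100,
                           stretch = 1, kappa = 0, flow_angle_deg = 0,
                           seed_jitter = 0.35, rng_seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 8), n_cells >= 4,
            stretch >= 1, kappa >= 0, seed_jitter >= 0,
            flow_angle_deg > -90, flow_angle_deg <= 90)
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells), stretch = stretch,
                 kappa = kappa, flow_angle_deg = flow_angle_deg,
                 seed_jitter = seed_jitter, rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  code
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope rejection).
# Returns n angles in (-pi, pi]; kappa = 0 short-circuits to uniform.
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (sign(u3[ok] - 0.5) * acos(f[ok]) + mu))
  }
  out <- out[seq_len(n)]
  ((out + pi) %% (2 * pi)) - pi
}

#' Sample axial cell orientations
#'
#' Standard axial-data doubling: angles are drawn from a von Mises
#' distribution with mean `2 * mu` and concentration `kappa` on the full
#' circle, then halved and wrapped to `(-90, 90]`. `kappa = 0` gives the
#' uniform (unaligned) case; large `kappa` concentrates orientations at `mu`.
#'
#' @param n number of orientations.
#' @param kappa von Mises concentration, >= 0.
#' @param mu mean axial direction in degrees. Default 0.
#' @return numeric vector of `n` orientations in `(-90, 90]` degrees.
#' @export
sample_orientations <- function(n, kappa, mu = 0) {
  stopifnot(n >= 0, kappa >= 0)
  psi <- rvonmises(n, mu = 2 * mu * pi / 180, kappa = kappa)
  wrap_axial(psi * 90 / pi)
}

#' Generate a synthetic confluent monolayer
#'
#' Seeds are placed on a jittered lattice; each seed draws an orientation
#' from [sample_orientations()] and carries the spec's anisotropy. Every
#' pixel joins the seed minimising the anisotropic squared distance
#' (coordinates rotated into the seed's frame and shrunk by `1/stretch`
#' along its major axis), which yields elongated, individually oriented
#' cells with no background. A cleanup pass then enforces one 8-connected
#' component per label, reassigning detached fragments to the neighbouring
#' label with the longest shared boundary.
#'
#' @param spec a [synthetic_spec()].
#' @param image_id,condition,replicate metadata for the returned mask.
#' @return list with `mask` (a [label_mask()]) and `truth` (data frame:
#'   `label`, `seed_row`, `seed_col`, `true_orientation_deg`,
#'   `true_anisotropy`), one row per surviving label.
#' @export
#' @examples
#' sim <- generate_monolayer(synthetic_spec(c(96, 96), n_cells = 12,
#'                                          stretch = 3, kappa = 8))
#' n_cells(sim$mask)
generate_monolayer <- function(spec, image_id = NULL, condition = "synthetic",
                               replicate = "1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- spec$image_size[1]; C <- spec$image_size[2]
  res <- with_seed(spec$rng_seed, {
    # jittered lattice covering the frame with at least n_cells sites
    nr <- max(1L, round(sqrt(spec$n_cells * R / C)))
    nc <- ceiling(spec$n_cells / nr)
    if (nr * nc < spec$n_cells) nr <- nr + 1L
    sp_r <- R / nr; sp_c <- C / nc
    grid <- expand.grid(i = seq_len(nr), j = seq_len(nc))
    keep <- sort(sample(nrow(grid), spec$n_cells))
    seed_r <- (grid$i[keep] - 0.5) * sp_r +
      (runif(spec$n_cells) - 0.5) * spec$seed_jitter * sp_r
    seed_c <- (grid$j[keep] - 0.5) * sp_c +
      (runif(spec$n_cells) - 0.5) * spec$seed_jitter * sp_c
    seed_r <- pmin(pmax(seed_r, 1), R)
    seed_c <- pmin(pmax(seed_c, 1), C)
    phi <- sample_orientations(spec$n_cells, spec$kappa, spec$flow_angle_deg)
    list(seed_r = seed_r, seed_c = seed_c, phi = phi)
  })

  pr <- rep(seq_len(R), times = C)  # column-major pixel coordinates
  pc <- rep(seq_len(C), each = R)
  best_d <- rep(Inf, R * C)
  owner <- integer(R * C)
  inv_s2 <- 1 / spec$stretch^2
  for (i in seq_len(spec$n_cells)) {
    a <- res$phi[i] * pi / 180
    dx <- pc - res$seed_c[i]
    dy <- -(pr - res$seed_r[i])          # y-up frame
    u <- dx * cos(a) + dy * sin(a)       # along the cell's major axis
    v <- -dx * sin(a) + dy * cos(a)
    d <- u * u * inv_s2 + v * v
    upd <- d < best_d
    best_d[upd] <- d[upd]
    owner[upd] <- i
  }
  px <- matrix(owner, R, C)
  px <- enforce_connectivity(px)

  surviving <- sort(unique(as.vector(px)))
  if (length(surviving) < 4L) {
    stop("only ", length(surviving), " cells survived tessellation; ",
         "use a larger image or fewer cells")
  }
  if (is.null(image_id)) image_id <- sprintf("synthetic_%d", spec$rng_seed)
  mask <- label_mask(px, image_id = image_id, condition = condition,
                     replicate = replicate,
                     flow_angle_deg = spec$flow_angle_deg)
  truth <- data.frame(
    label = surviving,
    seed_row = res$seed_r[surviving], seed_col = res$seed_c[surviving],
    true_orientation_deg = res$phi[surviving],
    true_anisotropy = rep(spec$stretch, length(surviving)))
  list(mask = mask, truth = truth)
}

# Make every label one 8-connected component: per label keep the largest
# component and hand each smaller fragment to the 4-neighbouring label with
# the longest shared boundary. Reassignment can in principle split the
# recipient, so passes repeat until stable (bounded).
enforce_connectivity <- function(px) {
  for (pass in 1:25) {
    changed <- FALSE
    for (lab in sort(unique(as.vector(px)))) {
      idx <- which(px == lab, arr.ind = TRUE)
      comp <- connected_components_8(idx, nrow(px), ncol(px))
      if (max(comp) == 1L) next
      changed <- TRUE
      sizes <- tabulate(comp)
      keep <- which.max(sizes)
      for (k in seq_len(max(comp))) {
        if (k == keep) next
        frag <- idx[comp == k, , drop = FALSE]
        nb <- neighbour_labels(px, frag, lab)
        if (length(nb) == 0L) next  # fully enclosed by itself: keep
        target <- as.integer(names(nb)[which.max(nb)])
        px[frag] <- target
      }
    }
    if (!changed) break
  }
  px
}

# Tally of 4-neighbour labels (excluding `self`) around a pixel fragment.
neighbour_labels <- function(px, frag, self) {
  R <- nrow(px); C <- ncol(px)
  nb <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    rr <- frag[, 1] + d[1]; cc <- frag[, 2] + d[2]
    ok <- rr >= 1L & rr <= R & cc >= 1L & cc <= C
    nb <- c(nb, px[cbind(rr[ok], cc[ok])])
  }
  tab <- table(nb[nb != self])
  tab
}

#' Render synthetic fluorescence channels from a label mask
#'
#' A membrane (junction) channel — the inter-label boundary indicator
#' convolved with a Gaussian point-spread function — and a nuclei channel of
#' Gaussian blobs at cell centroids; both scaled to `photon_scale` and
#' optionally Poisson-corrupted. Deterministic given `rng_seed`.
#'
#' @param mask a [label_mask()] or integer matrix.
#' @param psf_sigma Gaussian PSF standard deviation in pixels (0 = none).
#' @param photon_scale peak expected photon count, > 0.
#' @param rng_seed integer seed for the shot noise.
#' @param poisson_noise apply Poisson shot noise? Default TRUE.
#' @return numeric array `(rows, cols, 2)`; channels named `membrane`,
#'   `nuclei`.
#' @export
render_channels <- function(mask, psf_sigma = 1.5, photon_scale = 100,
                            rng_seed = 1, poisson_noise = TRUE) {
  if (photon_scale <= 0) stop("photon_scale must be positive")
  px <- if (inherits(mask, "label_mask")) mask$pixels else mask
  R <- nrow(px); C <- ncol(px)
  boundary <- matrix(0, R, C)
  differs <- function(a, b) a != b
  boundary[-R, ] <- boundary[-R, ] + differs(px[-R, ], px[-1, ])
  boundary[-1, ] <- boundary[-1, ] + differs(px[-1, ], px[-R, ])
  boundary[, -C] <- boundary[, -C] + differs(px[, -C], px[, -1])
  boundary[, -1] <- boundary[, -1] + differs(px[, -1], px[, -C])
  membrane <- (boundary > 0) * 1

  cells <- measure_cells(px, warn_disconnected = FALSE)
  nuclei <- matrix(0, R, C)
  if (nrow(cells)) {
    rc <- cbind(pmin(pmax(round(cells$centroid_row), 1), R),
                pmin(pmax(round(cells$centroid_col), 1), C))
    nuclei[rc] <- 1
    nuc_sigma <- max(1, 0.12 * sqrt(mean(cells$area_px)))
    nuclei <- EBImage::gblur(nuclei, sigma = nuc_sigma)
    nuclei <- nuclei / max(nuclei)
  }
  if (psf_sigma > 0) {
    membrane <- EBImage::gblur(membrane, sigma = psf_sigma)
    membrane <- membrane / max(membrane)
  }
  out <- array(0, dim = c(R, C, 2), dimnames = list(NULL, NULL,
                                                    c("membrane", "nuclei")))
  out[, , 1] <- membrane * photon_scale
  out[, , 2] <- nuclei * photon_scale
  out <- pmax(out, 0)  # blur ringing can leave tiny negatives
  if (poisson_noise) {
    out <- with_seed(rng_seed, array(rpois(length(out), out), dim = dim(out),
                                     dimnames = dimnames(out)))
  }
  out
}
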