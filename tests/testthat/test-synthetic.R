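# The synthetic monolayer generator: orientation sampling, tessellation
# contracts (confluence, connectivity, determinism), and channel rendering.

test_that("sampled orientations live on the axial range", {
  set.seed(61)
  for (k in c(0, 0.5, 2, 10)) {
    th <- sample_orientations(300, kappa = k, mu = 25)
    expect_true(all(th > -90 & th <= 90))
  }
  expect_length(sample_orientations(0, 1), 0)
})

test_that("kappa = 0 gives uniform axial orientations", {
  set.seed(67)
  th <- sample_orientations(5000, kappa = 0)
  expect_gt(suppressWarnings(ks.test(th, "punif", -90, 90))$p.value, 0.01)
})

test_that("large kappa concentrates orientations at the flow direction", {
  set.seed(71)
  th <- sample_orientations(300, kappa = 1000, mu = 40)
  expect_true(all(abs(axial_difference(th, 40)) < 5))
  th2 <- sample_orientations(300, kappa = 1000, mu = 90)  # wrap-around mean
  expect_true(all(abs(axial_difference(th2, 90)) < 5))
  # moderate concentration: orientations centre on mu with real spread
  th3 <- sample_orientations(500, kappa = 200, mu = 40)
  expect_lt(abs(axial_difference(axial_mean(th3), 40)), 1)
  expect_gt(mean(abs(axial_difference(th3, 40)) < 5), 0.95)
})

test_that("generated monolayers are confluent with 8-connected labels", {
  sim <- generate_monolayer(synthetic_spec(c(120, 120), 30, stretch = 3,
                                           kappa = 4, rng_seed = 5))
  px <- sim$mask$pixels
  expect_equal(sum(px == 0), 0)                 # no background
  labs <- sort(unique(as.vector(px)))
  expect_gte(length(labs), 4)
  for (lab in labs) {
    idx <- which(px == lab, arr.ind = TRUE)
    expect_equal(max(flowshape:::connected_components_8(idx, nrow(px),
                                                        ncol(px))), 1L)
  }
  # ground truth covers exactly the surviving labels
  expect_equal(sim$truth$label, labs)
  expect_true(all(sim$truth$true_orientation_deg > -90 &
                    sim$truth$true_orientation_deg <= 90))
})

test_that("identical specs give identical masks; seeds change them", {
  spec <- synthetic_spec(c(80, 80), 16, stretch = 2, kappa = 2, rng_seed = 9)
  a <- generate_monolayer(spec)
  b <- generate_monolayer(spec)
  expect_identical(a$mask$pixels, b$mask$pixels)
  expect_identical(a$truth, b$truth)
  spec2 <- synthetic_spec(c(80, 80), 16, stretch = 2, kappa = 2, rng_seed = 10)
  expect_false(identical(generate_monolayer(spec2)$mask$pixels,
                         a$mask$pixels))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_monolayer(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("isotropic specs give round-ish cells, stretched specs elongated ones", {
  kept_ef <- function(stretch, seeds) {
    unlist(lapply(seeds, function(sd) {
      sim <- generate_monolayer(synthetic_spec(c(120, 120), 30,
                                               stretch = stretch, kappa = 8,
                                               rng_seed = sd))
      qc <- apply_qc(measure_cells(sim$mask, warn_disconnected = FALSE))
      qc$kept$elongation_factor
    }))
  }
  iso <- kept_ef(1, 1:10)
  aniso <- kept_ef(4, 1:10)
  expect_lt(median(iso), 2)
  expect_gt(median(aniso), median(iso))
})

test_that("the imposed flow direction is recovered from measured cells", {
  means <- vapply(1:10, function(sd) {
    sim <- generate_monolayer(synthetic_spec(c(120, 120), 30, stretch = 3,
                                             kappa = 8, flow_angle_deg = 30,
                                             rng_seed = 400 + sd))
    qc <- apply_qc(measure_cells(sim$mask, warn_disconnected = FALSE))
    axial_mean(qc$kept$orientation_deg)
  }, 0)
  pooled <- axial_mean(means)
  expect_lt(abs(axial_difference(pooled, 30)), 5)
})

test_that("rendered channels follow the construction and are deterministic", {
  sim <- generate_monolayer(synthetic_spec(c(64, 64), 9, rng_seed = 3))
  # no PSF, no noise: membrane channel is exactly the boundary indicator
  ch0 <- render_channels(sim$mask, psf_sigma = 0, photon_scale = 1,
                         poisson_noise = FALSE)
  mem <- ch0[, , "membrane"]
  expect_setequal(unique(as.vector(mem)), c(0, 1))
  px <- sim$mask$pixels
  interior_px <- px[2:63, 2:63]
  has_diff_nb <- (px[1:62, 2:63] != interior_px) |
    (px[3:64, 2:63] != interior_px) | (px[2:63, 1:62] != interior_px) |
    (px[2:63, 3:64] != interior_px)
  expect_equal(mem[2:63, 2:63] == 1, has_diff_nb)
  # blurred + noisy channels: boundary pixels brighter on average
  ch <- render_channels(sim$mask, psf_sigma = 1.5, photon_scale = 200,
                        rng_seed = 8)
  boundary_mask <- mem == 1
  expect_gt(mean(ch[, , "membrane"][boundary_mask]),
            mean(ch[, , "membrane"][!boundary_mask]))
  # determinism
  ch2 <- render_channels(sim$mask, psf_sigma = 1.5, photon_scale = 200,
                         rng_seed = 8)
  expect_identical(ch, ch2)
  expect_error(render_channels(sim$mask, photon_scale = 0), "positive")
})

test_that("impossible specs fail with guidance", {
  expect_error(synthetic_spec(c(64, 64), 3), "n_cells")
  expect_error(synthetic_spec(c(64, 64), 10, stretch = 0.5), "stretch")
  expect_error(synthetic_spec(c(64, 64), 10, kappa = -1), "kappa")
})
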