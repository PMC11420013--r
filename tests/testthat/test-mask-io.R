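# Label-mask containers, manifests, and the per-cell table serialisation.

test_that("TIFF label masks round-trip bit-exactly", {
  px <- matrix(0L, 20, 30)
  px[3:8, 4:10] <- 1L; px[12:18, 15:25] <- 2L; px[2:5, 20:28] <- 3L
  px[15, 2] <- 4L; px[1, 1] <- 5L
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(px, f)
  m <- read_label_mask(f, condition = "static", replicate = "2",
                       flow_angle_deg = 15)
  expect_identical(m$pixels, px)
  expect_equal(n_cells(m), 5)
  expect_equal(m$condition, "static")
  expect_equal(m$flow_angle_deg, 15)
  # 16-bit values survive
  px2 <- matrix(c(0L, 300L, 40000L, 65535L), 2, 2)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(px2, f2)
  expect_identical(read_label_mask(f2)$pixels, px2)
})

test_that("PNG masks round-trip for small label counts and refuse large ones", {
  px <- matrix(sample(0:12, 400, replace = TRUE), 20, 20)
  storage.mode(px) <- "integer"
  f <- withr::local_tempfile(fileext = ".png")
  write_label_mask(px, f)
  expect_identical(read_label_mask(f)$pixels, px)
  big <- matrix(c(0L, 300L), 2, 2)
  f2 <- withr::local_tempfile(fileext = ".png")
  expect_error(write_label_mask(big, f2), "16-bit")
})

test_that("invalid mask files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(runif(48), dim = c(4, 4, 3))
  tiff::writeTIFF(rgb, f)
  expect_error(read_label_mask(f), "4 x 4 x 3")
  # fractional pixel values are rejected by the shared mask validator
  expect_error(label_mask(matrix(c(0, 0.5, 1, 2), 2, 2)), "non-integer")
  expect_error(read_label_mask("no/such/file.tif"), "not found")
  expect_error(label_mask(matrix(-1L, 2, 2)), "negative")
  expect_error(label_mask(matrix(1L, 2, 2), flow_angle_deg = 95), "flow_angle")
})

test_that("manifests parse, default, resolve paths and catch errors", {
  dir <- withr::local_tempdir()
  px <- matrix(1L, 4, 4)
  for (f in c("a.tif", "b.tif", "c.tif")) {
    write_label_mask(px, file.path(dir, f))
  }
  mf <- file.path(dir, "manifest.csv")
  writeLines(c("# study manifest",
               "mask_path,condition,replicate,flow_angle_deg",
               "a.tif,static,1,0",
               "b.tif,static,2,",
               "c.tif,flow,1,30"), mf)
  man <- load_manifest(mf)
  expect_equal(nrow(man), 3)
  expect_equal(man$flow_angle_deg, c(0, 0, 30))  # blank -> default 0
  expect_true(all(file.exists(man$mask_path)))
  expect_equal(unique(man$condition), c("static", "flow"))
  # order preserved and parsing idempotent
  expect_identical(man, load_manifest(mf))

  writeLines(c("mask_path,condition,replicate",
               "a.tif,static,1", "a.tif,flow,1"), mf)
  expect_error(load_manifest(mf), "row 2.*duplicate")
  writeLines(c("mask_path,condition,replicate",
               "missing.tif,static,1"), mf)
  expect_error(load_manifest(mf), "row 1.*not found")
})

test_that("cells table serialises with full precision and round-trips", {
  m <- matrix(0L, 12, 40)
  m[2:11, 2:11] <- 1L; m[4:9, 14:33] <- 2L
  cells <- annotate_qc(measure_cells(m), qc_config(remove_border = FALSE))
  records <- cbind(image_id = "img1", condition = "static", replicate = "1",
                   cells)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cells_table(records, f)
  back <- read_cells_table(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$elongation_factor, records$elongation_factor,
               tolerance = 1e-12)
  expect_equal(names(back)[1:5],
               c("image_id", "condition", "replicate", "label", "area_px"))
  # degenerate: empty record list -> header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cells_table(records[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_cells_table(f2)), 0L)
})
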