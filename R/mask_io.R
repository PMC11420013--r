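# Label-mask and manifest I/O. Masks are integer matrices (row, col) with 0 =
# background; TIFF (8/16/32-bit unsigned) is the canonical container, PNG is
# accepted for <= 255 labels. Pixel values survive a write/read round trip
# bit-exactly.

#' Construct a label mask object
#'
#' @param pixels integer matrix, 0 = background, each positive integer one
#'   cell. Rows index the image row (top = row 1), columns the image column.
#' @param image_id character scalar identifying the image.
#' @param condition,replicate character labels for the experimental group.
#' @param flow_angle_deg flow direction in degrees from the horizontal image
#'   axis, in `(-90, 90]`. Default 0 (flow along x).
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(pixels, image_id = "image", condition = "unknown",
                       replicate = "1", flow_angle_deg = 0) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels))) {
      stop("label mask contains non-integer pixel values")
    }
    storage.mode(pixels) <- "integer"
  }
  if (any(pixels < 0L)) stop("label mask contains negative pixel values")
  if (!(flow_angle_deg > -90 && flow_angle_deg <= 90)) {
    stop("flow_angle_deg must lie in (-90, 90]")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         image_id = as.character(image_id), condition = as.character(condition),
         replicate = as.character(replicate),
         flow_angle_deg = as.numeric(flow_angle_deg)),
    class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$pixels)), 0L))
  cat(sprintf("label_mask '%s' (%d x %d px, %d cells, condition = %s, flow = %g deg)\n",
              x$image_id, x$height, x$width, n, x$condition, x$flow_angle_deg))
  invisible(x)
}

#' Number of distinct cells in a label mask
#' @param mask a `label_mask`.
#' @return integer count of distinct positive labels.
#' @export
n_cells <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  length(setdiff(unique(as.vector(mask$pixels)), 0L))
}

#' Read a label mask from a TIFF or PNG file
#'
#' Accepts single-channel integer images only. TIFF values are read as stored
#' (8/16/32-bit); PNG intensities are rescaled back to integer labels using
#' the file's recorded bit depth.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param image_id image identifier; defaults to the file name.
#' @inheritParams label_mask
#' @return a [label_mask()].
#' @export
read_label_mask <- function(path, image_id = NULL, condition = "unknown",
                            replicate = "1", flow_angle_deg = 0) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) {
      stop(sprintf(
        "expected a single-channel label image, got an array of shape %s in %s",
        paste(dim(img), collapse = " x "), path))
    }
    if (is.double(img) && any(img != round(img))) {
      stop("floating-point TIFF is not a valid label mask: ", path)
    }
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) != 2L) {
      stop(sprintf(
        "expected a single-channel label image, got an array of shape %s in %s",
        paste(dim(img), collapse = " x "), path))
    }
    depth <- attr(img, "info")$bit.depth
    img <- matrix(as.integer(round(img * (2^depth - 1))), nrow(img), ncol(img))
  } else {
    stop("unsupported mask format '", ext, "' (use TIFF or PNG): ", path)
  }
  if (any(img < 0)) stop("label mask contains negative pixel values: ", path)
  if (is.null(image_id)) image_id <- basename(path)
  label_mask(img, image_id = image_id, condition = condition,
             replicate = replicate, flow_angle_deg = flow_angle_deg)
}

#' Write a label mask to a TIFF or PNG file
#'
#' TIFF containers use the smallest of 8/16/32 bits that holds the largest
#' label; PNG is limited to labels up to 255 (use TIFF beyond that).
#'
#' @param mask a [label_mask()] or integer matrix.
#' @param path destination `.tif`/`.tiff` or `.png` path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  px <- if (inherits(mask, "label_mask")) mask$pixels else mask
  stopifnot(is.matrix(px))
  storage.mode(px) <- "double"
  maxv <- max(px)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    bits <- if (maxv <= 255) 8L else if (maxv <= 65535) 16L else 32L
    tiff::writeTIFF(px / (2^bits - 1), path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (maxv > 255) {
      stop("PNG label masks support at most 255 labels (largest here is ",
           maxv, "); write a 16-bit TIFF container instead")
    }
    png::writePNG(px / 255, path)
  } else {
    stop("unsupported mask format '", ext, "' (use TIFF or PNG)")
  }
  invisible(path)
}

#' Load a study manifest
#'
#' A comma-separated table with header columns `mask_path`, `condition`,
#' `replicate` and optionally `flow_angle_deg` (default 0). Lines starting
#' with `#` are ignored. Relative mask paths are resolved against the
#' manifest's own directory.
#'
#' @param path path to the manifest file.
#' @return a data frame with columns `mask_path`, `condition`, `replicate`,
#'   `flow_angle_deg`, rows in file order.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 strip.white = TRUE)
  need <- c("mask_path", "condition", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("manifest lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$flow_angle_deg)) df$flow_angle_deg <- 0
  df$flow_angle_deg[is.na(df$flow_angle_deg)] <- 0
  df$replicate <- as.character(df$replicate)
  if (any(!nzchar(df$condition)) || anyNA(df$condition)) {
    stop("manifest conditions must be non-empty")
  }
  bad_angle <- which(!(df$flow_angle_deg > -90 & df$flow_angle_deg <= 90))
  if (length(bad_angle)) {
    stop("manifest row ", bad_angle[1], ": flow_angle_deg must lie in (-90, 90]")
  }
  dup <- which(duplicated(df$mask_path))
  if (length(dup)) {
    stop("manifest row ", dup[1], ": duplicate mask_path '", df$mask_path[dup[1]], "'")
  }
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", df$mask_path)
  df$mask_path[rel] <- file.path(base, df$mask_path[rel])
  absent <- which(!file.exists(df$mask_path))
  if (length(absent)) {
    stop("manifest row ", absent[1], ": mask file not found: ",
         df$mask_path[absent[1]])
  }
  df[, c("mask_path", "condition", "replicate", "flow_angle_deg")]
}

# Fixed column order of the per-cell output table.
CELLS_TABLE_COLUMNS <- c(
  "image_id", "condition", "replicate", "label", "area_px", "centroid_row",
  "centroid_col", "orientation_deg", "major_len", "minor_len",
  "elongation_factor", "touches_border", "qc_kept", "qc_reason")

#' Write the per-cell measurement table
#'
#' Serialises QC-annotated cell records as a comma-separated table with a
#' fixed column order. Numbers keep full double precision (15 significant
#' digits), so elongation factors round-trip well below 1e-9.
#'
#' @param records data frame of measured, QC-annotated cells (as produced by
#'   [run_analysis()] or by combining [measure_cells()] and [apply_qc()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cells_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(logical(0)),
                                          length(CELLS_TABLE_COLUMNS)),
                                      CELLS_TABLE_COLUMNS))
  }
  missing_cols <- setdiff(CELLS_TABLE_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("cells table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  write.csv(records[, CELLS_TABLE_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a per-cell measurement table written by [write_cells_table()]
#' @param path path to the table.
#' @return data frame in the documented column order.
#' @export
read_cells_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
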