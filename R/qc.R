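# Segmentation quality control: the three mask filters applied after
# measurement — border contact, extreme aspect ratio (> 10), and relative
# area (< 20% of the largest cell in the image).

#' Quality-control configuration
#'
#' Defaults mirror the standard monolayer-segmentation cleanup: remove cells
#' smaller than 20% of the largest cell in the image, cells with a major to
#' minor axis ratio greater than 10, and cells touching the image border.
#' Both numeric thresholds are strict inequalities.
#'
#' @param min_area_fraction fraction of the largest cell's area below which a
#'   cell is removed; in `(0, 1)`, default 0.2. Use 0 to disable.
#' @param max_aspect elongation factor above which a cell is removed
#'   (strictly greater); default 10. Use `Inf` to disable.
#' @param remove_border remove cells touching the image border? Default TRUE.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_area_fraction = 0.2, max_aspect = 10,
                      remove_border = TRUE) {
  stopifnot(min_area_fraction >= 0, min_area_fraction < 1, max_aspect > 1,
            is.logical(remove_border))
  structure(list(min_area_fraction = min_area_fraction,
                 max_aspect = max_aspect, remove_border = remove_border),
            class = "qc_config")
}

#' Apply quality-control filters to measured cells
#'
#' All three rules are evaluated in a single pass over the original cell set:
#' the reference area (the largest cell) is computed before any removal, so
#' a border-touching largest cell still anchors the relative-area rule. A
#' cell failing several rules is reported under the first reason in the
#' order border, too_elongated, too_small.
#'
#' @param cells data frame from [measure_cells()] (one image).
#' @param config a [qc_config()].
#' @return list of class `qc_result`: `kept` and `removed` data frames
#'   (removed carries a `qc_reason` column), `reference_area`, and `config`.
#' @export
#' @examples
#' m <- matrix(0L, 12, 40)
#' m[2:11, 2:11] <- 1L; m[2:7, 14:19] <- 2L; m[5:7, 22:24] <- 3L
#' res <- apply_qc(measure_cells(m), qc_config())
#' res$removed$qc_reason  # the 9-px cell fails the 20% rule
apply_qc <- function(cells, config = qc_config()) {
  stopifnot(is.data.frame(cells), inherits(config, "qc_config"))
  if (nrow(cells) == 0L) {
    out <- list(kept = cells, removed = cbind(cells, qc_reason = character(0)),
                reference_area = 0, config = config)
    class(out) <- "qc_result"
    return(out)
  }
  reference_area <- max(cells$area_px)
  fail_border <- config$remove_border & cells$touches_border
  fail_aspect <- cells$elongation_factor > config$max_aspect
  fail_area <- cells$area_px < config$min_area_fraction * reference_area
  removed_idx <- fail_border | fail_aspect | fail_area
  reason <- rep(NA_character_, nrow(cells))
  reason[fail_area] <- "too_small"
  reason[fail_aspect] <- "too_elongated"
  reason[fail_border] <- "border"
  removed <- cells[removed_idx, , drop = FALSE]
  removed$qc_reason <- reason[removed_idx]
  out <- list(kept = cells[!removed_idx, , drop = FALSE], removed = removed,
              reference_area = reference_area, config = config)
  class(out) <- "qc_result"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("qc_result: %d kept, %d removed (reference area %g px)\n",
              nrow(x$kept), nrow(x$removed), x$reference_area))
  if (nrow(x$removed)) print(table(x$removed$qc_reason))
  invisible(x)
}

#' Annotate a measured cell table with QC outcomes
#'
#' Adds `qc_kept` and `qc_reason` columns without dropping any row, for
#' serialisation via [write_cells_table()].
#'
#' @inheritParams apply_qc
#' @return `cells` with the two QC columns appended.
#' @export
annotate_qc <- function(cells, config = qc_config()) {
  res <- apply_qc(cells, config)
  cells$qc_kept <- !(cells$label %in% res$removed$label)
  cells$qc_reason <- res$removed$qc_reason[match(cells$label, res$removed$label)]
  cells$qc_reason[is.na(cells$qc_reason)] <- ""
  cells
}
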