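# End-to-end orchestration: manifest -> per-cell morphometry -> QC ->
# per-image median-centred deviations -> per-condition pooling -> elongation
# and alignment summaries -> rank statistics -> tables / JSON / figures.

#' Analysis configuration
#'
#' Defaults reproduce the standard flow-alignment analysis settings: QC at
#' 20% relative area, aspect ratio 10, border removal on; deviations centred
#' on the per-image median and pooled per condition; 36 radial bins;
#' Kruskal-Wallis with Dunn's (Bonferroni) for three or more conditions and
#' two-tailed Mann-Whitney for two; alpha 0.05.
#'
#' @param qc a [qc_config()].
#' @param pooling `"condition"` (deviations and elongation factors pooled
#'   across the images of a condition; the default) or `"image"` (one
#'   summary per image).
#' @param n_bins radial histogram bins (must divide 360). Default 36.
#' @param adjustment multiplicity adjustment for Dunn's post hoc.
#' @param alpha significance threshold. Default 0.05.
#' @param rng_seed seed for any resampling (reserved; the core pipeline is
#'   deterministic).
#' @param verbose emit per-image progress messages? Default FALSE.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(qc = qc_config(), pooling = c("condition", "image"),
                            n_bins = 36, adjustment = "bonferroni",
                            alpha = 0.05, rng_seed = 1, verbose = FALSE) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(qc, "qc_config"), 360 %% n_bins == 0,
            alpha > 0, alpha < 1)
  structure(list(qc = qc, pooling = pooling, n_bins = n_bins,
                 adjustment = adjustment, alpha = alpha,
                 rng_seed = as.integer(rng_seed), verbose = isTRUE(verbose)),
            class = "analysis_config")
}

#' Run the full shape and alignment analysis
#'
#' For each manifest row: read the mask, measure every cell, apply QC, take
#' the orientations of kept cells, centre them on the per-image axial median.
#' Per condition: pool the deviations and elongation factors across images
#' (respecting replicates), compute the coefficient of variation and radial
#' histogram, and summarise elongation. Across conditions: Mann-Whitney for
#' two groups or Kruskal-Wallis plus Dunn's post hoc for three or more,
#' applied to the elongation factors. Rows may also be passed pre-loaded as
#' a list of [label_mask()] objects via `masks`.
#'
#' @param manifest data frame from [load_manifest()], or NULL when `masks`
#'   is given.
#' @param config an [analysis_config()].
#' @param masks optional list of [label_mask()] objects replacing the
#'   manifest (metadata is taken from each mask).
#' @return list of class `analysis_result`: `cells` (full annotated table),
#'   `per_image` (data frame of per-image counts, medians and CVs),
#'   `elongation` (per scope), `alignment` (list of `alignment_summary`),
#'   `stats`, `posthoc`, `log` (character vector), `config`.
#' @export
run_analysis <- function(manifest = NULL, config = analysis_config(),
                         masks = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(masks)) {
    stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
    masks <- lapply(seq_len(nrow(manifest)), function(i) {
      read_label_mask(manifest$mask_path[i],
                      condition = manifest$condition[i],
                      replicate = manifest$replicate[i],
                      flow_angle_deg = manifest$flow_angle_deg[i])
    })
  }
  log_lines <- sprintf(
    "flowshape analysis: %d image(s); QC min_area_fraction=%g max_aspect=%g remove_border=%s; pooling=%s; bins=%d",
    length(masks), config$qc$min_area_fraction, config$qc$max_aspect,
    config$qc$remove_border, config$pooling, config$n_bins)

  per_image <- list()
  all_cells <- list()
  image_dev <- list()   # per-image deviations of kept cells
  image_meta <- list()
  for (m in masks) {
    cells <- measure_cells(m, warn_disconnected = FALSE)
    annotated <- annotate_qc(cells, config$qc)
    annotated <- cbind(image_id = m$image_id, condition = m$condition,
                       replicate = m$replicate, annotated)
    all_cells[[length(all_cells) + 1L]] <- annotated
    kept <- annotated[annotated$qc_kept, , drop = FALSE]
    line <- sprintf("image %s [%s/%s]: %d cells, %d kept, %d removed",
                    m$image_id, m$condition, m$replicate, nrow(annotated),
                    nrow(kept), nrow(annotated) - nrow(kept))
    if (config$verbose) message(line)
    log_lines <- c(log_lines, line)
    if (nrow(kept) == 0L) {
      warning("image ", m$image_id, " has no cells after QC; excluded")
      next
    }
    med <- axial_median(kept$orientation_deg)
    dev <- axial_difference(kept$orientation_deg, med)
    per_image[[length(per_image) + 1L]] <- data.frame(
      image_id = m$image_id, condition = m$condition, replicate = m$replicate,
      n_cells = nrow(annotated), n_kept = nrow(kept),
      median_orientation_deg = med,
      cv = if (nrow(kept) >= 2) alignment_cv(dev) else NA_real_,
      median_elongation = median(kept$elongation_factor))
    image_dev[[length(image_dev) + 1L]] <- dev
    image_meta[[length(image_meta) + 1L]] <-
      list(condition = m$condition, image_id = m$image_id,
           elongation = kept$elongation_factor)
  }
  # canonical ordering so results are invariant to manifest row order
  cells_table <- do.call(rbind, all_cells)
  cells_table <- cells_table[order(cells_table$condition, cells_table$image_id,
                                   cells_table$label), ]
  rownames(cells_table) <- NULL
  per_image_df <- if (length(per_image)) do.call(rbind, per_image) else NULL
  if (!is.null(per_image_df)) {
    per_image_df <- per_image_df[order(per_image_df$condition,
                                       per_image_df$image_id), ]
    rownames(per_image_df) <- NULL
  }
  if (length(image_dev) == 0L) stop("no image retained any cell after QC")
  ord <- order(vapply(image_meta, `[[`, "", "condition"),
               vapply(image_meta, `[[`, "", "image_id"))
  image_dev <- image_dev[ord]
  image_meta <- image_meta[ord]

  conditions <- sort(unique(vapply(image_meta, `[[`, "", "condition")))
  alignment <- list(); elong_rows <- list(); elong_groups <- list()
  for (cond in conditions) {
    ii <- which(vapply(image_meta, `[[`, "", "condition") == cond)
    if (config$pooling == "condition") {
      dev <- unlist(image_dev[ii], use.names = FALSE)
      ef <- unlist(lapply(image_meta[ii], `[[`, "elongation"),
                   use.names = FALSE)
      alignment[[cond]] <- alignment_summary(deviations = dev, scope = cond,
                                             n_bins = config$n_bins)
      elong_rows[[cond]] <- elongation_summary(ef, scope = cond)
      elong_groups[[cond]] <- ef
    } else {
      for (k in ii) {
        id <- image_meta[[k]]$image_id
        alignment[[id]] <- alignment_summary(deviations = image_dev[[k]],
                                             scope = id,
                                             n_bins = config$n_bins)
        elong_rows[[id]] <- elongation_summary(image_meta[[k]]$elongation,
                                               scope = id)
      }
      elong_groups[[cond]] <- unlist(lapply(image_meta[ii], `[[`,
                                            "elongation"), use.names = FALSE)
    }
  }
  elongation <- do.call(rbind, elong_rows)
  rownames(elongation) <- NULL

  stats_res <- NULL; posthoc <- NULL
  if (length(elong_groups) >= 3) {
    stats_res <- kruskal_wallis(elong_groups)
    posthoc <- dunn_posthoc(elong_groups, adjustment = config$adjustment)
    log_lines <- c(log_lines, sprintf(
      "kruskal_wallis on elongation: H=%.4f p=%.3g",
      stats_res$statistic, stats_res$p_value))
  } else if (length(elong_groups) == 2) {
    stats_res <- mann_whitney_u(elong_groups[[1]], elong_groups[[2]])
    stats_res$groups <- names(elong_groups)
    log_lines <- c(log_lines, sprintf(
      "mann_whitney on elongation (%s vs %s): U=%.1f p=%.3g",
      names(elong_groups)[1], names(elong_groups)[2],
      stats_res$statistic, stats_res$p_value))
  } else {
    log_lines <- c(log_lines, "single condition: statistics skipped")
    warning("fewer than 2 conditions; statistics skipped")
  }

  structure(list(cells = cells_table, per_image = per_image_df,
                 elongation = elongation, alignment = alignment,
                 elongation_groups = elong_groups,
                 stats = stats_res, posthoc = posthoc,
                 log = log_lines, config = config),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("flowshape analysis_result\n")
  cat(sprintf("  %d cells measured across %d image(s), %d condition(s)\n",
              nrow(x$cells), length(unique(x$cells$image_id)),
              length(unique(x$cells$condition))))
  print(x$elongation)
  for (a in x$alignment) {
    cat(sprintf("  alignment %s: n=%d CV=%.3f\n", a$scope, a$n_cells, a$cv))
  }
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Write an analysis result bundle to disk
#'
#' Emits `cells.csv` (full per-cell table), `per_image.csv`,
#' `elongation.csv`, `alignment.csv` (scope, n, median, CV),
#' `radial_bins.json` (per-scope rose-plot bins), `stats.csv` /
#' `posthoc.csv` when computed, and `run_log.txt`.
#'
#' @param result an `analysis_result` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "analysis_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cells_table(result$cells, file.path(dir, "cells.csv"))
  if (!is.null(result$per_image)) {
    write.csv(result$per_image, file.path(dir, "per_image.csv"),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(result$elongation, file.path(dir, "elongation.csv"),
            row.names = FALSE, quote = FALSE)
  align_df <- do.call(rbind, lapply(result$alignment, function(a) {
    data.frame(scope = a$scope, n_cells = a$n_cells,
               median_orientation_deg = a$median_orientation_deg, cv = a$cv)
  }))
  write.csv(align_df, file.path(dir, "alignment.csv"), row.names = FALSE,
            quote = FALSE)
  bins <- lapply(result$alignment, function(a) {
    list(bin_start_deg = a$radial_bins$bin_start_deg,
         count = a$radial_bins$count)
  })
  jsonlite::write_json(bins, file.path(dir, "radial_bins.json"),
                       auto_unbox = FALSE, digits = NA)
  if (!is.null(result$stats)) {
    write.csv(data.frame(method = result$stats$method,
                         groups = paste(result$stats$groups, collapse = "|"),
                         statistic = result$stats$statistic,
                         p_value = result$stats$p_value,
                         stars = significance_stars(result$stats$p_value)),
              file.path(dir, "stats.csv"), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$posthoc)) {
    write.csv(result$posthoc, file.path(dir, "posthoc.csv"),
              row.names = FALSE, quote = FALSE)
  }
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
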