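# Report figures: elongation-factor violins with significance stars and
# per-condition rose (radial) plots in which each cell is a diameter.

#' Build report figures from an analysis result
#'
#' Produces a violin/box plot of elongation factors per condition (annotated
#' with n and, for two-condition comparisons, the significance stars of the
#' configured test) and one point-symmetric rose plot per alignment scope.
#'
#' @param result an `analysis_result` from [run_analysis()].
#' @param dir optional directory; when given, figures are also written as
#'   PNG files (`elongation.png`, `rose_<scope>.png`).
#' @return list with `elongation` (a ggplot) and `roses` (named list of
#'   ggplots), invisibly when `dir` is given.
#' @export
make_report <- function(result, dir = NULL) {
  stopifnot(inherits(result, "analysis_result"))
  if (length(result$elongation_groups) == 0L) stop("empty result bundle")
  ef <- do.call(rbind, lapply(names(result$elongation_groups), function(g) {
    data.frame(condition = g, elongation_factor = result$elongation_groups[[g]])
  }))
  ef$condition <- factor(ef$condition, levels = names(result$elongation_groups))
  ns <- vapply(result$elongation_groups, length, 0L)
  subtitle <- paste(sprintf("%s: n = %d", names(ns), ns), collapse = ", ")
  if (!is.null(result$stats)) {
    subtitle <- paste0(subtitle, sprintf("  (%s, p = %.3g %s)",
                                         result$stats$method,
                                         result$stats$p_value,
                                         significance_stars(result$stats$p_value)))
  }
  p_ef <- ggplot2::ggplot(ef, ggplot2::aes(x = condition,
                                           y = elongation_factor)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "elongation factor (major/minor axis)",
                  subtitle = subtitle) +
    ggplot2::theme_classic()

  roses <- lapply(result$alignment, function(a) {
    b <- a$radial_bins
    width <- 360 / nrow(b)
    b$mid <- b$bin_start_deg + width / 2
    ggplot2::ggplot(b, ggplot2::aes(x = mid, y = count)) +
      ggplot2::geom_col(width = width, fill = "steelblue", colour = "grey30",
                        linewidth = 0.2) +
      ggplot2::coord_polar(start = -pi / 2, direction = -1) +
      ggplot2::scale_x_continuous(limits = c(0, 360),
                                  breaks = seq(0, 330, 30)) +
      ggplot2::labs(x = NULL, y = "cells",
                    subtitle = sprintf("%s (n = %d, CV = %.2f)", a$scope,
                                       a$n_cells, a$cv)) +
      ggplot2::theme_minimal()
  })

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(file.path(dir, "elongation.png"), p_ef, width = 5,
                    height = 4, dpi = 150)
    for (nm in names(roses)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
      ggplot2::ggsave(file.path(dir, paste0("rose_", safe, ".png")),
                      roses[[nm]], width = 4, height = 4, dpi = 150)
    }
    return(invisible(list(elongation = p_ef, roses = roses)))
  }
  list(elongation = p_ef, roses = roses)
}
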