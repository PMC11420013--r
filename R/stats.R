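# Rank-based group comparisons: two-tailed Mann-Whitney U for two groups,
# Kruskal-Wallis for three or more, Dunn's pairwise post hoc with multiplicity
# adjustment. Test engines are the base-R implementations; Dunn's z is
# computed here from pooled ranks with the standard tie correction.

#' Two-tailed Mann-Whitney U test
#'
#' Exact enumeration when the pooled sample size is at most 12 and there are
#' no ties; otherwise the tie-corrected normal approximation with continuity
#' correction. The reported statistic is U for the first sample.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list of class `stat_result`: `method`, `groups`, `statistic` (U),
#'   `p_value`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact p = 0.1
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney_u() requires two non-empty groups")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero rank variance: every value tied across groups
  structure(list(method = if (use_exact) "mann_whitney_exact"
                 else "mann_whitney_normal",
                 groups = c("x", "y"),
                 statistic = unname(wt$statistic),  # W == U for sample x
                 p_value = min(p, 1)),
            class = "stat_result")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-squared reference on k-1 degrees of freedom.
#' Intended for three or more groups; two groups are tolerated with a
#' warning (the Mann-Whitney test is the usual choice there).
#'
#' @param groups list of non-empty numeric vectors, named or not.
#' @return list of class `stat_result` with `statistic` (H) and `p_value`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 32/7
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) {
    stop("kruskal_wallis() requires non-empty groups")
  }
  if (length(groups) == 2L) {
    warning("kruskal_wallis() with 2 groups; consider mann_whitney_u()")
  }
  labels <- if (is.null(names(groups))) paste0("g", seq_along(groups))
            else names(groups)
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  p <- unname(kt$p.value)
  if (is.nan(H)) { H <- 0; p <- 1 }  # all values tied across every group
  structure(list(method = "kruskal_wallis", groups = labels,
                 statistic = H, p_value = p),
            class = "stat_result")
}

#' Dunn's post hoc pairwise comparisons
#'
#' For every pair of groups, the z statistic from pooled-rank means with the
#' standard tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups, and a two-sided p adjusted for
#' multiplicity (Bonferroni over all pairs by default).
#'
#' @inheritParams kruskal_wallis
#' @param adjustment a method accepted by [stats::p.adjust()]; default
#'   `"bonferroni"`.
#' @return data frame with `group_a`, `group_b`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjustment = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) {
    stop("dunn_posthoc() requires non-empty groups")
  }
  labels <- if (is.null(names(groups))) paste0("g", seq_along(groups))
            else names(groups)
  values <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_along(groups), lengths(groups))
  rk <- rank(values)
  N <- length(values)
  rbar <- tapply(rk, gidx, mean)
  n <- lengths(groups)
  tie_counts <- table(values)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(length(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
             z = z, p_unadjusted = p,
             p_adjusted = pmin(p.adjust(p, method = adjustment), 1))
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (groups: %s)\n", x$method,
              x$statistic, x$p_value, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Significance stars for a p value
#'
#' The conventional four-tier annotation: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001, `ns` otherwise.
#'
#' @param p numeric vector of p values.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
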