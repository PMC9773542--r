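## Cohort-level statistical comparisons.
##
## Policy: two-tailed Mann-Whitney U when either group is small (fewer
## than `smallNCutoff` observations), otherwise Welch's t test; Student's
## t test available by explicit request (the convention used for calcium
## kinetics and qPCR-style comparisons). Two-sided throughout; no
## multiple-testing correction is applied.

#' Significance stars for a p value
#'
#' Thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, otherwise `ns`.
#'
#' @param p p value(s) in [0, 1].
#' @return character vector of labels.
#' @examples
#' significanceStars(c(0.2, 0.04, 0.0009))
#' @export
significanceStars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  vapply(p, function(pp) {
    if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare one metric between two groups
#'
#' Applies the small-sample policy: a two-sided Mann-Whitney U test
#' (exact when both groups are below 50 and tie-free, normal
#' approximation with continuity correction otherwise) when
#' `min(n) < smallNCutoff`, else Welch's two-sided t test. `test`
#' overrides the policy; `"student_t"` gives the pooled-variance t test.
#' The test actually used is always recorded.
#'
#' @param x,y numeric samples (each with at least 2 values).
#' @param smallNCutoff group size below which the rank test is used
#'   (default 8; configurable, always reported).
#' @param test "auto" (policy), "mann_whitney", "welch_t" or "student_t".
#' @param metric optional metric name carried into the output.
#' @param labels length-2 group labels.
#' @return one-row data.frame of class `GroupComparison`: metric, group1,
#'   group2, n1, n2, test, statistic, p_value, stars, small_n_cutoff.
#' @examples
#' compareTwoGroups(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))  # exact p = 2/252
#' @export
compareTwoGroups <- function(x, y, smallNCutoff = 8,
                             test = c("auto", "mann_whitney", "welch_t",
                                      "student_t"),
                             metric = NA_character_,
                             labels = c("group1", "group2")) {
  test <- match.arg(test)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 non-missing values")
  if (test == "auto")
    test <- if (min(length(x), length(y)) < smallNCutoff)
      "mann_whitney" else "welch_t"
  res <- switch(test,
    mann_whitney = {
      ht <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided"))
      list(stat = unname(ht$statistic), p = ht$p.value)
    },
    welch_t = {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      list(stat = unname(ht$statistic), p = ht$p.value)
    },
    student_t = {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      list(stat = unname(ht$statistic), p = ht$p.value)
    })
  out <- data.frame(metric = metric, group1 = labels[1L],
                    group2 = labels[2L],
                    n1 = length(x), n2 = length(y), test = test,
                    statistic = res$stat, p_value = res$p,
                    stars = significanceStars(min(res$p, 1)),
                    small_n_cutoff = smallNCutoff,
                    stringsAsFactors = FALSE)
  class(out) <- c("GroupComparison", class(out))
  out
}

#' Cohort comparison table across metrics and strata
#'
#' Compares every non-reference group against the reference group for
#' each metric, separately within each stratum (typically the week), the
#' layout of a per-figure comparison table.
#'
#' @param data long data.frame of per-organoid metrics.
#' @param metrics character vector of metric column names.
#' @param groupCol grouping column name (default "group").
#' @param refGroup reference level; default the first level encountered.
#' @param by optional stratification column (e.g. "week").
#' @param ... passed to [compareTwoGroups()] (policy settings).
#' @return data.frame, one row per metric x group x stratum, with the
#'   stratum in a `by` column when requested.
#' @export
compareCohort <- function(data, metrics, groupCol = "group",
                          refGroup = NULL, by = NULL, ...) {
  stopifnot(groupCol %in% names(data), all(metrics %in% names(data)))
  groups <- unique(data[[groupCol]])
  if (is.null(refGroup)) refGroup <- groups[1L]
  others <- setdiff(groups, refGroup)
  strata <- if (is.null(by)) list(NULL) else unique(data[[by]])
  rows <- list()
  for (s in strata) {
    d <- if (is.null(by)) data else data[data[[by]] == s, , drop = FALSE]
    for (m in metrics) {
      for (g in others) {
        cmp <- compareTwoGroups(d[[m]][d[[groupCol]] == refGroup],
                                d[[m]][d[[groupCol]] == g],
                                metric = m, labels = c(refGroup, g), ...)
        if (!is.null(by)) cmp[[by]] <- s
        rows[[length(rows) + 1L]] <- cmp
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
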