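#' Nonparametric group comparison
#'
#' Two groups: two-sided Wilcoxon rank-sum; three or more: Kruskal-Wallis.
#' Both tie-corrected (delegated to `stats::wilcox.test` /
#' `stats::kruskal.test`; the rank-sum uses exact enumeration for small
#' untied groups and the normal approximation otherwise, matching base R's
#' switch at n = 50).
#'
#' @param values numeric vector.
#' @param labels group labels, same length, >= 2 groups with >= 1 value each.
#' @return list with `statistic_name`, `statistic`, `p`, `group_sizes`.
#' @export
compare_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.factor(as.character(labels))
  sizes <- table(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (nlevels(labels) == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(values[labels == levels(labels)[1]],
        values[labels == levels(labels)[2]])
    )
    p <- if (is.nan(ht$p.value)) 1 else ht$p.value
    list(statistic_name = "wilcoxon", statistic = unname(ht$statistic),
      p = p, group_sizes = as.vector(sizes))
  } else {
    ht <- stats::kruskal.test(values, labels)
    list(statistic_name = "kruskal", statistic = unname(ht$statistic),
      p = ht$p.value, group_sizes = as.vector(sizes))
  }
}

#' Batch multiple-testing adjustment
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param method `"bh"` (Benjamini-Hochberg step-up, default) or
#'   `"bonferroni"`.
#' @return adjusted q-values in the input order.
#' @export
adjust_batch <- function(p_values, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, if (method == "bh") "BH" else "bonferroni")
}
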