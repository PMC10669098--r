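#' Per-sample relative abundance of cell subtypes
#'
#' Relative abundance of a subtype in a sample is the number of its cells
#' divided by the number of cells of its parent major type in the same
#' sample; samples where the major type is absent get `NA` (missing, not 0).
#'
#' @param ann a [cell_annotation()].
#' @param tissue one of `"tumor"`, `"normal"`, `"both"`.
#' @return samples x subtypes numeric matrix with a `major_of` attribute
#'   (named character: subtype -> major type).
#' @export
relative_abundance <- function(ann, tissue = c("tumor", "normal", "both")) {
  tissue <- match.arg(tissue)
  ann <- cell_annotation(ann)
  if (tissue != "both") ann <- ann[ann$tissue == tissue, , drop = FALSE]
  if (!nrow(ann)) stop("no samples pass the tissue filter '", tissue, "'")

  samples <- sort(unique(ann$sample_id))
  parent <- unique(ann[, c("subtype", "major_type")])
  subtypes <- sort(parent$subtype)
  major_of <- stats::setNames(parent$major_type, parent$subtype)[subtypes]

  n_sub <- table(factor(ann$sample_id, samples), factor(ann$subtype, subtypes))
  n_major <- table(factor(ann$sample_id, samples),
    factor(ann$major_type, unique(major_of)))
  denom <- n_major[, major_of[subtypes], drop = FALSE]
  ab <- unclass(n_sub) / unclass(denom)
  ab[unclass(denom) == 0] <- NA_real_
  dimnames(ab) <- list(samples, subtypes)
  attr(ab, "major_of") <- major_of
  ab
}

#' Pairwise Spearman correlation of subtype abundances
#'
#' Spearman correlation (tie-corrected ranks, two-sided p from the t
#' approximation) between every pair of subtype abundance profiles across
#' samples, pairwise-complete, with Benjamini-Hochberg q over all tested
#' pairs. Pairs with fewer than `min_samples` complete samples are skipped
#' with a warning.
#'
#' @param tab abundance matrix from [relative_abundance()].
#' @param min_samples minimum complete samples per pair (default 10).
#' @return data.frame with `subtype_a`, `subtype_b` (a < b), `r`, `n`,
#'   `p_raw`, `q`.
#' @export
correlate_abundance <- function(tab, min_samples = 10) {
  subtypes <- colnames(tab)
  if (length(subtypes) < 3) stop("need at least 3 subtypes")
  pairs <- utils::combn(subtypes, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- tab[, pr[1]]
    y <- tab[, pr[2]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < min_samples) {
      return(data.frame(subtype_a = pr[1], subtype_b = pr[2], r = NA_real_,
        n = sum(ok), p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    data.frame(subtype_a = pr[1], subtype_b = pr[2],
      r = unname(ct$estimate), n = sum(ok), p_raw = ct$p.value,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (anyNA(res$r)) {
    warning(sum(is.na(res$r)), " pair(s) skipped: fewer than ", min_samples,
      " complete samples")
  }
  res$q <- NA_real_
  ok <- !is.na(res$p_raw)
  res$q[ok] <- stats::p.adjust(res$p_raw[ok], "BH")
  res
}

# mean silhouette width of a partition given a full distance matrix
.mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
      function(l) mean(d[i, labels == l]), numeric(1))
    b <- min(bs)
    sil[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

#' Cluster correlated subtypes into subTME modules
#'
#' Builds the full subtype correlation matrix from the edge list, runs
#' average-linkage agglomerative clustering on distance `1 - r`, and cuts at
#' the number of modules maximizing the mean silhouette width over
#' `k in [2, min(10, n_subtypes - 1)]` unless `k` is forced. A subtype whose
#' best within-module edge fails the quality thresholds (`r > r_pos` and
#' `q < q_max`) is flagged weakly assigned rather than removed.
#'
#' @param edges edge list from [correlate_abundance()].
#' @param k optional forced module count.
#' @param r_pos,q_max edge-quality thresholds (defaults 0.3, 0.05).
#' @return object of class `subtme_modules`: data.frame with `module_id`
#'   (`"module1"`, ... in order of first appearance by subtype name),
#'   `subtype`, `weakly_assigned`; attributes `k`, `silhouette`, `cor`.
#' @export
build_modules <- function(edges, k = NULL, r_pos = 0.3, q_max = 0.05) {
  subtypes <- sort(unique(c(edges$subtype_a, edges$subtype_b)))
  n <- length(subtypes)
  if (!is.null(k) && k > n) stop("k exceeds the number of subtypes")
  cm <- diag(1, n)
  dimnames(cm) <- list(subtypes, subtypes)
  ia <- match(edges$subtype_a, subtypes)
  ib <- match(edges$subtype_b, subtypes)
  r <- ifelse(is.na(edges$r), 0, edges$r)
  cm[cbind(ia, ib)] <- r
  cm[cbind(ib, ia)] <- r

  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  sil <- NA_real_
  if (is.null(k)) {
    ks <- seq(2, min(10, n - 1))
    sils <- vapply(ks, function(kk) .mean_silhouette(d, stats::cutree(hc, kk)),
      numeric(1))
    # exact ties (e.g. a structureless correlation matrix) resolve to the
    # finest partition rather than merging unrelated subtypes
    k <- max(ks[sils >= max(sils) - 1e-12])
    sil <- max(sils)
  } else if (k > 1) {
    sil <- .mean_silhouette(d, stats::cutree(hc, k))
  }
  labels <- stats::cutree(hc, k)

  # quality flag: best within-module edge must clear the r/FDR thresholds
  weak <- vapply(seq_len(n), function(i) {
    mates <- setdiff(which(labels == labels[i]), i)
    if (!length(mates)) return(TRUE)
    idx <- (edges$subtype_a == subtypes[i] & edges$subtype_b %in% subtypes[mates]) |
      (edges$subtype_b == subtypes[i] & edges$subtype_a %in% subtypes[mates])
    e <- edges[idx & !is.na(edges$r), , drop = FALSE]
    !any(e$r > r_pos & e$q < q_max)
  }, logical(1))

  # stable module ids in order of first appearance over sorted subtype names
  first <- !duplicated(labels)
  renum <- stats::setNames(seq_len(k), labels[first])
  out <- data.frame(
    module_id = sprintf("module%d", renum[as.character(labels)]),
    subtype = subtypes, weakly_assigned = weak,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("subtme_modules", "data.frame"),
    k = k, silhouette = sil, cor = cm)
}

#' @export
print.subtme_modules <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("subTME modules: %d module(s) over %d subtypes (mean silhouette %.3f)\n",
    k, nrow(x), attr(x, "silhouette")))
  for (m in unique(x$module_id)) {
    memb <- x$subtype[x$module_id == m]
    flag <- x$weakly_assigned[x$module_id == m]
    cat(sprintf("  %s: %s\n", m,
      paste0(memb, ifelse(flag, "*", ""), collapse = ", ")))
  }
  if (any(x$weakly_assigned)) cat("  (* weakly assigned: no edge with r > threshold and q < FDR)\n")
  invisible(x)
}

#' Tumor-vs-normal comparison of a per-sample module score
#'
#' Two-sided Wilcoxon rank-sum test of a score between tumor and normal
#' samples, with the enrichment direction at `alpha`.
#'
#' @param score named numeric vector of per-sample scores.
#' @param tissue named character vector (`"tumor"`/`"normal"`) over the same
#'   samples.
#' @param alpha significance level for the direction call (default 0.05).
#' @return list with `p`, `direction` (`"tumor-enriched"`,
#'   `"normal-enriched"`, `"n.s."`), and the group medians.
#' @export
compare_module_presence <- function(score, tissue, alpha = 0.05) {
  common <- intersect(names(score), names(tissue))
  if (length(common)) {
    score <- score[common]
    tissue <- tissue[common]
  }
  tum <- score[tissue == "tumor"]
  nor <- score[tissue == "normal"]
  if (!length(tum) || !length(nor)) stop("both tissue groups must be non-empty")
  p <- suppressWarnings(stats::wilcox.test(tum, nor, exact = FALSE)$p.value)
  if (is.nan(p)) p <- 1
  dir <- if (p >= alpha) {
    "n.s."
  } else if (stats::median(tum) > stats::median(nor)) {
    "tumor-enriched"
  } else {
    "normal-enriched"
  }
  list(p = p, direction = dir,
    median_tumor = stats::median(tum), median_normal = stats::median(nor))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors over the same items.
#' @return the adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
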