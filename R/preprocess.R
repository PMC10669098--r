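#' Quality-control thresholds
#'
#' @param min_cells_per_gene genes expressed by fewer cells are dropped (50).
#' @param min_genes_per_cell,max_genes_per_cell cells whose expressed-gene
#'   count falls outside `[min, max]` are dropped (200, 6000).
#' @param max_mito_fraction cells with a higher mitochondrial count fraction
#'   are dropped (0.20).
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 50, min_genes_per_cell = 200,
                          max_genes_per_cell = 6000, max_mito_fraction = 0.20,
                          mito_prefix = "MT-") {
  stopifnot(
    min_genes_per_cell > 0, min_genes_per_cell < max_genes_per_cell,
    max_mito_fraction > 0, max_mito_fraction <= 1
  )
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Filter genes and cells on standard QC rules
#'
#' Removes genes expressed in fewer than `min_cells_per_gene` cells, then
#' cells whose expressed-gene count lies outside
#' `[min_genes_per_cell, max_genes_per_cell]` or whose mitochondrial count
#' fraction exceeds `max_mito_fraction`. The gene filter is computed before
#' the cell filter, but the mitochondrial fraction uses the pre-filter totals
#' so dropping mitochondrial-poor genes cannot rescue a dying cell.
#'
#' @param m an `expr_matrix` (counts).
#' @param ann matching [cell_annotation()].
#' @param t a [qc_thresholds()].
#' @return list with the filtered `matrix`, `annotation`, and a `report`
#'   data.frame of removals per rule.
#' @export
qc_filter <- function(m, ann, t = qc_thresholds()) {
  stopifnot(inherits(m, "expr_matrix"), inherits(t, "qc_thresholds"))
  ann <- cell_annotation(ann, m)
  counts <- m$counts
  expressed <- counts > 0

  gene_cells <- Matrix::rowSums(expressed)
  keep_gene <- gene_cells >= t$min_cells_per_gene

  genes_per_cell <- Matrix::colSums(expressed[keep_gene, , drop = FALSE])
  mito <- startsWith(rownames(counts), t$mito_prefix)
  mito_frac <- if (any(mito)) {
    tot <- Matrix::colSums(counts)
    frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1)
    frac
  } else {
    rep(0, ncol(counts))
  }
  low <- genes_per_cell < t$min_genes_per_cell
  high <- genes_per_cell > t$max_genes_per_cell
  mito_bad <- mito_frac > t$max_mito_fraction
  keep_cell <- !(low | high | mito_bad)
  if (!any(keep_cell)) stop("all cells removed by QC filters")

  report <- data.frame(
    rule = c("gene_min_cells", "cell_min_genes", "cell_max_genes", "cell_mito_fraction"),
    removed = c(sum(!keep_gene), sum(low), sum(high), sum(mito_bad))
  )
  mf <- m[keep_gene, keep_cell]
  list(
    matrix = mf,
    annotation = cell_annotation(ann[ann$cell_id %in% observations(mf), ], mf),
    report = report
  )
}

# vectorized two-sided Wilcoxon rank-sum, normal approximation with
# tie-corrected variance, no continuity correction. `ranks` is genes x cells
# (mid-ranks within each gene row), `tiecor` the per-gene sum of (t^3 - t)
# over tie groups, `in_group` a logical cell selector.
.ranksum_p <- function(ranks, tiecor, in_group) {
  n1 <- sum(in_group)
  n2 <- ncol(ranks) - n1
  n <- n1 + n2
  r1 <- rowSums(ranks[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiecor / (n * (n - 1)))
  z <- (u - n1 * n2 / 2) / sqrt(pmax(sigma2, .Machine$double.eps))
  2 * stats::pnorm(-abs(z))
}

#' Per-subtype marker genes by Wilcoxon rank-sum
#'
#' For every subtype with at least `min_cells` cells, tests each gene's
#' normalized expression in the subtype against all other cells with a
#' two-sided tie-corrected rank-sum test (normal approximation), and reports
#' the Seurat-style log fold change
#' `log(mean(expm1(x_in)) + 1) - log(mean(expm1(x_out)) + 1)`.
#' Both Benjamini-Hochberg and Bonferroni adjustments over all tests are
#' reported; retention filters on `pct_in`, `log_fc`, and the configured
#' adjustment.
#'
#' @param m an `expr_matrix` with a normalized layer.
#' @param ann matching [cell_annotation()].
#' @param min_pct minimum fraction of subtype cells expressing (default 0.5).
#' @param min_lfc retain genes with `log_fc` strictly greater (default 0).
#' @param q_max maximum adjusted q (default 0.05).
#' @param adjust which adjusted column the `q_max` filter uses.
#' @param min_cells subtypes with fewer cells are skipped with a warning.
#' @param filter if `FALSE`, return every test instead of the filtered list.
#' @return data.frame with columns `cluster`, `gene`, `pct_in`, `pct_out`,
#'   `log_fc`, `p_raw`, `q_bh`, `q_bonf`, sorted by (cluster, -log_fc).
#' @export
find_markers <- function(m, ann, min_pct = 0.5, min_lfc = 0, q_max = 0.05,
                         adjust = c("bh", "bonferroni"), min_cells = 3,
                         filter = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  adjust <- match.arg(adjust)
  ann <- cell_annotation(ann, m)
  x <- .norm_layer(m)
  x <- x[, ann$cell_id, drop = FALSE]
  dx <- as.matrix(x)

  sizes <- table(ann$subtype)
  usable <- names(sizes)[sizes >= min_cells]
  skipped <- setdiff(names(sizes), usable)
  if (length(skipped)) {
    warning("skipping subtype(s) with < ", min_cells, " cells: ",
      paste(skipped, collapse = ", "))
  }
  if (length(usable) < 2) stop("need at least 2 subtypes with >= ", min_cells, " cells")

  ranks <- t(apply(dx, 1, rank))
  tiecor <- apply(ranks, 1, function(r) {
    tt <- tabulate(match(r, unique(r)))
    sum(tt^3 - tt)
  })
  expressed <- dx > 0

  out <- lapply(sort(usable), function(s) {
    inside <- ann$subtype == s
    p <- .ranksum_p(ranks, tiecor, inside)
    mean_in <- rowMeans(expm1(dx[, inside, drop = FALSE]))
    mean_out <- rowMeans(expm1(dx[, !inside, drop = FALSE]))
    data.frame(
      cluster = s, gene = rownames(dx),
      pct_in = rowMeans(expressed[, inside, drop = FALSE]),
      pct_out = rowMeans(expressed[, !inside, drop = FALSE]),
      log_fc = log(mean_in + 1) - log(mean_out + 1),
      p_raw = p, stringsAsFactors = FALSE, row.names = NULL
    )
  })
  res <- do.call(rbind, out)
  res$q_bh <- stats::p.adjust(res$p_raw, "BH")
  res$q_bonf <- stats::p.adjust(res$p_raw, "bonferroni")
  if (filter) {
    q <- if (adjust == "bh") res$q_bh else res$q_bonf
    res <- res[res$pct_in >= min_pct & res$log_fc > min_lfc & q <= q_max, ,
      drop = FALSE]
  }
  res[order(res$cluster, -res$log_fc), , drop = FALSE]
}

#' Top-n markers per subtype as gene sets
#'
#' Convenience wrapper turning a [find_markers()] table into the per-subtype
#' top-`n` gene sets used for bulk signature scoring.
#'
#' @param markers a marker table from [find_markers()].
#' @param n genes per subtype (default 10).
#' @return named list of gene vectors.
#' @export
top_markers <- function(markers, n = 10) {
  split_tab <- split(markers, markers$cluster)
  lapply(split_tab, function(d) utils::head(d$gene[order(-d$log_fc)], n))
}
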