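#' Expressing-cell fractions of a gene in and out of a subtype
#'
#' "Highly expressing" is defined against a threshold `t`: the lower quartile
#' (linear-interpolation quantile) of the gene's nonzero normalized values
#' within the subtype. `Pgi` is the fraction of subtype cells with value
#' strictly above `t`; `Qgi` is the fraction of all other cells above the
#' same `t` (the threshold is deliberately shared so the two fractions are
#' comparable). A gene with no nonzero value in the subtype is ineligible.
#'
#' @param m an `expr_matrix` with a normalized layer.
#' @param ann matching [cell_annotation()].
#' @param gene gene symbol.
#' @param subtype subtype label.
#' @return list with `Pgi`, `Qgi`, `threshold`, `eligible`.
#' @export
expressing_fraction <- function(m, ann, gene, subtype) {
  stopifnot(inherits(m, "expr_matrix"))
  ann <- cell_annotation(ann, m)
  if (!gene %in% genes(m)) stop("gene not present: ", gene)
  inside <- ann$cell_id[ann$subtype == subtype]
  if (!length(inside)) stop("subtype has no cells: ", subtype)
  x <- .norm_layer(m)[gene, ]
  xin <- x[inside]
  nz <- xin[xin > 0]
  if (!length(nz)) {
    return(list(Pgi = 0, Qgi = NA_real_, threshold = NA_real_, eligible = FALSE))
  }
  t <- stats::quantile(nz, 0.25, names = FALSE, type = 7)
  xout <- x[setdiff(names(x), inside)]
  list(
    Pgi = mean(xin > t),
    Qgi = if (length(xout)) mean(xout > t) else 0,
    threshold = t, eligible = TRUE
  )
}

#' Signature-gene specificity score
#'
#' `Sgi = 1 - Qgi / Pgi`: 1 when no outside cell clears the subtype's
#' expression threshold, 0 when in- and out-fractions match, negative when
#' the gene is more prevalent outside (never selected at the 0.7 cutoff).
#'
#' @param Pgi in-subtype highly-expressing fraction (> 0).
#' @param Qgi out-of-subtype fraction (same threshold).
#' @return the score, a real `<= 1`.
#' @export
signature_gene_score <- function(Pgi, Qgi) {
  stopifnot(all(Pgi >= 0 & Pgi <= 1), all(Qgi >= 0 & Qgi <= 1))
  if (any(Pgi == 0)) stop("Sgi undefined for Pgi = 0 (gene ineligible)")
  1 - Qgi / Pgi
}

#' Build a subtype's signature gene set and score
#'
#' Scores every eligible gene with [expressing_fraction()] +
#' [signature_gene_score()] (vectorized), retains genes with `Sgi > s_min`,
#' and averages their scores into the subtype score `Ssubj`.
#'
#' @param m an `expr_matrix` with a normalized layer.
#' @param ann matching [cell_annotation()].
#' @param subtype subtype label.
#' @param s_min selection cutoff on `Sgi` (default 0.7).
#' @param min_cells guard: subtypes with fewer cells are refused (default 10).
#' @return list of class `subtype_signature` with `subtype`, `genes`
#'   (selected symbols), `Ssubj`, and `table` — all scored genes with `Pgi`,
#'   `Qgi`, `Sgi`, `selected` (negative scores kept for diagnostics).
#' @export
build_subtype_signature <- function(m, ann, subtype, s_min = 0.7, min_cells = 10) {
  stopifnot(inherits(m, "expr_matrix"))
  ann <- cell_annotation(ann, m)
  inside <- ann$cell_id[ann$subtype == subtype]
  if (length(inside) < min_cells) {
    stop("subtype ", subtype, " has fewer than ", min_cells, " cells")
  }
  x <- .norm_layer(m)
  xin <- as.matrix(x[, inside, drop = FALSE])
  xout <- as.matrix(x[, setdiff(colnames(x), inside), drop = FALSE])
  thr <- apply(xin, 1, function(v) {
    nz <- v[v > 0]
    if (!length(nz)) NA_real_ else stats::quantile(nz, 0.25, names = FALSE, type = 7)
  })
  eligible <- !is.na(thr)
  P <- rowMeans(xin > thr)
  Q <- rowMeans(xout > thr)
  tab <- data.frame(
    gene = rownames(xin), Pgi = P, Qgi = Q,
    Sgi = ifelse(eligible & P > 0, 1 - Q / P, NA_real_),
    eligible = eligible & P > 0, stringsAsFactors = FALSE, row.names = NULL
  )
  tab$selected <- !is.na(tab$Sgi) & tab$Sgi > s_min
  if (!any(tab$selected)) {
    stop("no gene passes Sgi > ", s_min, " for subtype ", subtype)
  }
  sel <- tab[tab$selected, , drop = FALSE]
  structure(
    list(subtype = subtype, genes = sel$gene, Ssubj = mean(sel$Sgi), table = tab),
    class = "subtype_signature"
  )
}

#' @export
print.subtype_signature <- function(x, ...) {
  cat(sprintf("subtype signature '%s': %d gene(s), Ssubj = %.3f\n",
    x$subtype, length(x$genes), x$Ssubj))
  invisible(x)
}

#' Per-sample subTME score from subtype signatures and abundances
#'
#' For each sample, `SsubTME = mean over module subtypes of Ssubj * Psubj`,
#' with `Psubj` the subtype's relative abundance in that sample. Subtypes with
#' missing abundance (parent major type absent) are skipped and the divisor
#' reduced; a sample with no usable subtype gets `NA`.
#'
#' @param signatures list of [build_subtype_signature()] results covering the
#'   module's subtypes.
#' @param abundance matrix from [relative_abundance()].
#' @param module character vector of the module's subtype names.
#' @return data.frame with `sample_id`, `score`, `n_subtypes` (used per
#'   sample), `incomplete` flag.
#' @export
subtme_score <- function(signatures, abundance, module) {
  names(signatures) <- vapply(signatures, `[[`, "", "subtype")
  missing_sig <- setdiff(module, names(signatures))
  if (length(missing_sig)) {
    stop("no signature for subtype(s): ", paste(missing_sig, collapse = ", "))
  }
  missing_ab <- setdiff(module, colnames(abundance))
  if (length(missing_ab)) {
    stop("no abundance column for subtype(s): ", paste(missing_ab, collapse = ", "))
  }
  ssub <- vapply(signatures[module], `[[`, numeric(1), "Ssubj")
  contrib <- sweep(abundance[, module, drop = FALSE], 2, ssub, `*`)
  n_used <- rowSums(!is.na(contrib))
  score <- rowSums(contrib, na.rm = TRUE) / n_used
  score[n_used == 0] <- NA_real_
  data.frame(
    sample_id = rownames(abundance), score = unname(score),
    n_subtypes = unname(n_used), incomplete = unname(n_used < length(module)),
    stringsAsFactors = FALSE
  )
}

#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Ranks the expression vector descending (ties broken by gene name so the
#' score is deterministic and invariant under monotone transforms), then
#' accumulates a running statistic whose in-set increments are
#' rank-weighted (`rank^alpha`, normalized over the set) and whose out-set
#' decrements are uniform. The score is the sum of the running statistic
#' over all positions, optionally divided by the range of the running
#' statistic.
#'
#' @param expr named numeric expression vector (the gene universe).
#' @param gene_set character vector of set genes; genes absent from `expr`
#'   are ignored.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalization `"range"` (default) or `"none"`.
#' @return a single numeric score; positive means enrichment at the top of
#'   the ranking.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25,
                         normalization = c("range", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(alpha >= 0, !is.null(names(expr)))
  gene_set <- intersect(unique(gene_set), names(expr))
  n <- length(expr)
  if (!length(gene_set)) stop("gene set has no overlap with the expression vector")
  if (length(gene_set) >= n) stop("gene set covers the whole gene universe")
  ord <- order(-expr, names(expr))
  in_set <- names(expr)[ord] %in% gene_set
  rk <- n - seq_len(n) + 1 # rank value: N for the top-expressed gene
  w <- rk^alpha * in_set
  steps <- w / sum(w) - (!in_set) / (n - length(gene_set))
  running <- cumsum(steps)
  s <- sum(running)
  if (normalization == "range") s <- s / (max(running) - min(running))
  s
}

#' ssGSEA scores of one gene set across a matrix's samples
#'
#' Applies [ssgsea_score()] to every column and, under the conventional
#' cohort-level `"range"` normalization, divides the score vector by its
#' range across samples (an affine rescaling: rankings and correlations are
#' unchanged).
#'
#' @param x numeric genes x samples matrix.
#' @param gene_set character vector of set genes.
#' @param alpha rank-weight exponent.
#' @param normalization `"range"` (across samples) or `"none"`.
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_matrix <- function(x, gene_set, alpha = 0.25,
                          normalization = c("range", "none")) {
  normalization <- match.arg(normalization)
  s <- apply(x, 2, function(v) ssgsea_score(v, gene_set, alpha, "none"))
  if (normalization == "range" && length(s) > 1) {
    rg <- max(s) - min(s)
    if (rg > 0) s <- s / rg
  }
  s
}

#' Bulk subTME score from top-DEG subtype signatures
#'
#' Scores every sample of a bulk matrix against each subtype signature of a
#' module with ssGSEA (or a mean z-score alternative) and averages across the
#' module's signatures. Signatures overlapping the bulk gene universe in
#' fewer than 2 genes are skipped with a warning.
#'
#' @param bulk an `expr_matrix` with a normalized layer (genes x samples).
#' @param module_signatures named list: subtype -> gene set (e.g. top-10 DEGs
#'   from [top_markers()]).
#' @param method `"ssgsea"` (default) or `"mean_z"`.
#' @param alpha,normalization passed to [ssgsea_matrix()].
#' @return data.frame with `sample_id` and `score`.
#' @export
bulk_subtme_score <- function(bulk, module_signatures,
                              method = c("ssgsea", "mean_z"),
                              alpha = 0.25, normalization = "range") {
  stopifnot(inherits(bulk, "expr_matrix"))
  method <- match.arg(method)
  x <- as.matrix(.norm_layer(bulk))
  keep <- vapply(module_signatures, function(s) sum(toupper(s) %in% rownames(x)) >= 2,
    logical(1))
  if (!all(keep)) {
    warning("skipping signature(s) with < 2 genes in bulk: ",
      paste(names(module_signatures)[!keep], collapse = ", "))
  }
  module_signatures <- module_signatures[keep]
  if (!length(module_signatures)) stop("no signature overlaps the bulk matrix")
  per_sig <- vapply(module_signatures, function(s) {
    s <- toupper(s)
    if (method == "ssgsea") {
      ssgsea_matrix(x, s, alpha, normalization)
    } else {
      z <- t(scale(t(x[intersect(s, rownames(x)), , drop = FALSE])))
      z[is.nan(z)] <- 0
      colMeans(z)
    }
  }, numeric(ncol(x)))
  data.frame(sample_id = colnames(x), score = rowMeans(per_sig),
    stringsAsFactors = FALSE)
}
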