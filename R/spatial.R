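#' Per-spot signature scores for two gene signatures
#'
#' Scores every spot of a spatial expression matrix against two signatures
#' with [ssgsea_score()].
#'
#' @param spots an `expr_matrix` (genes x spots) with a normalized layer.
#' @param sig_a,sig_b gene-symbol vectors (>= 2 genes present each).
#' @param coordinates optional data.frame (`spot_id`, `x`, `y`).
#' @param alpha,normalization passed to [ssgsea_matrix()].
#' @return data.frame with `spot_id`, optional `x`/`y`, `score_a`, `score_b`.
#' @export
spot_signature_scores <- function(spots, sig_a, sig_b, coordinates = NULL,
                                  alpha = 0.25, normalization = "range") {
  stopifnot(inherits(spots, "expr_matrix"))
  x <- as.matrix(.norm_layer(spots))
  for (s in list(a = sig_a, b = sig_b)) {
    if (sum(toupper(s) %in% rownames(x)) < 2) {
      stop("signature overlaps fewer than 2 genes of the spot matrix")
    }
  }
  score <- function(sig) ssgsea_matrix(x, toupper(sig), alpha, normalization)
  out <- data.frame(spot_id = colnames(x), score_a = score(sig_a),
    score_b = score(sig_b), stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(coordinates)) {
    out <- merge(coordinates, out, by = "spot_id", sort = FALSE)
  }
  out
}

#' Spatial co-localization of two signature score fields
#'
#' Spearman correlation of the two per-spot scores.
#'
#' @param s a [spot_signature_scores()] data.frame (>= 10 spots).
#' @return list with `r` and two-sided `p`.
#' @export
colocalization <- function(s) {
  if (nrow(s) < 10) stop("need at least 10 spots")
  if (stats::sd(s$score_a) == 0 || stats::sd(s$score_b) == 0) {
    stop("constant score vector: correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(s$score_a, s$score_b, method = "spearman", exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spot-level co-expression of a gene pair
#'
#' Spearman correlation of two genes' normalized expression across spots,
#' plus a per-spot co-expression flag (both values > 0).
#'
#' @param spots an `expr_matrix` with a normalized layer.
#' @param gene_a,gene_b gene symbols.
#' @return list with `r`, `p`, and `flags` — data.frame (`spot_id`,
#'   `coexpressed`).
#' @export
gene_pair_coexpression <- function(spots, gene_a, gene_b) {
  stopifnot(inherits(spots, "expr_matrix"))
  x <- .norm_layer(spots)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(x)) stop("gene absent: ", g)
  }
  a <- as.numeric(x[gene_a, ])
  b <- as.numeric(x[gene_b, ])
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(
    r = unname(ct$estimate), p = ct$p.value,
    flags = data.frame(spot_id = colnames(x), coexpressed = a > 0 & b > 0,
      stringsAsFactors = FALSE)
  )
}
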