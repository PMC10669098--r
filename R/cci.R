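.pair_components <- function(pair) {
  if (is.data.frame(pair)) {
    list(ligand = toupper(pair$ligand[[1]]), receptor = toupper(pair$receptor[[1]]),
      pair_id = pair$pair_id[[1]])
  } else {
    list(ligand = toupper(pair$ligand), receptor = toupper(pair$receptor),
      pair_id = if (is.null(pair$pair_id)) NA_character_ else pair$pair_id)
  }
}

#' Ligand-receptor interaction score for one subtype pair
#'
#' The ligand summary is the mean normalized expression of the ligand in the
#' sender cells (for multi-component complexes, the minimum over component
#' means); the receptor summary likewise in the receiver cells. The score is
#' their arithmetic mean, gated to 0 if any component is expressed in fewer
#' than `min_expr_frac` of the cells on its side.
#'
#' @param m an `expr_matrix` with a normalized layer.
#' @param ann matching [cell_annotation()].
#' @param pair a single-row `lr_database` slice or a list with `ligand` /
#'   `receptor` component vectors.
#' @param sender,receiver subtype labels (>= 10 cells each).
#' @param min_expr_frac expressing-cell gate (default 0.1).
#' @return list with `score`, `ligand_summary`, `receptor_summary`, `gated`.
#' @export
interaction_score <- function(m, ann, pair, sender, receiver, min_expr_frac = 0.1) {
  stopifnot(inherits(m, "expr_matrix"))
  ann <- cell_annotation(ann, m)
  cmp <- .pair_components(pair)
  absent <- setdiff(c(cmp$ligand, cmp$receptor), genes(m))
  if (length(absent)) stop("pair gene(s) absent: ", paste(absent, collapse = ", "))
  x <- .norm_layer(m)
  side <- function(components, subtype) {
    cells <- ann$cell_id[ann$subtype == subtype]
    if (length(cells) < 10) stop("subtype ", subtype, " has fewer than 10 cells")
    sub <- x[components, cells, drop = FALSE]
    list(summary = min(Matrix::rowMeans(sub)),
      min_frac = min(Matrix::rowMeans(sub > 0)))
  }
  lig <- side(cmp$ligand, sender)
  rec <- side(cmp$receptor, receiver)
  gated <- lig$min_frac < min_expr_frac || rec$min_frac < min_expr_frac
  list(
    score = if (gated) 0 else (lig$summary + rec$summary) / 2,
    ligand_summary = lig$summary, receptor_summary = rec$summary, gated = gated
  )
}

#' Permutation significance of L-R interactions over all subtype pairs
#'
#' Scores every (sender, receiver) ordered subtype pair for every database
#' pair, then builds a null by shuffling the subtype labels of the
#' participating cells `n_perm` times and recomputing the mean-based score
#' (the expression gate applies to the observed score only). The p-value uses
#' the add-one estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`; an
#' observed score of 0 gets `p = 1` by convention. Benjamini-Hochberg q over
#' all tests.
#'
#' @param m an `expr_matrix` with a normalized layer.
#' @param ann matching [cell_annotation()].
#' @param pairs an `lr_database` (see [read_lr_database()]).
#' @param n_perm number of label permutations (default 1000; < 100 warns,
#'   < 10 errors).
#' @param seed integer seed for the permutations.
#' @param subtypes optional subtype subset (e.g. one module's members).
#' @param min_cells subtypes with fewer cells are excluded (default 10).
#' @param min_expr_frac expressing-cell gate on observed scores.
#' @return data.frame of class `interaction_scores`: `pair_id`, `sender`,
#'   `receiver`, `score`, `p`, `q`.
#' @export
permutation_test <- function(m, ann, pairs, n_perm = 1000, seed = 1L,
                             subtypes = NULL, min_cells = 10,
                             min_expr_frac = 0.1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (n_perm < 10) stop("n_perm must be at least 10")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  ann <- cell_annotation(ann, m)
  if (!is.null(subtypes)) ann <- ann[ann$subtype %in% subtypes, , drop = FALSE]
  sizes <- table(ann$subtype)
  keep <- names(sizes)[sizes >= min_cells]
  if (length(keep) < 2) stop("need at least 2 subtypes with >= ", min_cells, " cells")
  ann <- ann[ann$subtype %in% keep, , drop = FALSE]

  glist <- lapply(seq_len(nrow(pairs)), function(i) .pair_components(pairs[i, ]))
  present <- vapply(glist, function(g) all(c(g$ligand, g$receptor) %in% genes(m)),
    logical(1))
  if (!all(present)) {
    warning("skipping ", sum(!present), " pair(s) with absent gene(s)")
    glist <- glist[present]
  }
  if (!length(glist)) stop("no testable pairs")
  used_genes <- unique(unlist(lapply(glist, function(g) c(g$ligand, g$receptor))))
  x <- as.matrix(.norm_layer(m)[used_genes, ann$cell_id, drop = FALSE])
  lab <- factor(ann$subtype, sort(keep))
  K <- nlevels(lab)
  n_cells <- ncol(x)
  n_per <- tabulate(lab, K)

  grp_means <- function(labels_int) {
    ind <- Matrix::sparseMatrix(i = seq_len(n_cells), j = labels_int, x = 1,
      dims = c(n_cells, K))
    sweep(as.matrix(x %*% ind), 2, n_per, `/`)
  }
  obs_mean <- grp_means(as.integer(lab))
  obs_frac <- sweep(as.matrix((x > 0) %*% Matrix::sparseMatrix(
    i = seq_len(n_cells), j = as.integer(lab), x = 1, dims = c(n_cells, K)
  )), 2, n_per, `/`)
  colnames(obs_mean) <- colnames(obs_frac) <- levels(lab)

  set.seed(seed)
  # one big multiply: genes x (K * n_perm) null group means
  ind_i <- rep(seq_len(n_cells), n_perm)
  ind_j <- unlist(lapply(seq_len(n_perm), function(b) {
    as.integer(lab)[sample.int(n_cells)] + (b - 1L) * K
  }))
  big <- Matrix::sparseMatrix(i = ind_i, j = ind_j, x = 1,
    dims = c(n_cells, K * n_perm))
  null_means <- as.matrix(x %*% big)
  null_means <- sweep(null_means, 2, rep(n_per, n_perm), `/`)
  dim(null_means) <- c(length(used_genes), K, n_perm)
  dimnames(null_means) <- list(used_genes, levels(lab), NULL)

  combos <- expand.grid(sender = levels(lab), receiver = levels(lab),
    stringsAsFactors = FALSE)
  res <- lapply(glist, function(g) {
    lig_obs <- apply(obs_mean[g$ligand, , drop = FALSE], 2, min)
    rec_obs <- apply(obs_mean[g$receptor, , drop = FALSE], 2, min)
    lig_ok <- apply(obs_frac[g$ligand, , drop = FALSE], 2, min) >= min_expr_frac
    rec_ok <- apply(obs_frac[g$receptor, , drop = FALSE], 2, min) >= min_expr_frac
    lig_null <- apply(null_means[g$ligand, , , drop = FALSE], c(2, 3), min)
    rec_null <- apply(null_means[g$receptor, , , drop = FALSE], c(2, 3), min)
    out <- combos
    out$pair_id <- g$pair_id
    sc <- (lig_obs[combos$sender] + rec_obs[combos$receiver]) / 2
    gated <- !(lig_ok[combos$sender] & rec_ok[combos$receiver])
    out$score <- ifelse(gated, 0, sc)
    null_sc <- (lig_null[combos$sender, , drop = FALSE] +
      rec_null[combos$receiver, , drop = FALSE]) / 2
    ge <- rowSums(null_sc >= sc)
    out$p <- ifelse(out$score == 0, 1, (1 + ge) / (1 + n_perm))
    out
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, "BH")
  res <- res[, c("pair_id", "sender", "receiver", "score", "p", "q")]
  res <- res[order(res$pair_id, res$sender, res$receiver), ]
  rownames(res) <- NULL
  class(res) <- c("interaction_scores", "data.frame")
  res
}

#' Count significant interactions per subtype pair
#'
#' @param scores an `interaction_scores` table from [permutation_test()].
#' @param alpha significance threshold on the permutation p (default 0.05).
#' @return subtype x subtype integer matrix of counts for ordered
#'   (sender, receiver) pairs, with attribute `total` — the symmetrized
#'   count matrix `counts + t(counts)` (diagonal not doubled).
#' @export
count_interactions <- function(scores, alpha = 0.05) {
  subtypes <- sort(unique(c(scores$sender, scores$receiver)))
  counts <- matrix(0L, length(subtypes), length(subtypes),
    dimnames = list(sender = subtypes, receiver = subtypes))
  sig <- scores[scores$p < alpha, , drop = FALSE]
  if (nrow(sig)) {
    tab <- table(factor(sig$sender, subtypes), factor(sig$receiver, subtypes))
    counts[] <- as.integer(tab)
  }
  total <- counts + t(counts)
  diag(total) <- diag(counts)
  attr(counts, "total") <- total
  counts
}

#' Subsample cells per subtype
#'
#' Uniform sampling without replacement, keeping all cells of subtypes
#' smaller than `per_subtype`; deterministic given the seed.
#'
#' @param ann a [cell_annotation()].
#' @param per_subtype cells to keep per subtype (>= 10).
#' @param seed integer seed.
#' @return the subsampled annotation (original row order preserved).
#' @export
subsample_cells <- function(ann, per_subtype = 300, seed = 1L) {
  stopifnot(per_subtype >= 10)
  ann <- cell_annotation(ann)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(ann)), ann$subtype), function(idx) {
    if (length(idx) <= per_subtype) idx else sort(sample(idx, per_subtype))
  }))
  cell_annotation(ann[sort(keep), , drop = FALSE])
}

#' Specificity ranking of L-R pairs by coefficient of variation
#'
#' For each cell subtype, the `top_n` highest-scoring interactions it
#' participates in (as sender or receiver; ties broken by pair_id, then
#' sender/receiver name) are retained. Every retained pair is then scored by
#' the coefficient of variation (population SD / mean, zeros included) of its
#' score vector across all subtype pairs; pairs with mean score 0 are dropped
#' with a warning. Output is sorted by cv descending.
#'
#' @param scores an `interaction_scores` table.
#' @param top_n interactions kept per subtype (default 100).
#' @return data.frame with `pair_id`, `cv`, `mean_score`, `top_sender`,
#'   `top_receiver` (the subtype pair where the pair scores highest).
#' @export
specificity_filter <- function(scores, top_n = 100) {
  if (length(unique(paste(scores$sender, scores$receiver))) < 2) {
    stop("need scores over at least 2 subtype pairs")
  }
  scores <- scores[order(-scores$score, scores$pair_id, scores$sender,
    scores$receiver), , drop = FALSE]
  subtypes <- unique(c(scores$sender, scores$receiver))
  retained <- unique(unlist(lapply(subtypes, function(s) {
    idx <- which(scores$sender == s | scores$receiver == s)
    scores$pair_id[utils::head(idx, top_n)]
  })))
  out <- lapply(sort(retained), function(pid) {
    v <- scores[scores$pair_id == pid, , drop = FALSE]
    mu <- mean(v$score)
    if (mu == 0) {
      return(NULL)
    }
    sdev <- sqrt(mean((v$score - mu)^2)) # population SD
    best <- v[which.max(v$score), ]
    data.frame(pair_id = pid, cv = sdev / mu, mean_score = mu,
      top_sender = best$sender, top_receiver = best$receiver,
      stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped) warning(dropped, " pair(s) with mean score 0 dropped")
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no pair has a nonzero mean score")
  out <- out[order(-out$cv, out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
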