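make_qc_matrix <- function() {
  # 250 ubiquitous genes + 1 rare gene; 10 cells with crafted profiles
  set.seed(11)
  genes <- c(sprintf("G%03d", 1:250), "RARE", "MT-CO1")
  counts <- matrix(1L, length(genes), 10,
    dimnames = list(genes, sprintf("c%02d", 1:10)))
  counts["RARE", ] <- 0L
  counts["RARE", 1] <- 5L
  counts["MT-CO1", ] <- 1L
  counts[, 2] <- 0L
  counts[1:100, 2] <- 1L # cell 2 expresses only 100 genes
  counts["MT-CO1", 3] <- 200L # cell 3: mito fraction 200/451 > 0.2
  ann <- data.frame(cell_id = colnames(counts), sample_id = "s1",
    tissue = "tumor", major_type = "M",
    subtype = rep(c("A", "B"), 5), stringsAsFactors = FALSE)
  list(m = expression_matrix(counts), ann = cell_annotation(ann))
}

test_that("qc_filter applies the gene, gene-count and mito rules", {
  d <- make_qc_matrix()
  t <- qc_thresholds(min_cells_per_gene = 5, min_genes_per_cell = 200,
    max_genes_per_cell = 6000, max_mito_fraction = 0.20)
  out <- qc_filter(d$m, d$ann, t)
  expect_false("RARE" %in% genes(out$matrix)) # expressed by 1 < 5 cells
  expect_false("c02" %in% observations(out$matrix)) # 100 < 200 genes
  expect_false("c03" %in% observations(out$matrix)) # 44% mito
  expect_setequal(out$report$rule,
    c("gene_min_cells", "cell_min_genes", "cell_max_genes", "cell_mito_fraction"))
  expect_equal(out$report$removed[out$report$rule == "gene_min_cells"], 1)

  # idempotence: a second pass removes nothing
  out2 <- qc_filter(out$matrix, out$annotation, t)
  expect_identical(as.matrix(out2$matrix$counts), as.matrix(out$matrix$counts))
  expect_equal(sum(out2$report$removed), 0)

  t_all <- qc_thresholds(min_genes_per_cell = 5000, max_genes_per_cell = 6000)
  expect_error(qc_filter(d$m, d$ann, t_all), "all cells removed")
})

test_that("normalization matches log1p(scale * count / total) and is scale invariant", {
  counts <- matrix(c(1L, 99L, 0L, 50L), 2, 2,
    dimnames = list(c("G1", "G2"), c("c1", "c2")))
  m <- normalize_counts(expression_matrix(counts))
  expect_equal(m$normalized["G1", "c1"], log(1 + 1e4 * 1 / 100))
  expect_equal(m$normalized["G1", "c2"], 0)

  doubled <- normalize_counts(expression_matrix(counts * 2L))
  expect_equal(as.matrix(doubled$normalized), as.matrix(m$normalized))

  counts0 <- cbind(counts, c03 = c(0L, 0L))
  expect_warning(m0 <- normalize_counts(expression_matrix(counts0)), "zero total")
  expect_equal(as.numeric(m0$normalized[, "c03"]), c(0, 0))
})

test_that("rank-sum p-values agree with stats::wilcox.test and are rank invariant", {
  set.seed(21)
  n <- 60
  counts <- matrix(rpois(20 * n, 4), 20,
    dimnames = list(sprintf("G%02d", 1:20), sprintf("c%02d", 1:n)))
  m <- normalize_counts(expression_matrix(counts))
  ann <- cell_annotation(data.frame(
    cell_id = colnames(counts), sample_id = "s1", tissue = "tumor",
    major_type = "M", subtype = rep(c("A", "B"), each = n / 2)
  ), m)
  res <- find_markers(m, ann, filter = FALSE)
  res_a <- res[res$cluster == "A", ]
  x <- as.matrix(m$normalized)
  for (g in c("G01", "G07", "G13")) {
    ref <- stats::wilcox.test(x[g, 1:(n / 2)], x[g, (n / 2 + 1):n],
      exact = FALSE, correct = FALSE)$p.value
    expect_equal(res_a$p_raw[res_a$gene == g], ref, tolerance = 1e-12)
  }

  # strictly monotone transform of expression leaves p unchanged
  m2 <- m
  m2$normalized <- m$normalized^3
  res2 <- find_markers(m2, ann, filter = FALSE)
  expect_equal(res2$p_raw[order(res2$gene, res2$cluster)],
    res$p_raw[order(res$gene, res$cluster)], tolerance = 1e-12)
})

test_that("planted markers are retained and tiny clusters are skipped", {
  set.seed(31)
  n_in <- 200; n_out <- 1800
  genes <- c("PLANT", sprintf("N%02d", 1:30))
  counts <- matrix(0L, length(genes), n_in + n_out,
    dimnames = list(genes, sprintf("c%04d", seq_len(n_in + n_out))))
  p_expr <- c(rep(0.9, n_in), rep(0, n_out))
  counts["PLANT", ] <- rbinom(n_in + n_out, 1, p_expr) *
    (1L + rpois(n_in + n_out, 4))
  for (g in genes[-1]) {
    counts[g, ] <- rbinom(n_in + n_out, 1, 0.5) * rpois(n_in + n_out, 3)
  }
  m <- normalize_counts(expression_matrix(counts))
  ann <- cell_annotation(data.frame(
    cell_id = colnames(counts), sample_id = "s1", tissue = "tumor",
    major_type = "M",
    subtype = c(rep("IN", n_in), rep("OUT", n_out))
  ), m)
  mk <- find_markers(m, ann)
  expect_true(any(mk$cluster == "IN" & mk$gene == "PLANT"))
  expect_false("PLANT" %in% mk$gene[mk$cluster == "OUT"])

  ann2 <- ann
  ann2$subtype[1:2] <- "TINY"
  ann2 <- cell_annotation(ann2, m)
  expect_warning(find_markers(m, ann2), "TINY")
})

test_that("top_markers extracts the highest-fold-change genes per cluster", {
  tab <- data.frame(
    cluster = rep(c("A", "B"), each = 3),
    gene = c("g1", "g2", "g3", "h1", "h2", "h3"),
    log_fc = c(3, 1, 2, 0.5, 2, 1)
  )
  top <- top_markers(tab, 2)
  expect_equal(top$A, c("g1", "g3"))
  expect_equal(top$B, c("h2", "h3"))
})
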