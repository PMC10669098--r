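# small in-code fixtures shared across test files

# deterministic toy matrix: 6 genes x 8 cells, two subtypes in one major type
toy_dataset <- function() {
  counts <- matrix(0L, 6, 8, dimnames = list(
    c("MARKA", "MARKB", "HOUSE", "MT-ND1", "LIGX", "RECX"),
    sprintf("c%02d", 1:8)
  ))
  counts["MARKA", 1:4] <- c(4L, 6L, 5L, 7L)
  counts["MARKB", 5:8] <- c(3L, 5L, 4L, 6L)
  counts["HOUSE", ] <- 2L
  counts["MT-ND1", ] <- 1L
  counts["LIGX", 1:4] <- 3L
  counts["RECX", 5:8] <- 3L
  m <- normalize_counts(expression_matrix(counts))
  ann <- data.frame(
    cell_id = colnames(counts),
    sample_id = rep(c("s1", "s2"), 4),
    tissue = rep(c("tumor", "normal"), each = 4),
    major_type = "T",
    subtype = rep(c("A", "B"), each = 4),
    stringsAsFactors = FALSE
  )
  list(matrix = m, annotation = cell_annotation(ann, m))
}

# build an lr_database in code (components given as "G1+G2" strings)
make_lr_db <- function(pair_id, ligand, receptor) {
  db <- data.frame(pair_id = pair_id, stringsAsFactors = FALSE)
  db$ligand <- strsplit(toupper(ligand), "+", fixed = TRUE)
  db$receptor <- strsplit(toupper(receptor), "+", fixed = TRUE)
  class(db) <- c("lr_database", "data.frame")
  db
}

# two-subtype matrix with one planted L-R pair (ligand scaled `fold`-fold in
# the sender, receptor in the receiver) plus label-independent background
planted_cci_data <- function(seed, n_cells = 200, fold = 3, n_bg = 20) {
  set.seed(seed)
  genes <- c("PLIG", "PREC", sprintf("BGX%02d", seq_len(n_bg)))
  n <- 2 * n_cells
  subtype <- rep(c("SND", "RCV"), each = n_cells)
  counts <- matrix(0L, length(genes), n,
    dimnames = list(genes, sprintf("c%04d", 1:n)))
  mu_lig <- ifelse(subtype == "SND", 2 * fold, 2)
  mu_rec <- ifelse(subtype == "RCV", 2 * fold, 2)
  counts["PLIG", ] <- rbinom(n, 1, 0.5) * rnbinom(n, size = 2, mu = mu_lig)
  counts["PREC", ] <- rbinom(n, 1, 0.5) * rnbinom(n, size = 2, mu = mu_rec)
  for (g in genes[-(1:2)]) {
    counts[g, ] <- rbinom(n, 1, 0.6) * rnbinom(n, size = 2, mu = 3)
  }
  m <- normalize_counts(expression_matrix(counts))
  ann <- data.frame(
    cell_id = colnames(counts), sample_id = "s1", tissue = "tumor",
    major_type = "M", subtype = subtype, stringsAsFactors = FALSE
  )
  list(matrix = m, annotation = cell_annotation(ann, m))
}

# independent brute-force ssGSEA: explicit two-loop running sum
ssgsea_bruteforce <- function(expr, gene_set, alpha = 0.25,
                              normalization = "range") {
  gene_set <- intersect(unique(gene_set), names(expr))
  n <- length(expr)
  ord <- order(-expr, names(expr))
  gs <- names(expr)[ord]
  denom_in <- 0
  for (i in seq_len(n)) {
    if (gs[i] %in% gene_set) denom_in <- denom_in + (n - i + 1)^alpha
  }
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (gs[i] %in% gene_set) {
      acc <- acc + (n - i + 1)^alpha / denom_in
    } else {
      acc <- acc - 1 / (n - length(gene_set))
    }
    running[i] <- acc
  }
  s <- sum(running)
  if (normalization == "range") s <- s / (max(running) - min(running))
  s
}

# brute-force expressing-fraction oracle: loops and explicit quantile
expressing_fraction_bruteforce <- function(x, in_cells, gene) {
  v_in <- x[gene, in_cells]
  nz <- sort(v_in[v_in > 0])
  if (!length(nz)) return(list(Pgi = 0, eligible = FALSE))
  h <- (length(nz) - 1) * 0.25
  lo <- floor(h) + 1
  t <- if (lo >= length(nz)) nz[length(nz)] else nz[lo] + (h - floor(h)) * (nz[lo + 1] - nz[lo])
  out_cells <- setdiff(colnames(x), in_cells)
  p <- sum(v_in > t) / length(v_in)
  q <- sum(x[gene, out_cells] > t) / length(out_cells)
  list(Pgi = p, Qgi = q, threshold = unname(t), eligible = TRUE)
}
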