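#' Read a MatrixMarket count matrix with gene and barcode lists
#'
#' Reads sparse counts in MTX format together with the usual one-column (or
#' first-column-used) `genes.tsv` / `barcodes.tsv` side files. The on-disk
#' orientation is auto-detected by matching the declared MTX dimensions against
#' the two list lengths; the result is always genes x observations. A square
#' matrix with equal list lengths is ambiguous and taken as genes-in-rows with
#' a warning.
#'
#' @param matrix_path MTX file.
#' @param genes_path TSV whose first column holds gene symbols.
#' @param barcodes_path TSV whose first column holds observation identifiers.
#' @return an [expression_matrix()] with counts only.
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  mm <- Matrix::readMM(matrix_path)
  gn <- utils::read.table(genes_path, sep = "\t", header = FALSE,
    stringsAsFactors = FALSE)[[1]]
  bc <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
    stringsAsFactors = FALSE)[[1]]
  d <- dim(mm)
  if (d[1] == length(gn) && d[2] == length(bc)) {
    if (d[1] == d[2]) {
      warning("square matrix with equal list lengths; assuming genes x observations")
    }
  } else if (d[1] == length(bc) && d[2] == length(gn)) {
    mm <- Matrix::t(mm)
  } else {
    stop(sprintf(
      "dimension mismatch: %s declares %d x %d but %s has %d entries and %s has %d",
      matrix_path, d[1], d[2], genes_path, length(gn), barcodes_path, length(bc)
    ))
  }
  if (anyDuplicated(gn)) stop("duplicate gene identifiers in ", genes_path)
  if (anyDuplicated(bc)) stop("duplicate identifiers in ", barcodes_path)
  dimnames(mm) <- list(toupper(gn), bc)
  expression_matrix(mm)
}

#' Write an expression matrix as MTX + gene/barcode TSVs
#'
#' @param m an `expr_matrix`.
#' @param dir output directory (created if absent); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return the directory, invisibly.
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "expr_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(genes(m), file.path(dir, "genes.tsv"))
  writeLines(observations(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a ligand-receptor pair database
#'
#' CSV with header columns `pair_id`, `ligand`, `receptor`; multi-component
#' complexes are written `GENE1+GENE2`. Symbols are uppercased; duplicated
#' pair_ids are collapsed to their first record with a warning.
#'
#' @param csv_path CSV file path.
#' @return data.frame of class `lr_database` with columns `pair_id`,
#'   `ligand` (list of character vectors), `receptor` (list).
#' @export
read_lr_database <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("L-R database missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$pair_id)) {
    warning("duplicated pair_id rows collapsed to first occurrence")
    df <- df[!duplicated(df$pair_id), , drop = FALSE]
  }
  split_cmp <- function(x) {
    out <- strsplit(toupper(x), "+", fixed = TRUE)
    if (any(!lengths(out))) stop("empty component list in L-R database")
    out
  }
  out <- data.frame(pair_id = df$pair_id, stringsAsFactors = FALSE)
  out$ligand <- split_cmp(df$ligand)
  out$receptor <- split_cmp(df$receptor)
  class(out) <- c("lr_database", "data.frame")
  out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>gene...`.
#' @return named list of uppercased gene symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  stats::setNames(
    lapply(parts, function(p) toupper(p[-(1:2)])),
    vapply(parts, `[[`, "", 1L)
  )
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time`, `event`; time must be positive and
#' event coded 0 (censored) / 1 (event).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_survival(df)
}

validate_survival <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in survival table")
  if (any(df$time <= 0)) stop("survival time must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  df[need]
}

#' Write a result table with a reproducibility header
#'
#' TSV with a leading comment line recording the package version, the RNG seed
#' and a parameter hash, then a header and the records in a deterministic
#' order (sorted by the first column, then the second, and so on).
#'
#' @param records data.frame.
#' @param path output file.
#' @param seed integer seed recorded in the header comment.
#' @param params optional list of parameters; a compact signature is recorded.
#' @param allow_empty allow zero-row tables (header-only output).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, seed = NA_integer_, params = list(),
                        allow_empty = FALSE) {
  records <- as.data.frame(records)
  if (!nrow(records) && !allow_empty) stop("refusing to write empty table ", path)
  if (nrow(records) > 1) {
    ord <- do.call(order, unname(as.list(records)))
    records <- records[ord, , drop = FALSE]
  }
  phash <- sum(utf8ToInt(paste(names(params), unlist(params), collapse = ";",
    sep = "=")) * 31L^(0:(max(0, nchar(paste(names(params), unlist(params),
    collapse = ";", sep = "="))) - 1) %% 7)) %% 1e9
  header <- sprintf("# subtme %s seed=%s params=%09.0f",
    as.character(utils::packageVersion("subtme")), as.character(seed), phash)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' The packaged CRC subTME1 11-gene risk model
#'
#' Loads the colorectal-cancer subTME1 univariate-Cox risk model shipped with
#' the package (gene symbols and log-hazard coefficients) as a [risk_model()].
#'
#' @return a `risk_model` with 11 genes.
#' @export
crc_subtme1_model <- function() {
  read_risk_model(system.file("extdata", "crc_subtme1_model.tsv",
    package = "subtme", mustWork = TRUE))
}
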