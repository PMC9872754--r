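#' Read a scored ortholog table from TSV
#'
#' Expects a BioMart-export-compatible tab-separated file with header columns
#' `gene_a`, `gene_b`, `homology_type`, `goc_score`, `wga_score`.
#'
#' @param path path to a tab-separated file.
#' @return an unfiltered `ortholog_table` (a data.frame).
#' @seealso [filter_high_quality()]
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  as_ortholog_table(df, filtered = FALSE)
}

#' Write an ortholog table to TSV
#' @param table an `ortholog_table`.
#' @param path output path.
#' @export
write_ortholog_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples count (or expression) matrix from TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes x samples matrix to TSV
#' @param m matrix with gene rownames.
#' @param path output path.
#' @param id_col name for the gene-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: term id, description, then member genes. Uses
#' `fgsea::gmtPathways()` when fgsea is installed, otherwise a plain parser.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors (genes per term).
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-c(1, 2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx` (genes x cells sparse counts), `features.tsv`
#' (gene ids, first column) and `barcodes.tsv` (cell barcodes).
#'
#' @param dir directory holding the three files.
#' @return a sparse `dgCMatrix` with dimnames (genes, barcodes).
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                    stringsAsFactors = FALSE)
  dimnames(m) <- list(feats[[1]], bcs[[1]])
  methods::as(m, "CsparseMatrix")
}

#' Write a sparse count matrix as a 10x-style MTX triplet
#' @param m matrix or sparse Matrix with dimnames.
#' @param dir output directory (created if missing).
#' @export
write_mtx_dir <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an externally computed DEG table
#'
#' Tab-separated with columns `gene`, `direction`, `lfc`, `p`, `q`. This is
#' the first-class entry point for differential-expression results produced
#' outside the package (e.g. edgeR or limma runs).
#'
#' @param path path to a TSV file.
#' @return a `deg_list` data.frame.
#' @export
read_deg_list <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("gene", "direction", "lfc", "p", "q")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("DEG table is missing columns: ", paste(missing, collapse = ", "))
  }
  structure(df[needed], class = c("deg_list", "data.frame"))
}
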