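#' Construct an ortholog table
#'
#' An ortholog table records scored cross-species gene pairs: each row has a
#' gene in species A, its candidate homolog in species B, the homology class
#' (`one2one`, `one2many`, `many2many`), a gene-order-conservation (GOC)
#' score and a whole-genome-alignment (WGA) score, both in \[0, 100\].
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, `homology_type`,
#'   `goc_score`, `wga_score`.
#' @param filtered logical; has [filter_high_quality()] been applied?
#' @return an `ortholog_table`.
#' @export
as_ortholog_table <- function(df, filtered = FALSE) {
  needed <- c("gene_a", "gene_b", "homology_type", "goc_score", "wga_score")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols)) {
    stop("ortholog table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[needed]
  bad <- which(is.na(df$goc_score) | is.na(df$wga_score) |
                 !nzchar(df$gene_a) | !nzchar(df$gene_b))
  if (length(bad)) {
    stop("malformed ortholog records (missing score or empty identifier) ",
         "at rows: ", paste(head(bad, 10L), collapse = ", "))
  }
  if (any(df$goc_score < 0 | df$goc_score > 100 |
            df$wga_score < 0 | df$wga_score > 100)) {
    stop("GOC/WGA scores must lie in [0, 100]")
  }
  structure(df, filtered = filtered,
            class = c("ortholog_table", "data.frame"))
}

#' Test whether an ortholog table has been quality-filtered
#' @param table an `ortholog_table`.
#' @return logical.
#' @export
is_filtered <- function(table) {
  isTRUE(attr(table, "filtered"))
}

#' Select high-quality strict 1:1 orthologs
#'
#' Keeps records that are annotated `one2one` with both GOC and WGA score
#' strictly above the thresholds, drops duplicated (gene_a, gene_b) pairs,
#' and then enforces a strict bijection: if, after the score filter, a gene
#' still participates in more than one record, every record touching it is
#' dropped (strictness over salvage) and the count is reported via message.
#'
#' @param table an `ortholog_table`.
#' @param min_goc,min_wga score thresholds in \[0, 100\]; records must score
#'   strictly above both. Default 75.
#' @return a filtered `ortholog_table` whose `gene_a` and `gene_b` columns
#'   are each duplicate-free.
#' @examples
#' tab <- as_ortholog_table(data.frame(
#'   gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
#'   homology_type = c("one2one", "one2many"),
#'   goc_score = c(90, 90), wga_score = c(90, 90)))
#' nrow(filter_high_quality(tab))  # 1: the one2many record is excluded
#' @export
filter_high_quality <- function(table, min_goc = 75, min_wga = 75) {
  table <- as_ortholog_table(table, filtered = is_filtered(table))
  stopifnot(min_goc >= 0, min_goc <= 100, min_wga >= 0, min_wga <= 100)
  keep <- table$homology_type == "one2one" &
    table$goc_score > min_goc & table$wga_score > min_wga
  out <- table[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("gene_a", "gene_b")]), , drop = FALSE]
  ambiguous <- duplicated(out$gene_a) | duplicated(out$gene_a, fromLast = TRUE) |
    duplicated(out$gene_b) | duplicated(out$gene_b, fromLast = TRUE)
  if (any(ambiguous)) {
    message("dropping ", sum(ambiguous),
            " records whose genes map ambiguously after score filtering")
    out <- out[!ambiguous, , drop = FALSE]
  }
  rownames(out) <- NULL
  as_ortholog_table(out, filtered = TRUE)
}

#' Project a gene-keyed object across the ortholog mapping
#'
#' Renames the gene keys of `x` from one species' namespace to the other
#' using a filtered 1:1 ortholog table. Genes without a mapping are dropped
#' and their number reported (attribute `n_dropped`, plus a message). Values
#' are carried unchanged.
#'
#' @param x a character vector of genes, a named vector, or a matrix /
#'   data.frame with gene rownames.
#' @param table a *filtered* `ortholog_table` (see [filter_high_quality()]).
#' @param direction `"a_to_b"` or `"b_to_a"`.
#' @return object of the same shape keyed by the mapped gene names, with
#'   attribute `n_dropped`.
#' @export
map_gene_space <- function(x, table, direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  if (!is_filtered(table)) {
    stop("ortholog table must be filtered (strict 1:1) before mapping; ",
         "call filter_high_quality() first")
  }
  map <- if (direction == "a_to_b") {
    setNames(table$gene_b, table$gene_a)
  } else {
    setNames(table$gene_a, table$gene_b)
  }
  rename <- function(keys) unname(map[keys])
  if (is.matrix(x) || is.data.frame(x)) {
    new <- rename(rownames(x))
    keep <- !is.na(new)
    out <- x[keep, , drop = FALSE]
    rownames(out) <- new[keep]
  } else if (!is.null(names(x))) {
    new <- rename(names(x))
    keep <- !is.na(new)
    out <- x[keep]
    names(out) <- new[keep]
  } else if (is.character(x)) {
    new <- rename(x)
    keep <- !is.na(new)
    out <- unname(new[keep])
  } else {
    stop("cannot map object of class ", paste(class(x), collapse = "/"),
         ": need gene names as rownames, names, or a character vector")
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " genes had no 1:1 ortholog and were dropped")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
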