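#' Reads-per-kilobase-per-million (RPKM) normalization
#'
#' RPKM for gene g in sample s is
#' `reads[g,s] * 1e3 * 1e6 / (total_mapped[s] * length_bp[g])`,
#' i.e. read counts corrected for gene length (per kb) and sequencing depth
#' (per million mapped reads).
#'
#' @param counts non-negative genes x samples count matrix with gene
#'   rownames.
#' @param gene_length_bp per-gene length in bp; named vector or vector in
#'   row order.
#' @param total_mapped per-sample total mapped reads; defaults to column
#'   sums of `counts`.
#' @return genes x samples matrix of RPKM values, attribute `space = "rpkm"`.
#' @export
rpkm <- function(counts, gene_length_bp, total_mapped = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(gene_length_bp)) && !is.null(rownames(counts))) {
    gene_length_bp <- gene_length_bp[rownames(counts)]
  }
  if (length(gene_length_bp) != nrow(counts)) {
    stop("gene_length_bp must cover every gene of the count matrix")
  }
  bad_len <- which(is.na(gene_length_bp) | gene_length_bp <= 0)
  if (length(bad_len)) {
    stop("non-positive or missing gene length for gene(s): ",
         paste(head(rownames(counts)[bad_len], 5L), collapse = ", "))
  }
  if (length(total_mapped) != ncol(counts)) {
    stop("total_mapped must have one entry per sample")
  }
  bad_tot <- which(total_mapped <= 0)
  if (length(bad_tot)) {
    stop("non-positive total mapped reads for sample(s): ",
         paste(head(colnames(counts)[bad_tot], 5L), collapse = ", "))
  }
  out <- counts * 1e9 / outer(as.numeric(gene_length_bp),
                              as.numeric(total_mapped))
  dimnames(out) <- dimnames(counts)
  attr(out, "space") <- "rpkm"
  out
}

#' log2 transform with pseudocount
#'
#' @param em non-negative expression matrix (typically RPKM).
#' @param pseudocount value added before taking log2; default 1.
#' @return matrix of `log2(x + pseudocount)`, attribute `space = "log2"`.
#' @export
log2_transform <- function(em, pseudocount = 1) {
  if (any(em < 0)) stop("expression values must be non-negative before log2")
  out <- log2(em + pseudocount)
  attr(out, "space") <- "log2"
  out
}

#' Select genes with the most conserved expression ranks across samples
#'
#' Eligible genes lie in the inner quartile range: by default (`eligibility
#' = "mean"`) a gene qualifies when its cross-sample mean expression falls
#' within \[Q1, Q3\] of the distribution of gene means, which leaves half
#' the genes eligible regardless of sample count; `"every_sample"` instead
#' requires the gene's value to sit inside each sample's own \[Q1, Q3\], a
#' much stricter criterion whose pool shrinks rapidly as samples accrue.
#' Each eligible gene's conservation score is the variance, across samples,
#' of its within-sample rank (average ranks for ties, computed over all
#' genes of the matrix). The `n_genes` genes with the smallest score are
#' returned; ties are broken by gene identifier order.
#'
#' @param em expression matrix with gene rownames, >= 2 samples.
#' @param n_genes number of genes to return.
#' @param eligibility `"mean"` (default) or `"every_sample"`.
#' @return character vector of `n_genes` gene identifiers.
#' @export
select_rank_conserved <- function(em, n_genes,
                                  eligibility = c("mean", "every_sample")) {
  eligibility <- match.arg(eligibility)
  em <- as.matrix(em)
  if (ncol(em) < 2) stop("need at least 2 samples to assess rank conservation")
  eligible <- iqr_eligible(em, eligibility)
  pool <- sum(eligible)
  if (n_genes > pool) {
    stop("requested ", n_genes, " genes but only ", pool,
         " satisfy the inner-quartile eligibility criterion")
  }
  ranks <- apply(em, 2, rank, ties.method = "average")
  score <- apply(ranks[eligible, , drop = FALSE], 1, var)
  ids <- rownames(em)[eligible]
  ord <- order(score, ids)
  sort(ids[ord][seq_len(n_genes)])
}

#' Genes inside the inner quartile range
#'
#' Eligibility mask used by [select_rank_conserved()]. `"mean"`: the gene's
#' cross-sample mean expression lies within \[Q1, Q3\] of the gene-mean
#' distribution (half the genes qualify). `"every_sample"`: the gene's
#' value lies within each sample's own \[Q1, Q3\] in all samples — a
#' demanding criterion whose pool shrinks as samples accrue; query
#' `sum(iqr_eligible(em, "every_sample"))` before requesting a fixed
#' number of conserved genes under it.
#'
#' @param em expression matrix.
#' @param eligibility `"mean"` (default) or `"every_sample"`.
#' @return logical vector over genes.
#' @export
iqr_eligible <- function(em, eligibility = c("mean", "every_sample")) {
  eligibility <- match.arg(eligibility)
  em <- as.matrix(em)
  if (eligibility == "mean") {
    m <- rowMeans(em)
    q <- quantile(m, probs = c(0.25, 0.75), names = FALSE)
    return(m >= q[1] & m <= q[2])
  }
  q <- apply(em, 2, quantile, probs = c(0.25, 0.75), names = FALSE)
  inside <- sweep(em, 2, q[1, ], ">=") & sweep(em, 2, q[2, ], "<=")
  rowSums(inside) == ncol(em)
}

#' Cross-species median scaling anchored on conserved genes
#'
#' Computes each sample's median expression over the conserved gene set,
#' takes the mean of those medians as the common value, and rescales every
#' sample by `common_value / sample_median`. After scaling, each sample's
#' median over the conserved genes equals the common value.
#'
#' @param em expression matrix (all genes) with gene rownames.
#' @param conserved gene identifiers to anchor the scaling (a subset of
#'   `rownames(em)`), typically from [select_rank_conserved()].
#' @return list with `matrix` (scaled expression, attribute
#'   `space = "scaled"`) and `scaling` (a `scaling_result`: `conserved_genes`,
#'   per-sample `sample_median` and `factor`, and `common_value`).
#' @export
cross_species_scale <- function(em, conserved) {
  em <- as.matrix(em)
  missing_genes <- setdiff(conserved, rownames(em))
  if (length(missing_genes)) {
    stop("conserved genes absent from the matrix: ",
         paste(head(missing_genes, 5L), collapse = ", "))
  }
  med <- apply(em[conserved, , drop = FALSE], 2, median)
  zero <- which(med <= 0)
  if (length(zero)) {
    stop("non-positive conserved-gene median in sample(s): ",
         paste(head(colnames(em)[zero], 5L), collapse = ", "))
  }
  common <- mean(med)
  factor <- common / med
  out <- sweep(em, 2, factor, "*")
  attr(out, "space") <- "scaled"
  scaling <- structure(
    list(conserved_genes = conserved, sample_median = med,
         common_value = common, factor = factor),
    class = "scaling_result")
  list(matrix = out, scaling = scaling)
}

#' Two-group differential expression (plumbing test)
#'
#' A deliberately simple per-gene two-sample test (Welch t or Wilcoxon
#' rank-sum) on log-scale expression, with Benjamini-Hochberg adjustment.
#' It exists so the pipeline can run end-to-end on synthetic data; studies
#' with proper count-model DE results (edgeR, limma-voom) should load them
#' with [read_deg_list()] instead.
#'
#' @param em log-scale expression matrix.
#' @param group_a,group_b column names or indices of the two groups
#'   (>= 2 samples each).
#' @param method `"welch"` or `"wilcoxon"`.
#' @param min_expr independent-filtering threshold: genes whose mean
#'   log-scale expression across the tested samples is below this are not
#'   tested (their `p` and `q` are `NA` and they cannot be called DEGs).
#'   Filtering weakly expressed genes before testing is standard practice:
#'   it removes the skewed near-zero-count tests and reduces the
#'   multiple-testing family. Set to `-Inf` to test everything. Default 1.
#' @return a `deg_list` data.frame over all genes: `gene`, `direction`
#'   (`up`/`down`, A relative to B; `NA` if untested), `lfc` (mean
#'   difference A - B), `p`, `q` (BH over the tested family).
#' @export
simple_de <- function(em, group_a, group_b, method = c("welch", "wilcoxon"),
                      min_expr = 1) {
  method <- match.arg(method)
  a <- as.matrix(em[, group_a, drop = FALSE])
  b <- as.matrix(em[, group_b, drop = FALSE])
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 samples per group")
  tested <- rowMeans(cbind(a, b)) >= min_expr
  n_const <- 0L
  p <- rep(NA_real_, nrow(a))
  p[tested] <- vapply(which(tested), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (method == "welch") {
      if (var(x) == 0 && var(y) == 0) {
        n_const <<- n_const + 1L
        return(1)
      }
      t.test(x, y)$p.value
    } else {
      suppressWarnings(wilcox.test(x, y)$p.value)
    }
  }, numeric(1))
  if (n_const > 0) {
    warning(n_const, " constant genes assigned p = 1 under the Welch test")
  }
  lfc <- rowMeans(a) - rowMeans(b)
  structure(
    data.frame(gene = rownames(a),
               direction = ifelse(tested, ifelse(lfc >= 0, "up", "down"),
                                  NA_character_),
               lfc = lfc, p = p, q = p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("deg_list", "data.frame"))
}

#' Subset a DEG table to significant genes
#' @param deg a `deg_list`.
#' @param q_cut FDR threshold (default 0.05).
#' @return the significant rows.
#' @export
significant_degs <- function(deg, q_cut = 0.05) {
  deg[!is.na(deg$q) & deg$q < q_cut, , drop = FALSE]
}
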