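#' Quality-control filter for a single-cell UMI matrix
#'
#' Cells are kept when their number of detected genes (UMI count > 0) lies
#' in `[min_genes, max_genes]` and their mitochondrial-count percentage is
#' at most `max_mito_pct`. Genes are then kept when expressed in at least
#' `min_cells_per_gene` of the *retained* cells (cell filter first, gene
#' filter second).
#'
#' @param counts genes x cells UMI matrix (dense or sparse) with dimnames.
#' @param mito_genes character vector of mitochondrial gene ids, or a
#'   logical vector over rows.
#' @param min_genes,max_genes detected-gene bounds per cell (default
#'   200-2500, inclusive).
#' @param max_mito_pct maximum mitochondrial percentage per cell (default 5).
#' @param min_cells_per_gene minimum retained cells expressing a gene
#'   (default 3).
#' @return the filtered matrix; attributes `n_cells_removed` and
#'   `n_genes_removed`.
#' @export
qc_filter <- function(counts, mito_genes = character(0), min_genes = 200,
                      max_genes = 2500, max_mito_pct = 5,
                      min_cells_per_gene = 3) {
  if (is.logical(mito_genes)) {
    stopifnot(length(mito_genes) == nrow(counts))
    mito <- mito_genes
  } else {
    mito <- rownames(counts) %in% mito_genes
  }
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_pct <- ifelse(total > 0,
                     100 * Matrix::colSums(counts[mito, , drop = FALSE]) /
                       total, 0)
  keep_cell <- detected >= min_genes & detected <= max_genes &
    mito_pct <= max_mito_pct
  if (!any(keep_cell)) stop("QC removed every cell")
  out <- counts[, keep_cell, drop = FALSE]
  keep_gene <- Matrix::rowSums(out > 0) >= min_cells_per_gene
  out <- out[keep_gene, , drop = FALSE]
  attr(out, "n_cells_removed") <- sum(!keep_cell)
  attr(out, "n_genes_removed") <- sum(!keep_gene)
  out
}

# library-size normalization to counts per `scale` (default 10k), log1p'd
.normalize_cells <- function(counts, scale = 1e4) {
  sf <- Matrix::colSums(counts)
  sf[sf == 0] <- 1
  log1p(t(t(as.matrix(counts)) / sf * scale))
}

#' One-vs-rest marker genes per cluster
#'
#' For each cluster, each gene is tested against all remaining cells with a
#' Wilcoxon rank-sum test on log-normalized expression; the average log
#' fold-change is the natural-log difference of the cluster and rest mean
#' expression (`log(mean_in + 1) - log(mean_out + 1)` on normalized
#' counts). Only positive markers above `min_logfc` are reported; p-values
#' are BH-adjusted within each cluster. Clusters with fewer than 3 cells
#' are skipped with a warning.
#'
#' @param counts genes x cells UMI matrix.
#' @param labels cluster label per cell.
#' @param min_logfc minimum average log fold-change (natural log,
#'   default 0.25).
#' @return data.frame: `cluster`, `gene`, `avg_logfc`, `p`, `q`.
#' @export
find_markers <- function(counts, labels, min_logfc = 0.25) {
  stopifnot(length(labels) == ncol(counts))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 clusters")
  norm <- .normalize_cells(counts)
  expm <- expm1(norm)
  rows <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    if (sum(in_cl) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    lfc <- log(rowMeans(expm[, in_cl, drop = FALSE]) + 1) -
      log(rowMeans(expm[, !in_cl, drop = FALSE]) + 1)
    cand <- which(lfc > min_logfc)
    if (length(cand) == 0) next
    p <- vapply(cand, function(i) {
      suppressWarnings(
        wilcox.test(norm[i, in_cl], norm[i, !in_cl])$p.value)
    }, numeric(1))
    rows[[cl]] <- data.frame(cluster = cl, gene = rownames(counts)[cand],
                             avg_logfc = lfc[cand], p = p,
                             q = p.adjust(p, method = "BH"),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(cluster = character(0), gene = character(0),
                      avg_logfc = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type DEG lists from markers and bulk DE results
#'
#' Per cell type, intersects its marker genes with the bulk DEG list at
#' `p < p_cut`; directions and statistics are inherited from the bulk list.
#'
#' @param markers output of [find_markers()].
#' @param deg a `deg_list` from bulk differential expression.
#' @param p_cut bulk p-value threshold (default 0.05).
#' @return named list (per cell type) of `deg_list` data.frames.
#' @export
celltype_deg_lists <- function(markers, deg, p_cut = 0.05) {
  sig <- deg[deg$p < p_cut, , drop = FALSE]
  out <- lapply(split(markers$gene, markers$cluster), function(genes) {
    hit <- sig[sig$gene %in% genes, , drop = FALSE]
    rownames(hit) <- NULL
    structure(hit, class = c("deg_list", "data.frame"))
  })
  out
}

#' Call directed ligand-receptor interactions between cell subsets
#'
#' A directed call (source -> target, pair) is made when the ligand is
#' detected (UMI > 0) in more than `min_expr_fraction` of the source
#' cluster's cells and the receptor in more than that fraction of the
#' target cluster's cells. Self-loops (A -> A) are allowed.
#'
#' @param counts genes x cells UMI matrix.
#' @param labels cluster label per cell.
#' @param lr_pairs data.frame with columns `ligand` and `receptor`.
#' @param min_expr_fraction detection-fraction threshold (default 0.1).
#' @return data.frame of calls: `source`, `target`, `ligand`, `receptor`,
#'   `ligand_fraction`, `receptor_fraction`, `present` (all TRUE rows kept),
#'   `vns_up` (NA until [vns_response()]).
#' @export
call_interactions <- function(counts, labels, lr_pairs,
                              min_expr_fraction = 0.1) {
  stopifnot(length(labels) == ncol(counts), nrow(lr_pairs) > 0)
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  genes <- intersect(genes, rownames(counts))
  frac <- sapply(clusters, function(cl) {
    Matrix::rowMeans(counts[genes, labels == cl, drop = FALSE] > 0)
  })
  frac <- matrix(frac, nrow = length(genes),
                 dimnames = list(genes, clusters))
  rows <- list()
  for (i in seq_len(nrow(lr_pairs))) {
    lig <- lr_pairs$ligand[i]; rec <- lr_pairs$receptor[i]
    if (!(lig %in% genes) || !(rec %in% genes)) next
    for (src in clusters) {
      if (frac[lig, src] <= min_expr_fraction) next
      for (tgt in clusters) {
        if (frac[rec, tgt] <= min_expr_fraction) next
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, target = tgt, ligand = lig, receptor = rec,
          ligand_fraction = frac[lig, src],
          receptor_fraction = frac[rec, tgt],
          present = TRUE, vns_up = NA, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      ligand = character(0), receptor = character(0),
                      ligand_fraction = numeric(0),
                      receptor_fraction = numeric(0),
                      present = logical(0), vns_up = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag interactions upregulated under vagal nerve stimulation
#'
#' An interaction gains the `vns_up` flag when its ligand's or receptor's
#' differential-expression p-value under VNS is smaller than without VNS
#' (either gene suffices; both per-gene comparisons are recorded). Genes
#' missing from a table are treated as p = 1 with a warning.
#'
#' @param calls output of [call_interactions()].
#' @param de_p_naive,de_p_vns named numeric vectors of per-gene
#'   differential-expression p-values without / with VNS.
#' @return `calls` with `vns_up`, `ligand_vns_up` and `receptor_vns_up`
#'   filled in.
#' @export
vns_response <- function(calls, de_p_naive, de_p_vns) {
  lookup <- function(tab, genes) {
    p <- tab[genes]
    miss <- is.na(p)
    if (any(miss)) {
      warning(sum(miss), " gene(s) missing from a p-value table; ",
              "treated as p = 1")
      p[miss] <- 1
    }
    unname(p)
  }
  if (nrow(calls) == 0) return(calls)
  lig_naive <- lookup(de_p_naive, calls$ligand)
  lig_vns <- lookup(de_p_vns, calls$ligand)
  rec_naive <- lookup(de_p_naive, calls$receptor)
  rec_vns <- lookup(de_p_vns, calls$receptor)
  calls$ligand_vns_up <- lig_vns < lig_naive
  calls$receptor_vns_up <- rec_vns < rec_naive
  calls$vns_up <- calls$present & (calls$ligand_vns_up | calls$receptor_vns_up)
  calls
}

#' Cells required to capture every rare cell type
#'
#' Smallest number of sampled cells N such that, with `n_types` independent
#' cell types each present at frequency `fraction`, the probability that a
#' sample of N contains at least `min_cells` cells of *every* type reaches
#' `confidence`. The per-type probability uses the exact binomial upper
#' tail, types are treated as independent, and N is found by incremental
#' search upward from `min_cells`.
#'
#' @param n_types number of cell types to capture.
#' @param fraction frequency of each type, in (0, 1].
#' @param min_cells minimum cells required per type (>= 1).
#' @param confidence required joint probability, in (0, 1).
#' @return integer N.
#' @examples
#' cells_required(10, 0.02, 6, 0.95)  # 702
#' cells_required(5, 0.10, 6, 0.95)   # 127
#' @export
cells_required <- function(n_types, fraction, min_cells, confidence) {
  stopifnot(n_types >= 1, fraction > 0, fraction <= 1, min_cells >= 1,
            confidence > 0, confidence < 1)
  if (n_types * fraction > 1) {
    warning("n_types * fraction exceeds 1; the independent-types model ",
            "is only an approximation here")
  }
  n <- as.integer(min_cells)
  prob <- function(N) {
    pbinom(min_cells - 1, N, fraction, lower.tail = FALSE)^n_types
  }
  while (prob(n) < confidence) n <- n + 1L
  n
}
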