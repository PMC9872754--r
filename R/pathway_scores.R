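#' Match WikiPathway gene sets against DEG lists
#'
#' Intersects each pathway's gene set with a DEG list, split by direction.
#' When an ortholog table is supplied, DEGs without a strict 1:1 ortholog
#' are dropped first (the count is reported), so only ortholog-supported
#' genes are matched.
#'
#' @param deg a `deg_list` data.frame (`gene`, `direction`, ...).
#' @param wp_db a `geneset_db` or named list of pathway gene sets.
#' @param ortholog_table optional *filtered* `ortholog_table`; DEGs are
#'   restricted to its `gene_a` namespace.
#' @return named list (per pathway) of lists with `up`, `down` and `all`
#'   gene vectors; attribute `n_dropped` reports ortholog-filtered DEGs.
#' @export
match_wp_degs <- function(deg, wp_db, ortholog_table = NULL) {
  sets <- if (inherits(wp_db, "geneset_db")) wp_db$sets else wp_db
  n_dropped <- 0L
  if (!is.null(ortholog_table)) {
    if (!is_filtered(ortholog_table)) {
      stop("ortholog table must be filtered before matching")
    }
    keep <- deg$gene %in% ortholog_table$gene_a
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message(n_dropped, " DEGs without a 1:1 ortholog dropped before matching")
    }
    deg <- deg[keep, , drop = FALSE]
  }
  out <- lapply(sets, function(g) {
    hit <- deg[deg$gene %in% g, , drop = FALSE]
    list(up = hit$gene[hit$direction == "up"],
         down = hit$gene[hit$direction == "down"],
         all = hit$gene)
  })
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Combine p-values by the harmonic mean (HMP)
#'
#' The harmonic-mean p-value for L p-values with equal weights is
#' `HMP = L / sum(1 / p_i)`. Unlike Fisher's method it tolerates dependence
#' between the combined tests, which is why it is used to pool per-DEG
#' significance within a pathway (the DEGs of one list are correlated
#' events). The plain harmonic mean is anti-conservative as a p-value for
#' small significance levels; it is used here as a ranking/combination
#' score across pathways.
#'
#' @param p numeric vector of p-values in (0, 1], length >= 1.
#' @param adjust only `"none"` is implemented (the plain harmonic mean).
#' @return the combined value, in \[min(p), max(p)\].
#' @examples
#' combine_hmp(c(0.01, 0.04))  # 0.016
#' @export
combine_hmp <- function(p, adjust = c("none")) {
  adjust <- match.arg(adjust)
  if (length(p) == 0) stop("need at least one p-value")
  if (any(p <= 0)) stop("p = 0 is degenerate for the harmonic mean")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  length(p) / sum(1 / p)
}

#' Fraction of a DEG list captured by a pathway
#'
#' @param n_matched number of DEGs matched to the pathway.
#' @param n_total size of the DEG list (> 0).
#' @return `n_matched / n_total` in \[0, 1\].
#' @export
gene_percent <- function(n_matched, n_total) {
  if (n_total <= 0) stop("DEG list size must be positive")
  stopifnot(n_matched >= 0, n_matched <= n_total)
  n_matched / n_total
}

#' Up/down enrichment ratio of a pathway
#'
#' The ratio of up- to down-regulated enrichment strength on the
#' -log10(q) scale: `(-log10 q_up) / (-log10 q_down)`. When the
#' down-regulated side is unenriched (`q_down = 1`) the ratio is infinite;
#' when both sides are unenriched it is undefined (`NaN`). Both cases carry
#' a `flag` attribute (`"infinite"` / `"undefined"`).
#'
#' @param q_up,q_down adjusted p-values in (0, 1].
#' @param scale `"neglog10"` (default) or `"raw"` (plain `q_down / q_up`).
#' @return numeric ratio, possibly `Inf` or `NaN` with a `flag` attribute.
#' @export
enrichment_ratio <- function(q_up, q_down, scale = c("neglog10", "raw")) {
  scale <- match.arg(scale)
  if (q_up <= 0 || q_up > 1 || q_down <= 0 || q_down > 1) {
    stop("q-values must lie in (0, 1]")
  }
  if (scale == "raw") {
    return(q_down / q_up)
  }
  num <- -log10(q_up)
  den <- -log10(q_down)
  if (num == 0 && den == 0) {
    return(structure(NaN, flag = "undefined"))
  }
  if (den == 0) {
    return(structure(Inf, flag = "infinite"))
  }
  num / den
}

#' Ratio of shared biological processes with pro- vs anti-inflammatory sets
#'
#' Measures, on an enrichment map, how strongly a pathway's neighborhood
#' leans pro- vs anti-inflammatory: the ratio of map nodes shared between
#' the pathway's term neighborhood (its terms plus their direct neighbors)
#' and the pro-inflammatory term set, over nodes shared with the
#' anti-inflammatory set. A zero denominator yields `Inf` (flag
#' `"infinite"`); both zero yields `NaN` (flag `"undefined"`).
#'
#' @param pathway_terms term ids on the map associated with the pathway.
#' @param pro_terms,anti_terms term ids of the pro-/anti-inflammatory
#'   signatures on the same map.
#' @param map an `enrichment_map`.
#' @return numeric ratio with optional `flag` attribute; the shared counts
#'   are attached as attributes `n_pro` and `n_anti`.
#' @export
pro_anti_ratio <- function(pathway_terms, pro_terms, anti_terms, map) {
  all_ids <- map$nodes$term_id
  pathway_terms <- intersect(pathway_terms, all_ids)
  nbrs <- unique(c(
    pathway_terms,
    map$edges$term_b[map$edges$term_a %in% pathway_terms],
    map$edges$term_a[map$edges$term_b %in% pathway_terms]))
  n_pro <- length(intersect(nbrs, pro_terms))
  n_anti <- length(intersect(nbrs, anti_terms))
  out <- if (n_pro == 0 && n_anti == 0) {
    structure(NaN, flag = "undefined")
  } else if (n_anti == 0) {
    structure(Inf, flag = "infinite")
  } else {
    n_pro / n_anti
  }
  attr(out, "n_pro") <- n_pro
  attr(out, "n_anti") <- n_anti
  out
}

#' Gene-gene functional similarity from shared annotations
#'
#' Similarity between two genes is the Jaccard index of their annotated
#' biological-process term sets: `|BP(g1) ∩ BP(g2)| / |BP(g1) ∪ BP(g2)|`.
#' This is a set-overlap simplification of information-content semantic
#' similarity. Genes without any annotation are excluded with a warning.
#'
#' @param annotations named list: per gene, its annotated term ids.
#' @return symmetric gene x gene matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
similarity_matrix <- function(annotations) {
  empty <- lengths(annotations) == 0
  if (any(empty)) {
    warning(sum(empty), " unannotated gene(s) excluded: ",
            paste(head(names(annotations)[empty], 5L), collapse = ", "))
    annotations <- annotations[!empty]
  }
  annotations <- lapply(annotations, unique)
  g <- names(annotations)
  n <- length(g)
  m <- diag(1, n)
  dimnames(m) <- list(g, g)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- annotations[[i]]; b <- annotations[[j]]
        m[i, j] <- m[j, i] <-
          length(intersect(a, b)) / length(union(a, b))
      }
    }
  }
  m
}

#' Pearson correlation between two pathways' enrichment profiles
#'
#' @param a,b numeric vectors of per-term enrichment scores over a common
#'   term index (length >= 3).
#' @return list with `r` and `p` (t-based); constant input yields `NA`
#'   values with a warning.
#' @export
pathway_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must share a common term index")
  if (length(a) < 3) stop("need >= 3 terms")
  if (var(a) == 0 || var(b) == 0) {
    warning("constant enrichment vector; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  res <- cor.test(a, b, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value)
}

#' Score WikiPathways against a DEG list
#'
#' For each pathway: matches DEGs (by direction), computes the gene percent
#' (matched / list size), and combines the per-DEG significance (the bulk
#' DE p-values of the matched genes) into one pathway-level value with the
#' harmonic mean ([combine_hmp()]); the combined values are BH-adjusted
#' across pathways within each direction.
#'
#' @param deg a `deg_list`.
#' @param wp_db a `geneset_db` or named list of pathway gene sets.
#' @param ortholog_table optional filtered `ortholog_table` applied before
#'   matching (see [match_wp_degs()]).
#' @return data.frame: `pathway_id`, `direction`, `n_matched`,
#'   `gene_percent`, `combined_p`, `q`.
#' @export
score_wikipathways <- function(deg, wp_db, ortholog_table = NULL) {
  matches <- match_wp_degs(deg, wp_db, ortholog_table)
  pvals <- setNames(pmax(deg$p, .Machine$double.xmin), deg$gene)
  rows <- list()
  for (dir in c("up", "down")) {
    n_list <- sum(deg$direction == dir)
    for (pw in names(matches)) {
      genes <- matches[[pw]][[dir]]
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pw, direction = dir, n_matched = length(genes),
        gene_percent = if (n_list > 0) length(genes) / n_list else NA_real_,
        combined_p = if (length(genes) > 0) combine_hmp(pvals[genes]) else
          NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (dir in c("up", "down")) {
    sel <- out$direction == dir & !is.na(out$combined_p)
    out$q[sel] <- p.adjust(out$combined_p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}
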