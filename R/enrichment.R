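#' Construct a gene-set database
#'
#' Bundles a named list of gene sets (as read from GMT) with an optional
#' sidecar of per-term annotation: `name`, `source` (GOBP, WikiPathways,
#' custom), `go_level` (term depth, used for specificity filtering) and
#' `associated_gene_count` (full annotation size, which may exceed the
#' number of member genes present in any particular background).
#'
#' @param sets named list of character vectors (genes per term).
#' @param info optional data.frame keyed by `term_id` with any of the
#'   columns above.
#' @return a `geneset_db`.
#' @export
geneset_db <- function(sets, info = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a term id")
  }
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  if (is.null(info)) {
    info <- data.frame(term_id = names(sets), stringsAsFactors = FALSE)
  }
  if (!"term_id" %in% colnames(info)) stop("info needs a term_id column")
  info <- info[match(names(sets), info$term_id), , drop = FALSE]
  info$term_id <- names(sets)
  rownames(info) <- NULL
  structure(list(sets = sets, info = info), class = "geneset_db")
}

#' @export
print.geneset_db <- function(x, ...) {
  cat("geneset_db with", length(x$sets), "terms; set sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' Over-representation test (one-sided hypergeometric, BH-corrected)
#'
#' For each term, tests whether the DEG list contains more term genes than
#' expected by chance given the background, using the upper tail of the
#' hypergeometric distribution (equivalent to a one-sided Fisher exact test
#' on the 2x2 table), then adjusts over all tested terms with
#' Benjamini-Hochberg.
#'
#' @param deg_genes character vector of differentially expressed genes
#'   (must be a subset of `background`).
#' @param background character vector: all genes detected in the assay.
#' @param db a `geneset_db` or named list of gene sets.
#' @return data.frame: `term_id`, `overlap_count`, `term_size` (in
#'   background), `p`, `q`, ordered by p.
#' @export
enrich_fisher <- function(deg_genes, background, db) {
  sets <- if (inherits(db, "geneset_db")) db$sets else db
  deg_genes <- unique(deg_genes)
  background <- unique(background)
  stray <- setdiff(deg_genes, background)
  if (length(stray)) {
    stop("DEG genes outside the background: ",
         paste(head(stray, 5L), collapse = ", "))
  }
  N <- length(background)
  n <- length(deg_genes)
  term_bg <- lapply(sets, intersect, background)
  empty <- lengths(term_bg) == 0
  if (any(empty)) {
    warning(sum(empty), " term(s) have no background genes and were skipped")
    term_bg <- term_bg[!empty]
  }
  K <- lengths(term_bg)
  k <- vapply(term_bg, function(g) length(intersect(g, deg_genes)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(term_bg), overlap_count = k,
                    term_size = K, p = p, q = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Filter enrichment results to specific terms
#'
#' Keeps terms whose ontology level lies in `level_range`, with at least
#' `min_genes` DEGs mapped, and where the mapped genes represent strictly
#' more than `min_mapped_fraction` of the term's full annotation
#' (`associated_gene_count`). Terms lacking a level annotation are excluded
#' with a warning.
#'
#' @param results output of [enrich_fisher()].
#' @param db a `geneset_db` whose `info` carries `go_level` and
#'   `associated_gene_count`.
#' @param min_genes minimum mapped DEGs per term (default 1).
#' @param min_mapped_fraction mapped / associated must exceed this
#'   (default 0.5).
#' @param level_range inclusive `c(lo, hi)` band of GO levels (default 7-15).
#' @return the retained rows of `results`, with `go_level` and
#'   `associated_gene_count` columns added.
#' @export
filter_specific_terms <- function(results, db, min_genes = 1,
                                  min_mapped_fraction = 0.5,
                                  level_range = c(7, 15)) {
  info <- db$info
  idx <- match(results$term_id, info$term_id)
  lev <- if (is.null(info$go_level)) rep(NA_real_, length(idx)) else
    info$go_level[idx]
  assoc <- if (is.null(info$associated_gene_count))
    rep(NA_integer_, length(idx)) else info$associated_gene_count[idx]
  no_level <- is.na(lev)
  if (any(no_level)) {
    warning(sum(no_level), " term(s) lack a GO level and were excluded")
  }
  keep <- !no_level &
    lev >= level_range[1] & lev <= level_range[2] &
    results$overlap_count >= min_genes &
    results$overlap_count / assoc > min_mapped_fraction
  out <- results[keep, , drop = FALSE]
  out$go_level <- lev[keep]
  out$associated_gene_count <- assoc[keep]
  out
}

#' Select the minimum informative GO level
#'
#' Returns the smallest ontology level at which at least `min_bps` terms are
#' significant at `q < q_cut`; `NA` (with a message) if no level qualifies.
#'
#' @param results data.frame with `go_level` and `q` columns.
#' @param min_bps minimum significant terms required at a level (default 3).
#' @param q_cut FDR threshold (default 0.05).
#' @return integer level, or `NA_integer_` if none qualifies.
#' @export
select_go_level <- function(results, min_bps = 3, q_cut = 0.05) {
  sig <- results[!is.na(results$go_level) & results$q < q_cut, , drop = FALSE]
  counts <- table(sig$go_level)
  ok <- as.integer(names(counts)[counts >= min_bps])
  if (length(ok) == 0) {
    message("no GO level has >= ", min_bps, " significant terms at q < ",
            q_cut)
    return(NA_integer_)
  }
  min(ok)
}

#' Build an enrichment map (term-overlap network)
#'
#' Nodes are enriched terms; an edge joins two terms when their member gene
#' sets overlap with overlap coefficient `|A∩B| / min(|A|,|B|)` at or above
#' the cutoff (and share at least one gene). Edge weight is the number of
#' shared genes — a "functional linkage" between the two terms.
#'
#' @param term_genes named list: per significant term, its member gene set
#'   (typically DEGs in the term).
#' @param overlap_cutoff minimum overlap coefficient for an edge
#'   (default 0.25).
#' @param node_info optional data.frame keyed by `term_id` with extra node
#'   attributes (e.g. `q`, `direction`).
#' @return an `enrichment_map`: list with `nodes` (data.frame), `edges`
#'   (data.frame: `term_a`, `term_b`, `shared_gene_count`,
#'   `overlap_coefficient`) and `genes` (the input list).
#' @export
build_enrichment_map <- function(term_genes, overlap_cutoff = 0.25,
                                 node_info = NULL) {
  if (is.null(names(term_genes))) stop("term_genes must be named by term id")
  term_genes <- lapply(term_genes, unique)
  ids <- sort(names(term_genes))
  term_genes <- term_genes[ids]
  nodes <- data.frame(term_id = ids, n_genes = lengths(term_genes),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(node_info)) {
    nodes <- merge(nodes, node_info, by = "term_id", all.x = TRUE,
                   sort = TRUE)
  }
  edges <- data.frame(term_a = character(0), term_b = character(0),
                      shared_gene_count = integer(0),
                      overlap_coefficient = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(ids) >= 2) {
    pairs <- combn(ids, 2)
    shared <- integer(ncol(pairs))
    oc <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- term_genes[[pairs[1, j]]]
      b <- term_genes[[pairs[2, j]]]
      s <- length(intersect(a, b))
      shared[j] <- s
      oc[j] <- s / min(length(a), length(b))
    }
    keep <- shared >= 1 & oc >= overlap_cutoff
    edges <- data.frame(term_a = pairs[1, keep], term_b = pairs[2, keep],
                        shared_gene_count = shared[keep],
                        overlap_coefficient = oc[keep],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, genes = term_genes,
                 overlap_cutoff = overlap_cutoff),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat("enrichment_map:", nrow(x$nodes), "terms,", nrow(x$edges),
      "linkage edges (overlap coefficient >=", x$overlap_cutoff, ")\n")
  invisible(x)
}

#' Highlight map terms containing given DEGs
#'
#' @param map an `enrichment_map`.
#' @param deg_subset character vector of genes.
#' @return character vector of term ids whose member set intersects
#'   `deg_subset`.
#' @export
highlight_terms <- function(map, deg_subset) {
  hit <- vapply(map$genes, function(g) any(g %in% deg_subset), logical(1))
  names(map$genes)[hit]
}

#' Functional-linkage coverage of a DEG subset
#'
#' An edge of the map is *covered* by a DEG set when the terms it joins are
#' highlighted by that set (both endpoints by default; `endpoint_rule =
#' "either"` relaxes this for sensitivity analysis). Linkage coverage is the
#' ratio of the subset's covered linkage to the reference set's covered
#' linkage — counting linkage either as summed shared-gene weight
#' (`mode = "weight"`, default) or as the number of edges (`mode = "edge"`).
#'
#' @param map an `enrichment_map`.
#' @param subset_degs genes whose network footprint is being assessed.
#' @param reference_degs genes defining the reference footprint (often the
#'   full DEG list behind the map).
#' @param mode `"weight"` or `"edge"`.
#' @param endpoint_rule `"both"` (default) or `"either"`.
#' @return a `coverage_report` list: highlighted/total node counts, covered/
#'   total edge counts and linkage weights (for the subset), `node_fraction`
#'   and `linkage_coverage`, plus the mode and rule used.
#' @export
linkage_coverage <- function(map, subset_degs, reference_degs,
                             mode = c("weight", "edge"),
                             endpoint_rule = c("both", "either")) {
  mode <- match.arg(mode)
  endpoint_rule <- match.arg(endpoint_rule)
  covered_stats <- function(degs) {
    hi <- highlight_terms(map, degs)
    e <- map$edges
    inA <- e$term_a %in% hi
    inB <- e$term_b %in% hi
    cov <- if (endpoint_rule == "both") inA & inB else inA | inB
    list(nodes = hi, n_edges = sum(cov),
         weight = sum(e$shared_gene_count[cov]))
  }
  sub <- covered_stats(subset_degs)
  ref <- covered_stats(reference_degs)
  ref_total <- if (mode == "weight") ref$weight else ref$n_edges
  if (ref_total == 0) {
    stop("reference DEG set covers zero linkages; coverage is undefined")
  }
  sub_total <- if (mode == "weight") sub$weight else sub$n_edges
  structure(
    list(highlighted_node_count = length(sub$nodes),
         total_node_count = nrow(map$nodes),
         covered_edge_count = sub$n_edges,
         total_edge_count = nrow(map$edges),
         covered_linkage_weight = sub$weight,
         total_linkage_weight = sum(map$edges$shared_gene_count),
         reference_edge_count = ref$n_edges,
         reference_linkage_weight = ref$weight,
         node_fraction = if (nrow(map$nodes) > 0)
           length(sub$nodes) / nrow(map$nodes) else NA_real_,
         linkage_coverage = sub_total / ref_total,
         mode = mode, endpoint_rule = endpoint_rule),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage_report (%s mode, %s endpoints): %.1f%% linkage coverage; %d/%d nodes highlighted, %d/%d edges covered\n",
    x$mode, x$endpoint_rule, 100 * x$linkage_coverage,
    x$highlighted_node_count, x$total_node_count,
    x$covered_edge_count, x$total_edge_count))
  invisible(x)
}

#' Fraction of grouped networks directly involving a DEG set
#'
#' The percentage of up- and down-regulated network nodes that a DEG set
#' highlights directly: `100 * (highlighted_up + highlighted_down) /
#' (total_up + total_down)`.
#'
#' @param highlighted_up,highlighted_down highlighted node counts in the up-
#'   and down-regulated networks.
#' @param total_up,total_down total node counts of those networks.
#' @return percentage in \[0, 100\].
#' @examples
#' involvement_fraction(47, 135, 48, 86)  # ~43
#' @export
involvement_fraction <- function(highlighted_up, total_up,
                                 highlighted_down, total_down) {
  stopifnot(highlighted_up <= total_up, highlighted_down <= total_down,
            highlighted_up >= 0, highlighted_down >= 0)
  denom <- total_up + total_down
  if (denom == 0) stop("total node counts sum to zero")
  100 * (highlighted_up + highlighted_down) / denom
}

#' Match a foreign species' DEGs against a native enrichment map
#'
#' Projects the foreign DEG list into the native gene space through the
#' filtered 1:1 ortholog table, then measures its linkage coverage on the
#' native map relative to the native DEG set.
#'
#' @param map_native an `enrichment_map` built from the native DEG list.
#' @param foreign_degs character vector of DEGs in the foreign gene space.
#' @param ortholog_table a *filtered* `ortholog_table`.
#' @param direction mapping direction passed to [map_gene_space()]
#'   (`"b_to_a"` if the foreign genes are in the B namespace).
#' @param native_degs reference DEG set in native space; defaults to the
#'   union of the map's member genes.
#' @param ... passed to [linkage_coverage()] (`mode`, `endpoint_rule`).
#' @return a `coverage_report`.
#' @export
cross_species_match <- function(map_native, foreign_degs, ortholog_table,
                                direction = c("b_to_a", "a_to_b"),
                                native_degs = NULL, ...) {
  direction <- match.arg(direction)
  mapped <- map_gene_space(foreign_degs, ortholog_table, direction)
  if (is.null(native_degs)) {
    native_degs <- unique(unlist(map_native$genes, use.names = FALSE))
  }
  if (length(mapped) == 0) {
    warning("no foreign DEG maps through the ortholog table; coverage is 0")
  }
  linkage_coverage(map_native, mapped, native_degs, ...)
}

#' Convert an enrichment map to an igraph graph
#' @param map an `enrichment_map`.
#' @return an undirected `igraph` graph with node and edge attributes.
#' @export
map_to_igraph <- function(map) {
  igraph::graph_from_data_frame(map$edges, directed = FALSE,
                                vertices = map$nodes)
}

#' Export an enrichment map to GraphML or SIF (+ attribute TSVs)
#'
#' @param map an `enrichment_map`.
#' @param path output path; for `"sif"` this is a prefix and three files are
#'   written (`<path>.sif`, `<path>.nodes.tsv`, `<path>.edges.tsv`).
#' @param format `"graphml"` or `"sif"`.
#' @return the main output path, invisibly.
#' @export
write_enrichment_map <- function(map, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(map_to_igraph(map), path, format = "graphml")
    return(invisible(path))
  }
  sif <- sprintf("%s\tshares_genes\t%s", map$edges$term_a, map$edges$term_b)
  writeLines(sif, paste0(path, ".sif"))
  write.table(map$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(map$edges, paste0(path, ".edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paste0(path, ".sif"))
}
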