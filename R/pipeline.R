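#' Default end-to-end pipeline configuration
#'
#' All analysis thresholds at their study defaults: ortholog GOC/WGA > 75,
#' DEG q < 0.05, enrichment-map overlap coefficient 0.25, GO levels 7-15
#' with min 1 gene/term and > 50% mapped, minimum 3 significant terms per
#' level, marker logFC > 0.25, single-cell QC 200-2500 genes / <= 5% mito /
#' >= 3 cells per gene, ligand-receptor detection fraction 0.1. Mode
#' switches (linkage mode, endpoint rule, log pseudocount) are explicit so
#' every run records the choices in its provenance file.
#'
#' @param seed integer seed driving the synthetic generators.
#' @return named list; pass to [run_compare()], overriding entries as
#'   needed. `n_conserved` is the size of the rank-conserved anchor set
#'   used for cross-species median scaling.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = TRUE,          # generate synthetic inputs (no external data)
    bulk = list(), genesets = list(), cells = list(),  # generator overrides
    min_goc = 75, min_wga = 75,
    n_conserved = 800,
    pseudocount = 1,
    de_method = "welch",
    q_cut = 0.05,
    overlap_cutoff = 0.25,
    level_range = c(7, 15), min_genes_per_term = 1,
    min_mapped_fraction = 0.5, min_bps = 3,
    linkage_mode = "weight", endpoint_rule = "both",
    marker_logfc = 0.25,
    qc = list(min_genes = 200, max_genes = 2500, max_mito_pct = 5,
              min_cells_per_gene = 3),
    lr_fraction = 0.1,
    cells_required = list(n_types = 10, fraction = 0.02, min_cells = 6,
                          confidence = 0.95)
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys of [pipeline_config()].
#' @return configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  utils::modifyList(pipeline_config(), yaml::read_yaml(path))
}

# mean expression per region over naive MG replicates, given sample metadata
.region_means <- function(em, meta, regions) {
  sapply(regions, function(r) {
    cols <- meta$sample[meta$region == r & meta$plexus == "MG" &
                          meta$condition == "naive"]
    rowMeans(em[, cols, drop = FALSE])
  })
}

#' Run the full cross-species comparison on synthetic inputs
#'
#' Executes the pipeline end-to-end: ortholog filtering -> RPKM ->
#' cross-species median scaling on rank-conserved genes -> log2 ->
#' regional similarity testing (KS, chi-squared, Spearman) -> differential
#' expression per species -> GO over-representation, specificity filtering,
#' enrichment-map construction -> cross-species linkage coverage ->
#' WikiPathway scores (harmonic-mean-p combination, gene percent,
#' enrichment ratios) -> single-cell summaries (QC, markers, cell-type DEG
#' lists, ligand-receptor calls with VNS flags) -> cells-required
#' calculation. When `out_dir` is set, every table is written as TSV along
#' with a provenance YAML recording seed and thresholds.
#'
#' @param config list from [pipeline_config()] (entries may be overridden),
#'   or a YAML path.
#' @param out_dir optional output directory.
#' @return a report bundle (named list of all stage outputs).
#' @export
run_compare <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  if (!isTRUE(cfg$simulate)) {
    stop("only synthetic-input runs are bundled; set simulate = TRUE or ",
         "call the stage functions directly on your own files")
  }

  # --- stage: simulate -----------------------------------------------------
  bulk_cfg <- utils::modifyList(list(seed = cfg$seed), cfg$bulk)
  bulk <- generate_bulk(bulk_cfg)
  pig_meta <- bulk$meta$pig
  hum_meta <- bulk$meta$human

  # --- stage: orthologs ----------------------------------------------------
  orth <- filter_high_quality(bulk$orthologs, cfg$min_goc, cfg$min_wga)

  # --- stage: normalize ----------------------------------------------------
  rpkm_pig <- rpkm(bulk$counts$pig, bulk$gene_length$pig)
  rpkm_hum <- rpkm(bulk$counts$human, bulk$gene_length$human)
  # project the human matrix into the pig gene namespace and join
  rpkm_hum_a <- suppressMessages(map_gene_space(rpkm_hum, orth, "b_to_a"))
  shared <- intersect(rownames(rpkm_pig), rownames(rpkm_hum_a))
  joint <- cbind(rpkm_pig[shared, , drop = FALSE],
                 rpkm_hum_a[shared, , drop = FALSE])
  pool <- sum(iqr_eligible(joint))
  conserved <- select_rank_conserved(joint, min(cfg$n_conserved, pool))
  scaled <- cross_species_scale(joint, conserved)
  log_em <- log2_transform(scaled$matrix, cfg$pseudocount)

  # --- stage: similarity ---------------------------------------------------
  pig_means <- .region_means(log_em, pig_meta, unique(pig_meta$region))
  hum_means <- .region_means(log_em, hum_meta, unique(hum_meta$region))
  colnames(pig_means) <- paste0("pig_", colnames(pig_means))
  colnames(hum_means) <- paste0("hum_", colnames(hum_means))
  region_pairs <- data.frame(pig = colnames(pig_means),
                             human = colnames(hum_means),
                             stringsAsFactors = FALSE)
  similarity <- do.call(rbind, lapply(seq_len(nrow(region_pairs)), function(i)
    cbind(region_pairs[i, ],
          similarity_report(pig_means[, region_pairs$pig[i]],
                            hum_means[, region_pairs$human[i]]))))
  spearman <- spearman_pairwise(cbind(pig_means, hum_means))

  # --- stage: differential expression --------------------------------------
  # within-species contrasts run on per-species median-normalized RPKM
  # (composition-robust); the conserved-anchored joint matrix above serves
  # the cross-species similarity stage
  de_cols <- function(meta, region, plexus = "MG", condition = "naive") {
    meta$sample[meta$region == region & meta$plexus == plexus &
                  meta$condition == condition]
  }
  lg_pig <- log2_transform(
    cross_species_scale(rpkm_pig, rownames(rpkm_pig))$matrix,
    cfg$pseudocount)
  lg_hum <- log2_transform(
    cross_species_scale(rpkm_hum, rownames(rpkm_hum))$matrix,
    cfg$pseudocount)
  deg_pig <- simple_de(lg_pig,
                       de_cols(pig_meta, pig_meta$region[1]),
                       de_cols(pig_meta, "dC"), method = cfg$de_method)
  deg_hum <- simple_de(lg_hum,
                       de_cols(hum_meta, hum_meta$region[1]),
                       de_cols(hum_meta, "dC"), method = cfg$de_method)
  sig_pig <- significant_degs(deg_pig, cfg$q_cut)
  sig_hum <- significant_degs(deg_hum, cfg$q_cut)
  # project the human DEG list into the pig namespace for network matching
  sig_hum_mapped <- suppressMessages(
    map_gene_space(sig_hum$gene, orth, "b_to_a"))

  # --- stage: enrichment and map -------------------------------------------
  background <- rownames(lg_pig)
  gs_cfg <- utils::modifyList(list(seed = cfg$seed), cfg$genesets)
  gs <- generate_genesets(background, gs_cfg, planted_degs = sig_pig$gene)
  enr <- suppressWarnings(enrich_fisher(sig_pig$gene, background, gs$go))
  specific <- filter_specific_terms(enr, gs$go, cfg$min_genes_per_term,
                                    cfg$min_mapped_fraction, cfg$level_range)
  go_level <- select_go_level(specific, cfg$min_bps, cfg$q_cut)
  sig_terms <- enr$term_id[enr$q < cfg$q_cut & enr$overlap_count >= 1]
  term_degs <- lapply(gs$go$sets[sig_terms], intersect, sig_pig$gene)
  term_degs <- term_degs[lengths(term_degs) > 0]
  emap <- build_enrichment_map(term_degs, cfg$overlap_cutoff,
                               node_info = enr[c("term_id", "q")])

  coverage <- NULL
  if (nrow(emap$edges) > 0) {
    coverage <- linkage_coverage(emap, sig_hum_mapped, sig_pig$gene,
                                 mode = cfg$linkage_mode,
                                 endpoint_rule = cfg$endpoint_rule)
  }

  # --- stage: pathway scores -----------------------------------------------
  wp_scores <- score_wikipathways(deg_restrict(sig_pig, background), gs$wp)
  ratios <- do.call(rbind, lapply(unique(wp_scores$pathway_id), function(pw) {
    qs <- wp_scores[wp_scores$pathway_id == pw, ]
    qu <- qs$q[qs$direction == "up"]; qd <- qs$q[qs$direction == "down"]
    r <- if (length(qu) == 1 && length(qd) == 1 &&
               !is.na(qu) && !is.na(qd)) {
      as.numeric(enrichment_ratio(qu, qd))
    } else NA_real_
    data.frame(pathway_id = pw, ratio_up_down = r, stringsAsFactors = FALSE)
  }))
  pro_terms <- highlight_terms(emap, gs$pro)
  anti_terms <- highlight_terms(emap, gs$anti)

  # --- stage: celltype -----------------------------------------------------
  # ligand/receptor genes named from the bulk namespace so the VNS-response
  # flags can consult the bulk differential-expression p-value tables
  n_lr <- utils::modifyList(cell_config(), cfg$cells)$lr_pairs
  lr_names <- list(
    ligand_names = head(c(bulk$truth$deg_vns$up, background), n_lr),
    receptor_names = head(c(bulk$truth$deg_region$up, background), n_lr))
  cell_cfg <- utils::modifyList(c(list(seed = cfg$seed), lr_names),
                                cfg$cells)
  cells <- generate_cells(cell_cfg)
  qc <- qc_filter(cells$counts, cells$mito_genes,
                  cfg$qc$min_genes, cfg$qc$max_genes, cfg$qc$max_mito_pct,
                  cfg$qc$min_cells_per_gene)
  labels_qc <- cells$labels[colnames(qc)]
  markers <- find_markers(qc, labels_qc, cfg$marker_logfc)
  calls <- call_interactions(qc, labels_qc, cells$lr_pairs, cfg$lr_fraction)
  # VNS response: compare each gene's regional-DE p-value computed among
  # stimulated samples with the one computed among naive samples
  deg_vns <- simple_de(lg_pig,
                       de_cols(pig_meta, pig_meta$region[1],
                               condition = "VNS"),
                       de_cols(pig_meta, "dC", condition = "VNS"),
                       method = cfg$de_method)
  p_naive <- setNames(deg_pig$p, deg_pig$gene)
  p_vns <- setNames(deg_vns$p, deg_vns$gene)
  calls <- suppressWarnings(vns_response(calls, p_naive, p_vns))
  n_cells_needed <- do.call(cells_required, cfg$cells_required)

  report <- list(
    config = cfg,
    orthologs = orth,
    conserved_genes = conserved,
    scaling = scaled$scaling,
    similarity = similarity,
    spearman = spearman,
    deg = list(pig = deg_pig, human = deg_hum, vns = deg_vns),
    enrichment = enr, specific_terms = specific, go_level = go_level,
    map = emap, coverage = coverage,
    wp_scores = wp_scores, wp_ratios = ratios,
    inflammatory_terms = list(pro = pro_terms, anti = anti_terms),
    markers = markers, interaction_calls = calls,
    cells_required = n_cells_needed,
    truth = list(bulk = bulk$truth, genesets = gs$truth,
                 cells = cells$truth))
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

# keep only DEGs present in the background (guards composed stages)
deg_restrict <- function(deg, background) {
  deg[deg$gene %in% background, , drop = FALSE]
}

.write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  w(report$similarity, "similarity")
  w(report$deg$pig, "deg_pig")
  w(report$deg$human, "deg_human")
  w(report$enrichment, "enrichment")
  w(report$specific_terms, "specific_terms")
  w(report$map$nodes, "map_nodes")
  w(report$map$edges, "map_edges")
  w(report$wp_scores, "wp_scores")
  w(report$wp_ratios, "wp_ratios")
  w(report$markers, "markers")
  w(report$interaction_calls, "interaction_calls")
  if (!is.null(report$coverage)) {
    cov <- report$coverage
    w(data.frame(field = names(unlist(cov)), value = unlist(cov)),
      "coverage")
  }
  cfg <- report$config
  provenance <- list(
    package = "crossens",
    version = as.character(utils::packageVersion("crossens")),
    seed = cfg$seed,
    thresholds = cfg[c("min_goc", "min_wga", "q_cut", "overlap_cutoff",
                       "level_range", "min_bps", "marker_logfc",
                       "lr_fraction", "linkage_mode", "endpoint_rule",
                       "pseudocount", "de_method")],
    cells_required = report$cells_required,
    go_level = report$go_level)
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}
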