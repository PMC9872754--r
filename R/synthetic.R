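#' Default configuration for the bulk synthetic generator
#'
#' The defaults mirror the comparative study design the package targets:
#' pig samples over three colonic regions (pC, tC, dC) in two plexus layers
#' (myenteric MG, inner submucosal ISG) with 6 naive and 3
#' vagal-nerve-stimulated (VNS) replicates per region x plexus, and human
#' myenteric samples over the analogous regions (aC, tC, dC) with 4
#' replicates each. Counts are negative binomial around a latent log2
#' expression program shared across species through a 1:1 ortholog
#' bijection, with planted differential programs of |log2FC| = 1.5 and
#' dispersion 0.1.
#'
#' @return named list of generator parameters.
#' @export
bulk_config <- function() {
  list(
    n_genes = 2000,
    pig_regions = c("pC", "tC", "dC"),
    human_regions = c("aC", "tC", "dC"),
    plexus = c("MG", "ISG"),
    n_naive = 6, n_vns = 3, n_human = 4,
    n_deg_region = 300,   # planted pC-vs-dC program (half up, half down)
    n_deg_plexus = 60,    # planted MG-vs-ISG program
    n_deg_vns = 60,       # planted VNS-response program
    effect_log2 = 1.5,
    dispersion = 0.1,
    species_sd = 0.25,    # per-gene cross-species perturbation (log2)
    libsize_range = c(1e6, 3e6),
    gene_length_range = c(500, 5000),
    frac_non121 = 0.1,    # extra one2many/many2many ortholog records
    frac_low_score = 0.1, # extra sub-threshold-score records
    seed = 1L
  )
}

# planted gene programs: sample disjoint up/down sets from the gene pool
.plant_program <- function(pool, n, effect) {
  up <- pool[seq_len(n / 2)]
  down <- pool[(n / 2 + 1):n]
  list(up = up, down = down,
       effect = setNames(c(rep(effect, length(up)),
                           rep(-effect, length(down))), c(up, down)))
}

#' Generate synthetic cross-species bulk RNA-seq data
#'
#' Simulates two species sharing one latent expression program through a
#' strict 1:1 ortholog bijection, with planted regional, plexus and VNS
#' differential programs, negative-binomial counts, library-size variation
#' and gene lengths. The ortholog table additionally carries decoy records
#' (non-1:1 homology, sub-threshold GOC/WGA scores) that
#' [filter_high_quality()] must remove.
#'
#' @param config list from [bulk_config()] (entries may be overridden).
#' @param out_dir optional directory; when given, counts, metadata, gene
#'   lengths, the ortholog table and the truth JSON are written there.
#' @return list with `counts` (per species), `gene_length` (per species),
#'   `meta` (per species sample metadata), `orthologs` (unfiltered
#'   `ortholog_table`) and `truth` (planted programs, library sizes, seed).
#' @export
generate_bulk <- function(config = bulk_config(), out_dir = NULL) {
  cfg <- utils::modifyList(bulk_config(), config)
  n_deg_total <- cfg$n_deg_region + cfg$n_deg_plexus + cfg$n_deg_vns
  if (n_deg_total > cfg$n_genes) {
    stop("more planted DEGs (", n_deg_total, ") than genes (", cfg$n_genes, ")")
  }
  set.seed(cfg$seed)
  genes_a <- sprintf("pigG%04d", seq_len(cfg$n_genes))
  genes_b <- sprintf("humG%04d", seq_len(cfg$n_genes))

  # sample sheets
  meta_pig <- expand.grid(replicate = seq_len(cfg$n_naive + cfg$n_vns),
                          plexus = cfg$plexus, region = cfg$pig_regions,
                          stringsAsFactors = FALSE)
  meta_pig$condition <- ifelse(meta_pig$replicate <= cfg$n_naive,
                               "naive", "VNS")
  meta_pig$species <- "pig"
  meta_human <- expand.grid(replicate = seq_len(cfg$n_human),
                            plexus = "MG", region = cfg$human_regions,
                            stringsAsFactors = FALSE)
  meta_human$condition <- "naive"
  meta_human$species <- "human"
  finish_meta <- function(m, prefix) {
    m$sex <- rep_len(c("M", "F"), nrow(m))
    m$subject <- paste0(prefix, "S", m$replicate)
    m$sample <- sprintf("%s_%s_%s_%s_r%d", prefix, m$region, m$plexus,
                        m$condition, m$replicate)
    m[c("sample", "species", "region", "plexus", "condition", "sex",
        "subject")]
  }
  meta_pig <- finish_meta(meta_pig, "pig")
  meta_human <- finish_meta(meta_human, "hum")

  base_log2 <- rnorm(cfg$n_genes, mean = 4, sd = 1.5)
  len_a <- round(runif(cfg$n_genes, cfg$gene_length_range[1],
                       cfg$gene_length_range[2]))
  len_b <- pmax(200L, round(len_a * runif(cfg$n_genes, 0.9, 1.1)))

  # planted programs over disjoint blocks of adequately expressed genes: a
  # planted effect whose low side drops into shot-noise territory is
  # untestable truth, so require the low side to keep >= 8 RPKM-scale
  # expression and >= 30 expected reads at the smallest library size
  low_expr <- 2^(base_log2 - cfg$effect_log2)
  low_mu <- low_expr * (len_a / 1e3) * (cfg$libsize_range[1] / 1e6)
  expressed <- which(low_expr >= 8 & low_mu >= 30)
  if (length(expressed) < n_deg_total) {
    stop("not enough adequately expressed genes to plant ", n_deg_total,
         " DEGs; increase n_genes")
  }
  shuffled <- sample(expressed)
  prog_region <- .plant_program(shuffled[1:cfg$n_deg_region],
                                cfg$n_deg_region, cfg$effect_log2)
  off <- cfg$n_deg_region
  prog_plexus <- .plant_program(shuffled[(off + 1):(off + cfg$n_deg_plexus)],
                                cfg$n_deg_plexus, cfg$effect_log2)
  off <- off + cfg$n_deg_plexus
  prog_vns <- .plant_program(shuffled[(off + 1):(off + cfg$n_deg_vns)],
                             cfg$n_deg_vns, cfg$effect_log2)

  latent <- function(meta, species_shift, first_region) {
    L <- matrix(base_log2, nrow = cfg$n_genes, ncol = nrow(meta))
    L <- L + species_shift  # per-gene species perturbation
    for (s in seq_len(nrow(meta))) {
      if (meta$region[s] == first_region) {
        L[prog_region$up, s] <- L[prog_region$up, s] + cfg$effect_log2
        L[prog_region$down, s] <- L[prog_region$down, s] - cfg$effect_log2
      }
      if (meta$plexus[s] == "ISG") {
        L[prog_plexus$up, s] <- L[prog_plexus$up, s] + cfg$effect_log2
        L[prog_plexus$down, s] <- L[prog_plexus$down, s] - cfg$effect_log2
      }
      if (meta$condition[s] == "VNS") {
        L[prog_vns$up, s] <- L[prog_vns$up, s] + cfg$effect_log2
        L[prog_vns$down, s] <- L[prog_vns$down, s] - cfg$effect_log2
      }
    }
    L
  }
  shift_pig <- rnorm(cfg$n_genes, 0, cfg$species_sd / 2)
  shift_hum <- rnorm(cfg$n_genes, 0, cfg$species_sd / 2)

  draw_counts <- function(meta, species_shift, first_region, genes, len) {
    L <- latent(meta, species_shift, first_region)
    lib <- runif(nrow(meta), cfg$libsize_range[1], cfg$libsize_range[2])
    expr <- 2^L
    mu <- expr * outer(len / 1e3, lib / 1e6)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes,
                     dimnames = list(genes, meta$sample))
    list(counts = counts, lib = setNames(lib, meta$sample))
  }
  pig <- draw_counts(meta_pig, shift_pig, cfg$pig_regions[1], genes_a, len_a)
  hum <- draw_counts(meta_human, shift_hum, cfg$human_regions[1], genes_b,
                     len_b)

  # ortholog table: the true bijection plus decoy records
  core <- data.frame(gene_a = genes_a, gene_b = genes_b,
                     homology_type = "one2one",
                     goc_score = round(runif(cfg$n_genes, 76, 100), 1),
                     wga_score = round(runif(cfg$n_genes, 76, 100), 1),
                     stringsAsFactors = FALSE)
  n_non <- round(cfg$frac_non121 * cfg$n_genes)
  n_low <- round(cfg$frac_low_score * cfg$n_genes)
  decoy_non <- data.frame(
    gene_a = sprintf("pigX%04d", seq_len(n_non)),
    gene_b = sprintf("humX%04d", sample(n_non)),
    homology_type = sample(c("one2many", "many2many"), n_non, replace = TRUE),
    goc_score = round(runif(n_non, 76, 100), 1),
    wga_score = round(runif(n_non, 76, 100), 1),
    stringsAsFactors = FALSE)
  decoy_low <- data.frame(
    gene_a = sprintf("pigY%04d", seq_len(n_low)),
    gene_b = sprintf("humY%04d", seq_len(n_low)),
    homology_type = "one2one",
    goc_score = round(runif(n_low, 0, 75), 1),
    wga_score = round(runif(n_low, 0, 75), 1),
    stringsAsFactors = FALSE)
  orth <- as_ortholog_table(rbind(core, decoy_non, decoy_low),
                            filtered = FALSE)

  ids <- function(prog) {  # record planted programs by species-A gene id
    list(up = genes_a[prog$up], down = genes_a[prog$down],
         effect = setNames(unname(prog$effect),
                           genes_a[as.integer(names(prog$effect))]))
  }
  truth <- list(
    deg_region = ids(prog_region), deg_plexus = ids(prog_plexus),
    deg_vns = ids(prog_vns),
    library_size = list(pig = pig$lib, human = hum$lib),
    ortholog_bijection = setNames(genes_b, genes_a),
    seed = cfg$seed, config = cfg)
  sim <- list(counts = list(pig = pig$counts, human = hum$counts),
              gene_length = list(pig = setNames(len_a, genes_a),
                                 human = setNames(len_b, genes_b)),
              meta = list(pig = meta_pig, human = meta_human),
              orthologs = orth, truth = truth)
  if (!is.null(out_dir)) .write_bulk(sim, out_dir)
  sim
}

.write_bulk <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (sp in names(sim$counts)) {
    write_matrix_tsv(sim$counts[[sp]],
                     file.path(out_dir, paste0("counts_", sp, ".tsv")))
    write.table(data.frame(gene = names(sim$gene_length[[sp]]),
                           length_bp = sim$gene_length[[sp]]),
                file.path(out_dir, paste0("gene_length_", sp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim$meta[[sp]],
                file.path(out_dir, paste0("meta_", sp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_ortholog_table(sim$orthologs, file.path(out_dir, "orthologs.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth_bulk.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Default configuration for the gene-set generator
#' @return named list of generator parameters.
#' @export
geneset_config <- function() {
  list(
    n_go_terms = 30,
    go_size_range = c(10, 40),
    go_levels = 7:15,
    overlap_targets = c(0, 0.3, 0.5),  # coefficient with the previous term
    n_wp = 12,
    wp_size_range = c(15, 50),
    wp_categories = c("smooth_muscle", "gap_junction", "angiotensin",
                      "neurotransmission", "synaptic", "ion_channel",
                      "metabolism", "immune", "development"),
    n_inflam = 25,  # genes per pro-/anti-inflammatory signature
    # planted DEG-enriched terms: a chain of terms drawing overlapping
    # windows from the DEG list, so the enrichment map has real topology
    n_planted_terms = 6,
    planted_deg_genes = 12,     # DEGs per planted term
    planted_window_step = 8,    # window step (overlap = genes - step)
    planted_filler = 8,         # background filler genes per planted term
    seed = 1L
  )
}

#' Generate a synthetic gene-set database with controlled overlaps
#'
#' Builds a GOBP-like leveled term collection whose consecutive terms
#' overlap at configured coefficients (realized exactly, since shared genes
#' are drawn from the previous term and the remainder from an untouched
#' pool), a WikiPathways-like collection with the nine study categories as
#' a sidecar, and pro-/anti-inflammatory gene signatures. Optionally plants
#' one GO term enriched for a supplied DEG list.
#'
#' @param universe character vector: the gene universe to draw from.
#' @param config list from [geneset_config()] (entries may be overridden).
#' @param planted_degs optional gene vector; when given, a term
#'   `GO:PLANTED` is added whose members are mostly these genes.
#' @param out_dir optional directory for GMT files, sidecar TSVs and truth
#'   JSON.
#' @return list with `go` (a `geneset_db` with `go_level` and
#'   `associated_gene_count`), `wp` (a `geneset_db` with `category`),
#'   `pro`, `anti` (gene vectors) and `truth` (membership map, overlap
#'   targets, seed).
#' @export
generate_genesets <- function(universe, config = geneset_config(),
                              planted_degs = NULL, out_dir = NULL) {
  cfg <- utils::modifyList(geneset_config(), config)
  set.seed(cfg$seed)
  pool <- sample(universe)  # consumed left to right; keeps terms disjoint
  take <- function(n) {
    if (n > length(pool)) stop("gene universe exhausted; enlarge it or ",
                               "reduce term counts/sizes")
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  go_sets <- list()
  targets <- numeric(0)
  prev <- character(0)
  for (i in seq_len(cfg$n_go_terms)) {
    size <- sample(cfg$go_size_range[1]:cfg$go_size_range[2], 1)
    target <- if (i == 1) 0 else sample(cfg$overlap_targets, 1)
    n_shared <- round(target * min(size, length(prev)))
    members <- c(if (n_shared > 0) sample(prev, n_shared),
                 take(size - n_shared))
    id <- sprintf("GO:%07d", i)
    go_sets[[id]] <- members
    targets[id] <- target
    prev <- members
  }
  planted_ids <- character(0)
  if (!is.null(planted_degs)) {
    degs <- sample(unique(planted_degs))
    step <- cfg$planted_window_step
    need <- (cfg$n_planted_terms - 1) * step + cfg$planted_deg_genes
    n_terms <- if (length(degs) >= need) cfg$n_planted_terms else
      max(1, (length(degs) - cfg$planted_deg_genes) %/% step + 1)
    for (i in seq_len(n_terms)) {
      win <- degs[((i - 1) * step + 1):((i - 1) * step + cfg$planted_deg_genes)]
      id <- sprintf("GO:PLANTED%02d", i)
      go_sets[[id]] <- c(win, take(cfg$planted_filler))
      targets[id] <- NA_real_
      planted_ids <- c(planted_ids, id)
    }
  }
  lev <- sample(cfg$go_levels, length(go_sets), replace = TRUE)
  # the planted chain shares one specificity level, as a coherent planted
  # program would; the minimum-level selection rule then has a target
  lev[names(go_sets) %in% planted_ids] <- sample(cfg$go_levels, 1)
  go_info <- data.frame(
    term_id = names(go_sets),
    name = paste0("synthetic biological process ", seq_along(go_sets)),
    source = "GOBP",
    go_level = lev,
    associated_gene_count = lengths(go_sets),
    stringsAsFactors = FALSE)

  wp_sets <- list()
  for (i in seq_len(cfg$n_wp)) {
    size <- sample(cfg$wp_size_range[1]:cfg$wp_size_range[2], 1)
    wp_sets[[sprintf("WP%04d", i)]] <- sample(universe, size)
  }
  wp_info <- data.frame(
    term_id = names(wp_sets),
    name = paste0("synthetic pathway ", seq_len(cfg$n_wp)),
    source = "WikiPathways",
    category = sample(cfg$wp_categories, cfg$n_wp, replace = TRUE),
    stringsAsFactors = FALSE)

  # inflammatory signatures partially drawn from the DEG list (when given)
  # so that pro/anti sharing with the enriched network is a live scenario
  draw_sig <- function(exclude) {
    n_deg_part <- if (is.null(planted_degs)) 0 else
      min(round(0.4 * cfg$n_inflam), length(setdiff(planted_degs, exclude)))
    c(sample(setdiff(planted_degs, exclude), n_deg_part),
      sample(setdiff(universe, c(exclude, planted_degs)),
             cfg$n_inflam - n_deg_part))
  }
  pro <- draw_sig(character(0))
  anti <- draw_sig(pro)

  out <- list(go = geneset_db(go_sets, go_info),
              wp = geneset_db(wp_sets, wp_info),
              pro = pro, anti = anti,
              truth = list(overlap_targets = targets,
                           planted_terms = planted_ids,
                           membership = go_sets, seed = cfg$seed))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_gmt(go_sets, file.path(out_dir, "gobp.gmt"), go_info$name)
    write.table(go_info, file.path(out_dir, "gobp_sidecar.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gmt(wp_sets, file.path(out_dir, "wikipathways.gmt"), wp_info$name)
    write.table(wp_info, file.path(out_dir, "wikipathways_sidecar.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(list(pro_inflammatory = pro, anti_inflammatory = anti),
              file.path(out_dir, "inflammatory.gmt"))
    jsonlite::write_json(out$truth, file.path(out_dir, "truth_genesets.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Default configuration for the single-cell generator
#'
#' Emulates the five ENS subpopulations reported for porcine myenteric
#' preparations — cholinergic, glutamatergic and nitrergic neurons plus two
#' glial types — with planted marker genes (fold 4), a ~2% baseline
#' mitochondrial fraction, dropout, and planted ligand-receptor activity
#' from cholinergic neurons to glia. Small blocks of deliberately
#' low-complexity and high-mitochondrial cells exercise the QC filter.
#'
#' @return named list of generator parameters.
#' @export
cell_config <- function() {
  list(
    types = c("cholinergic", "glutamatergic", "nitrergic",
              "glia_SLC41A1", "glia_SPC24"),
    cells_per_type = 150,
    n_genes = 600,
    n_mito = 20,
    n_markers = 10,
    marker_fold = 4,
    base_meanlog = -0.2, base_sdlog = 0.8,  # per-gene lognormal mean UMI
    dropout = 0.2,
    mito_frac = 0.02,
    n_low_quality = 5,   # cells with almost no detected genes
    n_high_mito = 5,     # cells with ~10% mitochondrial counts
    lr_pairs = 8,
    ligand_names = NULL, receptor_names = NULL,  # default LIGxx / RECxx
    active_pairs = list(c("cholinergic", "glia_SLC41A1")),
    active_detection = c(0.5, 0.4),   # ligand (source), receptor (target)
    inactive_detection = 0.02,
    seed = 1L
  )
}

#' Generate a synthetic single-cell UMI fixture
#'
#' Poisson-lognormal UMI counts with dropout for five labelled cell types,
#' planted per-type marker genes, mitochondrial genes, QC-failing cell
#' blocks and a ligand-receptor table with planted active subset pairs.
#'
#' @param config list from [cell_config()] (entries may be overridden).
#' @param out_dir optional directory; writes the MTX triplet, labels TSV,
#'   L-R TSV and truth JSON.
#' @return list with `counts` (sparse genes x cells), `labels`,
#'   `mito_genes`, `lr_pairs` (data.frame) and `truth` (planted markers,
#'   active pairs, QC-fail barcodes, seed).
#' @export
generate_cells <- function(config = cell_config(), out_dir = NULL) {
  cfg <- utils::modifyList(cell_config(), config)
  set.seed(cfg$seed)
  n_types <- length(cfg$types)
  n_lig <- cfg$lr_pairs
  mito_genes <- sprintf("MT-%02d", seq_len(cfg$n_mito))
  lig_genes <- if (is.null(cfg$ligand_names)) {
    sprintf("LIG%02d", seq_len(n_lig))
  } else rep_len(cfg$ligand_names, n_lig)
  rec_genes <- if (is.null(cfg$receptor_names)) {
    sprintf("REC%02d", seq_len(n_lig))
  } else rep_len(cfg$receptor_names, n_lig)
  n_body <- cfg$n_genes - cfg$n_mito - 2 * n_lig
  body_genes <- sprintf("scG%04d", seq_len(n_body))
  genes <- c(body_genes, mito_genes, lig_genes, rec_genes)

  labels <- rep(cfg$types, each = cfg$cells_per_type)
  n_cells <- length(labels)
  barcodes <- sprintf("cell%04d", seq_len(n_cells))

  # per-type marker blocks drawn from the body genes
  markers <- split(body_genes[seq_len(cfg$n_markers * n_types)],
                   rep(cfg$types, each = cfg$n_markers))

  base <- rlnorm(length(genes), cfg$base_meanlog, cfg$base_sdlog)
  names(base) <- genes
  base[mito_genes] <- sum(base[body_genes]) * cfg$mito_frac /
    (1 - cfg$mito_frac) / cfg$n_mito
  base[c(lig_genes, rec_genes)] <- -log(1 - cfg$inactive_detection)

  mu <- matrix(base, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, barcodes))
  for (ty in cfg$types) {
    mu[markers[[ty]], labels == ty] <-
      mu[markers[[ty]], labels == ty] * cfg$marker_fold
  }
  for (i in seq_along(cfg$active_pairs)) {
    pair <- cfg$active_pairs[[i]]
    # detection fraction f under Poisson => mean -log(1 - f), pre-dropout
    mu[lig_genes[i], labels == pair[1]] <-
      -log(1 - cfg$active_detection[1]) / (1 - cfg$dropout)
    mu[rec_genes[i], labels == pair[2]] <-
      -log(1 - cfg$active_detection[2]) / (1 - cfg$dropout)
  }
  counts <- matrix(rpois(length(mu), mu), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  keep <- matrix(rbinom(length(mu), 1, 1 - cfg$dropout), nrow = nrow(mu))
  counts <- counts * keep

  qc_fail <- list(low_quality = character(0), high_mito = character(0))
  if (cfg$n_low_quality > 0) {
    idx <- sample(n_cells, cfg$n_low_quality)
    for (j in idx) {  # wipe all but ~50 random genes
      off <- sample(length(genes), length(genes) - 50)
      counts[off, j] <- 0
    }
    qc_fail$low_quality <- barcodes[idx]
  }
  if (cfg$n_high_mito > 0) {
    idx <- sample(setdiff(seq_len(n_cells),
                          match(qc_fail$low_quality, barcodes)),
                  cfg$n_high_mito)
    for (j in idx) {  # raise mito content to ~10% of the cell's counts
      tot <- sum(counts[, j])
      counts[mito_genes, j] <- rpois(cfg$n_mito, 0.12 * tot / cfg$n_mito)
    }
    qc_fail$high_mito <- barcodes[idx]
  }

  lr <- data.frame(ligand = lig_genes, receptor = rec_genes,
                   stringsAsFactors = FALSE)
  truth <- list(markers = markers, marker_fold = cfg$marker_fold,
                active_pairs = lapply(seq_along(cfg$active_pairs), function(i)
                  list(source = cfg$active_pairs[[i]][1],
                       target = cfg$active_pairs[[i]][2],
                       ligand = lig_genes[i], receptor = rec_genes[i])),
                qc_fail = qc_fail, labels = setNames(labels, barcodes),
                seed = cfg$seed, config = cfg)
  sim <- list(counts = Matrix::Matrix(counts, sparse = TRUE),
              labels = setNames(labels, barcodes),
              mito_genes = mito_genes, lr_pairs = lr, truth = truth)
  if (!is.null(out_dir)) {
    write_mtx_dir(sim$counts, file.path(out_dir, "cells"))
    write.table(data.frame(barcode = barcodes, label = labels),
                file.path(out_dir, "cell_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(lr, file.path(out_dir, "lr_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth[names(truth) != "config"],
                         file.path(out_dir, "truth_cells.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  sim
}
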