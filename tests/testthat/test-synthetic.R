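# small bulk configuration used where full study-scale runs are unneeded
small_bulk <- function(seed = 1) {
  list(seed = seed, n_genes = 600, n_deg_region = 60, n_deg_plexus = 20,
       n_deg_vns = 20)
}

test_that("the bulk generator is byte-deterministic under its seed", {
  a <- generate_bulk(small_bulk())
  b <- generate_bulk(small_bulk())
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$deg_region, b$truth$deg_region)
  c2 <- generate_bulk(small_bulk(seed = 2))
  expect_false(identical(a$counts$pig, c2$counts$pig))
})

test_that("bulk truth is consistent with the emitted objects", {
  sim <- generate_bulk(small_bulk())
  planted <- unlist(lapply(sim$truth[c("deg_region", "deg_plexus",
                                       "deg_vns")],
                           function(pr) c(pr$up, pr$down)),
                    use.names = FALSE)
  expect_true(all(unique(planted) %in% rownames(sim$counts$pig)))

  # the design mirrors the study: 3 regions x 2 plexus x (6 naive + 3 VNS)
  # pig samples and 3 regions x 4 human MG samples
  expect_equal(ncol(sim$counts$pig), 54)
  expect_equal(ncol(sim$counts$human), 12)
  expect_setequal(unique(sim$meta$pig$region), c("pC", "tC", "dC"))
  expect_setequal(unique(sim$meta$human$region), c("aC", "tC", "dC"))

  # filtering the emitted table recovers exactly the true 1:1 bijection
  orth <- filter_high_quality(sim$orthologs)
  expect_equal(nrow(orth), 600)
  expect_equal(setNames(orth$gene_b, orth$gene_a),
               sim$truth$ortholog_bijection)

  expect_error(generate_bulk(list(n_genes = 50, n_deg_region = 60)),
               "more planted DEGs")
})

test_that("bulk files round-trip through the emitted TSV formats", {
  dir <- tempfile()
  sim <- generate_bulk(small_bulk(), out_dir = dir)
  counts <- read_matrix_tsv(file.path(dir, "counts_pig.tsv"))
  expect_equal(counts, sim$counts$pig, ignore_attr = TRUE)
  orth <- read_ortholog_table(file.path(dir, "orthologs.tsv"))
  expect_equal(nrow(orth), nrow(sim$orthologs))
  expect_true(file.exists(file.path(dir, "truth_bulk.json")))
})

test_that("null data yields no planted-free discoveries across seeds", {
  # zero planted effects: the BH cut should return (almost) nothing
  fp <- vapply(1:5, function(s) {
    sim <- generate_bulk(list(seed = s, n_genes = 400, n_deg_region = 2,
                              n_deg_plexus = 2, n_deg_vns = 2,
                              effect_log2 = 0))
    lg <- log2_transform(rpkm(sim$counts$pig, sim$gene_length$pig))
    meta <- sim$meta$pig
    a <- meta$sample[meta$region == "pC" & meta$plexus == "MG" &
                       meta$condition == "naive"]
    b <- meta$sample[meta$region == "dC" & meta$plexus == "MG" &
                       meta$condition == "naive"]
    nrow(significant_degs(suppressWarnings(simple_de(lg, a, b))))
  }, numeric(1))
  expect_lte(mean(fp), 1)
})

test_that("gene sets realize their pairwise overlap targets", {
  set.seed(1)
  universe <- sprintf("u%04d", 1:3000)
  gs <- generate_genesets(universe, list(seed = 1))
  ids <- grep("^GO:[0-9]", names(gs$go$sets), value = TRUE)
  targets <- gs$truth$overlap_targets[ids]
  for (i in seq_along(ids)[-1]) {
    a <- gs$go$sets[[ids[i - 1]]]
    b <- gs$go$sets[[ids[i]]]
    oc <- length(intersect(a, b)) / min(length(a), length(b))
    expect_lt(abs(oc - targets[ids[i]]), 0.05 + 1e-9)
  }
  # disjoint targets give an edgeless map, 0.5 targets link at cutoff 0.25
  pair_terms <- which(targets == 0.5)
  if (length(pair_terms) > 0) {
    i <- pair_terms[1]
    m <- build_enrichment_map(gs$go$sets[ids[c(i - 1, i)]], 0.25)
    expect_equal(nrow(m$edges), 1)
  }
})

test_that("a planted enriched term ranks first in the over-representation", {
  set.seed(99)  # DEG draw independent of the generator's own stream
  universe <- sprintf("u%04d", 1:2000)
  degs <- sample(universe, 80)
  gs <- generate_genesets(universe, list(seed = 2), planted_degs = degs)
  res <- suppressWarnings(enrich_fisher(degs, universe, gs$go))
  expect_true(grepl("^GO:PLANTED", res$term_id[1]))
  expect_true(all(res$q[grep("^GO:PLANTED", res$term_id)] < 0.05))
})

test_that("cell fixture plants recoverable markers and QC failures", {
  cells <- generate_cells(list(seed = 3))
  det <- Matrix::colSums(cells$counts > 0)
  qc <- qc_filter(cells$counts, cells$mito_genes)
  gone <- setdiff(colnames(cells$counts), colnames(qc))
  # every planted QC-failure cell is removed
  expect_true(all(unlist(cells$truth$qc_fail) %in% gone))

  labels <- cells$labels[colnames(qc)]
  mk <- find_markers(qc, labels)
  for (ty in names(cells$truth$markers)) {
    hit <- cells$truth$markers[[ty]] %in%
      mk$gene[mk$cluster == ty & mk$q < 0.05]
    expect_gte(mean(hit), 0.9)
  }

  # the planted ligand-receptor pair is called, inactive pairs are not
  calls <- call_interactions(qc, labels, cells$lr_pairs)
  act <- cells$truth$active_pairs[[1]]
  expect_true(any(calls$source == act$source & calls$target == act$target &
                    calls$ligand == act$ligand))
  inactive <- setdiff(cells$lr_pairs$ligand, act$ligand)
  expect_false(any(calls$ligand %in% inactive))
})

test_that("replicate samples share a regional expression distribution", {
  # two samples from one regional program pass the KS comparison, and a
  # planted 1-log2 location shift is detected
  pass <- shift_fail <- logical(0)
  for (s in 1:3) {
    sim <- generate_bulk(list(seed = s))
    lg <- log2_transform(
      cross_species_scale(rpkm(sim$counts$pig, sim$gene_length$pig),
                          rownames(sim$counts$pig))$matrix)
    meta <- sim$meta$pig
    for (rg in unique(meta$region)) {
      cols <- meta$sample[meta$region == rg & meta$plexus == "MG" &
                            meta$condition == "naive"]
      prs <- combn(cols, 2)
      for (j in seq_len(ncol(prs))) {
        x <- lg[, prs[1, j]]; y <- lg[, prs[2, j]]
        pass <- c(pass, ks_compare(x, y)$p > 0.05)
        shift_fail <- c(shift_fail, ks_compare(x + 1, y)$p <= 0.05)
      }
    }
  }
  expect_gte(mean(pass), 0.94)
  expect_gte(mean(shift_fail), 0.90)
})
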