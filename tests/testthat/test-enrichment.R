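test_that("hypergeometric enrichment matches a brute-force draw oracle", {
  # enumerate every possible DEG draw on a reduced instance and count how
  # often the term overlap is at least as large as observed
  oracle_p <- function(N, K, n, k) {
    draws <- combn(N, n)
    mean(colSums(draws <= K) >= k)
  }
  set.seed(17)
  for (rep in 1:15) {
    N <- sample(6:10, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    bg <- sprintf("g%02d", 1:N)
    term <- bg[1:K]
    # a DEG set realizing a specific overlap k
    k_range <- max(0, n - (N - K)):min(n, K)
    k <- k_range[sample.int(length(k_range), 1)]
    deg <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
    res <- enrich_fisher(deg, bg, list(t1 = term))
    expect_equal(res$p, oracle_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("terms without background genes are skipped, empty overlap p is 1", {
  bg <- sprintf("g%d", 1:20)
  db <- list(present = bg[1:5], absent = c("x1", "x2"))
  expect_warning(res <- enrich_fisher(bg[10:14], bg, db), "skipped")
  expect_equal(res$term_id, "present")
  expect_equal(res$overlap_count, 0L)
  expect_equal(res$p, 1)
  expect_error(enrich_fisher(c("zz"), bg, db), "outside")
})

test_that("BH threshold at q < 0.05 partitions like p.adjust", {
  set.seed(23)
  bg <- sprintf("g%03d", 1:60)
  sets <- lapply(1:12, function(i) sample(bg, 8))
  names(sets) <- sprintf("t%02d", 1:12)
  deg <- c(sets[[1]], sample(bg, 5))  # first term strongly enriched
  res <- enrich_fisher(unique(deg), bg, sets)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_equal(res$term_id[1], "t01")
})

test_that("specificity filter applies level band, gene floor and ratio", {
  db <- geneset_db(
    list(shallow = letters[1:5], good = letters[1:5], border = letters[1:2]),
    data.frame(term_id = c("shallow", "good", "border"),
               go_level = c(6, 8, 8),
               associated_gene_count = c(5, 5, 2)))
  res <- data.frame(term_id = c("shallow", "good", "border"),
                    overlap_count = c(3, 3, 1),
                    p = c(0.01, 0.01, 0.01), q = c(0.02, 0.02, 0.02))
  out <- filter_specific_terms(res, db)
  expect_equal(out$term_id, "good")       # 3/5 = 0.6 > 0.5 at level 8
  # level 6 fails the band; 1/2 = 0.5 fails the strict ratio

  db2 <- geneset_db(list(nolevel = letters[1:3]),
                    data.frame(term_id = "nolevel"))
  res2 <- data.frame(term_id = "nolevel", overlap_count = 3,
                     p = 0.01, q = 0.02)
  expect_warning(out2 <- filter_specific_terms(res2, db2), "lack")
  expect_equal(nrow(out2), 0)
})

test_that("minimum informative GO level needs enough significant terms", {
  res <- data.frame(
    go_level = c(7, 8, 8, 8, 9, 9, 9, 9, 9),
    q = c(0.01, 0.01, 0.02, 0.03, rep(0.01, 5)))
  expect_equal(select_go_level(res), 8L)
  expect_equal(select_go_level(res, min_bps = 1), 7L)
  none <- data.frame(go_level = c(7, 8), q = c(0.5, 0.9))
  expect_message(lev <- select_go_level(none), "no GO level")
  expect_true(is.na(lev))
})

test_that("enrichment-map edges follow the overlap coefficient rule", {
  # |A∩B| = 2, min size 4: coefficient 0.5 passes the 0.25 cutoff
  m <- build_enrichment_map(list(A = c("a", "b", "x", "y"),
                                 B = c("a", "b", paste0("z", 1:6))))
  expect_equal(nrow(m$edges), 1)
  expect_equal(m$edges$shared_gene_count, 2L)
  expect_equal(m$edges$overlap_coefficient, 0.5)

  ident <- build_enrichment_map(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(ident$edges$overlap_coefficient, 1)

  disj <- build_enrichment_map(list(A = letters[1:4], B = letters[5:8]))
  expect_equal(nrow(disj$edges), 0)

  # stability under term input ordering
  sets <- list(A = letters[1:5], B = letters[3:9], C = letters[8:12])
  m1 <- build_enrichment_map(sets)
  m2 <- build_enrichment_map(rev(sets))
  expect_equal(m1$edges, m2$edges)
})

test_that("term highlighting is exact set membership", {
  m <- build_enrichment_map(list(n1 = "g1", n2 = "g2", n3 = c("g1", "g3")))
  expect_equal(highlight_terms(m, "g1"), c("n1", "n3"))
  expect_equal(highlight_terms(m, character(0)), character(0))
  expect_setequal(highlight_terms(m, c("g1", "g2", "g3")),
                  c("n1", "n2", "n3"))
})

test_that("linkage coverage reproduces the hand-counted toy map", {
  m <- toy_map()
  expect_equal(nrow(m$edges), 2)
  all_genes <- unique(unlist(m$genes))
  # g3 highlights n1 and n2 only: edge (n1,n2) covered, weight 2 of 5
  cov_w <- linkage_coverage(m, "g3", all_genes, mode = "weight")
  expect_equal(cov_w$linkage_coverage, 2 / 5)
  cov_e <- linkage_coverage(m, "g3", all_genes, mode = "edge")
  expect_equal(cov_e$linkage_coverage, 1 / 2)

  # self-coverage is exactly 1 in both modes; empty subset covers nothing
  expect_equal(linkage_coverage(m, all_genes, all_genes)$linkage_coverage, 1)
  expect_equal(
    linkage_coverage(m, all_genes, all_genes, "edge")$linkage_coverage, 1)
  expect_equal(linkage_coverage(m, character(0), all_genes)$linkage_coverage,
               0)
  expect_error(linkage_coverage(m, all_genes, character(0)), "zero linkage")
})

test_that("coverage grows monotonically with the DEG subset", {
  set.seed(31)
  for (rep in 1:25) {
    m <- random_map()
    genes <- unique(unlist(m$genes))
    small <- sample(genes, ceiling(length(genes) / 4))
    large <- union(small, sample(genes, ceiling(length(genes) / 2)))
    for (mode in c("weight", "edge")) {
      expect_lte(
        linkage_coverage(m, small, genes, mode)$linkage_coverage,
        linkage_coverage(m, large, genes, mode)$linkage_coverage)
    }
  }
})

test_that("involvement fraction matches its printed arithmetic", {
  expect_equal(round(involvement_fraction(47, 135, 48, 86)), 43)
  expect_equal(involvement_fraction(1, 2, 1, 2), 50)
  expect_equal(involvement_fraction(135, 135, 86, 86), 100)
  expect_error(involvement_fraction(0, 0, 0, 0), "zero")
  expect_error(involvement_fraction(5, 4, 0, 0))
})

test_that("a few orthologous driver genes can cover a whole foreign map", {
  # foreign DEGs constructed to hit every term of the native map through
  # the bijection: full coverage despite being far fewer than native DEGs
  orth <- toy_orthologs(10, filtered = TRUE)
  native_sets <- list(t1 = c("pig01", "pig02", "pig03"),
                      t2 = c("pig03", "pig04"),
                      t3 = c("pig04", "pig05", "pig06"))
  m <- build_enrichment_map(native_sets)
  native_degs <- sprintf("pig%02d", 1:6)
  drivers <- c("hum03", "hum04")  # map to pig03/pig04, touching every term
  cov <- cross_species_match(m, drivers, orth, native_degs = native_degs)
  expect_equal(cov$linkage_coverage, 1)

  expect_warning(
    cov0 <- cross_species_match(m, "hum99", orth, native_degs = native_degs),
    "no foreign DEG")
  expect_equal(cov0$linkage_coverage, 0)
})

test_that("maps round-trip through igraph and export cleanly", {
  m <- toy_map()
  g <- map_to_igraph(m)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  tmp <- tempfile(fileext = ".graphml")
  write_enrichment_map(m, tmp)
  expect_true(file.exists(tmp))
  sif <- tempfile()
  write_enrichment_map(m, sif, format = "sif")
  expect_equal(length(readLines(paste0(sif, ".sif"))), 2)
})
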