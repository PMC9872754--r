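# small in-code fixtures shared across test files

# a filtered-quality ortholog table mapping pigNN <-> humNN
toy_orthologs <- function(n = 10, filtered = FALSE) {
  tab <- as_ortholog_table(data.frame(
    gene_a = sprintf("pig%02d", seq_len(n)),
    gene_b = sprintf("hum%02d", seq_len(n)),
    homology_type = rep("one2one", n),
    goc_score = rep(90, n), wga_score = rep(90, n),
    stringsAsFactors = FALSE))
  if (filtered) filter_high_quality(tab) else tab
}

# the three-node map used by the coverage examples:
# edges (n1,n2, shared 2) and (n2,n3, shared 3)
toy_map <- function() {
  build_enrichment_map(
    list(n1 = c("g1", "g2", "g3", "g4"),
         n2 = c("g3", "g4", "g5", "g6", "g7"),
         n3 = c("g5", "g6", "g7")),
    overlap_cutoff = 0.25)
}

# random enrichment map over a small gene universe; always has >= 1 edge
# covered by the full gene set
random_map <- function(n_terms = 6, universe = sprintf("g%02d", 1:30)) {
  repeat {
    sets <- lapply(seq_len(n_terms), function(i) {
      sample(universe, sample(4:10, 1))
    })
    names(sets) <- sprintf("t%02d", seq_len(n_terms))
    m <- build_enrichment_map(sets, 0.25)
    if (nrow(m$edges) >= 1) return(m)
  }
}
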