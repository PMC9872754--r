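# builds a UMI matrix with prescribed detected-gene counts and mito share
make_qc_fixture <- function() {
  n_genes <- 3000
  genes <- c(sprintf("MT-%02d", 1:10), sprintf("g%04d", 1:(n_genes - 10)))
  detected <- c(150, 200, 2500, 2600, 300, 300)
  counts <- matrix(0L, n_genes, 6,
                   dimnames = list(genes, paste0("c", 1:6)))
  for (j in 1:6) {
    picked <- sample(11:n_genes, detected[j])  # non-mito genes
    counts[picked, j] <- 1L
  }
  # cells 5 and 6: add mito counts worth 6% and 5% of their totals
  counts["MT-01", 5] <- ceiling(0.06 / 0.94 * sum(counts[, 5]))
  counts["MT-01", 6] <- floor(0.05 / 0.95 * sum(counts[, 6]))
  counts
}

test_that("QC keeps cells by detected genes and mito share, then genes", {
  set.seed(55)
  counts <- make_qc_fixture()
  out <- qc_filter(counts, sprintf("MT-%02d", 1:10),
                   min_cells_per_gene = 1)
  # 150 too few, 2600 too many, 6% mito too high; 200/2500/5% inclusive
  expect_setequal(colnames(out), c("c2", "c3", "c6"))
  expect_equal(attr(out, "n_cells_removed"), 3L)

  # gene filter counts only retained cells: a gene seen in two passing
  # cells and one failing cell disappears at min_cells_per_gene = 3
  tiny <- matrix(c(1, 1, 0, 0,   # gA: 2 of the 3 retained cells
                   1, 1, 1, 0,   # gB: all retained cells
                   1, 1, 1, 0,   # gC: all retained cells
                   0, 0, 0, 9),  # gD: only the single-gene failing cell
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC", "gD"),
                                 c("k1", "k2", "k3", "fail")))
  out3 <- qc_filter(tiny, character(0), min_genes = 2, max_genes = 10,
                    min_cells_per_gene = 3)
  expect_setequal(colnames(out3), c("k1", "k2", "k3"))
  expect_setequal(rownames(out3), c("gB", "gC"))

  expect_error(qc_filter(counts[, 1, drop = FALSE],
                         sprintf("MT-%02d", 1:10)), "every cell")
})

test_that("QC output is independent of cell and gene ordering", {
  set.seed(56)
  counts <- make_qc_fixture()
  mito <- sprintf("MT-%02d", 1:10)
  a <- qc_filter(counts, mito, min_cells_per_gene = 1)
  perm <- counts[sample(nrow(counts)), sample(ncol(counts))]
  b <- qc_filter(perm, mito, min_cells_per_gene = 1)
  expect_setequal(colnames(a), colnames(b))
  expect_setequal(rownames(a), rownames(b))
})

test_that("markers recover a gene exclusive to one cluster", {
  set.seed(57)
  counts <- matrix(rpois(50 * 30, 2), 50, 30,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:30)))
  labels <- rep(c("A", "B", "C"), each = 10)
  counts["g01", ] <- 0L
  counts["g01", labels == "A"] <- 8L  # exclusive to cluster A
  mk <- find_markers(counts, labels)
  expect_true("g01" %in% mk$gene[mk$cluster == "A" & mk$q < 0.05])
  expect_true(all(mk$avg_logfc > 0.25))

  # permuted labels on exchangeable cells: no significant markers expected
  null_counts <- matrix(rpois(50 * 30, 2), 50, 30,
                        dimnames = dimnames(counts))
  mk0 <- find_markers(null_counts, sample(labels))
  expect_lte(sum(mk0$q < 0.05), 1)  # BH keeps chance markers near zero

  expect_error(find_markers(counts, rep("A", 30)), ">= 2 clusters")
  expect_warning(find_markers(counts, c(rep("A", 28), "B", "B")),
                 "fewer than 3")
})

test_that("cell-type DEG lists inherit bulk directions at p < 0.05", {
  markers <- data.frame(cluster = rep("glia", 5),
                        gene = sprintf("g%d", 1:5),
                        avg_logfc = 1, p = 0.01, q = 0.02)
  deg <- structure(data.frame(
    gene = sprintf("g%d", c(1, 2, 3, 6)),
    direction = c("up", "down", "up", "up"),
    lfc = c(1, -1, 2, 1), p = c(0.01, 0.04, 0.2, 0.01),
    q = c(0.05, 0.1, 0.4, 0.05), stringsAsFactors = FALSE),
    class = c("deg_list", "data.frame"))
  out <- celltype_deg_lists(markers, deg)
  # g3 fails p < 0.05, g6 is not a marker: g1 and g2 remain
  expect_setequal(out$glia$gene, c("g1", "g2"))
  expect_equal(out$glia$direction[out$glia$gene == "g2"], "down")

  none <- celltype_deg_lists(markers[0, ], deg)
  expect_length(none, 0)
})

test_that("interaction calls require detection fractions above threshold", {
  set.seed(58)
  genes <- c("LigA", "RecA", "LigB", "RecB", "other")
  counts <- matrix(0L, 5, 20, dimnames = list(genes, sprintf("c%d", 1:20)))
  labels <- rep(c("chol", "glia"), each = 10)
  counts["LigA", 1:5] <- 1L          # 50% of chol cells
  counts["RecA", 11:14] <- 1L        # 40% of glia cells
  counts["LigB", 1] <- 1L            # 10%: not strictly above threshold
  counts["RecB", 11:20] <- 1L
  lr <- data.frame(ligand = c("LigA", "LigB"), receptor = c("RecA", "RecB"))
  calls <- call_interactions(counts, labels, lr)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$source, "chol")
  expect_equal(calls$target, "glia")
  expect_equal(calls$ligand, "LigA")

  # self-loops are allowed when both thresholds are met within one subset
  counts["RecA", 1:5] <- 1L
  calls2 <- call_interactions(counts, labels, lr)
  expect_true(any(calls2$source == "chol" & calls2$target == "chol"))

  # absent ligand: no call anywhere
  lr3 <- data.frame(ligand = "ghost", receptor = "RecA")
  expect_equal(nrow(call_interactions(counts, labels, lr3)), 0)
})

test_that("VNS flags mark calls whose genes gain significance", {
  calls <- data.frame(source = "chol", target = "glia",
                      ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                      ligand_fraction = 0.5, receptor_fraction = 0.5,
                      present = TRUE, vns_up = NA)
  p_naive <- c(L1 = 0.20, L2 = 0.5, R1 = 0.9, R2 = 0.5)
  p_vns <- c(L1 = 0.001, L2 = 0.5, R1 = 0.9, R2 = 0.5)
  out <- vns_response(calls, p_naive, p_vns)
  expect_true(out$vns_up[1])    # ligand p dropped 0.20 -> 0.001
  expect_false(out$vns_up[2])   # identical tables: no flag

  # receptor missing from the naive table: compared against p = 1
  p_naive2 <- c(L1 = 0.2, L2 = 0.5)
  expect_warning(out2 <- vns_response(calls, p_naive2, p_vns), "missing")
  expect_true(out2$vns_up[2])   # R2: 0.5 < 1
  expect_true(all(out2$vns_up <= out2$present))
})

test_that("cells_required searches the exact binomial tail model", {
  expect_equal(cells_required(1, 1.0, 1, 0.95), 1L)

  # brute-force oracle on a small instance: walk N upward summing the
  # binomial pmf directly
  oracle <- function(n_types, f, m, conf) {
    N <- m
    tail_ge <- function(N) {
      p <- sum(vapply(m:N, function(x) choose(N, x) * f^x * (1 - f)^(N - x),
                      numeric(1)))
      p^n_types
    }
    while (tail_ge(N) < conf) N <- N + 1
    N
  }
  for (case in list(c(2, 0.5, 2, 0.9), c(3, 0.3, 1, 0.8),
                    c(2, 0.25, 3, 0.95))) {
    expect_equal(cells_required(case[1], case[2], case[3], case[4]),
                 oracle(case[1], case[2], case[3], case[4]))
  }

  # monotone: rarer types need more cells, higher confidence never fewer
  expect_gte(cells_required(5, 0.05, 6, 0.95), cells_required(5, 0.1, 6, 0.95))
  expect_gte(cells_required(5, 0.1, 6, 0.99), cells_required(5, 0.1, 6, 0.95))
  expect_warning(cells_required(20, 0.2, 1, 0.5), "approximation")
})
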