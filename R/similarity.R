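#' Empirical cumulative distribution function of an expression profile
#'
#' Thin wrapper around [stats::ecdf()] with input validation; F(x) is the
#' fraction of values <= x.
#'
#' @param values numeric vector with at least one finite value.
#' @return an `ecdf` step function.
#' @export
ecdf_profile <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("ECDF requires at least one finite value")
  ecdf(values)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' from [stats::ks.test()] (exact for small samples, asymptotic otherwise).
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `statistic` (D) and `p`.
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  res <- suppressWarnings(ks.test(x, y))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Chi-squared homogeneity comparison of two samples
#'
#' Bins the pooled sample into `n_bins` quantile bins, tabulates the two
#' samples over the bins, and runs Pearson's chi-squared test of homogeneity
#' on the 2 x n_bins table (no continuity correction; df = n_bins - 1 for a
#' full-rank table). If the pooled sample is too small or too tied to
#' support `n_bins` distinct bins, the bin count is reduced with a warning.
#'
#' @param x,y numeric vectors (non-empty).
#' @param n_bins number of quantile bins of the pooled sample; default 10.
#' @return list with `statistic`, `p`, and `n_bins` actually used.
#' @export
chisq_compare <- function(x, y, n_bins = 10) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  n_bins <- min(n_bins, max(2L, floor(length(pooled) / 2)))
  repeat {
    breaks <- unique(quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1),
                              names = FALSE))
    if (length(breaks) >= 3 || n_bins <= 2) break
    n_bins <- n_bins - 1L
  }
  used_bins <- length(breaks) - 1L
  if (used_bins < n_bins) {
    warning("reduced to ", used_bins, " bins (ties or small sample)")
  }
  cx <- table(cut(x, breaks, include.lowest = TRUE))
  cy <- table(cut(y, breaks, include.lowest = TRUE))
  tab <- rbind(as.integer(cx), as.integer(cy))
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       n_bins = used_bins)
}

#' Pairwise Spearman correlation between expression profiles
#'
#' Computes the Spearman rank correlation (with p-values from
#' [stats::cor.test()]) between every pair of columns, e.g. per-region mean
#' expression profiles of the two species over the shared ortholog set.
#' Constant columns yield `NA` entries (off-diagonal) with a warning.
#'
#' @param em genes x profiles matrix (>= 3 genes).
#' @return list of two symmetric matrices, `rho` (unit diagonal) and `p`.
#' @export
spearman_pairwise <- function(em) {
  em <- as.matrix(em)
  if (nrow(em) < 3) stop("need >= 3 shared genes per profile pair")
  k <- ncol(em)
  rho <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(colnames(em), colnames(em))
  const <- apply(em, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning("constant profile(s): ",
            paste(colnames(em)[const], collapse = ", "),
            "; their correlations are reported as missing")
  }
  if (k < 2) return(list(rho = rho, p = p))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (const[i] || const[j]) {
        rho[i, j] <- rho[j, i] <- NA_real_
        next
      }
      res <- suppressWarnings(
        cor.test(em[, i], em[, j], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(res$estimate)
      p[i, j] <- p[j, i] <- res$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Full distributional-similarity report for two profiles
#'
#' Runs [ks_compare()], [chisq_compare()] and Spearman correlation on one
#' pair of profiles (e.g. the per-gene mean expression of a colonic region
#' in each species over the shared ortholog set).
#'
#' @param x,y numeric vectors over a common gene index.
#' @param n_bins bins for the chi-squared comparison.
#' @return one-row data.frame: `ks_statistic`, `ks_p`, `chisq_statistic`,
#'   `chisq_p`, `n_bins`, `spearman_rho`, `spearman_p`.
#' @export
similarity_report <- function(x, y, n_bins = 10) {
  ks <- ks_compare(x, y)
  cs <- chisq_compare(x, y, n_bins)
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  data.frame(ks_statistic = ks$statistic, ks_p = ks$p,
             chisq_statistic = cs$statistic, chisq_p = cs$p,
             n_bins = cs$n_bins,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}
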