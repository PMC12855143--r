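#' Equal-frequency pseudotime bins
#'
#' Assigns cells to `n_bins` bins by pseudotime rank; bin sizes differ
#' by at most one. Ties in pseudotime break by cell id so the binning
#' is deterministic.
#'
#' @param pseudotime numeric vector of finite pseudotime values.
#' @param n_bins number of bins (default 20); must not exceed the
#'   number of cells.
#' @param cell_ids optional ids used for tie-breaking (defaults to
#'   input order).
#' @return integer vector of bin indices in 1..n_bins, aligned with
#'   `pseudotime`.
#' @export
bin_cells <- function(pseudotime, n_bins = 20L, cell_ids = NULL) {
  n <- length(pseudotime)
  if (n_bins > n) stop("n_bins exceeds the number of cells")
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  if (is.null(cell_ids)) cell_ids <- seq_len(n)
  ord <- order(pseudotime, cell_ids)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  bin
}

# Per-gene statistic for one bin labeling, from per-bin sums; the
# per-gene totals are invariant under permutation (internal).
bin_stat <- function(bin_sizes, sums, n, tot, tot2, stat) {
  means <- sums / bin_sizes                      # bins x genes
  grand <- tot / n
  ss_tot <- tot2 - n * grand^2
  dev <- sweep(means, 2, grand)
  ss_between <- colSums(bin_sizes * dev^2)
  df_w <- n - length(bin_sizes)
  var_w <- pmax(ss_tot - ss_between, 0) / df_w   # pooled within-bin variance
  if (stat == "frat") {
    s <- (ss_between / (length(bin_sizes) - 1)) / var_w
    s[!is.finite(s)] <- 0
    return(s)
  }
  dev <- abs(dev) * sqrt(bin_sizes)              # |bin mean - grand| * sqrt(nb)
  mx <- do.call(pmax, lapply(seq_len(nrow(dev)), function(b) dev[b, ]))
  s <- mx / sqrt(var_w)
  s[!is.finite(s) | var_w == 0] <- 0
  s
}

#' Permutation test for pseudotime-dependent expression
#'
#' Per gene, the statistic is the maximum over bins of the standardized
#' bin-mean deviation `|bin mean - grand mean| / (pooled within-bin sd /
#' sqrt(bin size))`; the null distribution is obtained by permuting the
#' bin labels across cells `n_perm` times, so the p-value is
#' `(1 + #permuted >= observed) / (n_perm + 1)`. Constant genes get
#' statistic 0 and p 1. An F-like variance-ratio statistic is available
#' via `stat = "frat"`. Deterministic given `seed`.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param bins per-cell bin indices from [bin_cells()].
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param fdr Benjamini-Hochberg threshold deciding `significant`.
#' @param stat `"max_bin"` (default) or `"frat"`.
#' @return data.frame with `gene_id`, `statistic`, `p_perm`, `q`,
#'   `significant`.
#' @export
permutation_de <- function(ds, bins, n_perm = 999L, seed = 1L, fdr = 0.05,
                           stat = c("max_bin", "frat")) {
  stat <- match.arg(stat)
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (length(unique(bins)) < 2) stop("need at least 2 bins")
  x <- norm_matrix(ds)
  n <- nrow(x)
  binf <- factor(bins)
  sizes <- as.integer(table(binf))
  tot <- colSums(x)
  tot2 <- colSums(x^2)
  sums_obs <- rowsum(x, binf)
  s_obs <- bin_stat(sizes, sums_obs, n, tot, tot2, stat)
  set.seed(seed)
  exceed <- integer(ncol(x))
  for (p in seq_len(n_perm)) {
    perm_lab <- binf[sample.int(n)]              # permute labels, not the matrix
    sums_p <- rowsum(x, perm_lab)
    s_p <- bin_stat(sizes, sums_p, n, tot, tot2, stat)
    exceed <- exceed + (s_p >= s_obs)
  }
  p_perm <- (1 + exceed) / (n_perm + 1)
  q <- stats::p.adjust(p_perm, "BH")
  data.frame(gene_id = ds$genes$gene_id, statistic = s_obs, p_perm = p_perm,
             q = q, significant = q < fdr, stringsAsFactors = FALSE)
}

#' Binned pseudotime expression profiles
#'
#' Mean normalized expression per pseudotime bin for each gene.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param bins per-cell bin indices.
#' @param genes optional gene-id subset.
#' @return numeric matrix genes x bins.
#' @export
bin_profiles <- function(ds, bins, genes = NULL) {
  x <- norm_matrix(ds, genes)
  binf <- factor(bins)
  prof <- t(rowsum(x, binf) / as.integer(table(binf)))
  rownames(prof) <- if (is.null(genes)) ds$genes$gene_id else genes
  prof
}

# Moving-average smoothing (window 3, shrunk at the edges) and row
# z-scoring; constant rows become zeros (internal).
smooth_zscore <- function(prof, window = 3L) {
  half <- window %/% 2
  nb <- ncol(prof)
  sm <- vapply(seq_len(nb), function(b) {
    cols <- max(1, b - half):min(nb, b + half)
    rowMeans(prof[, cols, drop = FALSE])
  }, numeric(nrow(prof)))
  sm <- matrix(sm, nrow = nrow(prof), dimnames = dimnames(prof))
  mu <- rowMeans(sm)
  sd <- apply(sm, 1, stats::sd)
  z <- (sm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Group significant genes into pseudotime modules
#'
#' Smooths each binned profile with a window-3 moving average, z-scores
#' it, and clusters genes by hierarchical clustering with correlation
#' distance and average linkage, cutting the tree at `K`. Module ids
#' are ordered by the pseudotime position of each module's mean-profile
#' peak (earliest peak = module 1).
#'
#' @param profiles genes x bins matrix from [bin_profiles()], usually
#'   restricted to significant genes.
#' @param K number of modules (>= 2).
#' @return data.frame with `gene_id`, `module_id`, plus attribute
#'   `module_profiles` (K x bins matrix of module mean z-profiles).
#' @export
cluster_modules <- function(profiles, K) {
  if (K < 2) stop("K must be >= 2")
  if (nrow(profiles) < K) stop("fewer genes than modules")
  z <- smooth_zscore(profiles)
  cr <- suppressWarnings(stats::cor(t(z)))
  cr[!is.finite(cr)] <- 0
  d <- stats::as.dist(1 - cr)
  if (all(d < 1e-12)) {
    warning("all profiles identical; module split is degenerate")
  }
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = K)
  centers <- do.call(rbind, lapply(seq_len(K), function(k) {
    colMeans(z[raw == k, , drop = FALSE])
  }))
  peak <- apply(centers, 1, which.max)
  ord <- order(peak, seq_len(K))
  relab <- match(raw, ord)
  out <- data.frame(gene_id = rownames(profiles), module_id = relab,
                    stringsAsFactors = FALSE)
  attr(out, "module_profiles") <- centers[ord, , drop = FALSE]
  out
}

#' Silhouette-based module-count suggestion
#'
#' Computes the mean silhouette width of [cluster_modules()] solutions
#' over a range of K and returns the best K. Printed as a suggestion
#' only; the pipeline never applies it automatically.
#'
#' @param profiles genes x bins matrix.
#' @param K_range candidate module counts.
#' @return the K with the highest mean silhouette width.
#' @export
suggest_module_count <- function(profiles, K_range = 2:20) {
  z <- smooth_zscore(profiles)
  cr <- suppressWarnings(stats::cor(t(z)))
  cr[!is.finite(cr)] <- 0
  dm <- 1 - cr
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  sil <- vapply(K_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    mean(vapply(seq_along(lab), function(i) {
      own <- mean(dm[i, lab == lab[i] & seq_along(lab) != i])
      if (is.nan(own)) return(0)
      oth <- min(vapply(setdiff(unique(lab), lab[i]), function(l) {
        mean(dm[i, lab == l])
      }, 0))
      (oth - own) / max(own, oth)
    }, 0))
  }, 0)
  K_range[which.max(sil)]
}

#' End-to-end pseudotime module discovery
#'
#' Convenience wrapper: bins cells, runs the permutation test, and
#' clusters the significant genes into modules.
#'
#' @param ds an `ExpressionDataset` with pseudotime in its cell table.
#' @param pseudotime_col cell-table column holding pseudotime.
#' @param n_bins,n_perm,fdr,K,seed,stat passed to the stages.
#' @return list with `de` (the [permutation_de()] table) and `modules`
#'   (the [cluster_modules()] assignment for significant genes).
#' @export
pseudotime_modules <- function(ds, pseudotime_col = "pseudotime",
                               n_bins = 20L, n_perm = 999L, fdr = 0.05,
                               K = 17L, seed = 1L, stat = "max_bin") {
  pt <- ds$cells[[pseudotime_col]]
  if (is.null(pt)) stop("no pseudotime column: ", pseudotime_col)
  bins <- bin_cells(pt, n_bins, cell_ids = ds$cells$cell_id)
  de <- permutation_de(ds, bins, n_perm = n_perm, seed = seed, fdr = fdr,
                       stat = stat)
  sig <- de$gene_id[de$significant]
  modules <- if (length(sig) >= K) {
    cluster_modules(bin_profiles(ds, bins, sig), K)
  } else NULL
  list(de = de, modules = modules, bins = bins)
}
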