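#' Graph-based clustering of cells
#'
#' The standard single-cell recipe: per-gene scaling to unit variance
#' (values clipped at `clip`), PCA, a k-nearest-neighbour graph on the
#' PC coordinates, and modularity-based (Louvain) community detection
#' at the given resolution. Deterministic given `seed`; cluster labels
#' are dense integers starting at 1, ordered by decreasing cluster size.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param resolution modularity resolution (default 0.8).
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbours per cell in the graph.
#' @param seed RNG seed for the community detection.
#' @param clip winsorization bound on scaled values.
#' @return the dataset with `cluster` filled in its cell table.
#' @export
cluster_cells <- function(ds, resolution = 0.8, n_pcs = 20L,
                          k_neighbors = 20L, seed = 1L, clip = 10) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  n <- nrow(ds$counts)
  if (n <= k_neighbors) stop("fewer cells than k_neighbors")
  x <- norm_matrix(ds)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE])
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  n_pcs <- min(n_pcs, ncol(x) - 1L, n - 1L)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x

  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k_neighbors)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  lab <- igraph::membership(comm)
  # dense labels from 1, largest cluster first
  ord <- order(-tabulate(lab))
  lab <- match(lab, ord)
  ds$cells$cluster <- as.integer(lab)
  ds
}

#' Wilcoxon marker-gene detection
#'
#' For every group in `group_col`, tests each gene with a two-sided
#' Wilcoxon rank-sum test of that group's cells against all others on
#' the normalized layer. The effect size is the natural-log fold change
#' of the de-logged group means with pseudocount 1:
#' `avg_logFC = ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`.
#' Benjamini-Hochberg adjusted p-values are always computed (within
#' group, over all genes tested); whether the retention threshold uses
#' the raw or adjusted p is controlled by `adjust`.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param group_col cell-table column holding group labels.
#' @param min_logFC retain genes with `avg_logFC` strictly above this.
#' @param max_p retain genes with p (or adjusted p) strictly below this.
#' @param adjust threshold on `p_adj` instead of raw `p_value`.
#' @param genes optional gene-id subset to test.
#' @return data.frame of marker records: `cluster`, `gene_id`,
#'   `avg_logFC`, `p_value`, `p_adj`, `pct_in`, `pct_out`, sorted by
#'   group then descending `avg_logFC`.
#' @export
find_markers <- function(ds, group_col = "cluster", min_logFC = 0.25,
                         max_p = 0.05, adjust = FALSE, genes = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!group_col %in% names(ds$cells)) stop("unknown group column: ", group_col)
  grp <- as.character(ds$cells[[group_col]])
  levels <- sort(unique(grp))
  if (length(levels) < 2) stop("need at least 2 groups")
  if (is.null(genes)) genes <- ds$genes$gene_id
  x <- norm_matrix(ds, genes)
  out <- list()
  for (g in levels) {
    inn <- grp == g
    if (sum(inn) < 3) {
      warning(sprintf("group '%s' has fewer than 3 cells; skipped", g))
      next
    }
    xin <- x[inn, , drop = FALSE]
    xout <- x[!inn, , drop = FALSE]
    stats_g <- marker_stats(xin, xout)
    stats_g$p_adj <- stats::p.adjust(stats_g$p_value, "BH")
    rec <- data.frame(cluster = g, gene_id = genes, stats_g,
                      stringsAsFactors = FALSE)
    pcol <- if (adjust) rec$p_adj else rec$p_value
    rec <- rec[rec$avg_logFC > min_logFC & pcol < max_p, , drop = FALSE]
    out[[g]] <- rec[order(-rec$avg_logFC), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exact two-sided rank-sum p by enumerating all group assignments of
# the midranks; valid under ties, used when the enumeration is small
# (internal). The permutation distribution of W is symmetric about its
# mean, so the two-sided p is P(|W' - E| >= |W - E|).
exact_ranksum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  dev <- abs(w - n1 * (n + 1) / 2)
  combos <- utils::combn(n, n1)
  wp <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(wp - n1 * (n + 1) / 2) >= dev - 1e-12)
}

# Wilcoxon p, log fold change and detection fractions for every column
# of xin vs xout; exact enumeration for small groups, rank-sum test
# otherwise (internal).
marker_stats <- function(xin, xout) {
  small <- choose(nrow(xin) + nrow(xout), nrow(xin)) <= 10000
  p <- vapply(seq_len(ncol(xin)), function(j) {
    a <- xin[, j]; b <- xout[, j]
    if (all(a == a[1]) && all(b == a[1])) return(1)
    if (small) return(exact_ranksum_p(a, b))
    stats::wilcox.test(a, b)$p.value
  }, 0)
  lfc <- log((colMeans(expm1(xin)) + 1) / (colMeans(expm1(xout)) + 1))
  data.frame(avg_logFC = unname(lfc), p_value = p,
             pct_in = unname(colMeans(xin > 0)),
             pct_out = unname(colMeans(xout > 0)))
}

#' Annotate clusters from a marker reference
#'
#' Each cluster is assigned the rule with the highest fraction of its
#' required marker genes present among the cluster's significant
#' markers; ties break alphabetically by cell-type name; clusters with
#' no rule coverage are labelled "unassigned". Rules may list excluded
#' genes whose presence vetoes the rule.
#'
#' @param markers a marker data.frame from [find_markers()].
#' @param rules list of [annotation_rule()] objects.
#' @param clusters optional character vector of cluster ids to annotate;
#'   defaults to the clusters present in `markers`. Clusters without
#'   any significant marker are labelled "unassigned".
#' @return named character vector, cluster id -> cell type.
#' @export
annotate_clusters <- function(markers, rules, clusters = NULL) {
  if (!length(rules)) stop("rules must be non-empty")
  cl <- if (is.null(markers) || !nrow(markers)) character(0)
        else sort(unique(as.character(markers$cluster)))
  all_cl <- if (is.null(clusters)) cl else as.character(clusters)
  res <- stats::setNames(rep("unassigned", length(all_cl)), all_cl)
  for (k in all_cl) {
    present <- markers$gene_id[as.character(markers$cluster) == k]
    best <- "unassigned"; best_cov <- 0
    nm <- vapply(rules, `[[`, "", "cell_type")
    for (r in order(nm)) {            # alphabetical scan makes ties stick to first
      rule <- rules[[r]]
      if (length(rule$excluded) && any(rule$excluded %in% present)) next
      cov <- mean(rule$required %in% present)
      if (cov > best_cov) { best_cov <- cov; best <- rule$cell_type }
    }
    res[k] <- best
  }
  res
}

#' Marker-based annotation rule
#'
#' @param cell_type name assigned when the rule wins.
#' @param required non-empty character vector of marker gene ids.
#' @param excluded optional gene ids whose presence vetoes the rule.
#' @return an `annotation_rule` list.
#' @export
annotation_rule <- function(cell_type, required, excluded = character(0)) {
  if (!length(required)) stop("required marker set must be non-empty")
  structure(list(cell_type = cell_type, required = required,
                 excluded = excluded), class = "annotation_rule")
}
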