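#' Select highly variable genes
#'
#' Ranks genes by the residual of their log-variance from a loess
#' mean-variance trend on the normalized layer (a variance-stabilized
#' dispersion score), and returns the top fraction. Deterministic; ties
#' break by gene id.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param top_fraction fraction of genes to keep, in (0, 1]. The count
#'   kept is `ceiling(top_fraction * n_genes)`.
#' @return character vector of gene ids, highest dispersion first.
#' @export
select_hvgs <- function(ds, top_fraction = 0.10) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]")
  }
  x <- ds$normalized
  if (is.null(x)) stop("normalized layer required; run normalize_dataset() first")
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  n <- nrow(x)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  # robust degree-1 trend so high-dispersion genes cannot lever the fit
  # through themselves
  score <- tryCatch({
    fit <- stats::loess(lv ~ mu, data = data.frame(lv = log1p(v), mu = mu),
                        span = 0.75, degree = 1, family = "symmetric")
    log1p(v) - stats::predict(fit)
  }, error = function(e) v)
  ord <- order(-score, ds$genes$gene_id)
  k <- ceiling(top_fraction * ncol(x))
  ds$genes$gene_id[ord[seq_len(k)]]
}

#' Age-related coefficient of variation of pairwise expression distances
#'
#' For one cell type and one (young, old) age pair, computes for every
#' gene the absolute expression difference `d = |X_i - X_j|` over all
#' young-cell x old-cell pairs on the normalized layer, then the mean
#' `mu`, the sample standard deviation `sigma` (n - 1 denominator), and
#' `cv = sigma / mu * 100`. Genes whose distances are all zero have an
#' undefined CV and are flagged rather than set to 0. If the number of
#' pairs exceeds `max_pairs`, that many pairs are drawn uniformly
#' without replacement under `seed`; below the cap the enumeration is
#' exact.
#'
#' @param ds an `ExpressionDataset` with a normalized layer and
#'   `cell_type` plus `age_group` in its cell table.
#' @param cell_type cell type analysed.
#' @param age_young,age_old age-group labels of the pair.
#' @param hvgs gene ids to analyse (typically from [select_hvgs()]).
#' @param max_pairs cap on enumerated pairs (default 1e6).
#' @param seed RNG seed for pair subsampling.
#' @param layer `"normalized"` (default) or `"counts"`.
#' @return data.frame with one row per gene: `cell_type`, `age_young`,
#'   `age_old`, `gene_id`, `mu`, `sigma`, `cv`, `cv_undefined`,
#'   `n_pairs_used`.
#' @export
compute_cv <- function(ds, cell_type, age_young, age_old, hvgs,
                       max_pairs = 1e6, seed = 1L, layer = "normalized") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ct <- as.character(ds$cells$cell_type)
  ag <- as.character(ds$cells$age_group)
  iy <- which(ct == cell_type & ag == as.character(age_young))
  io <- which(ct == cell_type & ag == as.character(age_old))
  if (!length(iy)) stop(sprintf("no '%s' cells in age group '%s'",
                                cell_type, age_young))
  if (!length(io)) stop(sprintf("no '%s' cells in age group '%s'",
                                cell_type, age_old))
  x <- if (layer == "counts") {
    j <- match(hvgs, ds$genes$gene_id)
    as.matrix(ds$counts[, j, drop = FALSE])
  } else norm_matrix(ds, hvgs)
  y <- length(iy); o <- length(io)
  n_all <- as.double(y) * o
  sub <- n_all > max_pairs
  if (sub) {
    set.seed(seed)
    pick <- sample(n_all, max_pairs)
    pi <- ((pick - 1) %% y) + 1
    pj <- ((pick - 1) %/% y) + 1
  }
  res <- lapply(seq_along(hvgs), function(g) {
    xy <- x[iy, g]; xo <- x[io, g]
    d <- if (sub) abs(xy[pi] - xo[pj]) else abs(outer(xy, xo, "-"))
    mu <- mean(d)
    sg <- stats::sd(d)
    list(mu = mu, sigma = sg,
         cv = if (mu > 0) sg / mu * 100 else NA_real_,
         undef = mu == 0, n = length(d))
  })
  data.frame(cell_type = cell_type, age_young = as.character(age_young),
             age_old = as.character(age_old), gene_id = hvgs,
             mu = vapply(res, `[[`, 0, "mu"),
             sigma = vapply(res, `[[`, 0, "sigma"),
             cv = vapply(res, `[[`, 0, "cv"),
             cv_undefined = vapply(res, `[[`, TRUE, "undef"),
             n_pairs_used = vapply(res, `[[`, 0, "n"),
             stringsAsFactors = FALSE)
}

#' Summarize CV results per cell type and age pair
#'
#' Computes the median CV, the mean of the per-gene mean pairwise
#' distances, and the number of genes with a defined CV; undefined-CV
#' genes are excluded from the summaries.
#'
#' @param results data.frame from [compute_cv()] (possibly several
#'   row-bound calls).
#' @return data.frame with `cell_type`, `age_young`, `age_old`,
#'   `median_cv`, `mean_mu`, `n_genes`.
#' @export
summarize_cv <- function(results) {
  def <- results[!results$cv_undefined, , drop = FALSE]
  if (!nrow(def)) stop("no genes with defined CV")
  key <- interaction(def$cell_type, def$age_young, def$age_old, drop = TRUE)
  out <- do.call(rbind, lapply(split(def, key), function(s) {
    data.frame(cell_type = s$cell_type[1], age_young = s$age_young[1],
               age_old = s$age_old[1], median_cv = stats::median(s$cv),
               mean_mu = mean(s$mu), n_genes = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare per-gene CV distributions between two comparisons
#'
#' Two-sided Wilcoxon rank-sum test on the defined per-gene CV values
#' of two [compute_cv()] result sets (e.g., two cell types for the same
#' age pair).
#'
#' @param results_A,results_B data.frames from [compute_cv()].
#' @return list with `statistic`, `p_value`, `median_A`, `median_B`.
#' @export
compare_cv <- function(results_A, results_B) {
  a <- results_A$cv[!results_A$cv_undefined]
  b <- results_B$cv[!results_B$cv_undefined]
  if (!length(a) || !length(b)) stop("all CV values undefined in one input")
  wt <- stats::wilcox.test(a, b)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_A = stats::median(a), median_B = stats::median(b))
}
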