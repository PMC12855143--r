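#' Assemble a senescence gene library
#'
#' Unions several source gene lists after synonym canonicalization and
#' case folding, recording per-entry provenance. Order of the input
#' lists does not affect the result.
#'
#' @param gene_lists named list of character vectors of gene symbols
#'   (e.g. human, mouse, and model-organism aging gene sets).
#' @param synonyms optional named character vector mapping synonym ->
#'   canonical symbol (applied case-insensitively).
#' @return a `senescence_library`: list with `entries` (data.frame of
#'   `symbol` and comma-separated `sources`) and `size`.
#' @export
build_library <- function(gene_lists, synonyms = NULL) {
  if (!length(gene_lists) || any(!lengths(gene_lists))) {
    stop("gene lists must be non-empty")
  }
  if (is.null(names(gene_lists))) {
    names(gene_lists) <- paste0("list", seq_along(gene_lists))
  }
  canon <- function(x) {
    x <- toupper(x)
    if (!is.null(synonyms)) {
      syn <- stats::setNames(toupper(synonyms), toupper(names(synonyms)))
      hit <- match(x, names(syn))
      x[!is.na(hit)] <- syn[hit[!is.na(hit)]]
    }
    x
  }
  long <- do.call(rbind, lapply(sort(names(gene_lists)), function(src) {
    data.frame(symbol = canon(gene_lists[[src]]), source = src,
               stringsAsFactors = FALSE)
  }))
  entries <- do.call(rbind, lapply(split(long, long$symbol), function(s) {
    data.frame(symbol = s$symbol[1],
               sources = paste(sort(unique(s$source)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  entries <- entries[order(entries$symbol), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, size = nrow(entries)),
            class = "senescence_library")
}

#' @export
print.senescence_library <- function(x, ...) {
  cat(sprintf("senescence library: %d unique genes\n", x$size))
  invisible(x)
}

# Dataset gene indices matched to a library, with a coverage log of
# library entries the gene table lacks (internal).
library_gene_idx <- function(ds, lib) {
  sym <- toupper(ds$genes$symbol)
  idx <- which(sym %in% lib$entries$symbol)
  missing <- setdiff(lib$entries$symbol, sym)
  if (length(missing)) {
    message(sprintf("%d of %d library genes absent from the gene table",
                    length(missing), lib$size))
  }
  idx
}

#' Count expressed senescence genes in an age group
#'
#' A library gene counts as expressed when it has at least one count in
#' at least `min_cells` cells of the age group (the same detection rule
#' the QC gene filter uses).
#'
#' @param ds an `ExpressionDataset`.
#' @param lib a [build_library()] result.
#' @param age_group age-group label.
#' @param min_cells detection support threshold.
#' @return integer count of expressed library genes.
#' @export
count_expressed <- function(ds, lib, age_group, min_cells = 3L) {
  ag <- as.character(ds$cells$age_group)
  if (!as.character(age_group) %in% ag) {
    stop("unknown age group: ", age_group)
  }
  idx <- library_gene_idx(ds, lib)
  if (!length(idx)) return(0L)
  inn <- ag == as.character(age_group)
  sup <- Matrix::colSums(ds$counts[inn, idx, drop = FALSE] > 0)
  sum(sup >= min_cells)
}

#' Age-related differential expression of senescence genes
#'
#' For each (young, old) age contrast, tests every library gene with a
#' two-sided Wilcoxon rank-sum test between the two age groups within
#' one cell type, on the normalized layer. `avg_logFC` is old vs young
#' with the same natural-log, pseudocount-1 convention as
#' [find_markers()]. P-values are Benjamini-Hochberg adjusted within
#' each (cell type, contrast); records with `|avg_logFC| > min_logFC`
#' and `p_adj < max_p_adj` are retained, with `direction` from the sign
#' of the fold change.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param lib a [build_library()] result.
#' @param cell_type cell type analysed.
#' @param contrasts list of length-2 vectors `c(young, old)`.
#' @param min_logFC,max_p_adj retention thresholds.
#' @param min_cells minimum cells per group; contrasts below it are
#'   skipped with a warning.
#' @return data.frame of retained records: `cell_type`, `gene_id`,
#'   `contrast`, `avg_logFC`, `p_value`, `p_adj`, `direction`.
#' @export
age_degs <- function(ds, lib, cell_type, contrasts, min_logFC = 0.25,
                     max_p_adj = 0.05, min_cells = 3L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  idx <- library_gene_idx(ds, lib)
  if (!length(idx)) stop("no library genes present in the dataset")
  gid <- ds$genes$gene_id[idx]
  ct <- as.character(ds$cells$cell_type)
  ag <- as.character(ds$cells$age_group)
  x <- norm_matrix(ds, gid)
  out <- list()
  for (con in contrasts) {
    young <- as.character(con[1]); old <- as.character(con[2])
    iy <- ct == cell_type & ag == young
    io <- ct == cell_type & ag == old
    if (sum(iy) < min_cells || sum(io) < min_cells) {
      warning(sprintf("contrast %s vs %s has fewer than %d '%s' cells; skipped",
                      young, old, min_cells, cell_type))
      next
    }
    st <- marker_stats(x[io, , drop = FALSE], x[iy, , drop = FALSE])
    st$p_adj <- stats::p.adjust(st$p_value, "BH")
    rec <- data.frame(cell_type = cell_type, gene_id = gid,
                      contrast = paste(young, old, sep = "_vs_"),
                      avg_logFC = st$avg_logFC, p_value = st$p_value,
                      p_adj = st$p_adj, stringsAsFactors = FALSE)
    rec <- rec[abs(rec$avg_logFC) > min_logFC & rec$p_adj < max_p_adj, ,
               drop = FALSE]
    rec$direction <- ifelse(rec$avg_logFC > 0, "up-with-age", "down-with-age")
    out[[length(out) + 1L]] <- rec
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_type = character(0), gene_id = character(0),
               contrast = character(0), avg_logFC = numeric(0),
               p_value = numeric(0), p_adj = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Per-age mean expression of selected genes
#'
#' Helper producing the table [classify_trends()] consumes: mean
#' normalized expression per age group (columns in age order) for the
#' given genes, restricted to one cell type when requested.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param genes gene ids (rows of the result).
#' @param cell_type optional cell-type restriction.
#' @return numeric matrix, genes x age groups.
#' @export
age_mean_expression <- function(ds, genes, cell_type = NULL) {
  x <- norm_matrix(ds, genes)
  keep <- if (is.null(cell_type)) rep(TRUE, nrow(x))
          else as.character(ds$cells$cell_type) == cell_type
  ages <- levels(factor(ds$cells$age_group))
  m <- vapply(ages, function(a) {
    inn <- keep & as.character(ds$cells$age_group) == a
    if (!any(inn)) return(rep(NA_real_, ncol(x)))
    colMeans(x[inn, , drop = FALSE])
  }, numeric(ncol(x)))
  m <- matrix(m, nrow = ncol(x), dimnames = list(genes, ages))
  m
}

#' Classify per-gene age trends
#'
#' The trend of a gene is the sign of the Spearman correlation between
#' its per-age mean expression and the age rank: "increasing" when
#' rho >= 0.5, "decreasing" when rho <= -0.5, "mixed" otherwise.
#'
#' @param mean_table numeric matrix genes x age groups (columns in age
#'   order), e.g. from [age_mean_expression()]. Needs >= 3 age groups.
#' @return data.frame with `gene_id`, `rho`, `trend`, plus an attribute
#'   `summary` giving the fractions increasing/decreasing/mixed.
#' @export
classify_trends <- function(mean_table) {
  if (ncol(mean_table) < 3) stop("need at least 3 age groups")
  rank_age <- seq_len(ncol(mean_table))
  rho <- apply(mean_table, 1, function(m) {
    if (anyNA(m) || stats::sd(m) == 0) return(NA_real_)
    suppressWarnings(stats::cor(m, rank_age, method = "spearman"))
  })
  trend <- ifelse(is.na(rho), "mixed",
           ifelse(rho >= 0.5, "increasing",
           ifelse(rho <= -0.5, "decreasing", "mixed")))
  out <- data.frame(gene_id = rownames(mean_table), rho = unname(rho),
                    trend = unname(trend), stringsAsFactors = FALSE)
  attr(out, "summary") <- c(increasing = mean(trend == "increasing"),
                            decreasing = mean(trend == "decreasing"),
                            mixed = mean(trend == "mixed"))
  out
}
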