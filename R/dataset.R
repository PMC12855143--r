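#' Construct an ExpressionDataset
#'
#' The central container of the pipeline: a sparse cells x genes count
#' matrix together with per-cell and per-gene metadata tables and an
#' optional normalized expression layer. All downstream stages consume
#' and produce this object.
#'
#' @param counts sparse (or dense) numeric matrix of non-negative integer
#'   counts, cells in rows and genes in columns.
#' @param cells data.frame of per-cell metadata. Must contain a `cell_id`
#'   column with unique values; typical columns are `sample_id`,
#'   `age_group` (an ordered factor), `cluster`, `cell_type`,
#'   `pseudotime`, and the QC metrics `n_genes_detected`,
#'   `mito_fraction`, `rbc_fraction`.
#' @param genes data.frame of per-gene metadata. Must contain a unique
#'   `gene_id` column; typical columns are `symbol` and the logical
#'   flags `is_mito`, `is_rbc`, `is_lincRNA`, `is_senescence`.
#' @param normalized optional matrix of non-negative reals with the same
#'   shape and axis ordering as `counts` (see [normalize_dataset()]).
#'
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `counts`, `normalized`, `cells`, `genes`.
#' @export
expression_dataset <- function(counts, cells, genes, normalized = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(is.data.frame(cells), is.data.frame(genes))
  if (!"cell_id" %in% names(cells)) stop("cells table must have a 'cell_id' column")
  if (!"gene_id" %in% names(genes)) stop("genes table must have a 'gene_id' column")
  if (nrow(counts) != nrow(cells)) {
    stop(sprintf("dimension mismatch on cell axis: counts has %d rows, cells table has %d",
                 nrow(counts), nrow(cells)))
  }
  if (ncol(counts) != nrow(genes)) {
    stop(sprintf("dimension mismatch on gene axis: counts has %d columns, genes table has %d",
                 ncol(counts), nrow(genes)))
  }
  dup_c <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dup_c)) stop("duplicate cell ids: ", paste(dup_c, collapse = ", "))
  dup_g <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup_g)) stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.null(normalized)) {
    if (!all(dim(normalized) == dim(counts))) {
      stop("normalized layer must have the same shape as counts")
    }
  }
  rownames(counts) <- cells$cell_id
  colnames(counts) <- genes$gene_id
  rownames(cells) <- NULL
  rownames(genes) <- NULL
  structure(list(counts = counts, normalized = normalized,
                 cells = cells, genes = genes),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  normalized layer: %s\n",
              if (is.null(x$normalized)) "absent" else "present"))
  extra <- setdiff(names(x$cells), "cell_id")
  if (length(extra)) cat("  cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Subset an ExpressionDataset
#'
#' @param x an `ExpressionDataset`.
#' @param i cell index (logical, integer, or cell ids).
#' @param j gene index (logical, integer, or gene ids).
#' @param ... ignored.
#' @return the subsetted `ExpressionDataset`.
#' @export
`[.ExpressionDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$cells$cell_id)
  if (is.character(j)) j <- match(j, x$genes$gene_id)
  norm <- if (is.null(x$normalized)) NULL else x$normalized[i, j, drop = FALSE]
  expression_dataset(x$counts[i, j, drop = FALSE],
                     x$cells[i, , drop = FALSE],
                     x$genes[j, , drop = FALSE],
                     normalized = norm)
}

#' Read a dataset triplet from disk
#'
#' Reads a Matrix Market sparse count matrix plus tab-separated cell and
#' gene metadata tables. On disk the matrix is stored genes x rows,
#' cells x columns (the 10x ecosystem convention); in memory the dataset
#' is cells x genes. Axis order follows file order.
#'
#' @param matrix_path path to a Matrix Market (.mtx) file, genes x cells.
#' @param cells_path path to a tab-separated cell table with header.
#' @param genes_path path to a tab-separated gene table with header.
#' @return an [expression_dataset()].
#' @export
read_dataset <- function(matrix_path, cells_path, genes_path) {
  m <- Matrix::readMM(matrix_path)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  for (fl in c("is_mito", "is_rbc", "is_lincRNA", "is_senescence")) {
    if (fl %in% names(genes)) genes[[fl]] <- as.logical(genes[[fl]])
  }
  if ("age_group" %in% names(cells) && !is.factor(cells$age_group)) {
    lv <- unique(cells$age_group)
    cells$age_group <- factor(cells$age_group, levels = lv, ordered = TRUE)
  }
  expression_dataset(Matrix::t(m), cells, genes)
}

#' Write a dataset triplet to disk
#'
#' Inverse of [read_dataset()]: writes `matrix.mtx` (genes x cells),
#' `cells.tsv` and `genes.tsv` into a directory.
#'
#' @param ds an `ExpressionDataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(ds$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Library-size normalization
#'
#' Scales each cell's counts to a common library size and applies a
#' natural-log transform: `normalized[i, g] = ln(1 + counts[i, g] *
#' scale / total_counts[i])`. This is the de-facto convention of the
#' major single-cell toolkits (counts per 10,000, log1p).
#'
#' @param ds an `ExpressionDataset` with counts.
#' @param scale target library size (default 1e4).
#' @return the dataset with its `normalized` layer filled.
#' @export
normalize_dataset <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals == 0)) {
    bad <- ds$cells$cell_id[totals == 0]
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  norm <- Matrix::Diagonal(x = scale / totals) %*% ds$counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(ds$counts)
  ds$normalized <- norm
  ds
}

#' Regress batch effects out of the normalized layer
#'
#' Fits, per gene, a ridge (L2-regularized) linear model of normalized
#' expression on one-hot batch indicators with an unpenalized intercept,
#' and replaces the layer with the residuals plus the gene's grand mean.
#' With the penalty taken to zero this reproduces ordinary least-squares
#' residualization; with a large penalty the layer is returned unchanged.
#' The fit is deterministic.
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param batch_keys character vector of cell-table column names treated
#'   as categorical batch variables.
#' @param ridge_penalty non-negative L2 penalty (default 1).
#' @return the dataset with a batch-corrected (dense) normalized layer.
#' @export
regress_out_batch <- function(ds, batch_keys, ridge_penalty = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$normalized)) stop("normalized layer required; run normalize_dataset() first")
  miss <- setdiff(batch_keys, names(ds$cells))
  if (length(miss)) stop("unknown batch columns: ", paste(miss, collapse = ", "))
  keep <- character(0)
  for (k in batch_keys) {
    if (length(unique(as.character(ds$cells[[k]]))) < 2) {
      warning(sprintf("batch column '%s' has a single level; ignored", k))
    } else keep <- c(keep, k)
  }
  if (!length(keep)) return(ds)

  # one-hot design over all levels of all batch keys; intercept handled by
  # centering, which leaves it unpenalized
  blocks <- lapply(keep, function(k) {
    f <- factor(as.character(ds$cells[[k]]))
    stats::model.matrix(~ f - 1)
  })
  X <- do.call(cbind, blocks)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Y <- as.matrix(ds$normalized)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  A <- crossprod(Xc) + diag(ridge_penalty, ncol(Xc))
  B <- solve(A, crossprod(Xc, Yc))
  res <- Yc - Xc %*% B
  out <- sweep(res, 2, mu, "+")
  dimnames(out) <- dimnames(ds$counts)
  ds$normalized <- out
  ds
}

# Dense column access to the normalized layer (internal).
norm_matrix <- function(ds, genes = NULL) {
  if (is.null(ds$normalized)) stop("normalized layer required; run normalize_dataset() first")
  m <- ds$normalized
  if (!is.null(genes)) {
    j <- if (is.character(genes)) match(genes, ds$genes$gene_id) else genes
    if (anyNA(j)) stop("unknown genes: ",
                       paste(genes[is.na(j)], collapse = ", "))
    m <- m[, j, drop = FALSE]
  }
  as.matrix(m)
}
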