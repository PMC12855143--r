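#' Quality-control thresholds
#'
#' Defaults read the filtering rules of thymus atlas practice: cells
#' retained when they express between `min_genes` and `max_genes` genes
#' (inclusive bounds), with mitochondrial expression strictly below
#' `max_mito` and red-blood-cell expression strictly below `max_rbc` of
#' the cell's library; lincRNA genes are removed before any metric is
#' computed, and genes detected in fewer than `min_cells_per_gene`
#' retained cells are dropped afterwards.
#'
#' @param min_genes,max_genes inclusive detected-gene bounds.
#' @param max_mito,max_rbc strict upper bounds on the flagged-class
#'   count fractions, in (0, 1).
#' @param min_cells_per_gene minimum retained cells a gene must be
#'   detected in.
#' @param drop_lincRNA drop lincRNA-flagged genes first.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 5000L,
                          max_mito = 0.05, max_rbc = 0.01,
                          min_cells_per_gene = 3L, drop_lincRNA = TRUE) {
  stopifnot(min_genes < max_genes,
            max_mito > 0, max_mito < 1, max_rbc > 0, max_rbc < 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito = max_mito, max_rbc = max_rbc,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 drop_lincRNA = isTRUE(drop_lincRNA)),
            class = "qc_thresholds")
}

#' Compute per-cell QC metrics
#'
#' Fills `n_genes_detected` (genes with count > 0), `mito_fraction` and
#' `rbc_fraction` (flagged-gene counts over total counts; 0 for
#' all-zero cells) in the cell table.
#'
#' @param ds an `ExpressionDataset` whose gene table carries `is_mito`
#'   and `is_rbc` flags.
#' @return the dataset with metric columns filled.
#' @export
compute_qc_metrics <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  for (fl in c("is_mito", "is_rbc")) {
    if (!fl %in% names(ds$genes)) stop("gene table lacks flag column ", fl)
  }
  totals <- Matrix::rowSums(ds$counts)
  detected <- Matrix::rowSums(ds$counts > 0)
  mito <- Matrix::rowSums(ds$counts[, ds$genes$is_mito, drop = FALSE])
  rbc <- Matrix::rowSums(ds$counts[, ds$genes$is_rbc, drop = FALSE])
  ds$cells$n_genes_detected <- as.integer(detected)
  ds$cells$mito_fraction <- ifelse(totals > 0, mito / totals, 0)
  ds$cells$rbc_fraction <- ifelse(totals > 0, rbc / totals, 0)
  ds
}

#' Filter cells and genes by QC rules
#'
#' lincRNA genes are removed first (so they never contribute to the
#' metrics), metrics are recomputed, then cells are kept when
#' `min_genes <= n_genes_detected <= max_genes` (inclusive) and
#' `mito_fraction < max_mito` and `rbc_fraction < max_rbc` (strict).
#' Finally genes detected in fewer than `min_cells_per_gene` retained
#' cells are dropped. The report tallies each excluded cell once, under
#' its first failing rule in the order gene-range, mito, rbc.
#'
#' @param ds an `ExpressionDataset`.
#' @param th a [qc_thresholds()] object.
#' @return list with `dataset` (filtered) and `report` (a `qc_report`:
#'   per-sample before/after counts, per-rule exclusion tallies, and the
#'   thresholds used).
#' @export
filter_cells <- function(ds, th = qc_thresholds()) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (th$drop_lincRNA && "is_lincRNA" %in% names(ds$genes)) {
    ds <- ds[, !ds$genes$is_lincRNA]
  }
  ds <- compute_qc_metrics(ds)
  cl <- ds$cells
  fail_range <- cl$n_genes_detected < th$min_genes |
    cl$n_genes_detected > th$max_genes
  fail_mito <- cl$mito_fraction >= th$max_mito
  fail_rbc <- cl$rbc_fraction >= th$max_rbc
  keep <- !(fail_range | fail_mito | fail_rbc)

  first_rule <- rep(NA_character_, nrow(cl))
  first_rule[fail_rbc] <- "rbc"
  first_rule[fail_mito] <- "mito"
  first_rule[fail_range] <- "gene_range"

  before <- table(cl$sample_id)
  out <- ds[keep, ]
  # gene-level support filter on retained cells
  support <- Matrix::colSums(out$counts > 0)
  out <- out[, support >= th$min_cells_per_gene]
  out <- compute_qc_metrics(out)
  after <- table(factor(out$cells$sample_id, levels = names(before)))

  per_sample <- data.frame(sample_id = names(before),
                           cells_before = as.integer(before),
                           cells_after = as.integer(after),
                           stringsAsFactors = FALSE)
  tallies <- c(gene_range = sum(first_rule == "gene_range", na.rm = TRUE),
               mito = sum(first_rule == "mito", na.rm = TRUE),
               rbc = sum(first_rule == "rbc", na.rm = TRUE))
  if (nrow(out$cells) == 0) warning("no cells pass QC")
  report <- structure(list(per_sample = per_sample, exclusions = tallies,
                           thresholds = th,
                           excluded_cells = cl$cell_id[!keep]),
                      class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  cells: %d -> %d\n", sum(x$per_sample$cells_before),
              sum(x$per_sample$cells_after)))
  cat("  exclusions:",
      paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
            collapse = ", "), "\n")
  invisible(x)
}
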