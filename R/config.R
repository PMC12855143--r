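#' Default pipeline configuration
#'
#' Collects the tunable thresholds of every stage in one list. Defaults
#' follow the conventions of the analysis the pipeline implements:
#' inclusive 200--5000 detected-gene bounds with strict 5% mitochondrial
#' and 1% red-blood-cell caps for QC, natural-log fold change 0.25 and
#' p 0.05 for markers, top 10% of genes as HVGs, 20 pseudotime bins with
#' 999 permutations, and clustering resolution 0.8.
#'
#' @param ... named overrides of any default, e.g.
#'   `pipeline_config(marker = list(min_logFC = 0.5))` replaces only the
#'   fields given.
#' @return a named list of stage settings with class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    normalize = list(scale = 1e4),
    qc = list(min_genes = 200L, max_genes = 5000L, max_mito = 0.05,
              max_rbc = 0.01, min_cells_per_gene = 3L, drop_lincRNA = TRUE),
    cluster = list(resolution = 0.8, n_pcs = 20L, k_neighbors = 20L),
    marker = list(min_logFC = 0.25, max_p = 0.05, adjust = FALSE),
    cv = list(top_fraction = 0.10, max_pairs = 1e6),
    conservation = list(min_pct = 0.05, min_log2fc = 0.5),
    senescence = list(min_logFC = 0.25, max_p_adj = 0.05, min_cells = 3L),
    modules = list(n_bins = 20L, n_perm = 999L, fdr = 0.05, K = 17L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a stage output table
#'
#' All stage outputs are tab-separated tables; a header comment records
#' the seed and a hash of the configuration so results can be traced.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param config a [pipeline_config()] (optional).
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    h <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")) *
               seq_along(utf8ToInt(paste(deparse(unclass(config)), collapse = "")))) %% 1e9
    writeLines(sprintf("# seed=%s config_hash=%09.0f", config$seed, h), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
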