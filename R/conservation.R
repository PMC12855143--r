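#' Resolve orthologue candidates to a one-to-one mapping
#'
#' For every group of candidate links that is not one-to-one (a
#' reference gene linked to several genes of the other species, or vice
#' versa), the candidate whose gene has the highest total expression in
#' its own species is kept; ties break by lexicographically smaller
#' gene id. The result is a bijection on its domain.
#'
#' @param links data.frame with columns `gene_a` (reference species) and
#'   `gene_b` (other species), one row per candidate link.
#' @param expr_totals list with named numeric vectors `a` and `b` giving
#'   each gene's total expression in its species.
#' @return data.frame of resolved links (`gene_a`, `gene_b`), a
#'   one-to-one mapping.
#' @export
resolve_orthologues <- function(links, expr_totals) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(links)))
  need_a <- setdiff(links$gene_a, names(expr_totals$a))
  need_b <- setdiff(links$gene_b, names(expr_totals$b))
  if (length(need_a) || length(need_b)) {
    stop("expression totals missing for: ",
         paste(c(need_a, need_b), collapse = ", "))
  }
  lk <- unique(links[, c("gene_a", "gene_b")])
  # one-to-many: a reference gene with several partners keeps the
  # partner most expressed in the other species
  keep <- unlist(lapply(split(seq_len(nrow(lk)), lk$gene_a), function(ix) {
    if (length(ix) == 1) return(ix)
    tot <- expr_totals$b[lk$gene_b[ix]]
    ix[order(-tot, lk$gene_b[ix])[1]]
  }))
  lk <- lk[sort(keep), , drop = FALSE]
  # many-to-one: several reference genes on one partner keep the most
  # expressed reference gene
  keep <- unlist(lapply(split(seq_len(nrow(lk)), lk$gene_b), function(ix) {
    if (length(ix) == 1) return(ix)
    tot <- expr_totals$a[lk$gene_a[ix]]
    ix[order(-tot, lk$gene_a[ix])[1]]
  }))
  lk <- lk[sort(keep), , drop = FALSE]
  rownames(lk) <- NULL
  lk
}

#' Cell-type-enriched marker genes
#'
#' A gene is enriched for a cell type when it is detected in more than
#' `min_pct` of the type's cells and its de-logged mean expression
#' exceeds that of all other cells by more than `min_log2fc` on the
#' log2 scale (pseudocount `eps`).
#'
#' @param ds an `ExpressionDataset` with a normalized layer.
#' @param cell_type_col cell-table column holding cell types.
#' @param min_pct minimum detection fraction within the type.
#' @param min_log2fc minimum log2 fold change vs all other cells.
#' @param eps pseudocount on the de-logged means.
#' @return named list mapping each cell type to its enriched gene ids.
#' @export
enriched_markers <- function(ds, cell_type_col = "cell_type",
                             min_pct = 0.05, min_log2fc = 0.5, eps = 1e-9) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ct <- as.character(ds$cells[[cell_type_col]])
  x <- norm_matrix(ds)
  ex <- expm1(x)
  types <- sort(unique(ct))
  out <- lapply(types, function(t) {
    inn <- ct == t
    det <- colMeans(x[inn, , drop = FALSE] > 0)
    l2 <- log2((colMeans(ex[inn, , drop = FALSE]) + eps) /
               (colMeans(ex[!inn, , drop = FALSE]) + eps))
    ds$genes$gene_id[det > min_pct & l2 > min_log2fc]
  })
  stats::setNames(out, types)
}

#' Detected genes of a dataset
#'
#' A gene counts as detected when it has at least one count in at least
#' `min_cells` cells, mirroring the gene-retention rule of the QC stage.
#'
#' @param ds an `ExpressionDataset`.
#' @param min_cells minimum supporting cells.
#' @return character vector of gene ids.
#' @export
detected_genes <- function(ds, min_cells = 3L) {
  ds$genes$gene_id[Matrix::colSums(ds$counts > 0) >= min_cells]
}

cons_levels <- c("NotDetected", "Loss", "Switch", "Conserved")

# Category for one (gene, species): enriched sets, matched type,
# expressed set (internal; also the shape the test oracle re-derives).
classify_one <- function(gene, matched_type, species_markers, expressed) {
  in_matched <- matched_type %in% names(species_markers) &&
    gene %in% species_markers[[matched_type]]
  if (in_matched) return("Conserved")
  others <- setdiff(names(species_markers), matched_type)
  if (any(vapply(others, function(t) gene %in% species_markers[[t]], TRUE)))
    return("Switch")
  if (gene %in% expressed) return("Loss")
  "NotDetected"
}

#' Classify cross-species conservation of reference markers
#'
#' Every enriched marker of the reference species is classified, per
#' other species, as Conserved (enriched for the matched cell type),
#' Switch (enriched only for a different type), Loss (detected but not
#' enriched anywhere), or NotDetected -- in that precedence order. The
#' overall category is Conserved only when every species is Conserved;
#' otherwise it is the weakest per-species category.
#'
#' @param ref_markers named list, reference cell type -> enriched gene
#'   ids (see [enriched_markers()]).
#' @param other_species named list of species entries, each a list with
#'   `markers` (that species' enriched-marker mapping), `expressed`
#'   (character vector of detected genes), and optionally `orthologues`
#'   (named character vector translating reference gene ids to that
#'   species' ids; identity when absent).
#' @param type_matching named list per species mapping each reference
#'   cell type to that species' corresponding type; a single named
#'   character vector is recycled for all species.
#' @return data.frame with `gene_id`, `cell_type`, one category column
#'   per species, and `category` (overall).
#' @export
classify_marker_conservation <- function(ref_markers, other_species,
                                         type_matching) {
  sp_names <- names(other_species)
  if (is.null(sp_names)) stop("other_species must be a named list")
  tm <- if (is.list(type_matching) && all(sp_names %in% names(type_matching))) {
    type_matching
  } else {
    stats::setNames(rep(list(type_matching), length(sp_names)), sp_names)
  }
  rows <- list()
  for (t in names(ref_markers)) {
    for (g in ref_markers[[t]]) {
      per <- vapply(sp_names, function(s) {
        mt <- tm[[s]][[t]]
        if (is.null(mt) || is.na(mt)) stop("no matched type for '", t,
                                           "' in species ", s)
        om <- other_species[[s]]$orthologues
        gs <- if (is.null(om)) g else unname(om[g])
        if (is.null(gs) || is.na(gs)) return("NotDetected")
        classify_one(gs, mt, other_species[[s]]$markers,
                     other_species[[s]]$expressed)
      }, "")
      overall <- if (all(per == "Conserved")) "Conserved"
                 else cons_levels[min(match(per, cons_levels))]
      row <- data.frame(gene_id = g, cell_type = t, stringsAsFactors = FALSE)
      for (s in sp_names) row[[paste0("category_", s)]] <- per[[s]]
      row$category <- overall
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify cross-species expression overlap per (gene, cell type)
#'
#' Complements the marker-level classification with a detection-level
#' one: a reference gene shows conserved expression for a cell type
#' when it is detected in more than `min_pct` of the matched type's
#' cells in every species; gain of expression when it is not detected
#' in the reference dataset but is detected in another species; loss of
#' expression when it is expressed in the reference type but, in some
#' species, only in a different type; otherwise unclassified (or absent
#' when undetected everywhere).
#'
#' @param datasets named list of `ExpressionDataset`s, the first entry
#'   being the reference species.
#' @param type_matching named list per non-reference species mapping
#'   reference cell types to that species' types (a single named vector
#'   is recycled).
#' @param orthologues named list per non-reference species of named
#'   character vectors translating reference gene ids (identity when
#'   absent).
#' @param min_pct detection-fraction threshold.
#' @param min_cells detection support threshold for "detected at all".
#' @return data.frame with `gene_id`, `cell_type`, `class` in
#'   {"conserved_expression", "gain_of_expression",
#'   "loss_of_expression", "unclassified", "absent"}.
#' @export
classify_expression_overlap <- function(datasets, type_matching,
                                        orthologues = NULL, min_pct = 0.05,
                                        min_cells = 3L) {
  sp <- names(datasets)
  ref <- datasets[[1]]
  others <- sp[-1]
  tm <- if (is.list(type_matching)) type_matching
        else stats::setNames(rep(list(type_matching), length(others)), others)
  det_frac <- function(ds, gene, type) {
    j <- match(gene, ds$genes$gene_id)
    if (is.na(j)) return(NA_real_)
    inn <- as.character(ds$cells$cell_type) == type
    if (!any(inn)) return(NA_real_)
    mean(ds$counts[inn, j] > 0)
  }
  detected_at_all <- function(ds, gene) {
    j <- match(gene, ds$genes$gene_id)
    !is.na(j) && sum(ds$counts[, j] > 0) >= min_cells
  }
  types <- sort(unique(as.character(ref$cells$cell_type)))
  rows <- list()
  for (g in ref$genes$gene_id) {
    ref_det <- detected_at_all(ref, g)
    for (t in types) {
      fr_ref <- det_frac(ref, g, t)
      per <- lapply(others, function(s) {
        om <- orthologues[[s]]
        gs <- if (is.null(om)) g else unname(om[g])
        mt <- tm[[s]][[t]]
        list(frac = if (is.na(gs) || is.null(mt)) NA_real_
                    else det_frac(datasets[[s]], gs, mt),
             det = !is.na(gs) && detected_at_all(datasets[[s]], gs))
      })
      fr_all <- c(fr_ref, vapply(per, `[[`, 0, "frac"))
      any_other_det <- any(vapply(per, `[[`, TRUE, "det"))
      cls <- if (all(!is.na(fr_all)) && all(fr_all > min_pct)) {
        "conserved_expression"
      } else if (!ref_det && any_other_det) {
        "gain_of_expression"
      } else if (!ref_det && !any_other_det) {
        "absent"
      } else if (!is.na(fr_ref) && fr_ref > min_pct &&
                 any(vapply(seq_along(others), function(k) {
                   s <- others[k]
                   fr <- per[[k]]$frac
                   (is.na(fr) || fr <= min_pct) &&
                     expressed_in_other_type(datasets[[s]], orthologues[[s]],
                                             g, tm[[s]][[t]], min_pct)
                 }, TRUE))) {
        "loss_of_expression"
      } else "unclassified"
      rows[[length(rows) + 1L]] <- data.frame(gene_id = g, cell_type = t,
                                              class = cls,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Is the (translated) gene expressed above min_pct in any type other
# than the matched one? (internal)
expressed_in_other_type <- function(ds, om, gene, matched_type, min_pct) {
  gs <- if (is.null(om)) gene else unname(om[gene])
  if (is.null(gs) || is.na(gs)) return(FALSE)
  j <- match(gs, ds$genes$gene_id)
  if (is.na(j)) return(FALSE)
  types <- setdiff(unique(as.character(ds$cells$cell_type)), matched_type)
  for (t in types) {
    inn <- as.character(ds$cells$cell_type) == t
    if (any(inn) && mean(ds$counts[inn, j] > 0) > min_pct) return(TRUE)
  }
  FALSE
}
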