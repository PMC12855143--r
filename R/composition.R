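#' Per-sample cell-type proportions
#'
#' For each sample, the proportion of a cell type is its cell count
#' divided by the number of the sample's cells in the same sorting
#' gate; within a (sample, gate) pair the proportions of its types sum
#' to 1. With the default single gate this is simply cells of the type
#' over all cells of the sample.
#'
#' @param cells a cell table with `sample_id`, `cell_type`, and
#'   optionally `age_group`.
#' @param gate_map named character vector mapping every cell type to a
#'   gate name; `NULL` puts all types in one gate `"all"`.
#' @return data.frame of proportion records: `sample_id`, `cell_type`,
#'   `gate`, `n_cells`, `denominator`, `proportion`, plus `age_group`
#'   when available. Types absent from a sample get explicit zero rows.
#' @export
compute_proportions <- function(cells, gate_map = NULL) {
  stopifnot(is.data.frame(cells))
  if (!"cell_type" %in% names(cells) || anyNA(cells$cell_type)) {
    stop("cell_type must be assigned for every cell")
  }
  types <- sort(unique(as.character(cells$cell_type)))
  if (is.null(gate_map)) gate_map <- stats::setNames(rep("all", length(types)), types)
  miss <- setdiff(types, names(gate_map))
  if (length(miss)) stop("cell types missing from gate_map: ",
                         paste(miss, collapse = ", "))
  samples <- unique(as.character(cells$sample_id))
  grid <- expand.grid(sample_id = samples, cell_type = types,
                      stringsAsFactors = FALSE)
  grid$gate <- unname(gate_map[grid$cell_type])
  cnt <- table(cells$sample_id, cells$cell_type)
  grid$n_cells <- as.integer(cnt[cbind(grid$sample_id, grid$cell_type)])
  den <- stats::aggregate(n_cells ~ sample_id + gate, grid, sum)
  names(den)[3] <- "denominator"
  grid <- merge(grid, den, by = c("sample_id", "gate"), sort = FALSE)
  grid$proportion <- ifelse(grid$denominator > 0,
                            grid$n_cells / grid$denominator, NA_real_)
  if ("age_group" %in% names(cells)) {
    ag <- unique(cells[, c("sample_id", "age_group")])
    grid <- merge(grid, ag, by = "sample_id", sort = FALSE)
  }
  grid <- grid[order(grid$sample_id, grid$cell_type),
               c("sample_id", if ("age_group" %in% names(grid)) "age_group",
                 "cell_type", "gate", "n_cells", "denominator", "proportion")]
  rownames(grid) <- NULL
  grid
}

#' Test a cell type's proportion change between age groups
#'
#' With at least two samples per group, a Welch two-sample t-test on the
#' per-sample proportions. When either group has exactly one sample (as
#' in a one-animal-per-age design), the test falls back to a
#' two-proportion z-test on the pooled cell counts and the result is
#' labelled accordingly so it is not over-interpreted as a
#' between-animal test.
#'
#' @param props proportion records from [compute_proportions()], with an
#'   `age_group` column.
#' @param cell_type the cell type tested.
#' @param groupA,groupB age-group labels defining the two groups.
#' @return list with `method` ("welch_t" or "pooled_z"), `statistic`,
#'   `p_value`, `estimateA`, `estimateB`, and per-group sample counts.
#' @export
test_proportion_change <- function(props, cell_type, groupA, groupB) {
  stopifnot(is.data.frame(props), "age_group" %in% names(props))
  sub <- props[props$cell_type == cell_type, , drop = FALSE]
  a <- sub[as.character(sub$age_group) %in% as.character(groupA), , drop = FALSE]
  b <- sub[as.character(sub$age_group) %in% as.character(groupB), , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("empty age group in comparison")
  if (nrow(a) >= 2 && nrow(b) >= 2) {
    tt <- stats::t.test(a$proportion, b$proportion)
    list(method = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value,
         estimateA = mean(a$proportion), estimateB = mean(b$proportion),
         n_samples = c(A = nrow(a), B = nrow(b)))
  } else {
    xa <- sum(a$n_cells); na <- sum(a$denominator)
    xb <- sum(b$n_cells); nb <- sum(b$denominator)
    p1 <- xa / na; p2 <- xb / nb
    pp <- (xa + xb) / (na + nb)
    se <- sqrt(pp * (1 - pp) * (1 / na + 1 / nb))
    z <- if (se == 0) 0 else (p1 - p2) / se
    list(method = "pooled_z", statistic = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         estimateA = p1, estimateB = p2,
         n_samples = c(A = nrow(a), B = nrow(b)))
  }
}
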