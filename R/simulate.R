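#' Describe a simulated cell type
#'
#' @param name cell-type name.
#' @param marker_genes character vector of gene ids (from the simulated
#'   catalog) up-regulated in this type.
#' @param marker_log_effect natural-log fold change applied to marker
#'   genes in cells of this type (> 0).
#' @param baseline_mean multiplier on the gene-level baseline means for
#'   cells of this type (> 0).
#' @return a `cell_type_profile` list.
#' @export
cell_type_profile <- function(name, marker_genes = character(0),
                              marker_log_effect = 1.5, baseline_mean = 1) {
  stopifnot(is.character(name), length(name) == 1,
            is.finite(marker_log_effect), marker_log_effect >= 0,
            baseline_mean > 0)
  structure(list(name = name, marker_genes = marker_genes,
                 marker_log_effect = marker_log_effect,
                 baseline_mean = baseline_mean),
            class = "cell_type_profile")
}

#' Describe a simulated age group
#'
#' @param name ordered age label (e.g. "3d").
#' @param composition named numeric vector of cell-type proportions,
#'   summing to 1.
#' @param n_cells total cells in the group (> 0).
#' @param n_samples number of biological samples the cells are split
#'   across (default 1, as in a one-animal-per-age design).
#' @param variance_inflation named numeric vector mapping cell types to
#'   a count-variance inflation factor (>= 1); types not named are
#'   uninflated.
#' @param senescence_shift per-rank natural-log shift applied to
#'   senescence-flagged genes; a gene's mean is multiplied by
#'   `exp(direction * senescence_shift * age_rank)` where age rank runs
#'   0, 1, 2, ... across groups.
#' @return an `age_group_spec` list.
#' @export
age_group_spec <- function(name, composition, n_cells, n_samples = 1L,
                           variance_inflation = numeric(0),
                           senescence_shift = 0) {
  stopifnot(n_cells > 0, n_samples >= 1)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop(sprintf("composition for age group '%s' sums to %.6f, not 1",
                 name, sum(composition)))
  }
  if (length(variance_inflation) && any(variance_inflation < 1)) {
    stop("variance_inflation factors must be >= 1")
  }
  structure(list(name = name, composition = composition,
                 n_cells = as.integer(n_cells),
                 n_samples = as.integer(n_samples),
                 variance_inflation = variance_inflation,
                 senescence_shift = senescence_shift),
            class = "age_group_spec")
}

#' Simulate a cell metadata table only
#'
#' Draws per-sample cell-type memberships from each age group's
#' composition (multinomial per sample) without generating expression.
#' Used by [generate_dataset()] and directly by composition power
#' studies, where expression is irrelevant.
#'
#' @param ages list of [age_group_spec()].
#' @param seed RNG seed.
#' @return a cell table (data.frame) with `cell_id`, `sample_id`,
#'   `age_group` (ordered factor), `cell_type`, `age_rank`.
#' @export
simulate_cell_table <- function(ages, seed = 1L) {
  set.seed(seed)
  age_names <- vapply(ages, `[[`, "", "name")
  rows <- list()
  for (a in seq_along(ages)) {
    sp <- ages[[a]]
    per <- rep(sp$n_cells %/% sp$n_samples, sp$n_samples)
    rem <- sp$n_cells - sum(per)
    if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
    for (s in seq_len(sp$n_samples)) {
      k <- drop(stats::rmultinom(1, per[s], sp$composition))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_s%d", sp$name, s),
        age_group = sp$name,
        cell_type = rep(names(sp$composition), k),
        age_rank = a - 1L,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  cells <- cbind(cell_id = sprintf("cell%06d", seq_len(nrow(cells))), cells)
  cells$age_group <- factor(cells$age_group, levels = age_names, ordered = TRUE)
  cells
}

# Gamma-Poisson size parameter giving variance v * (mu + mu^2/theta)
# at unchanged mean mu (internal).
inflated_size <- function(mu, theta, v) {
  if (v <= 1) return(rep(theta, length(mu)))
  mu^2 / (v * (mu + mu^2 / theta) - mu)
}

#' Generate an age-structured synthetic dataset with planted truth
#'
#' Counts follow a Gamma-Poisson (negative binomial) model: each gene
#' draws a log-normal baseline mean; cells of a type multiply their
#' type's marker genes by `exp(marker_log_effect)`; senescence-flagged
#' genes drift monotonically with age rank; designated mito / red-blood
#' cell / lincRNA gene classes receive fixed shares of the expected
#' library; and per-(age, type) variance inflation scales the count
#' variance at unchanged mean. Deterministic given `seed`.
#'
#' @param profiles list of [cell_type_profile()] (>= 2).
#' @param ages list of [age_group_spec()] (>= 2).
#' @param n_genes total genes in the catalog.
#' @param seed RNG seed.
#' @param theta baseline negative-binomial size (dispersion) parameter.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   gene baseline means.
#' @param n_senescence number of senescence-flagged genes.
#' @param n_mito,n_rbc,n_linc sizes of the flagged QC gene classes.
#' @param mito_share,rbc_share,linc_share expected fraction of each
#'   cell's library carried by the corresponding class.
#' @return a list with elements `dataset` (an [expression_dataset()])
#'   and `truth` (planted cell types, senescence directions, marker
#'   assignments, and the seed).
#' @export
generate_dataset <- function(profiles, ages, n_genes = 300L, seed = 1L,
                             theta = 2, baseline_meanlog = log(0.5),
                             baseline_sdlog = 1,
                             n_senescence = 20L, n_mito = 5L, n_rbc = 5L,
                             n_linc = 5L, mito_share = 0.02,
                             rbc_share = 0.003, linc_share = 0.01) {
  if (length(profiles) < 2) stop("need at least 2 cell types")
  if (length(ages) < 2) stop("need at least 2 age groups")
  type_names <- vapply(profiles, `[[`, "", "name")
  for (sp in ages) {
    miss <- setdiff(names(sp$composition), type_names)
    if (length(miss)) stop("composition names unknown to profiles: ",
                           paste(miss, collapse = ", "))
  }
  n_flag <- n_senescence + n_mito + n_rbc + n_linc
  if (n_flag >= n_genes) stop("flagged gene classes exceed n_genes")

  cells <- simulate_cell_table(ages, seed = seed)
  # simulate_cell_table set the seed; all later draws continue the stream

  gene_id <- sprintf("g%05d", seq_len(n_genes))
  n_reg <- n_genes - n_flag
  sen_idx <- seq(n_reg + 1L, length.out = n_senescence)
  mito_idx <- seq(n_reg + n_senescence + 1L, length.out = n_mito)
  rbc_idx <- seq(n_reg + n_senescence + n_mito + 1L, length.out = n_rbc)
  linc_idx <- seq(n_reg + n_senescence + n_mito + n_rbc + 1L, length.out = n_linc)
  genes <- data.frame(gene_id = gene_id, symbol = toupper(gene_id),
                      is_mito = FALSE, is_rbc = FALSE, is_lincRNA = FALSE,
                      is_senescence = FALSE, stringsAsFactors = FALSE)
  genes$is_senescence[sen_idx] <- TRUE
  genes$is_mito[mito_idx] <- TRUE
  genes$is_rbc[rbc_idx] <- TRUE
  genes$is_lincRNA[linc_idx] <- TRUE

  for (p in profiles) {
    bad <- setdiff(p$marker_genes, gene_id)
    if (length(bad)) stop("marker genes outside catalog: ",
                          paste(bad, collapse = ", "))
  }

  lambda <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  # give flagged classes their designated share of the expected library
  rescale_class <- function(lambda, idx, share) {
    if (!length(idx) || share <= 0) return(lambda)
    other <- sum(lambda[-idx])
    lambda[idx] <- lambda[idx] * share * other / ((1 - share) * sum(lambda[idx]))
    lambda
  }
  lambda <- rescale_class(lambda, mito_idx, mito_share)
  lambda <- rescale_class(lambda, rbc_idx, rbc_share)
  lambda <- rescale_class(lambda, linc_idx, linc_share)

  # planted monotone senescence trends: alternating directions
  sen_dir <- integer(n_genes)
  sen_dir[sen_idx] <- rep_len(c(1L, -1L), n_senescence)

  counts <- matrix(0L, nrow(cells), n_genes)
  for (a in seq_along(ages)) {
    sp <- ages[[a]]
    rank <- a - 1L
    for (p in profiles) {
      idx <- which(cells$age_group == sp$name & cells$cell_type == p$name)
      if (!length(idx)) next
      mu <- lambda * p$baseline_mean
      mk <- match(p$marker_genes, gene_id)
      mu[mk] <- mu[mk] * exp(p$marker_log_effect)
      shift <- sp$senescence_shift
      if (shift != 0 && rank > 0) {
        mu[sen_idx] <- mu[sen_idx] * exp(sen_dir[sen_idx] * shift * rank)
      }
      v <- unname(sp$variance_inflation[p$name])
      sz <- if (length(v) && !is.na(v)) inflated_size(mu, theta, v) else rep(theta, n_genes)
      nc <- length(idx)
      counts[idx, ] <- matrix(
        stats::rnbinom(nc * n_genes, mu = rep(mu, each = nc),
                       size = rep(sz, each = nc)),
        nrow = nc)
    }
  }

  cells_out <- cells
  cells_out$age_rank <- NULL
  truth <- list(
    cells = data.frame(cell_id = cells$cell_id, true_type = cells$cell_type,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_id,
                       baseline_mean = lambda,
                       senescence_direction = sen_dir,
                       stringsAsFactors = FALSE),
    markers = stats::setNames(lapply(profiles, `[[`, "marker_genes"), type_names),
    seed = seed)
  list(dataset = expression_dataset(counts, cells_out, genes), truth = truth)
}

#' Default age-structured simulation scene
#'
#' Four ordered age groups with composition trends that qualitatively
#' mirror an aging thymus: a regulatory-T-like fraction rising from
#' about 1.7% to 7.2%, double-negative-like fractions falling, and
#' variance inflation plus senescence drift in the older groups.
#'
#' @param n_cells cells per age group.
#' @param n_samples samples per age group.
#' @param marker_log_effect marker strength passed to every profile.
#' @param n_markers_per_type marker genes planted per cell type.
#' @return list with `profiles` and `ages`, ready for
#'   [generate_dataset()].
#' @export
default_scene <- function(n_cells = 800L, n_samples = 1L,
                          marker_log_effect = 1.5, n_markers_per_type = 5L) {
  types <- c("DN_early", "DN_Q", "DP_Q", "DP_C", "CD4_SP", "CD8_SP",
             "Treg", "B_naive")
  comp <- rbind(
    `3d`   = c(0.15, 0.20, 0.25, 0.15, 0.10, 0.08, 0.0168, 0.0532),
    `57d`  = c(0.12, 0.17, 0.26, 0.15, 0.12, 0.10, 0.0139, 0.0661),
    `1y`   = c(0.08, 0.12, 0.27, 0.15, 0.14, 0.12, 0.0409, 0.0791),
    `5y3m` = c(0.05, 0.08, 0.25, 0.15, 0.16, 0.14, 0.0720, 0.0980))
  colnames(comp) <- types
  profiles <- lapply(seq_along(types), function(i) {
    mk <- sprintf("g%05d", (i - 1L) * n_markers_per_type + seq_len(n_markers_per_type))
    cell_type_profile(types[i], marker_genes = mk,
                      marker_log_effect = marker_log_effect)
  })
  ages <- lapply(seq_len(nrow(comp)), function(a) {
    infl <- if (a >= 3) c(DN_Q = 2) else numeric(0)
    age_group_spec(rownames(comp)[a], comp[a, ], n_cells = n_cells,
                   n_samples = n_samples, variance_inflation = infl,
                   senescence_shift = 0.5)
  })
  list(profiles = profiles, ages = ages)
}

#' Generate a pseudotime lineage with planted gene modules
#'
#' Cells receive a true pseudotime ~ Uniform(0, 1). Module genes follow
#' a smooth Gaussian-bump template with a module-specific onset along
#' pseudotime (amplitude on the log scale) plus Gaussian noise; noise
#' genes are flat. The structure is planted directly on the log
#' (normalized) scale; an integer count layer is derived by inverting
#' the log1p transform.
#'
#' @param n_cells number of cells.
#' @param n_genes total genes.
#' @param K_modules number of planted modules (>= 2).
#' @param n_noise_genes genes with no pseudotime structure.
#' @param seed RNG seed.
#' @param amplitude template height on the log scale.
#' @param noise_sd per-cell Gaussian noise on the log scale.
#' @param baseline flat log-scale baseline for every gene.
#' @return list with `dataset` (normalized layer filled, pseudotime in
#'   the cell table) and `truth` (`genes$module_id`, NA for noise genes).
#' @export
generate_lineage <- function(n_cells = 1000L, n_genes = 200L, K_modules = 5L,
                             n_noise_genes = 50L, seed = 1L, amplitude = 3,
                             noise_sd = 0.5, baseline = 1) {
  if (K_modules < 2) stop("K_modules must be >= 2")
  if (n_noise_genes > n_genes) stop("n_noise_genes exceeds n_genes")
  set.seed(seed)
  pt <- stats::runif(n_cells)
  n_mod_genes <- n_genes - n_noise_genes
  module <- rep(NA_integer_, n_genes)
  if (n_mod_genes > 0) {
    module[seq_len(n_mod_genes)] <-
      sort(rep(seq_len(K_modules), length.out = n_mod_genes))
  }
  centers <- (seq_len(K_modules) - 0.5) / K_modules
  width <- 0.5 / K_modules
  expr <- matrix(baseline, n_cells, n_genes)
  for (g in seq_len(n_genes)) {
    if (!is.na(module[g])) {
      tpl <- exp(-(pt - centers[module[g]])^2 / (2 * width^2))
      expr[, g] <- expr[, g] + amplitude * tpl
    }
  }
  expr <- expr + matrix(stats::rnorm(n_cells * n_genes, 0, noise_sd),
                        n_cells, n_genes)
  expr <- pmax(expr, 0)
  counts <- round(expm1(expr))
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  genes <- data.frame(gene_id = gene_id, symbol = toupper(gene_id),
                      is_mito = FALSE, is_rbc = FALSE, is_lincRNA = FALSE,
                      is_senescence = FALSE, stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = sprintf("cell%06d", seq_len(n_cells)),
                      sample_id = "lineage",
                      age_group = factor(rep("all", n_cells), ordered = TRUE),
                      pseudotime = pt, stringsAsFactors = FALSE)
  ds <- expression_dataset(counts, cells, genes)
  dimnames(expr) <- dimnames(ds$counts)
  ds$normalized <- expr
  truth <- list(genes = data.frame(gene_id = gene_id, module_id = module,
                                   stringsAsFactors = FALSE),
                seed = seed)
  list(dataset = ds, truth = truth)
}

#' Build the QC boundary fixture
#'
#' A small deterministic dataset placing cells deliberately on each side
#' of every quality-control boundary: 199/200/5000/5001 detected genes,
#' 4.9%/5.0% mitochondrial fraction, 0.9%/1.0% red-blood-cell fraction,
#' plus lincRNA genes and a few unremarkable cells. The cell table
#' carries a `qc_class` column naming each boundary case.
#'
#' @param seed unused placeholder for interface symmetry; the fixture is
#'   fully deterministic.
#' @return an [expression_dataset()].
#' @export
make_qc_fixture <- function(seed = 1L) {
  n_reg <- 5100L
  reg <- sprintf("g%05d", seq_len(n_reg))
  mito <- sprintf("mt-%02d", 1:10)
  rbc <- sprintf("hb-%02d", 1:10)
  linc <- sprintf("linc-%02d", 1:20)
  gene_id <- c(reg, mito, rbc, linc)
  genes <- data.frame(gene_id = gene_id, symbol = toupper(gene_id),
                      is_mito = gene_id %in% mito,
                      is_rbc = gene_id %in% rbc,
                      is_lincRNA = gene_id %in% linc,
                      is_senescence = FALSE, stringsAsFactors = FALSE)

  cases <- list(
    genes_199 = list(reg = 199L),
    genes_200 = list(reg = 200L),
    genes_5000 = list(reg = 5000L),
    genes_5001 = list(reg = 5001L),
    mito_4.9pct = list(reg = 951L, mito = 49L),
    mito_5.0pct = list(reg = 950L, mito = 50L),
    rbc_0.9pct = list(reg = 991L, rbc = 9L),
    rbc_1.0pct = list(reg = 990L, rbc = 10L),
    normal_1 = list(reg = 500L, linc = 5L),
    normal_2 = list(reg = 500L, linc = 5L),
    normal_3 = list(reg = 500L, linc = 5L))

  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    j <- seq_len(cs$reg)                       # nested regular-gene support
    x <- rep(1L, cs$reg)
    if (!is.null(cs$mito)) { j <- c(j, n_reg + 1L); x <- c(x, cs$mito) }
    if (!is.null(cs$rbc)) { j <- c(j, n_reg + 11L); x <- c(x, cs$rbc) }
    if (!is.null(cs$linc)) {
      j <- c(j, n_reg + 20L + seq_len(cs$linc)); x <- c(x, rep(2L, cs$linc))
    }
    ii <- c(ii, rep(ci, length(j))); jj <- c(jj, j); xx <- c(xx, x)
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(length(cases), length(gene_id)))
  cells <- data.frame(
    cell_id = sprintf("qc_%s", names(cases)),
    sample_id = rep(c("s1", "s2"), length.out = length(cases)),
    age_group = factor(rep("3d", length(cases)), ordered = TRUE),
    qc_class = names(cases), stringsAsFactors = FALSE)
  expression_dataset(counts, cells, genes)
}
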