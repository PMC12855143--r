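# Small builders shared across tests.

# Minimal dataset from a dense cells x genes matrix; normalized layer
# can be planted directly.
toy_dataset <- function(counts, normalized = NULL, cell_type = NULL,
                        age_group = NULL, sample_id = NULL) {
  n <- nrow(counts); g <- ncol(counts)
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    sample_id = if (is.null(sample_id)) "s1" else sample_id,
    stringsAsFactors = FALSE)
  if (!is.null(age_group)) {
    cells$age_group <- factor(age_group, levels = unique(age_group),
                              ordered = TRUE)
  }
  if (!is.null(cell_type)) cells$cell_type <- cell_type
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(g)),
                      symbol = sprintf("G%03d", seq_len(g)),
                      is_mito = FALSE, is_rbc = FALSE, is_lincRNA = FALSE,
                      is_senescence = FALSE, stringsAsFactors = FALSE)
  ds <- expression_dataset(counts, cells, genes)
  if (!is.null(normalized)) {
    dimnames(normalized) <- dimnames(ds$counts)
    ds$normalized <- normalized
  }
  ds
}

# Independent brute-force oracle for the pairwise-distance CV: explicit
# double loop, sample sd.
cv_oracle <- function(young, old) {
  d <- numeric(0)
  for (i in seq_along(young)) {
    for (j in seq_along(old)) {
      d <- c(d, abs(young[i] - old[j]))
    }
  }
  mu <- mean(d)
  sigma <- stats::sd(d)
  list(mu = mu, sigma = sigma,
       cv = if (mu > 0) sigma / mu * 100 else NA_real_)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
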