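two_type_profiles <- function(effect = 1.5) {
  list(cell_type_profile("A", sprintf("g%05d", 1:3), effect),
       cell_type_profile("B", sprintf("g%05d", 4:6), effect))
}

test_that("the generator is deterministic and validates composition", {
  ages <- list(age_group_spec("y", c(A = 0.5, B = 0.5), 50),
               age_group_spec("o", c(A = 0.5, B = 0.5), 50))
  s1 <- generate_dataset(two_type_profiles(), ages, n_genes = 60, seed = 42)
  s2 <- generate_dataset(two_type_profiles(), ages, n_genes = 60, seed = 42)
  expect_identical(as.matrix(s1$dataset$counts), as.matrix(s2$dataset$counts))
  expect_error(age_group_spec("y", c(A = 0.6, B = 0.5), 50), "sums to")
})

test_that("realized cell-type counts follow the composition binomially", {
  ages <- list(age_group_spec("y", c(Treg = 0.05, Other = 0.95), 2000),
               age_group_spec("o", c(Treg = 0.05, Other = 0.95), 2000))
  cells <- simulate_cell_table(ages, seed = 5)
  n_treg <- sum(cells$cell_type == "Treg" & cells$age_group == "y")
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(n_treg, bounds[1])
  expect_lte(n_treg, bounds[2])
})

test_that("with zero marker effect, per-gene distributions are type-independent", {
  profs <- list(cell_type_profile("A", sprintf("g%05d", 1:3), 0),
                cell_type_profile("B", sprintf("g%05d", 4:6), 0),
                cell_type_profile("C", character(0), 0))
  ages <- list(age_group_spec("y", c(A = 1, B = 1, C = 1) / 3, 300),
               age_group_spec("o", c(A = 1, B = 1, C = 1) / 3, 300))
  sim <- generate_dataset(profs, ages, n_genes = 100, seed = 21)
  cnt <- as.matrix(sim$dataset$counts)
  type <- sim$truth$cells$true_type
  p <- apply(cnt, 2, function(x) {
    suppressWarnings(kruskal.test(x, factor(type))$p.value)
  })
  expect_lte(mean(p < 0.01, na.rm = TRUE), 0.05)
})

test_that("empirical gene means match the planted model means", {
  profs <- list(cell_type_profile("A", sprintf("g%05d", 1:5), 1.2),
                cell_type_profile("B", character(0)))
  ages <- list(age_group_spec("y", c(A = 0.5, B = 0.5), 4000),
               age_group_spec("o", c(A = 0.5, B = 0.5), 100))
  sim <- generate_dataset(profs, ages, n_genes = 80, seed = 8,
                          n_senescence = 0)
  cnt <- as.matrix(sim$dataset$counts)
  inn <- sim$truth$cells$true_type == "A" &
    sim$dataset$cells$age_group == "y"
  mu <- sim$truth$genes$baseline_mean
  mk <- match(sprintf("g%05d", 1:5), sim$dataset$genes$gene_id)
  mu[mk] <- mu[mk] * exp(1.2)
  theta <- 2
  se <- sqrt((mu + mu^2 / theta) / sum(inn))
  within3 <- abs(colMeans(cnt[inn, ]) - mu) <= 3 * se
  expect_gte(mean(within3), 0.97)
})

test_that("variance inflation scales empirical count variance by the factor", {
  v <- 3
  profs <- list(cell_type_profile("A", character(0)),
                cell_type_profile("B", character(0)))
  ages <- list(age_group_spec("y", c(A = 0.5, B = 0.5), 1600),
               age_group_spec("o", c(A = 0.5, B = 0.5), 1600,
                              variance_inflation = c(A = v)))
  sim <- generate_dataset(profs, ages, n_genes = 60, seed = 31,
                          n_senescence = 0)
  cnt <- as.matrix(sim$dataset$counts)
  type <- sim$truth$cells$true_type
  age <- as.character(sim$dataset$cells$age_group)
  vy <- apply(cnt[type == "A" & age == "y", ], 2, var)
  vo <- apply(cnt[type == "A" & age == "o", ], 2, var)
  expect_gt(median(vo / vy), 0.7 * v)
  expect_lt(median(vo / vy), 1.3 * v)
})

test_that("lineage generator plants orderable modules and flat noise", {
  lin <- generate_lineage(n_cells = 500, n_genes = 40, K_modules = 2,
                          n_noise_genes = 10, seed = 2)
  pt <- lin$dataset$cells$pseudotime
  x <- as.matrix(lin$dataset$normalized)
  first <- pt <= quantile(pt, 0.1)
  last <- pt >= quantile(pt, 0.9)
  m1 <- lin$truth$genes$module_id %in% 1
  m2 <- lin$truth$genes$module_id %in% 2
  expect_gt(mean(x[first, m1]), mean(x[last, m1]))
  expect_gt(mean(x[last, m2]), mean(x[first, m2]))
  # all-noise call leaves no planted modules
  flat <- generate_lineage(n_cells = 50, n_genes = 20, K_modules = 2,
                           n_noise_genes = 20, seed = 3)
  expect_true(all(is.na(flat$truth$genes$module_id)))
  # determinism
  again <- generate_lineage(n_cells = 500, n_genes = 40, K_modules = 2,
                            n_noise_genes = 10, seed = 2)
  expect_identical(as.matrix(lin$dataset$normalized),
                   as.matrix(again$dataset$normalized))
})

test_that("the QC fixture covers every boundary class", {
  fx <- make_qc_fixture()
  expect_setequal(
    fx$cells$qc_class,
    c("genes_199", "genes_200", "genes_5000", "genes_5001",
      "mito_4.9pct", "mito_5.0pct", "rbc_0.9pct", "rbc_1.0pct",
      "normal_1", "normal_2", "normal_3"))
  expect_true(any(fx$genes$is_lincRNA))
  res <- filter_cells(fx)
  expect_true("qc_genes_200" %in% res$dataset$cells$cell_id)
  expect_false(any(res$dataset$genes$is_lincRNA))
})
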