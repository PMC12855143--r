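test_that("library assembly dedupes case-insensitively through synonyms", {
  expect_equal(build_library(list(h = c("A", "B"), m = c("b", "C")))$size, 3)
  expect_equal(build_library(list(h = "A", m = "C"),
                             synonyms = c(C = "A"))$size, 1)
  expect_equal(build_library(list(h = c("A", "B"), m = c("C", "D", "E")))$size, 5)
})

test_that("library assembly is order-invariant and records provenance", {
  l1 <- build_library(list(h = c("TP53", "CDKN2A"), m = c("cdkn2a", "LMNB1")))
  l2 <- build_library(list(m = c("LMNB1", "cdkn2a"), h = c("CDKN2A", "TP53")))
  expect_equal(l1$entries, l2$entries)
  expect_equal(l1$entries$sources[l1$entries$symbol == "CDKN2A"], "h,m")
})

sen_scene <- function(seed, shift = 1, n_cells = 400) {
  profs <- list(cell_type_profile("A", character(0)),
                cell_type_profile("B", character(0)))
  ages <- lapply(c("a1", "a2", "a3", "a4"), function(nm) {
    age_group_spec(nm, c(A = 0.5, B = 0.5), n_cells,
                   senescence_shift = shift)
  })
  generate_dataset(profs, ages, n_genes = 100, seed = seed,
                   n_senescence = 20)
}

test_that("expressed senescence genes are counted with the support rule", {
  sim <- sen_scene(2)
  ds <- sim$dataset
  lib <- build_library(list(demo = ds$genes$symbol[ds$genes$is_senescence]))
  for (a in levels(ds$cells$age_group)) {
    expect_gte(count_expressed(ds, lib, a), 10)
    expect_lte(count_expressed(ds, lib, a), lib$size)
  }
  expect_error(count_expressed(ds, lib, "nonexistent"), "unknown age group")

  # boundary: a gene in exactly min_cells cells counts
  cnt <- rbind(diag(3L), matrix(0L, 1, 3)); cnt[4, 1] <- 1L
  ds2 <- toy_dataset(cnt, age_group = rep("young", 4))
  ds2$genes$symbol <- c("S1", "S2", "S3")
  lib2 <- build_library(list(x = c("S1", "S2")))
  expect_equal(count_expressed(ds2, lib2, "young", min_cells = 2), 1L)
})

test_that("planted senescence shifts surface as age DEGs with direction", {
  hits <- 0
  for (seed in 1:5) {
    sim <- sen_scene(seed, shift = 1, n_cells = 400)
    ds <- normalize_dataset(sim$dataset)
    ds$cells$cell_type <- sim$truth$cells$true_type
    lib <- build_library(list(demo = ds$genes$symbol[ds$genes$is_senescence]))
    degs <- age_degs(ds, lib, "A", contrasts = list(c("a1", "a4")))
    up_genes <- sim$truth$genes$gene_id[sim$truth$genes$senescence_direction == 1]
    found <- degs$gene_id[degs$direction == "up-with-age"]
    hits <- hits + (length(intersect(found, up_genes)) >= 8)
    # planted directions should not be contradicted
    down_genes <- sim$truth$genes$gene_id[sim$truth$genes$senescence_direction == -1]
    expect_length(intersect(found, down_genes), 0)
  }
  expect_gte(hits, 4)
})

test_that("age contrasts on label-permuted data stay near the BH threshold", {
  sim <- sen_scene(11, shift = 0, n_cells = 300)
  ds <- normalize_dataset(sim$dataset)
  ds$cells$cell_type <- sim$truth$cells$true_type
  set.seed(99)
  ds$cells$age_group <- sample(ds$cells$age_group)
  lib <- build_library(list(demo = ds$genes$symbol[ds$genes$is_senescence]))
  degs <- age_degs(ds, lib, "A", contrasts = list(c("a1", "a4")))
  expect_lte(nrow(degs), 1)
})

test_that("insufficient cells skip the contrast with a warning", {
  sim <- sen_scene(3, n_cells = 40)
  ds <- normalize_dataset(sim$dataset)
  ds$cells$cell_type <- "A"
  ds$cells$cell_type[1:38] <- "B"
  lib <- build_library(list(demo = ds$genes$symbol[ds$genes$is_senescence]))
  expect_warning(res <- age_degs(ds, lib, "A", list(c("a1", "a2"))),
                 "skipped")
  expect_equal(nrow(res), 0)
})

test_that("trend classification follows the Spearman sign with a mixed band", {
  m <- rbind(inc = c(1, 2, 3, 4), dec = c(4, 3, 2, 1), mix = c(1, 3, 2, 1))
  tr <- classify_trends(m)
  expect_equal(tr$trend, c("increasing", "decreasing", "mixed"))
  # hand Spearman for (1,3,2,1): midranks (1.5, 4, 3, 1.5) vs (1,2,3,4)
  rho_hand <- cor(c(1.5, 4, 3, 1.5), 1:4)
  expect_equal(tr$rho[3], rho_hand)
  expect_lt(abs(rho_hand), 0.5)
  s <- attr(tr, "summary")
  expect_equal(unname(s["increasing"]), 1 / 3)
  expect_error(classify_trends(m[, 1:2]), "3 age groups")
})

test_that("age mean expression table feeds trends per cell type", {
  sim <- sen_scene(7, shift = 1.2, n_cells = 300)
  ds <- normalize_dataset(sim$dataset)
  ds$cells$cell_type <- sim$truth$cells$true_type
  sen <- ds$genes$gene_id[ds$genes$is_senescence]
  m <- age_mean_expression(ds, sen, cell_type = "A")
  expect_equal(dim(m), c(length(sen), 4L))
  tr <- classify_trends(m)
  dir <- sim$truth$genes$senescence_direction[match(sen, sim$truth$genes$gene_id)]
  agree <- mean((tr$trend == "increasing") == (dir == 1))
  expect_gte(agree, 0.8)
})
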