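# Independent truth-table oracle for per-species marker conservation:
# derived directly from the category definitions, not from the
# implementation's precedence chain.
oracle_category <- function(enriched_matched, enriched_other, detected) {
  if (enriched_matched) "Conserved"
  else if (enriched_other) "Switch"
  else if (detected) "Loss"
  else "NotDetected"
}

test_that("orthologue resolution keeps the highest-expressed candidate", {
  links <- data.frame(gene_a = c("A1", "A1", "A2"),
                      gene_b = c("B1", "B2", "B3"))
  tot <- list(a = c(A1 = 5, A2 = 2), b = c(B1 = 10, B2 = 7, B3 = 1))
  res <- resolve_orthologues(links, tot)
  expect_equal(res$gene_b[res$gene_a == "A1"], "B1")
  expect_equal(nrow(res), 2)

  # ties break to the lexicographically smaller id
  tot$b <- c(B1 = 7, B2 = 7, B3 = 1)
  res <- resolve_orthologues(links, tot)
  expect_equal(res$gene_b[res$gene_a == "A1"], "B1")

  # already one-to-one input is unchanged
  l2 <- data.frame(gene_a = c("A1", "A2"), gene_b = c("B1", "B2"))
  expect_equal(resolve_orthologues(l2, tot), l2)
})

test_that("resolved orthologue maps are bijections on random candidate sets", {
  set.seed(8)
  for (rep in 1:50) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    links <- unique(data.frame(
      gene_a = sample(sprintf("A%02d", 1:na), 15, replace = TRUE),
      gene_b = sample(sprintf("B%02d", 1:nb), 15, replace = TRUE)))
    tot <- list(a = setNames(rexp(na), sprintf("A%02d", 1:na)),
                b = setNames(rexp(nb), sprintf("B%02d", 1:nb)))
    res <- resolve_orthologues(links, tot)
    expect_false(any(duplicated(res$gene_a)))
    expect_false(any(duplicated(res$gene_b)))
  }
})

test_that("enrichment needs both detection fraction and fold change", {
  # two types, 50 cells each; g1 exclusive to T1 at 50% detection,
  # g2 in only 4% of T1 cells, g3 flat everywhere
  norm <- matrix(0, 100, 3)
  norm[1:25, 1] <- 2
  norm[1:2, 2] <- 2
  norm[, 3] <- 1
  ds <- toy_dataset(matrix(1L, 100, 3), normalized = norm,
                    cell_type = rep(c("T1", "T2"), each = 50))
  mk <- enriched_markers(ds)
  expect_true("g001" %in% mk$T1)
  expect_false("g002" %in% mk$T1)               # 4% < 5% detection
  expect_false("g003" %in% mk$T1)               # no fold change
  expect_length(mk$T2, 0)
})

test_that("per-species categories follow the Conserved/Switch/Loss precedence", {
  ref <- list(T1 = c("gA", "gB", "gC", "gD"))
  sp <- list(
    human = list(markers = list(T1h = "gA", T2h = "gB"),
                 expressed = c("gA", "gB", "gC")))
  tm <- list(human = c(T1 = "T1h"))
  res <- classify_marker_conservation(ref, sp, tm)
  expect_equal(res$category[res$gene_id == "gA"], "Conserved")
  expect_equal(res$category[res$gene_id == "gB"], "Switch")
  expect_equal(res$category[res$gene_id == "gC"], "Loss")
  expect_equal(res$category[res$gene_id == "gD"], "NotDetected")

  # orthologue absent from the species => NotDetected
  sp$human$orthologues <- c(gA = NA_character_, gB = "gB", gC = "gC", gD = "gD")
  res <- classify_marker_conservation(ref, sp, tm)
  expect_equal(res$category[res$gene_id == "gA"], "NotDetected")
})

test_that("classification agrees with the flag-enumeration oracle", {
  set.seed(15)
  for (rep in 1:200) {
    em <- runif(1) < 0.4
    eo <- runif(1) < 0.4
    det <- runif(1) < 0.6
    markers <- list()
    if (em) markers$T1s <- "g"
    if (eo) markers$T2s <- "g"
    expressed <- if (det || em || eo) "g" else character(0)
    ref <- list(T1 = "g")
    res <- classify_marker_conservation(
      ref, list(s = list(markers = markers, expressed = expressed)),
      list(s = c(T1 = "T1s")))
    expect_equal(res$category_s,
                 oracle_category(em, eo, det || em || eo))
  }
})

test_that("multi-species combination reports Conserved only when unanimous", {
  ref <- list(T1 = "g")
  mk_cons <- list(markers = list(T1s = "g"), expressed = "g")
  mk_loss <- list(markers = list(), expressed = "g")
  res <- classify_marker_conservation(
    ref, list(h = mk_cons, p = mk_loss), c(T1 = "T1s"))
  expect_equal(res$category_h, "Conserved")
  expect_equal(res$category_p, "Loss")
  expect_equal(res$category, "Loss")            # weakest category overall
  res2 <- classify_marker_conservation(
    ref, list(h = mk_cons, p = mk_cons), c(T1 = "T1s"))
  expect_equal(res2$category, "Conserved")
})

test_that("identical species copies are 100% Conserved", {
  sim <- generate_dataset(
    list(cell_type_profile("A", sprintf("g%05d", 1:5), 2),
         cell_type_profile("B", sprintf("g%05d", 6:10), 2)),
    list(age_group_spec("y", c(A = 0.5, B = 0.5), 150),
         age_group_spec("o", c(A = 0.5, B = 0.5), 150)),
    n_genes = 60, seed = 23)
  ds <- normalize_dataset(sim$dataset)
  ds$cells$cell_type <- sim$truth$cells$true_type
  mk <- enriched_markers(ds)
  copy <- list(markers = mk, expressed = detected_genes(ds))
  res <- classify_marker_conservation(
    mk, list(s1 = copy, s2 = copy), c(A = "A", B = "B"))
  expect_gt(nrow(res), 0)
  expect_true(all(res$category == "Conserved"))
})

test_that("expression overlap separates conserved, gain and absent genes", {
  mk_ds <- function(det_frac) {
    norm <- matrix(0, 40, 3)
    if (det_frac > 0) norm[seq_len(det_frac * 20), 1] <- 1
    norm[, 2] <- 1                               # always-on gene
    cnt <- matrix(as.integer(norm > 0), 40, 3)
    toy_dataset(cnt, normalized = norm, cell_type = rep(c("T1", "T2"), each = 20))
  }
  dsets <- list(ref = mk_ds(0.20), h = mk_ds(0.20), p = mk_ds(0.20))
  res <- classify_expression_overlap(dsets, c(T1 = "T1", T2 = "T2"))
  expect_equal(res$class[res$gene_id == "g001" & res$cell_type == "T1"],
               "conserved_expression")
  # g003 detected nowhere => absent
  expect_true(all(res$class[res$gene_id == "g003"] == "absent"))
  # gene absent in the reference but present in another species => gain
  dsets$ref <- mk_ds(0)
  res2 <- classify_expression_overlap(dsets, c(T1 = "T1", T2 = "T2"))
  expect_true(all(res2$class[res2$gene_id == "g001"] == "gain_of_expression"))
})
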