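make_pb <- function(counts, cell_type, patient) {
  pseudobulk_aggregate(counts, cell_type, patient)
}

test_that("pseudobulk aggregation sums raw counts per (cell type, patient) group", {
  counts <- matrix(c(1, 2, 3, 4,
                     5, 0, 2, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
  pb <- make_pb(counts, c("epi", "epi", "str", "str"), rep("P1", 4))
  expect_equal(unname(pb$counts["gA", ]), c(3, 7))
  expect_equal(pb$n_cells, c(2L, 2L))

  # single cell per group is the identity
  pb1 <- make_pb(counts, paste0("t", 1:4), rep("P1", 4))
  expect_equal(unname(pb1$counts["gB", order(pb1$cell_type)]),
               unname(counts["gB", order(paste0("t", 1:4))]))
})

test_that("pseudobulk matches a brute-force regrouping oracle on a 3-patient dataset", {
  set.seed(7)
  n_cells <- 120
  counts <- matrix(rpois(20 * n_cells, 3), nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:n_cells)))
  ct <- sample(c("epi", "str", "mye"), n_cells, replace = TRUE)
  pt <- sample(paste0("P", 1:3), n_cells, replace = TRUE)
  pb <- make_pb(counts, ct, pt)
  # brute force: loop over groups and genes
  for (col in seq_along(pb$cell_type)) {
    sel <- ct == pb$cell_type[col] & pt == pb$patient[col]
    expect_equal(unname(pb$counts[, col]), unname(rowSums(counts[, sel, drop = FALSE])))
    expect_equal(pb$n_cells[col], sum(sel))
  }
  expect_equal(ncol(pb$counts), length(unique(paste(ct, pt))))
})

test_that("pseudobulk rejects missing labels and negative counts", {
  counts <- matrix(1, 2, 3, dimnames = list(c("a", "b"), c("c1", "c2", "c3")))
  expect_error(make_pb(counts, c("epi", NA, "epi"), rep("P1", 3)), "missing labels")
  expect_error(make_pb(counts, c("epi", "epi"), rep("P1", 3)), "one label per cell")
  counts[1, 1] <- -1
  expect_error(make_pb(counts, rep("epi", 3), rep("P1", 3)), "non-negative")
})

# Build a pseudobulk with a planted epithelial-specific gene (high counts in
# epithelial for every patient) and controlled rivals.
planted_pb <- function(n_pat = 5, epi_count = 100, rival_count = 2,
                       flip_patient = NULL) {
  types <- c("epithelial", "stroma", "myeloid")
  cells <- expand.grid(type = types, pat = paste0("P", seq_len(n_pat)),
                       stringsAsFactors = FALSE)
  set.seed(11)
  base <- matrix(rpois(20 * nrow(cells), 30), nrow = 20,
                 dimnames = list(paste0("g", 1:20), NULL))
  colnames(base) <- paste0("c", seq_len(ncol(base)))
  g1 <- ifelse(cells$type == "epithelial", epi_count, rival_count)
  if (!is.null(flip_patient))
    g1[cells$type == "epithelial" & cells$pat == flip_patient] <- 0
  base[1, ] <- g1
  pseudobulk_aggregate(base, cells$type, cells$pat)
}

test_that("a gene dominant in epithelium across all patients is epithelial-specific", {
  pb <- planted_pb()
  calls <- classify_specificity(pb)
  expect_identical(calls$class[calls$gene == "g1"], "specific-to:epithelial")
  expect_true(calls$margin[calls$gene == "g1"] >= 1)
  expect_lt(calls$max_p[calls$gene == "g1"], 0.01)
})

test_that("equal counts in two cell types fail the margin rule", {
  pb <- planted_pb(epi_count = 50, rival_count = 50)
  calls <- classify_specificity(pb)
  expect_identical(calls$class[calls$gene == "g1"], "non-specific")
})

test_that("one discordant patient breaks specificity via the pairwise p-value", {
  pb <- planted_pb(flip_patient = "P3")
  # recompute every pairwise Welch p as an oracle: the epithelial vs rival
  # comparison must now carry at least one p >= 0.01
  counts <- pb$counts
  lcpm <- log1p(sweep(counts, 2, colSums(counts) / 1e6, "/"))
  epi <- lcpm["g1", pb$cell_type == "epithelial"]
  ps <- vapply(c("stroma", "myeloid"), function(r)
    stats::t.test(epi, lcpm["g1", pb$cell_type == r])$p.value, numeric(1))
  calls <- classify_specificity(pb)
  if (max(ps) >= 0.01)
    expect_identical(calls$class[calls$gene == "g1"], "non-specific")
  expect_gte(max(ps), 0.01)
})

test_that("specificity is invariant to gene and patient-column order and single-labelled", {
  sim <- simulate_single_cell(sc_sim_config(n_patients = 3,
                                            cells_per_patient = 150,
                                            n_genes = 600, block_size = 40,
                                            stem_block_size = 20,
                                            lowq_fraction = 0), seed = 5)
  pb <- pseudobulk_aggregate(sim$counts, sim$cells$cell_type,
                             sim$cells$patient)
  calls <- classify_specificity(pb)
  # permute genes
  set.seed(9)
  perm <- sample(nrow(pb$counts))
  pb_g <- pb; pb_g$counts <- pb$counts[perm, ]
  calls_g <- classify_specificity(pb_g)
  expect_equal(calls_g[order(calls_g$gene), ], calls[order(calls$gene), ],
               ignore_attr = TRUE)
  # permute pseudobulk columns
  cperm <- sample(ncol(pb$counts))
  pb_c <- pb
  pb_c$counts <- pb$counts[, cperm]
  pb_c$cell_type <- pb$cell_type[cperm]
  pb_c$patient <- pb$patient[cperm]
  calls_c <- classify_specificity(pb_c)
  expect_equal(calls_c, calls, ignore_attr = TRUE)
  # at most one specific-to label per gene by construction of the rule
  expect_true(all(table(calls$gene) == 1))
})

test_that("specificity testing requires patient replication", {
  counts <- matrix(rpois(40, 20), 10, 4,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  pb <- pseudobulk_aggregate(counts, rep(c("epi", "str"), 2), rep("P1", 4))
  expect_error(classify_specificity(pb), "relax")
})

test_that("refinement keeps planted epithelial genes and drops stromal ones", {
  sim <- simulate_single_cell(seed = 3)
  pb <- pseudobulk_aggregate(sim$counts, sim$cells$cell_type,
                             sim$cells$patient)
  gt <- sim$genes
  epi <- head(gt$gene[gt$block == "epithelial"], 10)
  str <- head(gt$gene[gt$block == "stromal_block"], 5)
  sig <- gene_signature("draft", c(epi, str))
  out <- refine_signature(sig, pb)
  expect_identical(out$genes, epi)
})

test_that("refinement output is a subset, idempotent, and order-preserving", {
  sim <- simulate_single_cell(seed = 4)
  pb <- pseudobulk_aggregate(sim$counts, sim$cells$cell_type,
                             sim$cells$patient)
  gt <- sim$genes
  set.seed(21)
  sig <- gene_signature("draft",
                        sample(c(sample(gt$gene[gt$block == "epithelial"], 20),
                                 sample(gt$gene[gt$block == "stromal_block"], 10),
                                 sample(gt$gene[gt$block == "background"], 10))))
  out <- refine_signature(sig, pb)
  expect_true(all(out$genes %in% sig$genes))
  expect_identical(out$genes, sig$genes[sig$genes %in% out$genes])
  again <- refine_signature(out, pb)
  expect_identical(again$genes, out$genes)
})

test_that("a signature of constant genes refines to nothing, with a warning", {
  counts <- matrix(50, 6, 8,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:8)))
  pb <- pseudobulk_aggregate(counts, rep(c("epithelial", "stroma"), 4),
                             rep(paste0("P", 1:2), each = 4))
  sig <- gene_signature("flat", paste0("g", 1:6))
  expect_warning(out <- refine_signature(sig, pb), "empty")
  expect_length(out$genes, 0)
})

test_that("refinement needs at least 3 signature genes present", {
  counts <- matrix(rpois(80, 20), 10, 8,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:8)))
  pb <- pseudobulk_aggregate(counts, rep(c("epithelial", "stroma"), 4),
                             rep(paste0("P", 1:2), each = 4))
  sig <- gene_signature("tiny", c("g1", "g2", "absentA", "absentB"))
  expect_error(suppressWarnings(refine_signature(sig, pb)), "fewer than 3")
})
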