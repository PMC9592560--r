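#!/usr/bin/env Rscript
# Single-cell analysis: simulate a 5-patient epithelial-and-stroma cohort,
# apply QC gates, score every cell for the CBC and RSC signatures (mean
# logcounts over marker genes), fix positivity cutoffs at the 95th
# percentile, classify cells into CBC / RSC / mixed / negative, and refine
# a draft signature by pseudobulk cell-type specificity.
#
# Outputs under results/: cells table, cutoffs, specificity calls, refined
# signature GMT.

library(stemindex)

seed <- 20260924
dir.create("results", showWarnings = FALSE)

message("Simulating 2000 cells across 5 patients ...")
sim <- simulate_single_cell(seed = seed)
qc <- qc_filter(cbind(sim$cells,
                      cell_qc_metrics(sim$counts, sim$cells$patient)[, -(1:2)]))
message(sprintf("QC: %d/%d cells pass (>1000 UMI, <30%% mito, 2000-6000 genes)",
                sum(qc$qc_pass), nrow(qc)))

keep <- qc$qc_pass
lc <- sc_logcounts(sim$counts[, keep])
gt <- sim$genes
cbc_sig <- gene_signature("CBC", gt$gene[gt$block == "cbc_marker"])
rsc_sig <- gene_signature("RSC", gt$gene[gt$block == "rsc_marker"])

cells <- qc[keep, ]
cells$cbc_value <- cell_signature_value(lc, cbc_sig)
cells$rsc_value <- cell_signature_value(lc, rsc_sig)
cbc_cut <- derive_cutoffs(cells$cbc_value)   # 95th percentile, 0.05 rounding
rsc_cut <- derive_cutoffs(cells$rsc_value)
message(sprintf("Cutoffs (rounded to 0.05 logcounts): CBC %.2f, RSC %.2f",
                cbc_cut, rsc_cut))
cells <- classify_cells(cells, cbc_cut, rsc_cut)
print(table(truth = cells$population, call = cells$class))

utils::write.table(cells, "results/02_cells.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
jsonlite::write_json(list(cbc_cutoff = cbc_cut, rsc_cutoff = rsc_cut,
                          percentile = 95, rounding_step = 0.05),
                     "results/02_cutoffs.json", auto_unbox = TRUE)

message("Pseudobulk specificity classification and signature refinement ...")
pb <- pseudobulk_aggregate(sim$counts[, keep], sim$cells$cell_type[keep],
                           sim$cells$patient[keep])
calls <- classify_specificity(pb)
utils::write.table(calls, "results/02_specificity_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

set.seed(seed)
draft <- gene_signature(
  "RSC_draft",
  c(sample(gt$gene[gt$block == "epithelial"], 30),
    sample(gt$gene[gt$block == "stromal_block"], 15),
    sample(gt$gene[gt$block == "background"], 15)),
  provenance = "synthetic draft: epithelial + stromal + flat planted genes")
refined <- refine_signature(draft, pb)
message(sprintf("Refinement: %d/%d draft genes retained (%d planted epithelial)",
                length(refined$genes), length(draft$genes),
                sum(refined$genes %in% gt$gene[gt$block == "epithelial"])))
write_gmt(list(draft, refined), "results/02_signatures.gmt")
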