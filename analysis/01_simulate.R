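#!/usr/bin/env Rscript
# Step 1: generate the synthetic study with known ground truth.
#
# One 4 Mb chromosome ("chrS", 20,000 x 200 bp bins) carrying three hidden
# chromatin states (active A, bivalent M, silent S), five histone-mark
# tracks plus WGBS-style per-CpG methylation; 500 gene models placed on the
# state track; a ~300-cell islet scRNA-seq experiment with five sub-types
# (two dedifferentiated, disease-enriched); and a 62-donor bulk cohort with
# an HbA1c-like trait. Everything downstream reads these files.

suppressMessages(library(epistate))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- sim_spec(n_bins = 20000, seed = 20180605)
st <- simulate_state_track(spec)
tr <- simulate_tracks(st, spec)
message("state occupancy: ", paste(table(st), collapse = " / "))

for (m in colnames(tr$counts))
  write_bedgraph(tr$counts[, m], tr$bins, file.path(out, paste0(m, ".bedGraph")))
write_cpg_tsv(tr$cpg, file.path(out, "cpg_methylation.tsv"))
message(nrow(tr$cpg), " CpGs written (",
        round(nrow(tr$cpg) / (spec$n_bins * spec$bin_size / 50)), "x the 1/50bp target)")

gm <- simulate_gene_models(st, 500, seed = 20180606)
write_gtf(gm$genes, file.path(out, "genes.gtf"))
write.table(cbind(gm$truth, start = gm$genes$start, end = gm$genes$end),
            file.path(out, "gene_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(gm$genes), " genes placed, ",
        sum(gm$truth$homogeneous), " in state-homogeneous runs")

cells <- simulate_cells(gm$truth, spec)
write_umi_mtx(cells$counts, file.path(out, "umi"))
write.table(data.frame(cell = rownames(cells$counts), cluster = cells$cluster,
                       condition = cells$condition),
            file.path(out, "cell_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(cells$identity_genes, file.path(out, "identity_genes.txt"))
writeLines(cells$bivalent_genes, file.path(out, "bivalent_genes.txt"))
message(nrow(cells$counts), " cells (",
        sum(cells$condition == "HFD"), " HFD / ",
        sum(cells$condition == "Ctrl"), " Ctrl)")

coh <- simulate_cohort(gm$truth, spec)
cohort <- data.frame(sample = rownames(coh$expr), trait = coh$trait,
                     coh$expr, check.names = FALSE)
write.table(cohort, file.path(out, "cohort_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(cohort), " cohort samples, ",
        sum(coh$trait > 6.5), " in the diabetic trait range")

writeLines(as.character(st), file.path(out, "state_truth.txt"))
message("synthetic study written to ", out)
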