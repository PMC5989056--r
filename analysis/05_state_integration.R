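#!/usr/bin/env Rscript
# Step 5: the chromatin-state x transcriptome intersection.
#
# Stratifies single-cell expression statistics by chromatin state (CV
# across gene means per cluster; disease-vs-control differences), maps
# states onto the cohort's genes through a 1:1 ortholog table, regresses
# cohort expression on the glycemic trait per state, and counts
# differential genes at the volcano thresholds.

suppressMessages(library(epistate))
dat <- "results/data"
out <- "results"
lab_levels <- c("A", "M", "S")

umi <- read_umi_mtx(file.path(dat, "umi"))
truth <- read.table(file.path(dat, "cell_truth.tsv"), header = TRUE)
norm <- suppressMessages(downsample_cells(umi, target = 5000, seed = 4))
truth <- truth[match(rownames(norm), truth$cell), ]
gs <- read.table(file.path(out, "gene_states.tsv"), header = TRUE)

cv <- state_cluster_cv(norm, truth$cluster, gs)
cv$label <- lab_levels[cv$state]
write.table(cv, file.path(out, "state_cluster_cv.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
biv_cv <- cv[cv$label == "M", ]
message("bivalent-state CV across clusters: ",
        paste(round(biv_cv$cv, 2), collapse = " "))

cd <- state_condition_diff(norm, truth$cluster, truth$condition, gs)
cd$label <- lab_levels[cd$state]
write.table(cd, file.path(out, "state_condition_diff.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
m3 <- cd[cd$label == "M" & cd$cluster == 3, "diff"]
message("HFD-Ctrl bivalent-gene difference in the mixed cluster 3: ",
        round(m3, 3), " (log1p scale)")

# cohort: transfer gene states via 1:1 orthologs, regress on the trait
cohort <- read.table(file.path(dat, "cohort_expression.tsv"), header = TRUE,
                     check.names = FALSE)
expr <- as.matrix(cohort[, -(1:2)])
rownames(expr) <- cohort$sample
ortho <- data.frame(mouse = gs$gene_id, human = gs$gene_id)
gs_h <- map_orthologs(ortho, gs)
state_of <- setNames(gs_h$genebody_state, gs_h$gene_id)
common <- intersect(colnames(expr), names(state_of))
reg <- state_trait_regression(expr[, common], cohort$trait, state_of[common])
reg$label <- lab_levels[reg$state]
print(reg, digits = 3)
write.table(reg, file.path(out, "state_trait_regression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("states with q < 0.05: ",
        paste(reg$label[reg$q < 0.05], collapse = ", "))

# two-group DE table (diabetic vs normal trait range) and volcano counts
hi <- cohort$trait > 6.5
lo <- cohort$trait < 6.0
lfc <- (colMeans(expr[hi, ]) - colMeans(expr[lo, ])) / log(2)
pv <- vapply(seq_len(ncol(expr)), function(g)
  t.test(expr[hi, g], expr[lo, g])$p.value, numeric(1))
de <- data.frame(gene_id = colnames(expr), log2FC = lfc,
                 p = pv, padj = p.adjust(pv, "BH"))
write.table(de, file.path(out, "cohort_de.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ud <- count_up_down(de)
message("cohort DE at padj<0.05, |FC|>2: ", ud["n_up"], " up / ",
        ud["n_down"], " down (upregulation-biased, as in disease)")

marked <- gs$gene_id[gs$genebody_label == "M"]
shift <- marked_vs_unmarked_change(de, marked)
message("Polycomb-marked vs unmarked median log2FC shift: ",
        round(shift$shift, 2), " (rank-sum p = ", signif(shift$p, 2), ")")
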