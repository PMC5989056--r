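#!/usr/bin/env Rscript
# Step 6: pseudotemporal ordering and SOM co-expression modules.
#
# Orders cells along the maturity-to-dedifferentiation cluster chain by
# their projection coordinates between cluster medoids, filters genes to
# those with >= 3 transcripts in some cell, z-scores the pseudotime
# profiles, fits a 1D self-organizing map, and merges correlated
# neighboring nodes into co-expression modules (retaining modules with
# more than 5 member profiles).

suppressMessages(library(epistate))
dat <- "results/data"
out <- "results"

umi <- read_umi_mtx(file.path(dat, "umi"))
truth <- read.table(file.path(dat, "cell_truth.tsv"), header = TRUE)
norm <- suppressMessages(downsample_cells(umi, target = 5000, seed = 4))
truth <- truth[match(rownames(norm), truth$cell), ]
d <- spearman_distance(norm)

chain <- c(2, 3, 4, 5)
ord <- order_cells_on_chain(d, truth$cluster, chain, n_perm = 1000, seed = 6)
print(ord$links, digits = 3)
write.table(ord$ordering, file.path(out, "pseudotime_ordering.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(ord$ordering), " cells ordered along chain ",
        paste(chain, collapse = "-"), "; ",
        sum(ord$links$significant), "/", nrow(ord$links),
        " links significant at p < 0.05")

filt <- filter_min_transcripts(norm[ord$ordering$cell, , drop = FALSE], 3)
message(ncol(filt), " genes pass the >=3-transcript filter")
z <- suppressWarnings(zscore_pseudotime_profiles(filt, seq_len(nrow(filt))))
som <- fit_som1d(z, n_nodes = max(20L, nrow(z) %/% 10L), seed = 7)
ms <- merge_som_modules(som, z)
write.table(ms$modules, file.path(out, "som_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ms$summary, file.path(out, "som_module_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(ms$summary), " modules retained (strict >5-profile rule); sizes: ",
        paste(ms$summary$n_profiles, collapse = ", "))

# where do the planted programs end up?
biv <- readLines(file.path(dat, "bivalent_genes.txt"))
ident <- readLines(file.path(dat, "identity_genes.txt"))
mod_biv <- unique(ms$modules$module[ms$modules$gene %in% biv])
mod_id <- unique(ms$modules$module[ms$modules$gene %in% ident])
message("bivalent (rising) program in module(s) ",
        paste(mod_biv, collapse = ","), "; identity (falling) program in ",
        paste(mod_id, collapse = ","),
        if (length(intersect(mod_biv, mod_id)) == 0)
          " - the programs separate cleanly" else " - programs overlap")
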