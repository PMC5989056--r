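#' Coefficient of variation of gene means, per state and cluster
#'
#' For each chromatin state s and cell cluster c: every state-s gene's mean
#' normalized expression over the cells of c is computed, genes with zero
#' mean in that cluster are excluded (counted in the `n_excluded` column),
#' and the CV (sample sd / mean) is taken across the remaining gene means.
#' States with fewer than two expressed genes in a cluster give `NA`.
#'
#' @param mat cells x genes normalized matrix.
#' @param clusters integer cluster labels per cell.
#' @param gene_states data.frame with `gene_id` and `genebody_state` (as
#'   from [assign_gene_states()]).
#' @return data.frame: `state`, `cluster`, `cv`, `n_genes`, `n_excluded`.
#' @export
state_cluster_cv <- function(mat, clusters, gene_states) {
  gs <- gene_states[gene_states$gene_id %in% colnames(mat), , drop = FALSE]
  states <- sort(unique(gs$genebody_state))
  cls <- sort(unique(clusters))
  rows <- list()
  for (s in states) {
    genes <- gs$gene_id[gs$genebody_state == s]
    for (cl in cls) {
      sub <- mat[clusters == cl, genes, drop = FALSE]
      gmeans <- colMeans(sub)
      keep <- gmeans > 0
      cv <- if (sum(keep) >= 2) sd(gmeans[keep]) / mean(gmeans[keep]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        state = s, cluster = cl, cv = cv,
        n_genes = sum(keep), n_excluded = sum(!keep))
    }
  }
  do.call(rbind, rows)
}

#' Disease-vs-control expression difference, per state and cluster
#'
#' Within each cluster, per state: the mean over state genes of (mean
#' log1p expression in disease-condition cells) minus (mean in control
#' cells). Clusters lacking one of the two conditions give `NA`.
#'
#' @param mat cells x genes normalized matrix.
#' @param clusters integer cluster labels.
#' @param condition per-cell condition labels.
#' @param gene_states data.frame with `gene_id`, `genebody_state`.
#' @param disease,control the two condition labels (defaults "HFD",
#'   "Ctrl").
#' @return data.frame: `state`, `cluster`, `diff`, `n_disease`,
#'   `n_control`.
#' @export
state_condition_diff <- function(mat, clusters, condition, gene_states,
                                 disease = "HFD", control = "Ctrl") {
  lmat <- log1p(mat)
  gs <- gene_states[gene_states$gene_id %in% colnames(mat), , drop = FALSE]
  states <- sort(unique(gs$genebody_state))
  cls <- sort(unique(clusters))
  rows <- list()
  for (s in states) {
    genes <- gs$gene_id[gs$genebody_state == s]
    for (cl in cls) {
      in_cl <- clusters == cl
      nd <- sum(in_cl & condition == disease)
      nc <- sum(in_cl & condition == control)
      d <- if (nd > 0 && nc > 0) {
        md <- colMeans(lmat[in_cl & condition == disease, genes, drop = FALSE])
        mc <- colMeans(lmat[in_cl & condition == control, genes, drop = FALSE])
        mean(md - mc)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        state = s, cluster = cl, diff = d, n_disease = nd, n_control = nc)
    }
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$diff))
    message(sum(is.na(out$diff)), " state x cluster cell(s) lacked one condition")
  out
}

#' Transfer chromatin-state labels across species via 1:1 orthologs
#'
#' State labels move along the ortholog mapping only where both the source
#' and the target gene appear exactly once (1:many and many:many pairs are
#' dropped, with the count reported in the `n_dropped` attribute).
#'
#' @param mapping 2-column data.frame: source gene id, target gene id.
#' @param gene_states data.frame keyed by source `gene_id` with
#'   `genebody_state` (and any other columns to carry over).
#' @return `gene_states`-like data.frame keyed by target gene id.
#' @export
map_orthologs <- function(mapping, gene_states) {
  if (nrow(mapping) == 0) stop("empty ortholog mapping")
  src <- mapping[[1]]; tgt <- mapping[[2]]
  one2one <- !(src %in% src[duplicated(src)]) & !(tgt %in% tgt[duplicated(tgt)])
  n_dropped <- sum(!one2one)
  m <- mapping[one2one, , drop = FALSE]
  idx <- match(m[[1]], gene_states$gene_id)
  ok <- !is.na(idx)
  out <- gene_states[idx[ok], , drop = FALSE]
  out$gene_id <- m[[2]][ok]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-state linear regression of expression on a continuous trait
#'
#' Each gene's OLS slope of expression on the trait is computed; each
#' state's summary slope is the median of its member-gene slopes, with a
#' two-sided one-sample t test of the member slopes against zero and
#' Benjamini-Hochberg correction across states. States with fewer than 3
#' genes are skipped with a warning.
#'
#' @param expr samples x genes expression matrix.
#' @param trait numeric per-sample covariate (HbA1c-like).
#' @param state per-gene state labels (named by gene, or aligned to
#'   `colnames(expr)`).
#' @return data.frame: `state`, `n_genes`, `slope` (median member slope),
#'   `p`, `q` (BH-adjusted).
#' @export
state_trait_regression <- function(expr, trait, state) {
  stopifnot(nrow(expr) >= 4)
  if (var(trait) == 0) stop("trait does not vary")
  if (!is.null(names(state))) state <- state[colnames(expr)]
  stopifnot(length(state) == ncol(expr))
  tc <- trait - mean(trait)
  slopes <- as.vector(crossprod(tc, scale(expr, scale = FALSE))) / sum(tc^2)
  names(slopes) <- colnames(expr)
  out <- list()
  for (s in sort(unique(state))) {
    sl <- slopes[state == s]
    if (length(sl) < 3) {
      warning("state ", s, " has fewer than 3 genes; skipped")
      next
    }
    p <- if (sd(sl) < 1e-12) {
      # degenerate: all member slopes identical (e.g. noiseless data)
      as.numeric(median(sl) == 0)
    } else {
      t.test(sl, mu = 0)$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      state = s, n_genes = length(sl), slope = median(sl), p = p)
  }
  res <- do.call(rbind, out)
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Count significantly up- and downregulated genes
#'
#' Strict thresholds on an externally computed differential-expression
#' table: up = adjusted p strictly below `p_threshold` and fold change
#' strictly above `fc_threshold`; down analogously below
#' `1/fc_threshold`. Genes exactly at a boundary are excluded.
#'
#' @param de data.frame with `log2FC` and `padj` columns.
#' @param p_threshold adjusted-p cutoff (default 0.05).
#' @param fc_threshold fold-change cutoff (default 2).
#' @return named integer vector `c(n_up, n_down)`.
#' @export
count_up_down <- function(de, p_threshold = 0.05, fc_threshold = 2.0) {
  if (!all(c("log2FC", "padj") %in% names(de)))
    stop("DE table must have log2FC and padj columns")
  lfc <- log2(fc_threshold)
  sig <- !is.na(de$padj) & de$padj < p_threshold
  c(n_up = sum(sig & de$log2FC > lfc),
    n_down = sum(sig & de$log2FC < -lfc))
}

#' Fold-change shift between marked and unmarked genes
#'
#' Compares the log2 fold-change distributions of genes carrying a
#' chromatin mark (e.g. H3K27me3 in healthy tissue) against all other
#' genes: per-group medians, their difference, and a two-sided
#' Wilcoxon rank-sum p value.
#'
#' @param de data.frame with `gene_id` and `log2FC`.
#' @param marked_set gene ids in the marked group.
#' @return list: `median_marked`, `median_unmarked`, `shift`, `p`.
#' @export
marked_vs_unmarked_change <- function(de, marked_set) {
  marked <- de$log2FC[de$gene_id %in% marked_set]
  unmarked <- de$log2FC[!(de$gene_id %in% marked_set)]
  if (length(marked) == 0 || length(unmarked) == 0)
    stop("both marked and unmarked groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(marked, unmarked))
  list(median_marked = median(marked), median_unmarked = median(unmarked),
       shift = median(marked) - median(unmarked), p = wt$p.value)
}
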