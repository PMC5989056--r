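#' Downsampling normalization of a UMI matrix
#'
#' Every retained cell is subsampled without replacement (multivariate
#' hypergeometric) to exactly `target` total transcripts; cells with fewer
#' than `target` transcripts are removed. Equal totals make per-cell
#' statistics such as entropy directly comparable.
#'
#' @param mat cells x genes integer UMI matrix (rownames = cells).
#' @param target total transcripts per cell after normalization
#'   (default 5000).
#' @param seed RNG seed.
#' @return cells x genes matrix with every row summing to `target`;
#'   attribute `dropped` lists removed cells.
#' @export
downsample_cells <- function(mat, target = 5000L, seed = 1L) {
  stopifnot(target > 0)
  totals <- rowSums(mat)
  keep <- totals >= target
  if (!any(keep)) stop("all cells fall below the downsampling target")
  dropped <- rownames(mat)[!keep]
  if (length(dropped) > 0)
    message(length(dropped), " cell(s) below ", target, " transcripts removed")
  mat <- mat[keep, , drop = FALSE]
  set.seed(seed)
  G <- ncol(mat)
  out <- matrix(0L, nrow(mat), G, dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    tot <- sum(mat[i, ])
    if (tot == target) { out[i, ] <- mat[i, ]; next }
    picked <- sample.int(tot, target)
    # map sampled transcript indices back to genes via cumulative counts
    gene_of <- findInterval(picked - 1L, cumsum(mat[i, ]), left.open = FALSE) + 1L
    out[i, ] <- tabulate(gene_of, nbins = G)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Spearman-correlation distance between cells
#'
#' `d(i, j) = 1 - rho_Spearman(cell_i, cell_j)` over the gene subset, with
#' average ranks for ties. A constant cell has undefined correlation; its
#' distances are set to 1 with a warning.
#'
#' @param mat cells x genes normalized matrix.
#' @param gene_subset optional gene names/indices to restrict to.
#' @return symmetric cells x cells distance matrix with zero diagonal.
#' @export
spearman_distance <- function(mat, gene_subset = NULL) {
  stopifnot(nrow(mat) >= 2)
  if (!is.null(gene_subset)) mat <- mat[, gene_subset, drop = FALSE]
  rho <- suppressWarnings(cor(t(mat), method = "spearman"))
  if (anyNA(rho)) {
    warning("constant cell vector(s): undefined correlations set to distance 1")
    rho[is.na(rho)] <- 0
  }
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' K-medoids clustering of a cell distance matrix
#'
#' Partitioning around medoids (PAM: greedy BUILD then SWAP until the total
#' within-cluster distance stops decreasing), delegated to
#' [cluster::pam()], which is deterministic for a given distance matrix.
#'
#' @param dist symmetric distance matrix.
#' @param k number of clusters.
#' @param seed kept for interface stability; PAM itself is deterministic.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (integer per cell), `medoids` (cell indices), `objective`, `k`.
#' @export
cluster_kmedoids <- function(dist, k, seed = 1L) {
  n <- nrow(dist)
  if (k > n) stop("k exceeds the number of cells")
  fit <- cluster::pam(as.dist(dist), k = k, diss = TRUE)
  structure(list(cluster = as.integer(fit$clustering),
                 medoids = as.integer(fit$id.med),
                 objective = unname(fit$objective["swap"]),
                 k = k),
            class = "cluster_assignment")
}

#' Choose the cluster number by bootstrap Jaccard stability
#'
#' For each candidate k, cells are bootstrapped with replacement `n_boot`
#' times, the bootstrap sample is reclustered, bootstrap clusters are
#' matched to the reference clusters by maximal overlap, and each reference
#' cluster's mean Jaccard similarity across bootstraps is recorded. The
#' chosen k is the minimum k for which every cluster's mean Jaccard exceeds
#' `threshold`; if no k qualifies, the k maximizing the minimum Jaccard is
#' returned (documented fallback).
#'
#' @param dist distance matrix.
#' @param k_range candidate cluster numbers (within `[2, n_cells - 1]`).
#' @param n_boot bootstrap iterations per k (default 50).
#' @param threshold Jaccard stability threshold (default 0.6).
#' @param seed RNG seed.
#' @return list: `k` (chosen), `jaccard` (data.frame of per-k per-cluster
#'   mean Jaccard), `qualified` (logical per k).
#' @export
select_cluster_number <- function(dist, k_range, n_boot = 50L,
                                  threshold = 0.6, seed = 1L) {
  n <- nrow(dist)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1), n_boot >= 10)
  if (all(dist == 0)) stop("degenerate distance matrix (all zeros)")
  set.seed(seed)
  rows <- list()
  min_jac <- setNames(numeric(length(k_range)), k_range)
  all_pass <- setNames(logical(length(k_range)), k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    ref <- cluster_kmedoids(dist, k)$cluster
    jac_acc <- matrix(NA_real_, n_boot, k)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      uidx <- unique(idx)
      boot_cl <- cluster_kmedoids(dist[uidx, uidx, drop = FALSE], k)$cluster
      # match bootstrap clusters to reference clusters by maximal overlap
      ref_sets <- split(uidx, ref[uidx])
      boot_sets <- split(uidx, boot_cl)
      jac_acc[b, ] <- matched_jaccard(ref_sets, boot_sets, k)
    }
    mj <- colMeans(jac_acc, na.rm = TRUE)
    rows[[ki]] <- data.frame(k = k, cluster = seq_len(k), jaccard = mj)
    min_jac[ki] <- min(mj)
    all_pass[ki] <- all(mj > threshold)
  }
  chosen <- if (any(all_pass)) min(k_range[all_pass])
            else k_range[which.max(min_jac)]
  list(k = chosen, jaccard = do.call(rbind, rows), qualified = all_pass)
}

# per-reference-cluster Jaccard after optimal (max-total-overlap) matching
matched_jaccard <- function(ref_sets, boot_sets, k) {
  labs_r <- names(ref_sets)
  labs_b <- names(boot_sets)
  ov <- matrix(0, length(labs_r), length(labs_b))
  for (i in seq_along(labs_r))
    for (j in seq_along(labs_b))
      ov[i, j] <- length(intersect(ref_sets[[i]], boot_sets[[j]]))
  out <- rep(NA_real_, k)
  nm <- max(length(labs_r), length(labs_b))
  if (nm <= 8L) {
    sq <- matrix(0, nm, nm)
    sq[seq_along(labs_r), seq_along(labs_b)] <- ov
    perms <- permutations(nm)
    scores <- vapply(seq_len(nrow(perms)), function(p)
      sum(sq[cbind(seq_len(nm), perms[p, ])]), numeric(1))
    best <- perms[which.max(scores), ]
    for (i in seq_along(labs_r)) {
      j <- best[i]
      if (j <= length(labs_b))
        out[as.integer(labs_r[i])] <-
          jaccard(ref_sets[[i]], boot_sets[[j]])
    }
  } else {
    m <- ov
    repeat {
      if (max(m) < 0) break
      idx <- which(m == max(m), arr.ind = TRUE)[1, ]
      out[as.integer(labs_r[idx[1]])] <-
        jaccard(ref_sets[[idx[1]]], boot_sets[[idx[2]]])
      m[idx[1], ] <- -1; m[, idx[2]] <- -1
    }
  }
  out
}

#' Per-cell transcriptome entropy
#'
#' Shannon entropy of each cell's transcript-fraction distribution over its
#' nonzero genes, in nats: `-sum(p * ln p)`. High entropy indicates an
#' unfocused, progenitor-like transcriptome; terminally differentiated
#' cells concentrate transcripts in few genes and score low. Requires a
#' normalized matrix (equal totals) for cross-cell comparability.
#'
#' @param mat cells x genes normalized matrix.
#' @param clusters optional integer cluster labels; adds per-cluster
#'   medians.
#' @return list: `entropy` (per cell), `cluster_median` (named vector, when
#'   labels supplied).
#' @export
cell_entropy <- function(mat, clusters = NULL) {
  totals <- rowSums(mat)
  if (any(totals == 0)) stop("all-zero cell: entropy undefined")
  ent <- apply(mat, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  out <- list(entropy = ent)
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == nrow(mat))
    md <- tapply(ent, clusters, median)
    out$cluster_median <- setNames(as.vector(md), names(md))
  }
  out
}

#' Geneset mean expression per cell and cluster
#'
#' Per-cell mean normalized expression over a geneset; cluster value = mean
#' of its cells; relative value = cluster mean / grand mean over all cells
#' (so 1 means "at the dataset average").
#'
#' @param mat cells x genes normalized matrix.
#' @param clusters integer cluster labels per cell.
#' @param geneset gene names.
#' @param relative return cluster means divided by the grand mean.
#' @return list: `cell` (per-cell means), `cluster` (per-cluster means,
#'   relative if requested).
#' @export
geneset_cluster_means <- function(mat, clusters, geneset, relative = TRUE) {
  genes <- intersect(geneset, colnames(mat))
  if (length(genes) == 0) stop("geneset does not intersect the matrix genes")
  cellv <- rowMeans(mat[, genes, drop = FALSE])
  cl <- tapply(cellv, clusters, mean)
  clmeans <- setNames(as.vector(cl), names(cl))
  if (relative) clmeans <- clmeans / mean(cellv)
  list(cell = cellv, cluster = clmeans)
}
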