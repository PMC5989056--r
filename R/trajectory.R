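#' Pseudotemporal ordering of cells along a cluster chain
#'
#' Cells of each chain cluster are projected onto the link between their
#' cluster medoid and the adjacent chain medoid. The scalar projection is
#' computed directly from the distance matrix by the law of cosines:
#' `t = (d(i,a)^2 + d(a,b)^2 - d(i,b)^2) / (2 d(a,b)^2)`, clipped to
#' `[0, 1]`, where a is the cell's own medoid and b the next medoid on the
#' chain. Cells are ordered by chain position, then coordinate. Link
#' significance uses a permutation test: the observed number of cells whose
#' nearest inter-medoid segment is the link is compared against `n_perm`
#' shuffles of the cells' cluster labels (medoids recomputed per shuffle);
#' links failing `p_threshold` are flagged.
#'
#' @param dist cells x cells distance matrix.
#' @param clusters a `cluster_assignment` from [cluster_kmedoids()], or an
#'   integer label vector (medoids then recomputed from `dist`).
#' @param chain integer sequence of cluster labels, e.g. `c(1, 2, 3, 4)`.
#' @param p_threshold link significance threshold (default 0.05).
#' @param n_perm permutations for link significance (default 1000).
#' @param seed RNG seed.
#' @return object of class `pseudotime_ordering`: data.frame `ordering`
#'   (`cell`, `cluster`, `link`, `coord` in `[0, 1]`) in pseudotemporal order,
#'   and `links` (`from`, `to`, `n_cells`, `p`, `significant`).
#' @export
order_cells_on_chain <- function(dist, clusters, chain, p_threshold = 0.05,
                                 n_perm = 1000L, seed = 1L) {
  if (inherits(clusters, "cluster_assignment")) {
    medoids <- clusters$medoids
    labels <- clusters$cluster
  } else {
    labels <- clusters
    medoids <- compute_medoids(dist, labels)
  }
  if (any(!(chain %in% labels))) stop("chain references an unknown cluster")
  if (any(chain[-1] == chain[-length(chain)]))
    stop("consecutive chain clusters must be distinct")
  med_of <- setNames(medoids, sort(unique(labels)))
  n_links <- length(chain) - 1L
  proj <- function(i, a, b) {
    dab2 <- dist[a, b]^2
    if (dab2 == 0) return(0)
    (dist[i, a]^2 + dab2 - dist[i, b]^2) / (2 * dab2)
  }
  rows <- list()
  for (pos in seq_along(chain)) {
    cl <- chain[pos]
    cells <- which(labels == cl)
    a <- med_of[as.character(cl)]
    # project onto the outgoing link; the last cluster projects onto its
    # incoming link (coordinate measured from the previous medoid's end)
    if (pos < length(chain)) {
      b <- med_of[as.character(chain[pos + 1L])]
      link <- pos
      raw <- vapply(cells, proj, numeric(1), a = a, b = b)
    } else {
      b <- med_of[as.character(chain[pos - 1L])]
      link <- pos - 1L
      raw <- 1 - vapply(cells, proj, numeric(1), a = a, b = b)
    }
    rows[[pos]] <- data.frame(cell = cells, cluster = cl, link = link,
                              pos = pos, raw = raw,
                              coord = pmin(pmax(raw, 0), 1))
  }
  ord <- do.call(rbind, rows)
  # sort by the raw (unclipped) projection so cells past a terminal medoid
  # keep their relative order; the reported coordinate is clipped and stays
  # monotone along the output
  ord <- ord[order(ord$pos, ord$raw), c("cell", "cluster", "link", "coord")]
  rownames(ord) <- NULL
  links <- link_significance(dist, labels, chain, med_of, n_perm, seed)
  links$significant <- links$p < p_threshold
  structure(list(ordering = ord, links = links, chain = chain),
            class = "pseudotime_ordering")
}

compute_medoids <- function(dist, labels) {
  vapply(sort(unique(labels)), function(cl) {
    cells <- which(labels == cl)
    cells[which.min(rowSums(dist[cells, cells, drop = FALSE]))]
  }, integer(1))
}

# residual distance of cell i to segment (a, b), law of cosines in the
# distance-embedded space; nearest segment defines the cell's link
nearest_link <- function(dist, chain, med_of) {
  n_links <- length(chain) - 1L
  n <- nrow(dist)
  res <- matrix(Inf, n, n_links)
  for (l in seq_len(n_links)) {
    a <- med_of[as.character(chain[l])]
    b <- med_of[as.character(chain[l + 1L])]
    dab2 <- max(dist[a, b]^2, 1e-300)
    t <- pmin(pmax((dist[, a]^2 + dab2 - dist[, b]^2) / (2 * dab2), 0), 1)
    res[, l] <- pmax(dist[, a]^2 - t^2 * dab2, 0)
  }
  apply(res, 1, which.min)
}

# per-link support: number of cells of the link's two endpoint clusters
# whose nearest inter-medoid segment is that link (the raw nearest-segment
# counts always partition all n cells, so they carry no signal on their own)
link_support <- function(dist, labels, chain, med_of) {
  nl <- nearest_link(dist, chain, med_of)
  vapply(seq_len(length(chain) - 1L), function(l)
    sum(nl == l & labels %in% chain[c(l, l + 1L)]), integer(1))
}

link_significance <- function(dist, labels, chain, med_of, n_perm, seed) {
  # conditional permutation test: the nearest-segment assignment (the
  # observed medoid geometry) stays fixed; only the cells' cluster labels
  # are shuffled, so the null asks whether the cells sitting on a link are
  # enriched for that link's endpoint clusters
  nl <- nearest_link(dist, chain, med_of)
  support <- function(lab) vapply(seq_len(length(chain) - 1L), function(l)
    sum(nl == l & lab %in% chain[c(l, l + 1L)]), integer(1))
  obs <- support(labels)
  set.seed(seed)
  exceed <- integer(length(obs))
  for (p in seq_len(n_perm))
    exceed <- exceed + (support(sample(labels)) >= obs)
  data.frame(from = chain[-length(chain)], to = chain[-1],
             n_cells = obs, p = (exceed + 1) / (n_perm + 1))
}

#' Filter genes by minimum transcript evidence
#'
#' Keeps genes observed with at least `min_count` transcripts in at least
#' one cell (boundary inclusive). Idempotent.
#'
#' @param mat cells x genes count matrix.
#' @param min_count minimum per-cell count (default 3).
#' @return filtered matrix.
#' @export
filter_min_transcripts <- function(mat, min_count = 3L) {
  keep <- apply(mat, 2, max) >= min_count
  if (!any(keep)) stop("filter removed all genes")
  mat[, keep, drop = FALSE]
}

#' Z-score gene profiles along the pseudotime ordering
#'
#' Reorders cells pseudotemporally and z-scores each gene across the
#' ordered cells (mean 0, sample sd 1). Constant genes are dropped with a
#' warning.
#'
#' @param mat cells x genes matrix.
#' @param ordering a `pseudotime_ordering` (or integer cell order).
#' @return genes x ordered-cells z-profile matrix.
#' @export
zscore_pseudotime_profiles <- function(mat, ordering) {
  cells <- if (inherits(ordering, "pseudotime_ordering"))
    ordering$ordering$cell else ordering
  stopifnot(length(cells) >= 2)
  m <- t(mat[cells, , drop = FALSE])         # genes x ordered cells
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  keep <- s > 0
  if (any(!keep))
    warning(sum(!keep), " constant gene profile(s) dropped")
  (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
}

#' Fit a one-dimensional self-organizing map to gene profiles
#'
#' Standard online SOM on a 1D chain of `n_nodes` codebook vectors:
#' profiles are presented in random order, the best-matching node (BMU,
#' minimum Euclidean distance; ties to the lowest node) is updated together
#' with its neighbors under a Gaussian neighborhood whose radius decays
#' linearly from `n_nodes/10` to 1, with learning rate decaying linearly
#' 0.05 to 0.01. Codebooks are initialized by linear interpolation between
#' the profiles at the extremes of the first principal score, which gives
#' the map a topological head start. Deterministic for a fixed seed.
#'
#' @param profiles genes x cells z-profile matrix.
#' @param n_nodes number of SOM nodes (default 1000).
#' @param n_iter training presentations (default `10 * nrow(profiles)`).
#' @param seed RNG seed.
#' @return list: `node` (BMU index per gene, named), `codebook`
#'   (n_nodes x cells matrix), `n_nodes`.
#' @export
fit_som1d <- function(profiles, n_nodes = 1000L, n_iter = NULL, seed = 1L) {
  stopifnot(nrow(profiles) >= 1, n_nodes >= 2)
  if (n_nodes > 2L * nrow(profiles))
    warning("n_nodes exceeds twice the number of profiles; map will be sparse")
  if (is.null(n_iter)) n_iter <- 10L * nrow(profiles)
  set.seed(seed)
  G <- nrow(profiles); P <- ncol(profiles)
  # order-aware init: interpolate between the two most dissimilar profiles
  # along the first principal score
  pc1 <- prcomp(profiles, center = FALSE, rank. = 1)$x[, 1]
  lo <- profiles[which.min(pc1), ]
  hi <- profiles[which.max(pc1), ]
  w <- seq(0, 1, length.out = n_nodes)
  code <- outer(1 - w, lo) + outer(w, hi)
  radius <- seq(max(n_nodes / 10, 1), 1, length.out = n_iter)
  lrate <- seq(0.05, 0.01, length.out = n_iter)
  pick <- sample.int(G, n_iter, replace = TRUE)
  nodes <- seq_len(n_nodes)
  for (it in seq_len(n_iter)) {
    x <- profiles[pick[it], ]
    d2 <- rowSums((code - rep(x, each = n_nodes))^2)
    bmu <- which.min(d2)
    h <- exp(-((nodes - bmu)^2) / (2 * radius[it]^2))
    act <- which(h > 1e-3)
    code[act, ] <- code[act, ] +
      lrate[it] * h[act] * (rep(x, each = length(act)) - code[act, , drop = FALSE])
  }
  d <- as.matrix(stats::dist(rbind(code, profiles)))
  d <- d[(n_nodes + 1):(n_nodes + G), seq_len(n_nodes), drop = FALSE]
  node <- apply(d, 1, which.min)
  names(node) <- rownames(profiles)
  list(node = node, codebook = code, n_nodes = n_nodes)
}

#' Merge neighboring SOM nodes into co-expression modules
#'
#' Scans occupied nodes in topological order and merges a node into the
#' current module when the Pearson correlation between the module's running
#' average profile and the node's average profile exceeds `r_threshold`.
#' Modules with strictly more than `min_size` member profiles are retained.
#'
#' @param som result of [fit_som1d()].
#' @param profiles the genes x cells z-profile matrix the SOM was fitted
#'   on.
#' @param r_threshold Pearson correlation required to merge (default 0.9).
#' @param min_size modules must have more than this many profiles
#'   (default 5, strict).
#' @return object of class `module_set`: data.frame `modules` (`gene`,
#'   `node`, `module`) for retained genes, and `summary` (`module`,
#'   `first_node`, `last_node`, `n_profiles`); `avg_profile` is a matrix of
#'   per-module average z-profiles.
#' @export
merge_som_modules <- function(som, profiles, r_threshold = 0.9,
                              min_size = 5L) {
  node <- som$node
  if (length(node) == 0) stop("empty SOM assignment")
  occupied <- sort(unique(node))
  node_avg <- t(vapply(occupied, function(nd)
    colMeans(profiles[names(node)[node == nd], , drop = FALSE]),
    numeric(ncol(profiles))))
  module_id <- integer(length(occupied))
  cur <- 1L
  module_id[1] <- cur
  run_avg <- node_avg[1, ]
  run_n <- sum(node == occupied[1])
  for (i in seq_along(occupied)[-1]) {
    r <- suppressWarnings(cor(run_avg, node_avg[i, ]))
    n_i <- sum(node == occupied[i])
    if (!is.na(r) && r > r_threshold) {
      module_id[i] <- cur
      run_avg <- (run_avg * run_n + node_avg[i, ] * n_i) / (run_n + n_i)
      run_n <- run_n + n_i
    } else {
      cur <- cur + 1L
      module_id[i] <- cur
      run_avg <- node_avg[i, ]
      run_n <- n_i
    }
  }
  mod_of_node <- setNames(module_id, occupied)
  gene_mod <- mod_of_node[as.character(node)]
  sizes <- table(gene_mod)
  retained <- as.integer(names(sizes)[sizes > min_size])
  keep <- gene_mod %in% retained
  modules <- data.frame(gene = names(node)[keep], node = unname(node[keep]),
                        module = unname(gene_mod[keep]),
                        stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(retained, function(m) {
    nds <- occupied[module_id == m]
    data.frame(module = m, first_node = min(nds), last_node = max(nds),
               n_profiles = sum(gene_mod == m))
  }))
  avg <- if (length(retained) > 0)
    t(vapply(retained, function(m)
      colMeans(profiles[modules$gene[modules$module == m], , drop = FALSE]),
      numeric(ncol(profiles))))
  else matrix(numeric(0), 0, ncol(profiles))
  structure(list(modules = modules, summary = summ, avg_profile = avg),
            class = "module_set")
}
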