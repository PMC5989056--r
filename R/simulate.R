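#' Simulation specification for the synthetic study
#'
#' Collects every parameter of the synthetic genome, epigenome, single-cell
#' and cohort generators, with validation. The defaults encode the study
#' conditions the pipeline is evaluated under: a 20,000-bin single
#' chromosome ("chrS") of 200 bp bins with three chromatin states — an
#' active promoter-like state ("A": high H3K4me3/H3K27ac/Pol2, low
#' methylation), a bivalent Polycomb state ("M": H3K4me3 + H3K27me3, very
#' low methylation, transcriptionally quiescent) and a silent state ("S":
#' low marks, high methylation); ~300 cells in five clusters, two of which
#' are dedifferentiated disease clusters with derepressed bivalent-state
#' genes and reduced identity-gene expression; and a 62-sample cohort (11
#' diabetic-range + 51 normal-range trait values) in which only
#' bivalent-state genes have expression positively sloped in the trait.
#'
#' @param n_bins number of genome bins.
#' @param bin_size bin width in bp.
#' @param K_true number of hidden chromatin states.
#' @param transition K x K row-stochastic transition matrix.
#' @param emission_means K x M matrix of expected per-bin counts per mark.
#' @param dispersion per-state negative-binomial size parameter (scalar or
#'   length-K vector); larger = closer to Poisson.
#' @param meth_levels length-K vector of mean %methylation per state in
#'   `[0, 100]`.
#' @param cpg_rate mean CpGs per bp (default 1/50, Poisson-placed).
#' @param n_cells number of cells.
#' @param n_clusters number of cell clusters.
#' @param cluster_profiles data.frame with one row per cluster: columns
#'   `identity_mult`, `bivalent_mult`, `disease_frac` (fraction of the
#'   cluster's cells carrying the disease condition label), `size_frac`
#'   (relative cluster size).
#' @param cell_depth_mean mean library size per cell before normalization.
#' @param cell_dispersion NB size for UMI counts.
#' @param n_samples cohort size.
#' @param trait_range numeric length-2, range of the continuous covariate
#'   (HbA1c-like, default 4.5–10).
#' @param slope_per_state per-state true effect of the trait on
#'   log-expression (default: positive only for the bivalent state).
#' @param cohort_noise_sd residual sd of cohort log-expression.
#' @param seed integer RNG seed.
#' @return validated object of class `sim_spec`.
#' @export
sim_spec <- function(n_bins = 20000L,
                     bin_size = 200L,
                     K_true = 3L,
                     transition = NULL,
                     emission_means = NULL,
                     dispersion = 10,
                     meth_levels = c(20, 5, 85),
                     cpg_rate = 1 / 50,
                     n_cells = 300L,
                     n_clusters = 5L,
                     cluster_profiles = NULL,
                     cell_depth_mean = 15000,
                     cell_dispersion = 8,
                     n_samples = 62L,
                     trait_range = c(4.5, 10),
                     slope_per_state = c(0, 0.25, 0),
                     cohort_noise_sd = 0.5,
                     seed = 1L) {
  if (is.null(transition)) {
    transition <- matrix(0.05, K_true, K_true)
    diag(transition) <- 1 - 0.05 * (K_true - 1)
  }
  if (is.null(emission_means)) {
    stopifnot(K_true == 3L)
    emission_means <- rbind(
      A = c(H3K4me3 = 20, H3K27ac = 15, H3K27me3 = 1, H3K36me3 = 10, Pol2 = 12),
      M = c(H3K4me3 = 15, H3K27ac = 2,  H3K27me3 = 18, H3K36me3 = 1, Pol2 = 2),
      S = c(H3K4me3 = 1,  H3K27ac = 1,  H3K27me3 = 2,  H3K36me3 = 1, Pol2 = 1))
  }
  if (is.null(cluster_profiles)) {
    cluster_profiles <- data.frame(
      # clusters 1-2: mature identity; 3: intermediate ("hub"-like);
      # 4-5: dedifferentiated, bivalent-derepressed, disease-enriched
      identity_mult = c(1.0, 1.0, 0.7, 0.25, 0.2),
      bivalent_mult = c(1.0, 1.0, 1.5, 6.0, 8.0),
      disease_frac  = c(0.2, 0.2, 0.5, 0.8, 0.95),
      size_frac     = c(0.30, 0.28, 0.18, 0.12, 0.12))[seq_len(n_clusters), , drop = FALSE]
  }
  spec <- structure(list(
    n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
    K_true = as.integer(K_true), transition = transition,
    emission_means = emission_means,
    dispersion = rep_len(dispersion, K_true),
    meth_levels = meth_levels, cpg_rate = cpg_rate,
    n_cells = as.integer(n_cells), n_clusters = as.integer(n_clusters),
    cluster_profiles = cluster_profiles,
    cell_depth_mean = cell_depth_mean, cell_dispersion = cell_dispersion,
    n_samples = as.integer(n_samples), trait_range = trait_range,
    slope_per_state = rep_len(slope_per_state, K_true),
    cohort_noise_sd = cohort_noise_sd, seed = as.integer(seed)),
    class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  A <- spec$transition
  if (!is.matrix(A) || nrow(A) != spec$K_true || ncol(A) != spec$K_true)
    stop("transition must be a K x K matrix")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
    stop("transition matrix rows must be nonnegative and sum to 1")
  if (nrow(spec$emission_means) != spec$K_true || any(spec$emission_means < 0))
    stop("emission_means must be a nonnegative K x M matrix")
  if (length(spec$meth_levels) != spec$K_true ||
      any(spec$meth_levels < 0) || any(spec$meth_levels > 100))
    stop("meth_levels must be K values in [0, 100]")
  if (any(spec$dispersion <= 0)) stop("dispersion must be positive")
  invisible(spec)
}

#' Sample the hidden chromatin-state track
#'
#' Markov chain of length `n_bins` over states 1..K with the spec's
#' transition matrix and a uniform initial distribution.
#'
#' @param spec a [sim_spec()].
#' @return integer state vector of length `n_bins`.
#' @export
simulate_state_track <- function(spec) {
  validate_sim_spec(spec)
  set.seed(spec$seed)
  K <- spec$K_true
  if (K == 1L) return(rep(1L, spec$n_bins))
  states <- integer(spec$n_bins)
  states[1] <- sample.int(K, 1)
  if (spec$n_bins > 1) {
    u <- runif(spec$n_bins)
    cums <- apply(spec$transition, 1, cumsum)  # K x K, column = from-state
    for (i in 2:spec$n_bins)
      states[i] <- min(findInterval(u[i], cums[, states[i - 1]],
                                    left.open = TRUE) + 1L, K)
  }
  states
}

#' Simulate per-bin mark counts and a per-CpG methylation table
#'
#' Mark counts are negative binomial around the state-specific emission
#' means (shared per-state dispersion). CpG sites are Poisson-placed at
#' `cpg_rate` per bp; each site's %methylation is drawn from a normal around
#' the state's mean level (sd 10) truncated to `[0, 100]`.
#'
#' @param state_track integer state vector from [simulate_state_track()].
#' @param spec a [sim_spec()].
#' @return list: `counts` (n_bins x M matrix), `cpg` (data.frame `chrom`,
#'   `pos` 1-based, `meth`, `coverage`), `bins` ([genome_bins()]).
#' @export
simulate_tracks <- function(state_track, spec) {
  stopifnot(length(state_track) == spec$n_bins)
  set.seed(spec$seed + 1L)
  M <- ncol(spec$emission_means)
  counts <- matrix(0L, spec$n_bins, M,
                   dimnames = list(NULL, colnames(spec$emission_means)))
  for (j in seq_len(M)) {
    mu <- spec$emission_means[state_track, j]
    counts[, j] <- rnbinom(spec$n_bins, size = spec$dispersion[state_track],
                           mu = mu)
  }
  genome_len <- spec$n_bins * spec$bin_size
  n_cpg <- rpois(1, genome_len * spec$cpg_rate)
  pos0 <- sort(sample.int(genome_len, min(n_cpg, genome_len)))
  st <- state_track[(pos0 - 1L) %/% spec$bin_size + 1L]
  meth <- pmin(pmax(rnorm(length(pos0), spec$meth_levels[st], 10), 0), 100)
  cpg <- data.frame(chrom = "chrS", pos = pos0, meth = meth,
                    coverage = rpois(length(pos0), 20) + 1L)
  list(counts = counts, cpg = cpg,
       bins = genome_bins("chrS", spec$n_bins, spec$bin_size))
}

#' Simulate gene models over the state track
#'
#' Places non-overlapping genes on the synthetic chromosome. A majority
#' (`homogeneous_frac`) are placed wholly inside runs of a single chromatin
#' state so their true genebody/TSS state is known exactly; the rest are
#' placed at random and may span state boundaries. Strand, biotype and the
#' "basic" tag are populated; a small fraction of genes deliberately carry a
#' pseudogene biotype or lack the basic tag to exercise downstream filters.
#'
#' @param state_track integer state vector.
#' @param n_genes number of genes to place.
#' @param seed RNG seed.
#' @param bin_size bin width in bp.
#' @param homogeneous_frac fraction placed in state-homogeneous runs
#'   (default 0.7).
#' @return list: `genes` (data.frame with 0-based half-open `start`/`end`,
#'   `strand`, `biotype`, `basic`, `tss`), `truth` (data.frame with
#'   `gene_id`, `true_state`, `homogeneous`).
#' @export
simulate_gene_models <- function(state_track, n_genes, seed = 1L,
                                 bin_size = 200L, homogeneous_frac = 0.7) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  n_bins <- length(state_track)
  r <- rle(state_track)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  # candidate runs able to hold a >=1-bin gene with a margin bin on each side
  cand <- which(r$lengths >= 3L)
  n_homog <- round(n_genes * homogeneous_frac)
  if (length(cand) < 1L || n_bins < 4L * n_genes)
    stop("genome too short to place ", n_genes, " genes")
  genes <- vector("list", n_genes)
  used <- logical(n_bins)   # bin-level occupancy to keep genes disjoint
  place <- function(b0, b1) { used[b0:b1] <<- TRUE }
  free <- function(b0, b1) !any(used[b0:b1])
  gi <- 0L; tries <- 0L
  truth_state <- integer(n_genes); homog <- logical(n_genes)
  starts <- ends <- integer(n_genes)
  while (gi < n_genes && tries < n_genes * 200L) {
    tries <- tries + 1L
    want_homog <- gi < n_homog
    if (want_homog) {
      ri <- cand[sample.int(length(cand), 1)]
      len_bins <- sample.int(min(r$lengths[ri] - 2L, 10L), 1)
      b0 <- run_start[ri] + sample.int(r$lengths[ri] - len_bins - 1L, 1)
      b1 <- b0 + len_bins - 1L
    } else {
      len_bins <- sample.int(10L, 1)
      b0 <- sample.int(n_bins - len_bins, 1)
      b1 <- b0 + len_bins - 1L
    }
    if (!free(b0, b1)) next
    place(b0, b1)
    gi <- gi + 1L
    starts[gi] <- (b0 - 1L) * bin_size
    ends[gi] <- b1 * bin_size
    st_span <- state_track[b0:b1]
    truth_state[gi] <- as.integer(names(which.max(table(st_span))))
    homog[gi] <- length(unique(st_span)) == 1L
  }
  if (gi < n_genes) stop("genome too short to place ", n_genes, " genes")
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- sample(c("protein_coding", "lincRNA", "antisense", "pseudogene"),
                    n_genes, replace = TRUE, prob = c(0.8, 0.07, 0.05, 0.08))
  basic <- runif(n_genes) > 0.05
  genes <- data.frame(
    gene_id = sprintf("SG%04d", seq_len(n_genes)),
    name = sprintf("Gene%04d", seq_len(n_genes)),
    chrom = "chrS", start = starts, end = ends, strand = strand,
    biotype = biotype, basic = basic,
    tss = ifelse(strand == "+", starts, ends - 1L),
    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes$gene_id, true_state = truth_state,
                      homogeneous = homog, stringsAsFactors = FALSE)
  list(genes = genes, truth = truth)
}

#' Simulate a clustered single-cell UMI matrix
#'
#' Cells are drawn from `n_clusters` clusters with the spec's relative
#' sizes. Per-gene baseline expression depends on the gene's true chromatin
#' state (active-state genes expressed, bivalent-state genes near-silent,
#' silent-state genes off); a designated identity geneset (a subset of
#' active-state genes, mimicking lineage-defining transcription factors) is
#' scaled by each cluster's `identity_mult` and the bivalent-state geneset
#' by `bivalent_mult`, so disease clusters derepress bivalent genes and lose
#' identity-gene expression. In addition every cluster carries its own
#' marker geneset (disjoint subsets of the remaining active-state genes)
#' upregulated by `marker_mult`, mirroring the distinct sub-type programs
#' (e.g. a mitochondrial-high "hub" program) that make real beta-cell
#' sub-types separable. Counts are negative binomial; condition labels
#' ("Ctrl"/"HFD") are assigned per cluster by `disease_frac`.
#'
#' @param gene_truth the `truth` data.frame from [simulate_gene_models()]
#'   (needs `gene_id`, `true_state`).
#' @param spec a [sim_spec()].
#' @param active_state,bivalent_state state indices of the active and
#'   bivalent states (defaults 1 and 2).
#' @param identity_frac fraction of active-state genes in the identity set.
#' @param marker_mult fold-change of each cluster's own marker geneset
#'   (default 12; set to 1 for exchangeable null clusters).
#' @return list: `counts` (cells x genes integer matrix), `cluster` (true
#'   cluster per cell), `condition` (per cell), `identity_genes`,
#'   `bivalent_genes`, `marker_sets` (list per cluster).
#' @export
simulate_cells <- function(gene_truth, spec, active_state = 1L,
                           bivalent_state = 2L, identity_frac = 0.25,
                           marker_mult = 12) {
  if (spec$n_clusters < 2L) stop("need at least 2 clusters")
  set.seed(spec$seed + 2L)
  prof <- spec$cluster_profiles
  G <- nrow(gene_truth)
  st <- gene_truth$true_state
  active <- gene_truth$gene_id[st == active_state]
  bivalent <- gene_truth$gene_id[st == bivalent_state]
  if (length(active) == 0L || length(bivalent) == 0L)
    stop("empty geneset: no genes in the active or bivalent state")
  identity_genes <- sample(active, max(1L, round(length(active) * identity_frac)))
  # disjoint per-cluster marker programs from the remaining active genes
  pool <- sample(setdiff(active, identity_genes))
  marker_sets <- split(pool, rep_len(seq_len(spec$n_clusters), length(pool)))
  base <- numeric(G)
  base[st == active_state] <- exp(rnorm(sum(st == active_state), log(30), 0.8))
  base[st == bivalent_state] <- exp(rnorm(sum(st == bivalent_state), log(1.5), 0.5))
  base[!(st %in% c(active_state, bivalent_state))] <-
    exp(rnorm(sum(!(st %in% c(active_state, bivalent_state))), log(0.3), 0.5))
  id_idx <- gene_truth$gene_id %in% identity_genes
  biv_idx <- st == bivalent_state
  base[id_idx] <- base[id_idx] * 4   # identity genes are highly expressed
  sizes <- pmax(as.vector(rmultinom(1, spec$n_cells, prof$size_frac)), 1L)
  cluster <- rep(seq_len(spec$n_clusters), sizes)[seq_len(spec$n_cells)]
  counts <- matrix(0L, spec$n_cells, G,
                   dimnames = list(sprintf("cell_%03d", seq_len(spec$n_cells)),
                                   gene_truth$gene_id))
  condition <- character(spec$n_cells)
  marker_idx <- lapply(marker_sets, function(g) gene_truth$gene_id %in% g)
  # equalize marker-gene baselines so the per-cluster marker programs are
  # exchangeable (no cluster gets a systematically more concentrated
  # transcriptome from the luck of its marker draw)
  base[gene_truth$gene_id %in% pool] <- exp(log(30))
  for (i in seq_len(spec$n_cells)) {
    c_i <- cluster[i]
    mu <- base
    mu[id_idx] <- mu[id_idx] * prof$identity_mult[c_i]
    mu[biv_idx] <- mu[biv_idx] * prof$bivalent_mult[c_i]
    mu[marker_idx[[c_i]]] <- mu[marker_idx[[c_i]]] * marker_mult
    depth <- rnbinom(1, mu = spec$cell_depth_mean, size = 20) + 1
    mu <- mu / sum(mu) * depth
    counts[i, ] <- rnbinom(G, mu = mu, size = spec$cell_dispersion)
    condition[i] <- if (runif(1) < prof$disease_frac[c_i]) "HFD" else "Ctrl"
  }
  list(counts = counts, cluster = cluster, condition = condition,
       identity_genes = identity_genes, bivalent_genes = bivalent,
       marker_sets = marker_sets)
}

#' Simulate a bulk cohort with a continuous trait
#'
#' Per-gene log-expression is `baseline + slope_per_state[state] * trait +
#' noise`. When the trait range spans the clinical HbA1c cutoffs (6.0/6.5),
#' trait values are drawn as a two-group cohort — a fraction
#' `diabetic_frac` (default 11/62, matching an 11 diabetic + 51 non-diabetic
#' islet donor cohort) above 6.5 and the rest below 6.0; otherwise traits
#' are uniform over `trait_range`.
#'
#' @param gene_truth truth table from [simulate_gene_models()].
#' @param spec a [sim_spec()].
#' @param diabetic_frac fraction of samples in the high-trait group.
#' @return list: `expr` (samples x genes matrix of log-expression), `trait`
#'   (numeric per sample), `state` (per-gene true state).
#' @export
simulate_cohort <- function(gene_truth, spec, diabetic_frac = 11 / 62) {
  if (spec$n_samples < 4L) stop("need at least 4 samples")
  if (diff(spec$trait_range) <= 0) stop("degenerate trait_range")
  set.seed(spec$seed + 3L)
  n <- spec$n_samples
  rng <- spec$trait_range
  if (rng[1] < 6.0 && rng[2] > 6.5) {
    n_hi <- round(n * diabetic_frac)
    trait <- sort(c(runif(n - n_hi, rng[1], 6.0), runif(n_hi, 6.5, rng[2])))
  } else {
    trait <- sort(runif(n, rng[1], rng[2]))
  }
  G <- nrow(gene_truth)
  st <- gene_truth$true_state
  baseline <- rnorm(G, 5, 1)
  slopes <- spec$slope_per_state[st]
  expr <- matrix(0, n, G, dimnames = list(sprintf("sample_%02d", seq_len(n)),
                                          gene_truth$gene_id))
  for (g in seq_len(G))
    expr[, g] <- baseline[g] + slopes[g] * trait +
      rnorm(n, 0, spec$cohort_noise_sd)
  list(expr = expr, trait = trait, state = st)
}
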