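#' Load and filter gene models from a GTF file
#'
#' Reads gene records from a GTF (1-based closed coordinates, converted to
#' 0-based half-open internally) and applies the study filters: keep only
#' genes on the allowed chromosomes (autosomes by default), with an allowed
#' biotype (protein_coding, lincRNA, antisense), and — when `require_basic`
#' — carrying the "basic" tag. Counts of genes removed by each filter are
#' attached as the `filter_log` attribute.
#'
#' @param gtf_path path to a GTF file with `gene` feature rows.
#' @param allowed_biotypes character vector of biotypes to keep.
#' @param require_basic keep only genes tagged "basic".
#' @param allowed_chroms chromosomes to keep; default mouse autosomes 1-19
#'   (both "1" and "chr1" spellings) plus the synthetic "chrS".
#' @return data.frame: `gene_id`, `name`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `biotype`, `basic`, `tss`.
#' @export
load_gene_models <- function(gtf_path,
                             allowed_biotypes = c("protein_coding", "lincRNA",
                                                  "antisense"),
                             require_basic = TRUE,
                             allowed_chroms = c(as.character(1:19),
                                                paste0("chr", 1:19), "chrS")) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  md <- S4Vectors::mcols(gr)
  biotype <- if ("gene_biotype" %in% names(md)) md$gene_biotype else md$gene_type
  tag <- if ("tag" %in% names(md)) md$tag else NA_character_
  genes <- data.frame(
    gene_id = md$gene_id,
    name = if ("gene_name" %in% names(md)) md$gene_name else md$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GTF 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    basic = !is.na(tag) & tag == "basic",
    stringsAsFactors = FALSE)
  n0 <- nrow(genes)
  keep_chrom <- genes$chrom %in% allowed_chroms
  keep_bio <- genes$biotype %in% allowed_biotypes
  keep_basic <- if (require_basic) genes$basic else rep(TRUE, n0)
  filter_log <- c(input = n0,
                  dropped_chrom = sum(!keep_chrom),
                  dropped_biotype = sum(keep_chrom & !keep_bio),
                  dropped_basic = sum(keep_chrom & keep_bio & !keep_basic))
  genes <- genes[keep_chrom & keep_bio & keep_basic, , drop = FALSE]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  rownames(genes) <- NULL
  attr(genes, "filter_log") <- filter_log
  genes
}

#' Assign chromatin states to genes
#'
#' For each gene, the fraction of its genebody covered by each state is
#' computed from the decoded state track, weighting partially overlapped
#' bins by overlap bp. The genebody state is the state of maximum coverage
#' (ties break to the lowest state index); the TSS state is the state of
#' the bin containing the TSS. Genes with zero overlap with the segmented
#' region are excluded with a warning.
#'
#' @param genes gene model data.frame ([load_gene_models()] or
#'   [simulate_gene_models()]).
#' @param states a `state_track` from [decode_states()], or a bare integer
#'   state vector (then `bins` must be given).
#' @param bins a [genome_bins()] grid (taken from `states` when present).
#' @param K number of states (default `max(states)`).
#' @return data.frame: `gene_id`, `genebody_state`, `tss_state`, plus
#'   `coverage_1..K` fraction columns summing to 1 per gene.
#' @export
assign_gene_states <- function(genes, states, bins = NULL, K = NULL) {
  if (inherits(states, "state_track")) {
    if (is.null(bins)) bins <- states$bins
    states <- states$states
  }
  stopifnot(!is.null(bins))
  if (is.null(K)) K <- max(states)
  bs <- bins$bin_size
  glen <- bins$n_bins * bs
  n <- nrow(genes)
  cov <- matrix(0, n, K)
  gb <- tss_state <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- max(genes$start[i], 0L)
    e <- min(genes$end[i], glen)
    if (e <= s) next
    b0 <- s %/% bs + 1L
    b1 <- (e - 1L) %/% bs + 1L
    w <- numeric(b1 - b0 + 1L)
    for (b in b0:b1) {
      bin_s <- (b - 1L) * bs
      w[b - b0 + 1L] <- min(e, bin_s + bs) - max(s, bin_s)
    }
    st <- states[b0:b1]
    for (k in seq_len(K)) cov[i, k] <- sum(w[st == k])
    cov[i, ] <- cov[i, ] / sum(w)
    gb[i] <- which.max(cov[i, ])            # first max -> lowest index tie-break
    tpos <- genes$tss[i]
    if (tpos >= 0 && tpos < glen) tss_state[i] <- states[tpos %/% bs + 1L]
    ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " gene(s) with no overlap with the segmented region excluded")
  out <- data.frame(gene_id = genes$gene_id[ok],
                    genebody_state = gb[ok], tss_state = tss_state[ok],
                    stringsAsFactors = FALSE)
  covm <- cov[ok, , drop = FALSE]
  colnames(covm) <- paste0("coverage_", seq_len(K))
  cbind(out, as.data.frame(covm))
}

#' Genes x states coverage-fraction matrix
#'
#' Row-normalized per-gene state-coverage vectors, the input for 2D
#' embeddings of the gene-level chromatin-state landscape (the embedding
#' itself is delegated to any standard method).
#'
#' @param table output of [assign_gene_states()].
#' @return numeric matrix with genes as rownames and one column per state.
#' @export
gene_state_vector_matrix <- function(table) {
  stopifnot(nrow(table) > 0)
  covcols <- grep("^coverage_", names(table), value = TRUE)
  m <- as.matrix(table[, covcols, drop = FALSE])
  rownames(m) <- table$gene_id
  m / rowSums(m)
}

#' TSS-associated peak breadth and rank
#'
#' A gene's breadth is the length (end - start) of the widest peak
#' overlapping its TSS +/- `tss_window`; genes with no overlapping peak get
#' breadth 0. Rank 1 is the broadest gene; ties share the minimum rank.
#'
#' @param peaks data.frame of called peak intervals (`chrom`, `start`,
#'   `end`, 0-based half-open as in BED).
#' @param genes gene model data.frame with `chrom`, `tss`, `gene_id`.
#' @param tss_window association window around the TSS in bp (default 500).
#' @return data.frame: `gene_id`, `breadth`, `rank` (descending by breadth).
#' @export
peak_breadth_rank <- function(peaks, genes, tss_window = 500L) {
  if (tss_window < 0) stop("tss_window must be nonnegative")
  stopifnot(all(peaks$end > peaks$start))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(genes$tss - tss_window, 0L) + 1L,
                                                 genes$tss + tss_window + 1L))
  hits <- GenomicRanges::findOverlaps(win, pk)
  breadth <- numeric(nrow(genes))
  if (length(hits) > 0) {
    widths <- (peaks$end - peaks$start)[S4Vectors::subjectHits(hits)]
    agg <- tapply(widths, S4Vectors::queryHits(hits), max)
    breadth[as.integer(names(agg))] <- agg
  }
  data.frame(gene_id = genes$gene_id, breadth = breadth,
             rank = rank(-breadth, ties.method = "min"),
             stringsAsFactors = FALSE)
}

#' Top percent broadest genes, with exclusions
#'
#' Takes `ceiling(top_pct% * n)` genes by descending breadth after removing
#' the excluded names (so an excluded gene inside the top slice is replaced
#' by the next-ranked gene).
#'
#' @param ranked output of [peak_breadth_rank()].
#' @param top_pct percentage in (0, 100].
#' @param exclude gene ids to remove before slicing (e.g. expression
#'   outliers such as the insulin genes).
#' @return character vector of gene ids.
#' @export
top_broad_geneset <- function(ranked, top_pct = 2, exclude = character()) {
  if (nrow(ranked) == 0) stop("empty ranked table")
  stopifnot(top_pct > 0, top_pct <= 100)
  keep <- ranked[!(ranked$gene_id %in% exclude), , drop = FALSE]
  keep <- keep[order(keep$rank, keep$gene_id), , drop = FALSE]
  n_top <- ceiling(top_pct / 100 * nrow(keep))
  head(keep$gene_id, n_top)
}

#' Depth-normalized TSS area under curve
#'
#' Sum of per-bp signal over `[TSS - flank, TSS + flank]` (inclusive, so
#' 2*flank+1 positions), scaled to counts per million by `1e6 /
#' library_size`. Windows extending past the chromosome are truncated with
#' a warning.
#'
#' @param coverage numeric per-bp signal vector (position i = bp i-1,
#'   0-based).
#' @param gene one-row gene model (needs `tss`).
#' @param flank half-window in bp (default 100).
#' @param library_size total mapped fragments for depth normalization.
#' @return scalar AUC.
#' @export
tss_auc <- function(coverage, gene, flank = 100L, library_size) {
  stopifnot(flank >= 0, library_size > 0)
  tss <- gene$tss
  lo <- tss - flank
  hi <- tss + flank
  if (lo < 0 || hi >= length(coverage)) {
    warning("TSS window truncated at chromosome bounds")
    lo <- max(lo, 0L)
    hi <- min(hi, length(coverage) - 1L)
  }
  sum(coverage[(lo:hi) + 1L]) * 1e6 / library_size
}

#' Average metagene signal profile
#'
#' Per-gene signal around and across the genebody: upstream and downstream
#' flanks in fixed-width bp bins, the body linearly rescaled to `body_bins`
#' positions, minus-strand genes reversed so profiles read TSS to TES, all
#' depth-normalized to counts per million and averaged across genes.
#'
#' @param coverage numeric per-bp signal vector (0-based positions).
#' @param genes gene model data.frame.
#' @param upstream,downstream flank sizes in bp.
#' @param body_bins number of bins the genebody is rescaled to.
#' @param flank_bin_size width of flank bins in bp (default 50).
#' @param library_size total fragments for depth normalization.
#' @return numeric profile vector of length
#'   `upstream/flank_bin_size + body_bins + downstream/flank_bin_size`.
#' @export
metagene_profile <- function(coverage, genes, upstream = 2000L,
                             body_bins = 100L, downstream = 2000L,
                             flank_bin_size = 50L, library_size) {
  stopifnot(nrow(genes) >= 1, library_size > 0)
  n_up <- upstream %/% flank_bin_size
  n_dn <- downstream %/% flank_bin_size
  glen <- length(coverage)
  get_bp <- function(lo, hi) {            # 0-based inclusive, clipped
    idx <- lo:hi
    v <- numeric(length(idx))
    ok <- idx >= 0 & idx < glen
    v[ok] <- coverage[idx[ok] + 1L]
    v
  }
  bin_mean <- function(v, nb) {
    if (length(v) < nb) {                 # short gene: interpolate, logged
      message("gene shorter than body_bins; linear interpolation used")
      return(approx(seq_along(v), v, n = nb)$y)
    }
    cuts <- floor(seq(0, length(v), length.out = nb + 1))
    vapply(seq_len(nb), function(b) mean(v[(cuts[b] + 1):cuts[b + 1]]),
           numeric(1))
  }
  profs <- matrix(0, nrow(genes), n_up + body_bins + n_dn)
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]
    up <- bin_mean(get_bp(s - upstream, s - 1L), n_up)
    body <- bin_mean(get_bp(s, e - 1L), body_bins)
    dn <- bin_mean(get_bp(e, e + downstream - 1L), n_dn)
    p <- c(up, body, dn)
    if (genes$strand[i] == "-") p <- rev(p)
    profs[i, ] <- p
  }
  colMeans(profs) * 1e6 / library_size
}
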