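#' Write a per-bin track as bedGraph
#'
#' @param values numeric per-bin values.
#' @param bins a [genome_bins()] grid.
#' @param path output file.
#' @export
write_bedgraph <- function(values, bins, path) {
  stopifnot(length(values) == bins$n_bins)
  gr <- GenomicRanges::GRanges(
    bins$chrom,
    IRanges::IRanges(start = (seq_len(bins$n_bins) - 1L) * bins$bin_size + 1L,
                     width = bins$bin_size),
    score = values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph into a per-bin vector
#'
#' Values are assigned to bins by interval midpoint (consistent with
#' [bin_signal()]); bins not covered get 0.
#'
#' @param path bedGraph file.
#' @param bins a [genome_bins()] grid.
#' @return numeric vector of length `n_bins`.
#' @export
read_bedgraph_binned <- function(path, bins) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == bins$chrom]
  mid <- (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
  idx <- mid %/% bins$bin_size + 1L
  out <- numeric(bins$n_bins)
  ok <- idx >= 1 & idx <= bins$n_bins
  out[idx[ok]] <- gr$score[ok]
  out
}

#' Write gene models as GTF
#'
#' One `gene` feature per model, 1-based closed coordinates, with
#' `gene_biotype` and (for basic genes) `tag "basic"` attributes.
#'
#' @param genes gene model data.frame (0-based half-open `start`/`end`).
#' @param path output file.
#' @export
write_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "epistate", type = "gene",
    gene_id = genes$gene_id, gene_name = genes$name,
    gene_biotype = genes$biotype,
    tag = ifelse(genes$basic, "basic", NA_character_))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write a per-CpG methylation table
#'
#' Columns: chrom, 1-based position, %methylation, coverage.
#'
#' @param cpg data.frame from [simulate_tracks()].
#' @param path output file.
#' @export
write_cpg_tsv <- function(cpg, path) {
  write.table(cpg[, c("chrom", "pos", "meth", "coverage")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-CpG methylation table
#' @param path TSV with columns chrom, pos, meth, coverage.
#' @return data.frame.
#' @export
read_cpg_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a decoded state track as BED9
#'
#' Adjacent bins in the same state are merged into segments; the score is
#' `max posterior x 1000` over the segment when posteriors are available.
#'
#' @param track a `state_track` from [decode_states()].
#' @param path output file.
#' @param labels optional state label vector (index = state).
#' @export
write_segmentation_bed <- function(track, path, labels = NULL) {
  bins <- track$bins
  stopifnot(!is.null(bins))
  r <- rle(track$states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  score <- rep(0L, length(r$values))
  if (!is.null(track$posteriors)) {
    pmax_bin <- apply(track$posteriors, 1, max)
    score <- vapply(seq_along(starts), function(i)
      as.integer(round(max(pmax_bin[starts[i]:ends[i]]) * 1000)), integer(1))
  }
  lab <- if (is.null(labels)) paste0("state_", r$values) else labels[r$values]
  bed <- data.frame(chrom = bins$chrom,
                    start = (starts - 1L) * bins$bin_size,
                    end = ends * bins$bin_size,
                    name = lab, score = score, strand = ".",
                    thickStart = (starts - 1L) * bins$bin_size,
                    thickEnd = ends * bins$bin_size, itemRgb = "0,0,0")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a UMI matrix as MatrixMarket plus name files
#'
#' Writes `<prefix>.mtx` (genes x cells, the usual sparse convention),
#' `<prefix>.genes.txt` and `<prefix>.cells.txt`.
#'
#' @param mat cells x genes count matrix.
#' @param prefix path prefix.
#' @export
write_umi_mtx <- function(mat, prefix) {
  sp <- Matrix::Matrix(t(mat), sparse = TRUE)
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  writeLines(colnames(mat), paste0(prefix, ".genes.txt"))
  writeLines(rownames(mat), paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' Read a UMI matrix written by [write_umi_mtx()]
#' @param prefix path prefix.
#' @return cells x genes integer matrix.
#' @export
read_umi_mtx <- function(prefix) {
  sp <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- readLines(paste0(prefix, ".genes.txt"))
  cells <- readLines(paste0(prefix, ".cells.txt"))
  m <- t(as.matrix(sp))
  dimnames(m) <- list(cells, genes)
  storage.mode(m) <- "integer"
  m
}
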