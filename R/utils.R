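#' Round half away from zero
#'
#' Deterministic half-up rounding used for replicate averaging and the
#' methylation channel. `base::round()` rounds half to even, which makes
#' values like 6.5 depend on binary representation; the pipeline instead
#' commits to `floor(x + 0.5)` for nonnegative input.
#'
#' @param x numeric vector, assumed nonnegative.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Best label matching between two partitions
#'
#' Finds the permutation of predicted labels maximizing agreement with the
#' truth. Exact (enumerates all permutations) for up to 8 labels, which covers
#' every state/cluster count used in this pipeline; falls back to greedy
#' maximum-overlap matching for larger label sets.
#'
#' @param truth,pred integer/factor vectors of equal length.
#' @return list with `map` (named vector: predicted label -> truth label) and
#'   `accuracy` (fraction of positions agreeing after relabeling).
#' @export
match_labels <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tl <- sort(unique(truth))
  pl <- sort(unique(pred))
  tab <- table(factor(pred, levels = pl), factor(truth, levels = tl))
  if (length(pl) <= 8L && length(tl) <= 8L) {
    # pad to square so every predicted label receives some truth label
    n <- max(length(pl), length(tl))
    m <- matrix(0L, n, n)
    m[seq_along(pl), seq_along(tl)] <- tab
    perms <- permutations(n)
    scores <- vapply(seq_len(nrow(perms)), function(i) {
      sum(m[cbind(seq_len(n), perms[i, ])])
    }, numeric(1))
    best <- perms[which.max(scores), ]
    map <- setNames(rep(NA, length(pl)), pl)
    for (i in seq_along(pl)) {
      j <- best[i]
      map[i] <- if (j <= length(tl)) tl[j] else NA
    }
  } else {
    map <- setNames(rep(NA, length(pl)), pl)
    m <- tab
    repeat {
      if (all(m < 0)) break
      idx <- which(m == max(m), arr.ind = TRUE)[1, , drop = TRUE]
      if (m[idx[1], idx[2]] < 0) break
      map[rownames(tab)[idx[1]]] <- tl[idx[2]]
      m[idx[1], ] <- -1L
      m[, idx[2]] <- -1L
    }
  }
  relab <- map[as.character(pred)]
  list(map = map, accuracy = mean(relab == truth, na.rm = FALSE))
}

#' All permutations of 1..n
#' @keywords internal
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      row[row >= k] <- row[row >= k] + 1L
      out[r, ] <- c(k, row)
      r <- r + 1L
    }
  }
  out
}

#' Jaccard similarity of two index sets
#' @keywords internal
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}
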