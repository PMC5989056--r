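#' Genome bin grid
#'
#' A fixed-width tiling of one chromosome. All internal coordinates are
#' 0-based half-open; bin `i` (1-based index) covers
#' `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param chrom chromosome name.
#' @param n_bins number of bins.
#' @param bin_size bin width in bp (default 200).
#' @return object of class `genome_bins`.
#' @export
genome_bins <- function(chrom = "chrS", n_bins, bin_size = 200L) {
  stopifnot(n_bins >= 1, bin_size > 0)
  structure(list(chrom = chrom, n_bins = as.integer(n_bins),
                 bin_size = as.integer(bin_size)),
            class = "genome_bins")
}

#' Per-bin signal track matrix
#'
#' Bundles per-bin counts for M marks (and optionally the transformed
#' methylation channel as an extra column named `"meth"`) with the bin grid.
#'
#' @param counts n_bins x M nonnegative matrix with column names.
#' @param bins a [genome_bins()] grid.
#' @param meth_channel optional integer vector of length n_bins from
#'   [transform_methylation()]; appended as the last column.
#' @return object of class `track_matrix` (list: `bins`, `counts`, `marks`).
#' @export
track_matrix <- function(counts, bins, meth_channel = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == bins$n_bins, all(counts >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("mark_", seq_len(ncol(counts)))
  if (!is.null(meth_channel)) {
    stopifnot(length(meth_channel) == bins$n_bins)
    counts <- cbind(counts, meth = as.numeric(meth_channel))
  }
  structure(list(bins = bins, counts = counts, marks = colnames(counts)),
            class = "track_matrix")
}

#' Assign fragments to genome bins by midpoint
#'
#' Each fragment is counted in exactly the bin containing its midpoint, so no
#' fragment is double-counted. When a `replicate` column is present, per-
#' replicate tracks are computed first, averaged element-wise, and rounded
#' half-up to integers.
#'
#' @param intervals data.frame with 0-based half-open `start`, `end`, optional
#'   `replicate` id column.
#' @param bins a [genome_bins()] grid.
#' @return integer vector of length `n_bins`; attribute `n_skipped` counts
#'   fragments whose midpoint fell outside the chromosome.
#' @export
bin_signal <- function(intervals, bins) {
  n <- bins$n_bins
  if (nrow(intervals) == 0L) {
    out <- integer(n)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  stopifnot(all(c("start", "end") %in% names(intervals)))
  mid <- (intervals$start + intervals$end) %/% 2L
  idx <- mid %/% bins$bin_size + 1L
  ok <- idx >= 1L & idx <= n & mid >= 0L
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(sprintf("%d fragment(s) outside chromosome bounds skipped", n_skipped))
  rep_id <- if ("replicate" %in% names(intervals)) intervals$replicate else rep(1L, nrow(intervals))
  reps <- unique(rep_id)
  acc <- matrix(0, n, length(reps))
  for (r in seq_along(reps)) {
    sel <- ok & rep_id == reps[r]
    acc[, r] <- tabulate(idx[sel], nbins = n)
  }
  out <- as.integer(round_half_up(rowMeans(acc)))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Transform per-CpG methylation into an inverse-scaled binned channel
#'
#' For each bin the median %methylation of all CpGs within a window centered
#' on the bin (window = bin +/- (window - bin_size)/2 bp; defaults give a
#' 600 bp window stepped by 200 bp) is inverted and scaled:
#' `value = round_half_up(scale * (100 - median) / 100)`. Low methylation
#' (accessible chromatin) therefore yields high values, and windows without
#' any CpG yield 0 — i.e. they are treated as fully methylated background,
#' matching the empirical distribution where most bins carry high methylation.
#'
#' @param cpg data.frame with `pos` (1-based CpG position) and `meth`
#'   (percent methylation in `[0, 100]`); an optional `chrom` column is
#'   ignored for the single-chromosome grid.
#' @param bins a [genome_bins()] grid.
#' @param window window width in bp (default 600).
#' @param scale inverse-scaling constant (default 10), chosen so the channel
#'   is count-like and compatible with the count emission model.
#' @return integer vector of length `n_bins`.
#' @export
transform_methylation <- function(cpg, bins, window = 600L, scale = 10L) {
  stopifnot(window >= bins$bin_size)
  if (nrow(cpg) > 0 && (any(cpg$meth < 0) || any(cpg$meth > 100)))
    stop("%methylation values must lie in [0, 100]")
  flank <- (window - bins$bin_size) %/% 2L
  pos0 <- cpg$pos - 1L                      # to 0-based
  out <- integer(bins$n_bins)
  ord <- order(pos0)
  pos0 <- pos0[ord]
  meth <- cpg$meth[ord]
  starts <- (seq_len(bins$n_bins) - 1L) * bins$bin_size - flank
  ends <- starts + window                    # half-open window
  lo <- findInterval(starts - 1L, pos0) + 1L # first CpG with pos0 >= start
  hi <- findInterval(ends - 1L, pos0)        # last CpG with pos0 < end
  for (i in seq_len(bins$n_bins)) {
    if (hi[i] >= lo[i]) {
      med <- median(meth[lo[i]:hi[i]])
      out[i] <- as.integer(round_half_up(scale * (100 - med) / 100))
    }
  }
  out
}

## ---- emission models -------------------------------------------------------

# Per-state negative multinomial: the per-bin channel total follows a negative
# binomial (state mean mu, dispersion size), split across channels by
# state-specific proportions p. Log-density of one bin given state k.
nm_logdens <- function(counts, totals, mu, size, p, lgamma_cache) {
  # counts: n x C; totals: n; p: C-vector summing to 1
  n <- length(totals)
  ll <- dnbinom(totals, size = size, mu = mu, log = TRUE)
  lp <- log(pmax(p, 1e-12))
  ll + lgamma_cache$lt - rowSums(lgamma_cache$lx) + counts %*% lp
}

pois_logdens <- function(counts, lambda) {
  ll <- numeric(nrow(counts))
  for (j in seq_len(ncol(counts)))
    ll <- ll + dpois(counts[, j], pmax(lambda[j], 1e-10), log = TRUE)
  ll
}

# n x K matrix of per-bin per-state emission log-densities
emission_logdens <- function(model, counts) {
  counts <- as.matrix(counts)
  K <- model$K
  n <- nrow(counts)
  out <- matrix(0, n, K)
  if (model$emission == "negmultinom") {
    totals <- rowSums(counts)
    cache <- list(lt = lgamma(totals + 1), lx = lgamma(counts + 1))
    for (k in seq_len(K)) {
      out[, k] <- nm_logdens(counts, totals, model$mu[k], model$size[k],
                             model$p[k, ], cache)
    }
  } else {
    for (k in seq_len(K)) out[, k] <- pois_logdens(counts, model$lambda[k, ])
  }
  out
}

#' Per-state expected channel means of a segmentation model
#' @keywords internal
model_means <- function(model) {
  if (model$emission == "negmultinom") model$mu * model$p
  else model$lambda
}

## ---- forward / backward ----------------------------------------------------

# Scaled forward-backward. Returns log-likelihood, gamma (n x K posterior
# marginals) and summed xi (K x K expected transition counts).
forward_backward <- function(pi, A, logB) {
  n <- nrow(logB); K <- ncol(logB)
  # stabilize each row of logB before exponentiating
  m <- apply(logB, 1, max)
  m[!is.finite(m)] <- 0
  B <- exp(logB - m)
  alpha <- matrix(0, n, K)
  cvec <- numeric(n)
  a <- pi * B[1, ]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) return(list(loglik = -Inf))
  alpha[1, ] <- a / cvec[1]
  tA <- t(A)
  for (t in 2:n) {
    a <- (tA %*% alpha[t - 1, ])[, 1] * B[t, ]
    cvec[t] <- sum(a)
    if (cvec[t] <= 0) return(list(loglik = -Inf))
    alpha[t, ] <- a / cvec[t]
  }
  loglik <- sum(log(cvec)) + sum(m)
  beta <- matrix(0, n, K)
  beta[n, ] <- 1
  xi <- matrix(0, K, K)
  for (t in (n - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    beta[t, ] <- (A %*% bb)[, 1] / cvec[t + 1]
    xi <- xi + A * (alpha[t, ] %o% bb) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = loglik, gamma = gamma, xi = xi)
}

#' Forward log-likelihood of a track under a segmentation model
#'
#' Scaled forward recursion. A bin whose emission probability is zero in all
#' states makes the whole sequence impossible; the sentinel `-Inf` is
#' returned in that case.
#'
#' @param model a `segmentation_model` from [fit_hmm()].
#' @param track a [track_matrix()] (or bare count matrix) with the same
#'   channels the model was fitted on.
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
forward_loglik <- function(model, track) {
  counts <- if (inherits(track, "track_matrix")) track$counts else as.matrix(track)
  if (ncol(counts) != model$n_channels)
    stop("track has ", ncol(counts), " channels but model expects ", model$n_channels)
  logB <- emission_logdens(model, counts)
  if (nrow(counts) == 1L) {
    return(logsumexp(log(model$pi) + logB[1, ]))
  }
  forward_backward(model$pi, model$A, logB)$loglik
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## ---- EM --------------------------------------------------------------------

new_segmentation_model <- function(K, pi, A, emission, n_channels,
                                   mu = NULL, size = NULL, p = NULL,
                                   lambda = NULL, loglik_trace = numeric()) {
  structure(list(K = K, pi = pi, A = A, emission = emission,
                 n_channels = n_channels, mu = mu, size = size, p = p,
                 lambda = lambda, loglik_trace = loglik_trace),
            class = "segmentation_model")
}

# weighted NB dispersion: maximize weighted log-likelihood over log(size)
fit_nb_size <- function(totals, w, mu) {
  f <- function(ls) -sum(w * dnbinom(totals, size = exp(ls), mu = mu, log = TRUE))
  opt <- optimize(f, c(-7, 12))
  exp(opt$minimum)
}

#' Fit a K-state hidden Markov model to a binned signal track
#'
#' Baum–Welch EM with per-state negative-multinomial count emissions (the
#' per-bin channel total is negative binomial with state-specific mean and
#' dispersion, split across channels by state-specific proportions), or
#' independent Poisson emissions per channel. Initialization seeds state
#' means with k-means on `log1p(counts)`; several restarts are run and the
#' best local optimum kept. The per-iteration log-likelihood trace is stored
#' and checked to be non-decreasing.
#'
#' @param track a [track_matrix()].
#' @param K number of states.
#' @param max_iter maximum EM iterations per restart (default 100).
#' @param tol relative log-likelihood change for convergence (default 1e-6).
#' @param seed RNG seed for initialization.
#' @param emission `"negmultinom"` (default) or `"poisson"`.
#' @param n_restarts number of k-means initializations (default 3).
#' @return a `segmentation_model`: `pi`, `A`, emission parameters, and
#'   `loglik_trace` of the winning restart.
#' @export
fit_hmm <- function(track, K, max_iter = 100L, tol = 1e-6, seed = 1L,
                    emission = c("negmultinom", "poisson"), n_restarts = 3L) {
  emission <- match.arg(emission)
  counts <- if (inherits(track, "track_matrix")) track$counts else as.matrix(track)
  n <- nrow(counts); C <- ncol(counts)
  stopifnot(K >= 1, n >= K)
  if (K == 1L) {
    model <- moment_model_1state(counts, emission)
    model$loglik_trace <- forward_loglik(model, counts)
    return(model)
  }
  if (all(counts == 0))
    message("all-zero track: EM will converge to a degenerate model")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    init <- kmeans_init(counts, K, emission)
    fit <- run_em(counts, init, max_iter, tol)
    if (is.null(best) || tail_ll(fit) > tail_ll(best)) best <- fit
  }
  best
}

tail_ll <- function(m) {
  tr <- m$loglik_trace
  if (length(tr) == 0) -Inf else tr[length(tr)]
}

moment_model_1state <- function(counts, emission) {
  C <- ncol(counts)
  if (emission == "negmultinom") {
    totals <- rowSums(counts)
    mu <- mean(totals)
    p <- colSums(counts) / max(sum(counts), 1)
    if (sum(counts) == 0) p <- rep(1 / C, C)
    size <- if (var(totals) > mu) mu^2 / (var(totals) - mu) else 1e4
    new_segmentation_model(1L, 1, matrix(1, 1, 1), emission, C,
                           mu = mu, size = max(size, 1e-3), p = matrix(p, 1))
  } else {
    new_segmentation_model(1L, 1, matrix(1, 1, 1), emission, C,
                           lambda = matrix(colMeans(counts), 1))
  }
}

kmeans_init <- function(counts, K, emission) {
  C <- ncol(counts)
  cl <- tryCatch(
    suppressWarnings(kmeans(log1p(counts), centers = K, nstart = 5,
                            iter.max = 30))$cluster,
    error = function(e) sample(rep_len(seq_len(K), nrow(counts))))
  pi <- rep(1 / K, K)
  A <- matrix(0.1 / (K - 1), K, K); diag(A) <- 0.9
  if (emission == "negmultinom") {
    totals <- rowSums(counts)
    mu <- size <- numeric(K)
    p <- matrix(0, K, C)
    for (k in seq_len(K)) {
      sel <- cl == k
      mu[k] <- max(mean(totals[sel]), 1e-3)
      s <- colSums(counts[sel, , drop = FALSE])
      p[k, ] <- if (sum(s) > 0) s / sum(s) else rep(1 / C, C)
      v <- var(totals[sel])
      size[k] <- if (isTRUE(v > mu[k])) mu[k]^2 / (v - mu[k]) else 10
      size[k] <- min(max(size[k], 1e-2), 1e4)
    }
    new_segmentation_model(K, pi, A, emission, C, mu = mu, size = size, p = p)
  } else {
    lambda <- matrix(0, K, C)
    for (k in seq_len(K))
      lambda[k, ] <- pmax(colMeans(counts[cl == k, , drop = FALSE]), 1e-6)
    new_segmentation_model(K, pi, A, emission, C, lambda = lambda)
  }
}

run_em <- function(counts, model, max_iter, tol) {
  K <- model$K
  totals <- rowSums(counts)
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- emission_logdens(model, counts)
    fb <- forward_backward(model$pi, model$A, logB)
    if (!is.finite(fb$loglik)) break
    if (fb$loglik < prev - 1e-6 * max(1, abs(prev)))
      warning("EM log-likelihood decreased beyond numerical slack")
    trace <- c(trace, fb$loglik)
    if (is.finite(prev) &&
        abs(fb$loglik - prev) <= tol * max(1, abs(prev))) break
    prev <- fb$loglik
    g <- fb$gamma
    model$pi <- g[1, ] / sum(g[1, ])
    A <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
    model$A <- A
    wsum <- colSums(g)
    if (model$emission == "negmultinom") {
      for (k in seq_len(K)) {
        w <- g[, k]
        model$mu[k] <- max(sum(w * totals) / wsum[k], 1e-6)
        ch <- colSums(counts * w)
        model$p[k, ] <- if (sum(ch) > 0) ch / sum(ch) else rep(1 / ncol(counts), ncol(counts))
        model$size[k] <- fit_nb_size(totals, w, model$mu[k])
      }
    } else {
      for (k in seq_len(K))
        model$lambda[k, ] <- pmax(colSums(counts * g[, k]) / wsum[k], 1e-10)
    }
  }
  model$loglik_trace <- trace
  model
}

## ---- decoding --------------------------------------------------------------

#' Decode a chromatin-state track from a fitted model
#'
#' Posterior mode (default): per-bin argmax of the forward-backward
#' marginals, with posteriors stored. Viterbi mode: the single most probable
#' state path. Argmax ties break to the lowest state index.
#'
#' @param model a `segmentation_model`.
#' @param track a [track_matrix()] or count matrix.
#' @param mode `"posterior"` or `"viterbi"`.
#' @return object of class `state_track`: list with `states` (integer vector),
#'   `posteriors` (n x K matrix, posterior mode only), `bins` when available.
#' @export
decode_states <- function(model, track, mode = c("posterior", "viterbi")) {
  mode <- match.arg(mode)
  bins <- if (inherits(track, "track_matrix")) track$bins else NULL
  counts <- if (inherits(track, "track_matrix")) track$counts else as.matrix(track)
  if (ncol(counts) != model$n_channels)
    stop("track has ", ncol(counts), " channels but model expects ", model$n_channels)
  logB <- emission_logdens(model, counts)
  n <- nrow(counts); K <- model$K
  if (mode == "posterior") {
    if (K == 1L) {
      post <- matrix(1, n, 1)
    } else {
      fb <- forward_backward(model$pi, model$A, logB)
      if (!is.finite(fb$loglik)) stop("track impossible under model")
      post <- fb$gamma
    }
    states <- apply(post, 1, which.max)   # which.max: first (lowest) index on ties
    structure(list(bins = bins, states = as.integer(states), posteriors = post),
              class = "state_track")
  } else {
    lpi <- log(model$pi); lA <- log(pmax(model$A, 1e-300))
    delta <- matrix(-Inf, n, K)
    psi <- matrix(0L, n, K)
    delta[1, ] <- lpi + logB[1, ]
    if (n > 1) for (t in 2:n) {
      for (k in seq_len(K)) {
        v <- delta[t - 1, ] + lA[, k]
        psi[t, k] <- which.max(v)
        delta[t, k] <- v[psi[t, k]] + logB[t, k]
      }
    }
    states <- integer(n)
    states[n] <- which.max(delta[n, ])
    if (n > 1) for (t in (n - 1):1) states[t] <- psi[t + 1, states[t + 1]]
    structure(list(bins = bins, states = states, posteriors = NULL),
              class = "state_track")
  }
}

#' Per-state expected-count emission summary
#'
#' One row per state giving the expected count in every channel, with an
#' optional user-supplied state label map (manual annotation of states such
#' as "A" active, "M" bivalent, "S" silent).
#'
#' @param model a `segmentation_model`.
#' @param mark_names optional channel names (defaults to the model's).
#' @param label_map optional character vector of length K, or named vector
#'   mapping state index to label.
#' @return data.frame: `state`, `label`, one column per channel.
#' @export
emission_summary <- function(model, mark_names = NULL, label_map = NULL) {
  mm <- model_means(model)
  K <- model$K
  if (is.null(mark_names)) mark_names <- paste0("channel_", seq_len(ncol(mm)))
  stopifnot(length(mark_names) == ncol(mm))
  labels <- paste0("state_", seq_len(K))
  if (!is.null(label_map)) {
    if (!is.null(names(label_map))) {
      idx <- as.integer(names(label_map))
      if (any(is.na(idx)) || any(idx < 1) || any(idx > K))
        stop("label map references unknown states")
      labels[idx] <- unname(label_map)
    } else {
      if (length(label_map) != K) stop("label map references unknown states")
      labels <- label_map
    }
  }
  out <- data.frame(state = seq_len(K), label = labels)
  colnames(mm) <- mark_names
  cbind(out, as.data.frame(mm))
}
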