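# Shared fixtures, all generated in code.

# small end-to-end simulation reused across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sim_spec(n_bins = 4000, seed = 101)
      st <- simulate_state_track(spec)
      tr <- simulate_tracks(st, spec)
      gm <- simulate_gene_models(st, 400, seed = 102)
      cache <<- list(spec = spec, st = st, tr = tr, gm = gm)
    }
    cache
  }
})

# brute-force forward log-likelihood by path enumeration (independent oracle)
brute_force_loglik <- function(model, counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts); K <- model$K
  logB <- epistate:::emission_logdens(model, counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1, function(s) {
    v <- log(model$pi[s[1]]) + logB[1, s[1]]
    if (n > 1) for (t in 2:n)
      v <- v + log(model$A[s[t - 1], s[t]]) + logB[t, s[t]]
    v
  })
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

# brute-force best path (Viterbi oracle)
brute_force_best_path <- function(model, counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts); K <- model$K
  logB <- epistate:::emission_logdens(model, counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1, function(s) {
    v <- log(model$pi[s[1]]) + logB[1, s[1]]
    if (n > 1) for (t in 2:n)
      v <- v + log(model$A[s[t - 1], s[t]]) + logB[t, s[t]]
    v
  })
  as.integer(paths[which.max(lp), ])
}

# brute-force sliding-window median methylation transform (independent oracle)
brute_force_meth <- function(cpg, bins, window = 600L, scale = 10L) {
  flank <- (window - bins$bin_size) %/% 2L
  out <- integer(bins$n_bins)
  for (i in seq_len(bins$n_bins)) {
    ws <- (i - 1L) * bins$bin_size - flank
    we <- ws + window
    sel <- (cpg$pos - 1L) >= ws & (cpg$pos - 1L) < we
    if (any(sel)) out[i] <- as.integer(floor(scale * (100 - median(cpg$meth[sel])) / 100 + 0.5))
  }
  out
}

# fixed small Poisson-emission model for oracle tests
toy_model <- function(K = 2, C = 2) {
  lambda <- matrix(seq(1, K * C), K, C)
  A <- matrix(0.2 / (K - 1), K, K); diag(A) <- 0.8
  epistate:::new_segmentation_model(
    K = K, pi = rep(1 / K, K), A = A, emission = "poisson",
    n_channels = C, lambda = lambda)
}
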