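test_that("bin_signal applies the midpoint rule and averages replicates", {
  bins <- genome_bins(n_bins = 5, bin_size = 200)
  # fragment (50,250): midpoint 150 -> bin 1
  v <- bin_signal(data.frame(start = 50, end = 250), bins)
  expect_equal(as.integer(v), c(1L, 0L, 0L, 0L, 0L))
  # empty input
  expect_equal(as.integer(bin_signal(data.frame(start = integer(), end = integer()), bins)),
               rep(0L, 5))
  # replicates with per-bin counts 2 and 4 average to 3
  reps <- data.frame(
    start = c(rep(10, 2), rep(10, 4)), end = c(rep(20, 2), rep(20, 4)),
    replicate = c(1, 1, 2, 2, 2, 2))
  expect_equal(as.integer(bin_signal(reps, bins))[1], 3L)
  # averaging rounds half-up: counts 1 and 2 -> 1.5 -> 2
  reps2 <- data.frame(start = c(10, 10, 10), end = c(20, 20, 20),
                      replicate = c(1, 2, 2))
  expect_equal(as.integer(bin_signal(reps2, bins))[1], 2L)
  # out-of-bounds fragments skipped with warning
  expect_warning(v2 <- bin_signal(data.frame(start = c(10, 5000), end = c(20, 5100)), bins),
                 "skipped")
  expect_equal(attr(v2, "n_skipped"), 1L)
  # total count conserved for in-bounds fragments
  set.seed(1)
  frags <- data.frame(start = sample(0:900, 200, TRUE))
  frags$end <- frags$start + 80
  expect_equal(sum(bin_signal(frags, bins)), 200)
})

test_that("methylation transform matches formula, edge cases and oracle", {
  bins <- genome_bins(n_bins = 3, bin_size = 200)
  # all CpGs fully methylated -> all zero
  cpg <- data.frame(pos = c(50, 250, 450), meth = c(100, 100, 100))
  expect_equal(transform_methylation(cpg, bins), rep(0L, 3))
  # direct formula: window CpGs {20,40,60} -> median 40 -> round(10*0.6)=6
  cpg2 <- data.frame(pos = c(210, 250, 300), meth = c(20, 40, 60))
  expect_equal(transform_methylation(cpg2, bins)[2], 6L)
  # empty window -> 0 (bin 3's window is [200, 800); CpG at 100 outside)
  expect_equal(transform_methylation(data.frame(pos = 100, meth = 10), bins)[3], 0L)
  # out-of-range input rejected
  expect_error(transform_methylation(data.frame(pos = 1, meth = 101), bins),
               "\\[0, 100\\]")
  # brute-force sliding-median oracle on random layouts; invariance to order
  set.seed(42)
  bins10 <- genome_bins(n_bins = 10, bin_size = 200)
  for (i in 1:200) {
    n <- sample(0:40, 1)
    cpg <- data.frame(pos = sample.int(2000, n), meth = runif(n, 0, 100))
    got <- transform_methylation(cpg, bins10)
    expect_identical(got, brute_force_meth(cpg, bins10))
    expect_identical(got, transform_methylation(cpg[sample.int(n), , drop = FALSE], bins10))
  }
  # monotone decreasing in the median methylation level
  vals <- vapply(c(90, 60, 30, 0), function(m)
    transform_methylation(data.frame(pos = 250, meth = m), bins)[2], integer(1))
  expect_true(all(diff(vals) > 0))
})

test_that("forward log-likelihood matches closed form and path enumeration", {
  model <- toy_model(K = 2, C = 2)
  # single bin: log sum_k pi_k e_k(x)
  x1 <- matrix(c(2, 3), 1, 2)
  logB <- epistate:::emission_logdens(model, x1)
  direct <- log(sum(model$pi * exp(logB[1, ])))
  expect_equal(forward_loglik(model, x1), direct, tolerance = 1e-10)
  # exhaustive enumeration for all instances with <= 8 bins, K <= 3
  set.seed(7)
  for (K in 2:3) for (n in c(2, 4, 8)) {
    m <- toy_model(K = K, C = 2)
    counts <- matrix(rpois(n * 2, 3), n, 2)
    expect_equal(forward_loglik(m, counts), brute_force_loglik(m, counts),
                 tolerance = 1e-8)
  }
  # impossible-emission bin (probability 0 in all states) -> -Inf sentinel
  logB <- matrix(log(0.5), 3, 2)
  logB[2, ] <- -Inf
  fb <- epistate:::forward_backward(model$pi, model$A, logB)
  expect_identical(fb$loglik, -Inf)
  # dimension mismatch
  expect_error(forward_loglik(model, matrix(1, 3, 5)), "channels")
})

test_that("decoding matches brute-force best path and normalizes posteriors", {
  set.seed(11)
  for (K in 2:3) for (n in c(4, 8)) {
    m <- toy_model(K = K, C = 2)
    counts <- matrix(rpois(n * 2, 4), n, 2)
    vit <- decode_states(m, counts, mode = "viterbi")
    expect_equal(vit$states, brute_force_best_path(m, counts))
    post <- decode_states(m, counts, mode = "posterior")
    expect_equal(rowSums(post$posteriors), rep(1, n), tolerance = 1e-8)
    expect_true(all(post$states %in% seq_len(K)))
  }
})

test_that("K=1 fit reduces to moment matching", {
  bins <- genome_bins(n_bins = 50, bin_size = 200)
  set.seed(3)
  counts <- matrix(rpois(100, 5), 50, 2)
  tm <- track_matrix(counts, bins)
  fit <- fit_hmm(tm, K = 1)
  expect_equal(dim(fit$A), c(1L, 1L))
  expect_equal(fit$A[1, 1], 1)
  expect_equal(as.vector(epistate:::model_means(fit)), colMeans(counts),
               tolerance = 1e-8)
  summ <- emission_summary(fit, c("a", "b"))
  expect_equal(unlist(summ[1, c("a", "b")], use.names = FALSE), colMeans(counts),
               tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing across random fits", {
  bins <- genome_bins(n_bins = 300, bin_size = 200)
  for (s in 1:20) {
    set.seed(s)
    lam <- matrix(c(2, 10, 12, 3), 2, 2)
    st <- rep(1:2, length.out = 300)
    counts <- cbind(rpois(300, lam[st, 1]), rpois(300, lam[st, 2]))
    fit <- fit_hmm(track_matrix(counts, bins), K = 2, seed = s, max_iter = 30)
    tr <- fit$loglik_trace
    expect_gt(length(tr), 0)
    expect_true(all(diff(tr) >= -1e-6 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("emission summary labels states and validates the label map", {
  fx <- small_sim()
  meth <- transform_methylation(fx$tr$cpg, fx$tr$bins)
  tm <- track_matrix(fx$tr$counts, fx$tr$bins, meth)
  fit <- fit_hmm(tm, K = 3, seed = 1)
  summ <- emission_summary(fit)
  expect_equal(summ$label, paste0("state_", 1:3))
  summ2 <- emission_summary(fit, label_map = c("A", "M", "S"))
  expect_equal(summ2$label, c("A", "M", "S"))
  expect_error(emission_summary(fit, label_map = setNames("X", "9")),
               "unknown states")
  # recovered per-state means match truth after label matching (within 10%)
  dec <- decode_states(fit, tm)
  mm <- match_labels(fx$st, dec$states)
  expect_gt(mm$accuracy, 0.9)
  perm <- match(1:3, mm$map)   # model state index for each true state
  got <- epistate:::model_means(fit)[perm, seq_len(ncol(fx$tr$counts))]
  expect_lt(max(abs(got - fx$spec$emission_means) /
                  pmax(fx$spec$emission_means, 1)), 0.1)
})

test_that("all-zero tracks converge to a degenerate model without error", {
  bins <- genome_bins(n_bins = 60, bin_size = 200)
  tm <- track_matrix(matrix(0, 60, 2), bins)
  expect_message(fit <- fit_hmm(tm, K = 2, seed = 1, max_iter = 10),
                 "degenerate")
  expect_true(is.finite(tail(fit$loglik_trace, 1)))
})
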