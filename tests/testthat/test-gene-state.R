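bins8 <- genome_bins(n_bins = 8, bin_size = 200)

test_that("GTF loading converts coordinates and applies study filters", {
  genes <- data.frame(
    gene_id = paste0("G", 1:5), name = paste0("g", 1:5),
    chrom = c("chrS", "chrS", "X", "chrS", "chrS"),
    start = c(1000L, 200L, 50L, 400L, 600L),
    end = c(1600L, 400L, 450L, 800L, 1000L),
    strand = c("+", "-", "+", "+", "-"),
    biotype = c("protein_coding", "pseudogene", "protein_coding",
                "lincRNA", "protein_coding"),
    basic = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    tss = 0L, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gtf")
  write_gtf(genes, path)
  got <- load_gene_models(path)
  # pseudogene, chromosome X, and non-basic genes are excluded
  expect_setequal(got$gene_id, c("G1", "G4"))
  lg <- attr(got, "filter_log")
  expect_equal(unname(lg["dropped_chrom"]), 1)
  expect_equal(unname(lg["dropped_biotype"]), 1)
  expect_equal(unname(lg["dropped_basic"]), 1)
  # GTF 1-based closed -> stored 0-based half-open round trip
  g1 <- got[got$gene_id == "G1", ]
  expect_equal(g1$start, 1000L)
  expect_equal(g1$end, 1600L)
  expect_equal(g1$tss, 1000L)
})

test_that("gene state coverage, argmax and tie-breaks are exact", {
  # gene spanning 4 full bins with states A,A,B,C
  states <- c(1L, 1L, 2L, 3L, 1L, 1L, 1L, 1L)
  g <- data.frame(gene_id = "g1", chrom = "chrS", start = 0L, end = 800L,
                  strand = "+", tss = 0L)
  gs <- assign_gene_states(g, states, bins8)
  expect_equal(unlist(gs[1, paste0("coverage_", 1:3)], use.names = FALSE),
               c(0.5, 0.25, 0.25))
  expect_equal(gs$genebody_state, 1L)
  # exact 50/50 tie -> lower state index wins
  g2 <- data.frame(gene_id = "g2", chrom = "chrS", start = 400L, end = 800L,
                   strand = "+", tss = 400L)
  gs2 <- assign_gene_states(g2, states, bins8)
  expect_equal(gs2$genebody_state, 2L)
  # reversed tie order still gives the lower index
  g3 <- data.frame(gene_id = "g3", chrom = "chrS", start = 200L, end = 600L,
                   strand = "+", tss = 200L)
  gs3 <- assign_gene_states(g3, states, bins8)
  expect_equal(gs3$genebody_state, 1L)
  # partial bins weighted by bp: 100 bp in state 1 bin, 200 in state-2 bin
  g4 <- data.frame(gene_id = "g4", chrom = "chrS", start = 300L, end = 600L,
                   strand = "+", tss = 300L)
  gs4 <- assign_gene_states(g4, states, bins8)
  expect_equal(gs4$coverage_1[1], 1 / 3)
  expect_equal(gs4$coverage_2[1], 2 / 3)
  # TSS state is the state of the TSS bin
  g5 <- data.frame(gene_id = "g5", chrom = "chrS", start = 500L, end = 900L,
                   strand = "+", tss = 500L)
  expect_equal(assign_gene_states(g5, states, bins8)$tss_state, 2L)
  # zero-overlap gene excluded with warning
  g6 <- data.frame(gene_id = "g6", chrom = "chrS", start = 5000L, end = 5400L,
                   strand = "+", tss = 5000L)
  expect_warning(out <- assign_gene_states(rbind(g5, g6), states, bins8),
                 "excluded")
  expect_equal(out$gene_id, "g5")
})

test_that("coverage vector matrix is row-normalized and deterministic", {
  states <- c(1L, 1L, 2L, 3L, 1L, 1L, 1L, 1L)
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "chrS",
                  start = c(0L, 0L, 800L), end = c(800L, 800L, 1000L),
                  strand = "+", tss = c(0L, 0L, 800L))
  m <- gene_state_vector_matrix(assign_gene_states(g, states, bins8))
  expect_equal(rowSums(m), setNames(rep(1, 3), c("a", "b", "c")))
  # identical coverage -> identical rows
  expect_equal(m["a", ], m["b", ])
  # single-state gene -> one-hot row
  expect_equal(unname(m["c", ]), c(1, 0, 0))
})

test_that("peak breadth follows the widest-overlap rule and min-tie ranks", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chrS",
                      tss = c(400L, 2000L, 9000L))
  peaks <- data.frame(chrom = "chrS",
                      start = c(100L, 1800L, 1900L),
                      end = c(700L, 2200L, 2800L))
  br <- peak_breadth_rank(peaks, genes, tss_window = 500)
  # single overlapping peak: breadth = end - start
  expect_equal(br$breadth[br$gene_id == "g1"], 600)
  # two overlapping peaks of 400 and 900 bp: widest wins
  expect_equal(br$breadth[br$gene_id == "g2"], 900)
  # no peak near TSS: breadth 0, ranked last
  expect_equal(br$breadth[br$gene_id == "g3"], 0)
  expect_equal(br$rank[br$gene_id == "g3"], 3)
  expect_error(peak_breadth_rank(peaks, genes, tss_window = -1), "nonnegative")
  # invariant to peak input order; ties share the minimum rank
  br2 <- peak_breadth_rank(peaks[c(3, 1, 2), ], genes, tss_window = 500)
  expect_equal(br2[order(br2$gene_id), ], br[order(br$gene_id), ])
  tie <- peak_breadth_rank(data.frame(chrom = "chrS", start = c(0L, 1700L),
                                      end = c(600L, 2300L)),
                           genes, tss_window = 500)
  expect_equal(sort(tie$rank), c(1, 1, 3))
})

test_that("top broad geneset slices by ceiling with exclusions", {
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:100),
                       breadth = 101 - (1:100), rank = 1:100)
  expect_equal(top_broad_geneset(ranked, 2), c("g001", "g002"))
  # excluded gene inside the slice is replaced by the next-ranked gene
  expect_equal(top_broad_geneset(ranked, 2, exclude = "g001"), c("g002", "g003"))
  expect_length(top_broad_geneset(ranked, 100, exclude = c("g005", "g006")), 98)
  expect_equal(length(top_broad_geneset(ranked, 2.5)), ceiling(0.025 * 100))
  expect_error(top_broad_geneset(ranked[0, ], 2), "empty")
})

test_that("TSS AUC normalizes by depth and truncates at bounds", {
  gene <- data.frame(gene_id = "g", tss = 500L)
  cov <- rep(0, 2000)
  expect_equal(tss_auc(cov, gene, 100, library_size = 1e6), 0)
  # constant coverage c: AUC = c * (2*flank+1) * 1e6/lib
  cov2 <- rep(3, 2000)
  expect_equal(tss_auc(cov2, gene, 100, library_size = 2e6),
               3 * 201 * 1e6 / 2e6)
  # doubling both coverage and library size leaves AUC unchanged
  expect_equal(tss_auc(cov2 * 2, gene, 100, library_size = 4e6),
               tss_auc(cov2, gene, 100, library_size = 2e6))
  # window past the chromosome start is truncated with a warning
  gene0 <- data.frame(gene_id = "g0", tss = 20L)
  expect_warning(a <- tss_auc(cov2, gene0, 100, library_size = 1e6),
                 "truncated")
  expect_equal(a, 3 * 121)
})

test_that("metagene profiles are strand-aware and compose linearly", {
  glen <- 6000
  # constant coverage -> flat profile
  genes <- data.frame(gene_id = "g", chrom = "chrS", start = 2000L,
                      end = 3000L, strand = "+")
  p <- metagene_profile(rep(2, glen), genes, upstream = 500, body_bins = 10,
                        downstream = 500, library_size = 1e6)
  expect_equal(p, rep(2 * 1e6 / 1e6, 30))
  # minus-strand gene with a ramp: profile is the reversed ramp
  ramp <- seq_len(glen)
  gplus <- genes
  gminus <- transform(genes, strand = "-")
  pp <- metagene_profile(ramp, gplus, 500, 10, 500, library_size = 1e6)
  pm <- metagene_profile(ramp, gminus, 500, 10, 500, library_size = 1e6)
  expect_equal(pm, rev(pp))
  # profile of a union of sets = weighted mean of per-set profiles
  set.seed(5)
  cov <- runif(glen, 0, 10)
  gs1 <- data.frame(gene_id = c("a", "b"), chrom = "chrS",
                    start = c(1000L, 2500L), end = c(1800L, 3700L), strand = "+")
  gs2 <- data.frame(gene_id = "c", chrom = "chrS", start = 4000L,
                    end = 4600L, strand = "-")
  p1 <- metagene_profile(cov, gs1, 500, 10, 500, library_size = 1e6)
  p2 <- metagene_profile(cov, gs2, 500, 10, 500, library_size = 1e6)
  pu <- metagene_profile(cov, rbind(gs1, gs2), 500, 10, 500, library_size = 1e6)
  expect_equal(pu, (2 * p1 + 1 * p2) / 3)
  # gene shorter than body_bins is interpolated, with a log message
  tiny <- data.frame(gene_id = "t", chrom = "chrS", start = 100L, end = 105L,
                     strand = "+")
  expect_message(metagene_profile(cov, tiny, 100, 10, 100, library_size = 1e6),
                 "interpolation")
})
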