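test_that("truth generation is deterministic and non-overlapping per tissue", {
  cfg <- small_sim_config(seed = 5)
  t1 <- build_truth(cfg)
  t2 <- build_truth(cfg)
  expect_identical(t1$cpg, t2$cpg)
  expect_identical(t1$segments, t2$segments)

  for (tis in c("A", "B")) {
    s <- t1$segments[t1$segments$tissue == tis, ]
    s <- s[order(s$chrom, s$start), ]
    by_chr <- split(s, s$chrom)
    for (x in by_chr) {
      expect_true(all(diff(x$start) > 0))
      expect_true(all(utils::head(x$end, -1) <= utils::tail(x$start, -1)))
    }
  }
  expect_true(all(diff(t1$cpg$pos[t1$cpg$chrom == t1$cpg$chrom[1]]) > 0))
})

test_that("tissue-specific segments carry the four-level means", {
  truth <- build_truth(small_sim_config(seed = 2))
  spec_a <- truth$segments[truth$segments$class == "SPEC_A", ]
  expect_gt(nrow(spec_a), 0)
  inside <- truth$cpg$pos >= spec_a$start[1] &
    truth$cpg$pos < spec_a$end[1] & truth$cpg$chrom == spec_a$chrom[1]
  expect_true(all(truth$cpg$mu_A[inside] == 0.25))
  expect_true(all(truth$cpg$mu_B[inside] == 0.60))
  common <- truth$segments[truth$segments$class == "COMMON", ]
  inside <- truth$cpg$pos >= common$start[1] &
    truth$cpg$pos < common$end[1] & truth$cpg$chrom == common$chrom[1]
  expect_true(all(truth$cpg$mu_A[inside] == 0.03))
  expect_true(all(truth$cpg$mu_B[inside] == 0.03))
})

test_that("methylome simulation hits the configured means", {
  # degenerate truth: zero methylation everywhere
  t0 <- mk_truth(seq(0, 999) * 50L, mu_a = 0)
  m0 <- simulate_methylome(t0, "A")
  expect_true(all(m0$meth == 0L))

  # law of large numbers at background level 0.70, 36X, k = 20
  n <- 50000
  t7 <- mk_truth(seq_len(n) * 40L, mu_a = 0.7, chrom_len = n * 40 + 1000)
  m7 <- simulate_methylome(t7, "A", lambda = 36, k = 20)
  expect_equal(mean(m7$cov), 36, tolerance = 0.01)
  expect_equal(mean(meth_level(m7), na.rm = TRUE), 0.70, tolerance = 0.01 / 0.70)
  expect_equal(nrow(m7), n)  # zero-coverage sites are retained

  # planted-level recovery per class mean at >= 20k sites per level
  for (mu in c(0.03, 0.25, 0.60)) {
    tt <- mk_truth(seq_len(20000) * 40L, mu_a = mu, chrom_len = 2e6 * 40)
    mm <- simulate_methylome(tt, "A", lambda = 36, k = 20)
    expect_equal(mean(meth_level(mm), na.rm = TRUE), mu, tolerance = 0.02 / mu)
  }

  # determinism
  truth <- build_truth(small_sim_config())
  m1 <- simulate_methylome(truth, "A", seed = 99)
  m2 <- simulate_methylome(truth, "A", seed = 99)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("motif hit placement respects count, determinism and the null", {
  truth <- build_truth(small_sim_config())
  expect_equal(nrow(simulate_motif_hits(truth, n_hits = 0)), 0L)

  h1 <- simulate_motif_hits(truth, n_hits = 500, seed = 4)
  h2 <- simulate_motif_hits(truth, n_hits = 500, seed = 4)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 500L)
  expect_true(all(h1$end - h1$start == 10L))

  f <- simulate_motif_hits(truth, n_hits = 500, fold = 5,
                           target_class = "SPEC_A", seed = 4)
  expect_equal(nrow(f), 500L)
  expect_error(simulate_motif_hits(truth, n_hits = 10, fold = 1e6,
                                   target_class = "SPEC_A"),
               "infeasible")
})

test_that("simulated peaks land where requested", {
  truth <- build_truth(small_sim_config())
  p <- simulate_peaks(truth, n_in_hmr = 6, n_in_methylated = 6,
                      width = 150)
  expect_equal(nrow(p), 12L)
  expect_equal(sum(p$placement == "in_hmr"), 6L)
  common <- truth$segments[truth$segments$class == "COMMON", ]
  inh <- p[p$placement == "in_hmr", ]
  for (i in seq_len(nrow(inh))) {
    hit <- common$chrom == inh$chrom[i] & common$start <= inh$start[i] &
      common$end >= inh$end[i]
    expect_true(any(hit))
  }
  bg <- p[p$placement == "background", ]
  all_segs <- truth$segments
  for (i in seq_len(nrow(bg))) {
    touching <- all_segs$chrom == bg$chrom[i] &
      all_segs$start < bg$end[i] & all_segs$end > bg$start[i]
    expect_false(any(touching))
  }
  expect_identical(simulate_peaks(truth, 3, 3, seed = 8),
                   simulate_peaks(truth, 3, 3, seed = 8))
})

test_that("toy genes put common segments in promoters", {
  truth <- build_truth(small_sim_config())
  genes <- simulate_genes(truth, n_genes = 8)
  expect_equal(nrow(genes), 8L)
  common <- truth$segments[truth$segments$class == "COMMON",
                           c("chrom", "start", "end")]
  # at least one promoter window overlaps a common segment
  prom <- iv(genes$txStart - 2000L, genes$txStart, chrom = genes$chrom)
  expect_gt(interval_jaccard(prom, common), 0)
})
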