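test_that("level classes partition [0,1] with the stated boundaries", {
  expect_equal(as.character(classify_cpg_level(0.05)), "SPARSE")
  expect_equal(as.character(classify_cpg_level(0.10)), "LOW")
  expect_equal(as.character(classify_cpg_level(0.50)), "LOW")
  expect_equal(as.character(classify_cpg_level(0.51)), "HIGH")
  expect_equal(as.character(classify_cpg_level(0)), "SPARSE")
  expect_equal(as.character(classify_cpg_level(1)), "HIGH")
  expect_error(classify_cpg_level(1.2), "outside")
  # partition: every level gets exactly one class
  x <- seq(0, 1, by = 0.001)
  expect_false(any(is.na(classify_cpg_level(x))))
})

test_that("composition counts classes and restricts to regions", {
  m <- mk_methylome(c(100, 200, 300), c(0, 3, 9), c(10, 10, 10))
  comp <- composition(m)
  expect_equal(comp$n, c(1L, 1L, 1L))
  expect_equal(sum(comp$fraction), 1)

  inside <- composition(m, regions = iv(150L, 250L))
  expect_equal(sum(inside$n), 1L)
  expect_equal(inside$n[inside$class == "LOW"], 1L)

  none <- composition(m, regions = iv(integer(0), integer(0)))
  expect_equal(sum(none$n), 0L)
  expect_true(all(is.na(none$fraction)))
})

test_that("region means match a direct oracle", {
  m <- mk_methylome(c(100, 200), c(2, 4), c(10, 10))
  r <- region_mean_level(m, iv(0L, 1000L))
  expect_equal(r$mean_level, 0.3)
  expect_equal(r$n_cpg, 2L)
  expect_true(is.na(region_mean_level(m, iv(5000L, 6000L))$mean_level))

  set.seed(5)
  n <- 1000
  pos <- sort(sample.int(1e5, n))
  cov <- rpois(n, 20)
  mm <- mk_methylome(pos, rbinom(n, cov, 0.5), cov)
  reg <- iv(20000L, 70000L)
  got <- region_mean_level(mm, reg, min_cov = 5)
  sel <- pos >= 20000 & pos < 70000 & mm$cov >= 5
  expect_equal(got$mean_level, mean(mm$meth[sel] / mm$cov[sel]))
  expect_equal(got$n_cpg, sum(sel))
})

test_that("feature summary averages by assigned label", {
  g <- data.frame(chrom = "chr1", strand = "+", txStart = 10000L,
                  txEnd = 14000L, cdsStart = 10000L, cdsEnd = 14000L,
                  name = "g", stringsAsFactors = FALSE)
  g$exons <- list(data.frame(start = c(10000L, 12000L),
                             end = c(11000L, 14000L)))
  m <- mk_methylome(c(9000, 9500, 10200, 10800, 11500),
                    c(1, 1, 7, 9, 2), c(10, 10, 10, 10, 10))
  fs <- feature_summary(m, g)
  expect_equal(fs$mean_level[fs$feature == "Promoter"], 0.1)
  expect_equal(fs$mean_level[fs$feature == "Exon"], 0.8)
  expect_equal(fs$mean_level[fs$feature == "Intron"], 0.2)
  expect_equal(sum(fs$n), 5L)

  fs0 <- feature_summary(m, NULL)
  expect_true(all(is.na(fs0$mean_level[fs0$feature != "Intergenic"])))
  expect_equal(fs0$n[fs0$feature == "Intergenic"], 5L)
})

test_that("identical HMR sets leave the S1 levels missing", {
  set.seed(8)
  n <- 300
  cov <- rpois(n, 30)
  m <- mk_methylome(seq_len(n) * 50L, rbinom(n, cov, 0.5), cov)
  h <- iv(c(1000L, 5000L), c(2000L, 6000L))
  cmp <- compare_sets(h, h, c(chr1 = 20000), tau = 0)
  fl <- four_level_summary(cmp, m, m)
  expect_true(all(is.na(fl$mean_level[fl$class %in% c("ts_own",
                                                      "ts_other")])))
  expect_false(any(is.na(fl$mean_level[fl$class %in% c("common",
                                                       "background")])))
})

test_that("scaled matrices bin levels and conserve the region mean", {
  n <- 400
  m <- mk_methylome(seq_len(n) * 25L, 7, 10)
  reg <- iv(2000L, 6000L)
  sm <- scaled_matrix(reg, m, body_bins = 10, flank_bp = 1000,
                      flank_bins = 5)
  expect_equal(ncol(sm), 20L)
  vals <- sm[1, !is.na(sm[1, ])]
  expect_true(all(abs(vals - 0.7) < 1e-12))

  # region mean is conserved by CpG-weighted body cells
  set.seed(10)
  cov <- rpois(n, 20)
  m2 <- mk_methylome(seq_len(n) * 25L, rbinom(n, cov, 0.4), cov)
  sm2 <- scaled_matrix(reg, m2, body_bins = 7, flank_bp = 1000,
                       flank_bins = 4)
  cnt <- attr(sm2, "counts")
  body_cols <- 5:11
  w <- cnt[1, body_cols]
  got <- sum(sm2[1, body_cols] * w, na.rm = TRUE) / sum(w)
  expect_equal(got, region_mean_level(m2, reg)$mean_level)

  # a bin with no CpG is NA, not zero
  sparse <- mk_methylome(c(2100L, 5900L), c(2, 10), c(10, 10))
  sm3 <- scaled_matrix(reg, sparse, body_bins = 10, flank_bp = 1000,
                       flank_bins = 2)
  expect_true(any(is.na(sm3[1, ])))
  expect_setequal(sm3[1, !is.na(sm3[1, ])], c(0.2, 1.0))
})

test_that("neighbour correlation sees duplicated sites as r = 1", {
  set.seed(12)
  n <- 200
  base <- sort(sample.int(1e6, n)) * 50L
  lev <- runif(n)
  pos <- c(base, base + 2L)
  lv <- c(lev, lev)
  o <- order(pos)
  m <- mk_methylome(pos[o], round(lv[o] * 100), 100)
  nc <- neighbor_correlation(m, max_dist = 100, bin_width = 10)
  expect_equal(nc$r[1], 1.0, tolerance = 1e-6)
})

test_that("independent levels give near-zero correlation", {
  set.seed(13)
  n <- 11000
  m <- mk_methylome(seq_len(n) * 30L, round(runif(n) * 100), 100)
  nc <- neighbor_correlation(m, max_dist = 60, bin_width = 30)
  expect_gte(sum(nc$n_pairs), 10000)
  expect_true(all(abs(nc$r[!is.na(nc$r)]) < 0.05))
})

test_that("constant methylomes report missing correlation, not 0 or 1", {
  m <- mk_methylome(seq_len(100) * 10L, 5, 10)
  nc <- neighbor_correlation(m, max_dist = 50, bin_width = 10)
  expect_true(all(is.na(nc$r)))
  expect_gt(sum(nc$n_pairs), 0)
})

test_that("block-structured methylomes decay in correlation with distance", {
  set.seed(14)
  n_blocks <- 150
  block_levels <- runif(n_blocks)
  pos <- integer(0)
  lev <- numeric(0)
  for (b in seq_len(n_blocks)) {
    p <- (b - 1L) * 300L + seq(0L, 290L, by = 30L)
    pos <- c(pos, p)
    lev <- c(lev, rep(block_levels[b], length(p)))
  }
  noisy <- pmin(pmax(lev + rnorm(length(lev), 0, 0.05), 0), 1)
  m <- mk_methylome(pos, round(noisy * 1000), 1000)
  nc <- neighbor_correlation(m, max_dist = 600, bin_width = 100)
  expect_gt(nc$r[1], 0.7)
  expect_true(nc$r[1] > nc$r[3])
  expect_true(nc$r[3] > nc$r[6])
})
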