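test_that("overlap components follow A-B edges only", {
  a <- iv(0L, 100L)
  b0 <- iv(integer(0), integer(0))
  comps <- overlap_components(a, b0)
  expect_equal(length(comps), 1L)
  expect_equal(comps[[1]]$a, 1L)
  expect_equal(length(comps[[1]]$b), 0L)

  # B's second HMR overlaps B's first but not A: within-tissue overlap is
  # not an edge, so it forms its own component
  b <- iv(c(50L, 140L), c(150L, 200L))
  comps <- overlap_components(a, b)
  sizes <- sort(vapply(comps, function(x) length(x$a) + length(x$b),
                       integer(1)))
  expect_equal(length(comps), 2L)
  expect_equal(sizes, c(1L, 2L))
})

test_that("component construction matches a quadratic oracle", {
  set.seed(9)
  for (rep in 1:20) {
    a <- random_hmr_set(sample(0:60, 1))
    b <- random_hmr_set(sample(1:60, 1))
    comps <- overlap_components(a, b)
    want <- taxonomy_bruteforce(a, b, tau = 0)
    # same partition: compare membership signatures
    sig_got <- sort(vapply(comps, function(x)
      paste(paste0("a", x$a, collapse = ","),
            paste0("b", x$b, collapse = ","), sep = "|"), character(1)))
    sig_want <- sort(vapply(seq_len(max(c(want$comp_a, want$comp_b))),
                            function(k)
      paste(paste0("a", which(want$comp_a == k), collapse = ","),
            paste0("b", which(want$comp_b == k), collapse = ","),
            sep = "|"), character(1)))
    expect_equal(sig_got, sig_want)
  }
})

test_that("component classification implements the taxonomy rules", {
  expect_equal(classify_component(iv(100L, 300L), iv(100L, 300L),
                                  tau = 0)$label, "C1")
  r <- classify_component(iv(100L, 400L), iv(100L, 300L), tau = 0)
  expect_equal(r$label, "C2_A_LONGER")
  expect_equal(r$extension$start, 300L)
  expect_equal(r$extension$end, 400L)
  r2 <- classify_component(iv(150L, 300L), iv(100L, 300L), tau = 0)
  expect_equal(r2$label, "C2_B_LONGER")
  expect_equal(r2$extension[, c("start", "end")], iv(100L, 150L)[, 2:3])
  expect_equal(classify_component(iv(100L, 500L),
                                  iv(c(150L, 300L), c(250L, 450L)),
                                  tau = 0)$label, "C4")
  expect_equal(classify_component(iv(100L, 300L), iv(150L, 400L),
                                  tau = 0)$label, "C3")
  expect_equal(classify_component(iv(100L, 300L), iv(120L, 280L),
                                  tau = 0)$label, "C3")  # containment
  expect_equal(classify_component(iv(c(0L, 200L), c(150L, 350L)),
                                  iv(c(100L, 300L), c(250L, 400L)),
                                  tau = 0)$label, "C5")
  expect_equal(classify_component(iv(0L, 10L), iv(integer(0), integer(0)),
                                  tau = 0)$label, "S1_A")
  # tolerance turns a near-match into a shared boundary
  expect_equal(classify_component(iv(100L, 300L), iv(110L, 500L),
                                  tau = 20)$label, "C2_B_LONGER")
  expect_error(classify_component(iv(integer(0), integer(0)),
                                  iv(integer(0), integer(0))), "empty")
})

test_that("random instances classify exactly like the brute force", {
  set.seed(21)
  for (rep in 1:200) {
    a <- random_hmr_set(sample(0:8, 1), chrom_len = 5000L)
    b <- random_hmr_set(sample(1:8, 1), chrom_len = 5000L)
    tau <- sample(c(0L, 20L), 1)
    cmp <- compare_sets(a, b, c(chr1 = 5000), tau = tau)
    want <- taxonomy_bruteforce(a, b, tau = tau)
    expect_equal(sort(cmp$labels), sort(want$labels))
    # bp conservation per tissue
    tt <- cmp$class_table
    expect_equal(sum(tt$bp_a), sum(a$end - a$start))
    expect_equal(sum(tt$bp_b), sum(b$end - b$start))
  }
})

test_that("genome fractions and additivity come out exactly", {
  sizes <- c(chr1 = 10000)
  cmp <- compare_sets(iv(0L, 100L), iv(0L, 100L), sizes, tau = 0)
  tt <- cmp$class_table
  expect_equal(tt$frac_a[tt$class == "C1"], 0.01)
  expect_equal(tt$frac_b[tt$class == "C1"], 0.01)
  expect_equal(sum(tt$n_components), 1L)

  cmp2 <- compare_sets(iv(0L, 100L), iv(500L, 700L), sizes, tau = 0)
  tt2 <- cmp2$class_table
  expect_equal(tt2$bp_a[tt2$class == "S1_A"], 100)
  expect_equal(tt2$bp_b[tt2$class == "S1_B"], 200)
  expect_equal(sum(tt2$bp_a), 100)
  expect_equal(sum(tt2$bp_b), 200)

  expect_error(compare_sets(iv(0L, 10L, chrom = "chrX"), iv(0L, 10L),
                            sizes), "absent")
})

test_that("comparison is symmetric up to tissue relabeling", {
  set.seed(33)
  a <- random_hmr_set(40, chrom_len = 50000L)
  b <- random_hmr_set(40, chrom_len = 50000L)
  sizes <- c(chr1 = 50000)
  ab <- compare_sets(a, b, sizes, tau = 10)$class_table
  ba <- compare_sets(b, a, sizes, tau = 10)$class_table
  swap <- c(S1_A = "S1_B", S1_B = "S1_A", C1 = "C1",
            C2_A_LONGER = "C2_B_LONGER", C2_B_LONGER = "C2_A_LONGER",
            C3 = "C3", C4 = "C4", C5 = "C5")
  for (cl in names(swap)) {
    expect_equal(ab$n_components[ab$class == cl],
                 ba$n_components[ba$class == swap[[cl]]])
  }
})

test_that("planted class counts are reported exactly on truth-derived sets", {
  cfg <- sim_config()
  truth <- build_truth(cfg)
  hmr_a <- truth_hypo_segments(truth, "A", clip_to_cpgs = FALSE)
  hmr_b <- truth_hypo_segments(truth, "B", clip_to_cpgs = FALSE)
  cmp <- compare_sets(hmr_a, hmr_b, cfg$chrom_sizes, tau = 0)
  tt <- cmp$class_table
  counts <- stats::setNames(tt$n_components, tt$class)
  expect_equal(counts[["S1_A"]], cfg$n_spec_a)
  expect_equal(counts[["S1_B"]], cfg$n_spec_b)
  expect_equal(counts[["C1"]], cfg$n_common)
  expect_equal(counts[["C2_A_LONGER"]], cfg$n_ext_a)
  expect_equal(counts[["C2_B_LONGER"]], cfg$n_ext_b)
  expect_equal(counts[["C3"]], cfg$n_c3)
  expect_equal(counts[["C4"]], cfg$n_c4)
  expect_equal(counts[["C5"]], cfg$n_c5)
})

test_that("extension segments recover their planted methylation", {
  cfg <- sim_config()
  sim <- simulate_two_tissues(cfg)
  hmr_a <- truth_hypo_segments(sim$truth, "A", clip_to_cpgs = FALSE)
  hmr_b <- truth_hypo_segments(sim$truth, "B", clip_to_cpgs = FALSE)
  cmp <- compare_sets(hmr_a, hmr_b, cfg$chrom_sizes, tau = 0)
  ext <- extension_segments(cmp, sim$A, sim$B)
  expect_equal(nrow(ext), cfg$n_ext_a + cfg$n_ext_b)
  ext_a <- ext[ext$tissue == "A", ]
  # extension CpGs sit at the planted low-methylated level in the longer
  # tissue and near the footprint level in the other
  expect_equal(mean(ext_a$mean_a), cfg$level_extension,
               tolerance = 0.03 / cfg$level_extension)
  expect_gt(mean(ext_a$mean_b), 0.5)
})
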