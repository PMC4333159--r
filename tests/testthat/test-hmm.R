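test_that("beta-binomial emission matches closed forms and a naive oracle", {
  # zero coverage carries no information
  expect_equal(bb_loglik(0L, 0L, 2, 6), 0)
  # uniform Beta prior: P(meth | cov = n) = 1/(n+1) for every meth
  for (k in 0:10) {
    expect_equal(bb_loglik(k, 10L, 1, 1), log(1 / 11), tolerance = 1e-12)
  }
  # direct ratio-of-Beta-functions evaluation
  naive <- log(choose(10, 3) * beta(3 + 2, 7 + 6) / beta(2, 6))
  expect_equal(bb_loglik(3L, 10L, 2, 6), naive, tolerance = 1e-12)
  expect_error(bb_loglik(1L, 2L, -1, 2), "> 0")
})

test_that("forward-backward matches one-step Bayes and stays normalized", {
  p <- hmm_params(init = c(0.5, 0.5),
                  trans = matrix(0.5, 2, 2),
                  alpha_hypo = 2, beta_hypo = 8,
                  alpha_hyper = 8, beta_hyper = 2)
  m1 <- mk_methylome(100, 2, 10)
  r <- forward_backward(m1, p)
  e <- exp(c(bb_loglik(2L, 10L, 2, 8), bb_loglik(2L, 10L, 8, 2)))
  expect_equal(r$posterior, e[1] / sum(e), tolerance = 1e-12)
  expect_equal(r$loglik, log(mean(e)), tolerance = 1e-12)

  # uninformative data with the chain at stationarity: posterior constant
  m0 <- mk_methylome(c(100, 200, 300), 0, 0)
  p2 <- hmm_params(init = c(0.3, 0.7),
                   trans = matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2,
                                  byrow = TRUE))
  r2 <- forward_backward(m0, p2)
  expect_equal(r2$posterior, rep(0.3, 3), tolerance = 1e-12)

  expect_error(forward_backward(mk_methylome(integer(0), integer(0),
                                             integer(0)), p),
               "empty")
})

test_that("posteriors equal exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:10, 1)
    cov <- rpois(n, 20)
    meth <- rbinom(n, cov, runif(n))
    m <- mk_methylome(seq_len(n) * 100L, meth, cov)
    p <- hmm_params(init = c(0.4, 0.6),
                    trans = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                   byrow = TRUE),
                    alpha_hypo = 1.5, beta_hypo = 6,
                    alpha_hyper = 5, beta_hyper = 2)
    got <- forward_backward(m, p)
    logemit <- cbind(bb_loglik(m$meth, m$cov, 1.5, 6),
                     bb_loglik(m$meth, m$cov, 5, 2))
    want <- fb_bruteforce(logemit, c(0.4, 0.6),
                          matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
    expect_equal(got$posterior, want$posterior, tolerance = 1e-10)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
    expect_true(all(got$posterior >= 0 & got$posterior <= 1))
  }
})

test_that("EM recovers generating emission means from chain data", {
  set.seed(1)
  n <- 50000
  trans <- matrix(c(0.99, 0.01, 0.02, 0.98), 2, 2, byrow = TRUE)
  states <- integer(n)
  states[1] <- 1L
  u <- runif(n)
  for (i in 2:n) {
    states[i] <- if (u[i] < trans[states[i - 1], 1]) 1L else 2L
  }
  mu <- c(0.1, 0.7)[states]
  pp <- rbeta(n, 20 * mu, 20 * (1 - mu))
  cov <- rpois(n, 36)
  m <- mk_methylome(seq_len(n) * 50L, rbinom(n, cov, pp), cov)
  fit <- baum_welch_fit(m)
  means <- c(fit$params$alpha_hypo /
               (fit$params$alpha_hypo + fit$params$beta_hypo),
             fit$params$alpha_hyper /
               (fit$params$alpha_hyper + fit$params$beta_hyper))
  expect_equal(means[1], 0.1, tolerance = 0.03 / 0.1)
  expect_equal(means[2], 0.7, tolerance = 0.03 / 0.7)
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-8 * abs(fit$loglik_trace[-length(fit$loglik_trace)])))
})

test_that("EM started at the generating parameters stops immediately", {
  set.seed(2)
  n <- 5000
  mu <- rep(c(0.1, 0.7), each = n / 2)
  pp <- rbeta(n, 20 * mu, 20 * (1 - mu))
  cov <- rpois(n, 36)
  m <- mk_methylome(seq_len(n) * 50L, rbinom(n, cov, pp), cov)
  gen <- hmm_params(init = c(0.5, 0.5),
                    trans = matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2,
                                   byrow = TRUE),
                    alpha_hypo = 2, beta_hypo = 18,
                    alpha_hyper = 14, beta_hyper = 6)
  fit <- baum_welch_fit(m, init = gen, tol = 1e-4)
  expect_lte(length(fit$loglik_trace), 3)
})

test_that("single-state data starves the hypo state", {
  set.seed(3)
  n <- 5000
  pp <- rbeta(n, 20 * 0.7, 20 * 0.3)
  cov <- rpois(n, 36)
  m <- mk_methylome(seq_len(n) * 50L, rbinom(n, cov, pp), cov)
  fit <- baum_welch_fit(m)
  occupancy <- mean(fit$posterior)
  means <- c(fit$params$alpha_hypo /
               (fit$params$alpha_hypo + fit$params$beta_hypo),
             fit$params$alpha_hyper /
               (fit$params$alpha_hyper + fit$params$beta_hyper))
  expect_true(occupancy < 0.01 || abs(diff(means)) < 0.05)
})

test_that("segmentation applies threshold, maxgap and min_cpgs", {
  set.seed(4)
  n <- 500
  mu <- rep(0.7, n)
  mu[200:219] <- 0.05
  cov <- rpois(n, 36)
  m <- mk_methylome(seq_len(n) * 50L, rbinom(n, cov, rbeta(n, 20 * mu,
                                                           20 * (1 - mu))),
                    cov)
  fit <- baum_welch_fit(m)
  hmrs <- segment_hmrs(m, fit$posterior)
  expect_equal(nrow(hmrs), 1L)
  expect_equal(hmrs$start, m$pos[200])
  expect_equal(hmrs$end, m$pos[219] + 2L)
  expect_equal(hmrs$n_cpg, 20L)
  expect_lt(hmrs$mean_level, 0.2)

  # uniform methylome: nothing called
  mu7 <- mk_methylome(seq_len(n) * 50L,
                      rbinom(n, cov, rbeta(n, 14, 6)), cov)
  fit7 <- baum_welch_fit(mu7)
  expect_equal(nrow(segment_hmrs(mu7, fit7$posterior)), 0L)

  # a 2-CpG dip is filtered at min_cpgs = 4
  post <- rep(0, 100)
  post[50:51] <- 1
  mx <- mk_methylome(seq_len(100) * 50L, 0, 10)
  expect_equal(nrow(segment_hmrs(mx, post, min_cpgs = 4)), 0L)
  expect_equal(nrow(segment_hmrs(mx, post, min_cpgs = 2)), 1L)

  # runs split across CpG deserts
  post2 <- rep(1, 12)
  pos2 <- c(seq(0, 5) * 100L, 5000L + seq(0, 5) * 100L)
  my <- mk_methylome(pos2, 0, 10)
  segs <- segment_hmrs(my, post2, maxgap = 1000)
  expect_equal(nrow(segs), 2L)
})

test_that("HMR calling is deterministic and rejects empty input", {
  sim <- simulate_two_tissues(small_sim_config(seed = 6))
  h1 <- call_hmrs(sim$A)
  h2 <- call_hmrs(sim$A)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_error(call_hmrs(mk_methylome(integer(0), integer(0), integer(0))),
               "empty")
  # HMRs are sorted, disjoint, and below the genome-wide mean level
  expect_true(all(diff(h1$start[h1$chrom == h1$chrom[1]]) > 0))
  expect_true(all(h1$mean_level < mean(meth_level(sim$A), na.rm = TRUE)))
})
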