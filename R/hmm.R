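#' Beta-binomial log-likelihood of a methylation count observation
#'
#' The emission density of the two-state HMM: the number of methylated
#' reads at a site is Binomial(cov, p) with p ~ Beta(alpha, beta), giving
#' a beta-binomial marginal that absorbs both sampling noise and
#' site-to-site overdispersion. Computed via log-gamma; a site with zero
#' coverage carries no information and scores exactly 0.
#'
#' @param meth,cov integer vectors of methylated and total read counts.
#' @param alpha,beta Beta shape parameters (> 0).
#' @return numeric vector of log-likelihoods.
#' @export
bb_loglik <- function(meth, cov, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  lchoose(cov, meth) + lbeta(meth + alpha, cov - meth + beta) -
    lbeta(alpha, beta)
}

bb_mean <- function(alpha, beta) alpha / (alpha + beta)

#' Two-state HMM parameters
#'
#' @param init length-2 initial state probabilities (hypo, hyper).
#' @param trans 2x2 transition matrix, rows summing to 1.
#' @param alpha_hypo,beta_hypo Beta emission shapes of the hypomethylated
#'   state.
#' @param alpha_hyper,beta_hyper Beta emission shapes of the methylated
#'   background state.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(init = c(0.5, 0.5),
                       trans = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2,
                                      byrow = TRUE),
                       alpha_hypo = 1, beta_hypo = 3,
                       alpha_hyper = 3, beta_hyper = 1) {
  stopifnot(length(init) == 2, all(init >= 0), abs(sum(init) - 1) < 1e-8,
            all(dim(trans) == c(2, 2)), all(trans >= 0),
            all(abs(rowSums(trans) - 1) < 1e-8),
            alpha_hypo > 0, beta_hypo > 0, alpha_hyper > 0, beta_hyper > 0)
  if (bb_mean(alpha_hypo, beta_hypo) >= bb_mean(alpha_hyper, beta_hyper)) {
    stop("hypo-state emission mean must be below the hyper-state mean")
  }
  structure(list(init = init, trans = trans,
                 alpha_hypo = alpha_hypo, beta_hypo = beta_hypo,
                 alpha_hyper = alpha_hyper, beta_hyper = beta_hyper),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf(
    "two-state HMM: hypo mean %.3f (a=%.3g, b=%.3g), hyper mean %.3f (a=%.3g, b=%.3g)\n",
    bb_mean(x$alpha_hypo, x$beta_hypo), x$alpha_hypo, x$beta_hypo,
    bb_mean(x$alpha_hyper, x$beta_hyper), x$alpha_hyper, x$beta_hyper))
  cat(sprintf("self-transition hypo %.4f, hyper %.4f\n",
              x$trans[1, 1], x$trans[2, 2]))
  invisible(x)
}

emission_matrix <- function(m, params) {
  cbind(bb_loglik(m$meth, m$cov, params$alpha_hypo, params$beta_hypo),
        bb_loglik(m$meth, m$cov, params$alpha_hyper, params$beta_hyper))
}

# E-step over all chromosomes; returns posteriors (row order of m),
# total loglik, summed expected transition counts, averaged first-site
# posterior
fb_estep <- function(m, params) {
  if (nrow(m) == 0L) stop("empty methylome chunk")
  logemit <- emission_matrix(m, params)
  chroms <- unique(m$chrom)
  post <- matrix(NA_real_, nrow(m), 2)
  loglik <- 0
  xi <- matrix(0, 2, 2)
  gamma1 <- c(0, 0)
  for (ch in chroms) {
    idx <- which(m$chrom == ch)
    r <- fb_two_state(logemit[idx, , drop = FALSE], params$init,
                      params$trans)
    post[idx, ] <- r$posterior
    loglik <- loglik + r$loglik
    xi <- xi + r$xi
    gamma1 <- gamma1 + r$gamma1
  }
  list(posterior = post, loglik = loglik, xi = xi,
       gamma1 = gamma1 / length(chroms))
}

#' Forward-backward state posteriors
#'
#' Runs scaled forward-backward independently per chromosome (the chain
#' restarts at every chromosome boundary) and returns the posterior
#' probability of the hypomethylated state at each site together with the
#' total log-likelihood of the data.
#'
#' @param m a [methylome].
#' @param params an [hmm_params] object.
#' @return list with `posterior` (numeric vector, one value per site of
#'   `m`) and `loglik` (scalar).
#' @export
forward_backward <- function(m, params) {
  r <- fb_estep(m, params)
  list(posterior = r$posterior[, 1], loglik = r$loglik)
}

# expected complete-data emission log-likelihood of one state, over
# weight-aggregated unique (meth, cov) observations
q_emission <- function(w_agg, meth_u, cov_u, alpha, beta) {
  sum(w_agg * bb_loglik(meth_u, cov_u, alpha, beta))
}

param_box <- c(1e-2, 1e3)

# maximise q_emission in (alpha, beta), never returning parameters whose
# Q falls below the current ones (EM monotonicity)
mstep_emission <- function(w, levels, code, w_tab_template,
                           meth_u, cov_u, cur_alpha, cur_beta) {
  w_agg <- w_tab_template
  sums <- rowsum(w, code)
  w_agg[as.integer(rownames(sums))] <- sums[, 1]
  qfun <- function(logab) {
    ab <- exp(logab)
    -q_emission(w_agg, meth_u, cov_u, ab[1], ab[2])
  }
  best <- c(cur_alpha, cur_beta)
  best_q <- q_emission(w_agg, meth_u, cov_u, best[1], best[2])
  # method-of-moments candidate from posterior-weighted level moments
  sw <- sum(w)
  if (sw > 0) {
    mu <- sum(w * levels) / sw
    v <- sum(w * (levels - mu)^2) / sw
    if (is.finite(v) && v > 0 && mu > 0 && mu < 1) {
      nu <- mu * (1 - mu) / v - 1
      if (is.finite(nu) && nu > 0) {
        cand <- pmin(pmax(c(nu * mu, nu * (1 - mu)), param_box[1]),
                     param_box[2])
        qc <- q_emission(w_agg, meth_u, cov_u, cand[1], cand[2])
        if (qc > best_q) {
          best <- cand
          best_q <- qc
        }
      }
    }
  }
  opt <- stats::optim(log(best), qfun, method = "Nelder-Mead",
                      control = list(maxit = 200))
  fitted <- pmin(pmax(exp(opt$par), param_box[1]), param_box[2])
  qf <- q_emission(w_agg, meth_u, cov_u, fitted[1], fitted[2])
  if (qf > best_q) best <- fitted
  best
}

#' Fit the two-state HMM by expectation-maximisation
#'
#' Baum-Welch with exact updates for the initial and transition
#' probabilities and a numerical M-step for the beta-binomial emission
#' shapes (posterior-weighted likelihood maximisation seeded by
#' posterior-weighted method-of-moments; emission parameters are kept in
#' \[1e-2, 1e3\] and never accepted if they would lower the expected
#' complete-data likelihood, so the log-likelihood trace is
#' non-decreasing). States are relabelled after every iteration so state 1
#' is the one with the lower emission mean. The fit is deterministic: no
#' random restarts.
#'
#' @param m a [methylome]; needs sites with non-zero coverage.
#' @param init initial [hmm_params]; the default starts the hypo state at
#'   mean 0.25 and the hyper state at 0.75, both with concentration 4, and
#'   0.99 self-transitions.
#' @param tol relative log-likelihood change below which EM stops.
#' @param max_iter maximum EM iterations.
#' @return list with `params` (fitted [hmm_params]), `loglik_trace`
#'   (numeric vector, one value per iteration) and `posterior` (hypo-state
#'   posterior under the fitted parameters).
#' @export
baum_welch_fit <- function(m, init = hmm_params(), tol = 1e-4,
                           max_iter = 100L) {
  if (nrow(m) == 0L) stop("empty methylome")
  if (all(m$cov == 0L)) stop("all sites have zero coverage")
  covered <- m$cov > 0L
  levels <- m$meth[covered] / m$cov[covered]
  key <- paste(m$meth[covered], m$cov[covered])
  u <- !duplicated(key)
  meth_u <- m$meth[covered][u]
  cov_u <- m$cov[covered][u]
  code <- match(key, key[u])
  w_tab_template <- numeric(length(meth_u))

  params <- init
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    e <- fb_estep(m, params)
    trace <- c(trace, e$loglik)
    if (iter > 1 &&
        abs(trace[iter] - trace[iter - 1]) <
          tol * abs(trace[iter - 1])) {
      break
    }
    new_init <- e$gamma1 / sum(e$gamma1)
    rs <- rowSums(e$xi)
    new_trans <- params$trans
    for (s in 1:2) {
      if (rs[s] > 0) new_trans[s, ] <- e$xi[s, ] / rs[s]
    }
    w <- e$posterior[covered, , drop = FALSE]
    ab1 <- mstep_emission(w[, 1], levels, code, w_tab_template,
                          meth_u, cov_u, params$alpha_hypo,
                          params$beta_hypo)
    ab2 <- mstep_emission(w[, 2], levels, code, w_tab_template,
                          meth_u, cov_u, params$alpha_hyper,
                          params$beta_hyper)
    # relabel so state 1 has the lower emission mean
    if (bb_mean(ab1[1], ab1[2]) > bb_mean(ab2[1], ab2[2])) {
      tmp <- ab1; ab1 <- ab2; ab2 <- tmp
      new_init <- rev(new_init)
      new_trans <- new_trans[2:1, 2:1]
    }
    if (bb_mean(ab1[1], ab1[2]) >= bb_mean(ab2[1], ab2[2])) {
      # degenerate single-state fit: nudge apart minimally to keep the
      # parameter object valid; occupancy decides downstream
      ab2 <- c(ab2[1] * (1 + 1e-6), ab2[2])
    }
    params <- hmm_params(init = new_init, trans = new_trans,
                         alpha_hypo = ab1[1], beta_hypo = ab1[2],
                         alpha_hyper = ab2[1], beta_hyper = ab2[2])
  }
  final <- fb_estep(m, params)
  list(params = params, loglik_trace = trace,
       posterior = final$posterior[, 1])
}

#' Default EM starting parameters for HMR calling
#'
#' Hypo state mean 0.25, hyper state mean 0.75, concentration 4 each;
#' 0.99 self-transitions; uniform initial vector.
#' @export
default_hmr_init <- function() {
  hmm_params(init = c(0.5, 0.5),
             trans = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE),
             alpha_hypo = 1, beta_hypo = 3,
             alpha_hyper = 3, beta_hyper = 1)
}

#' Segment a methylome into hypomethylated regions from state posteriors
#'
#' Maximal runs of consecutive CpGs whose hypo-state posterior exceeds
#' `threshold` become candidate HMRs. Runs are broken where the gap
#' between consecutive CpGs exceeds `maxgap` (CpG deserts), and candidates
#' with fewer than `min_cpgs` member sites are dropped. Each HMR spans
#' from its first member CpG to two bp past its last (covering the final
#' CG dyad).
#'
#' @param m a [methylome].
#' @param posterior hypo-state posterior per site of `m` (from
#'   [forward_backward()] or [baum_welch_fit()]).
#' @param threshold posterior decoding threshold (default 0.5).
#' @param maxgap maximum intra-HMR gap between consecutive CpGs, bp.
#' @param min_cpgs minimum CpG count per HMR.
#' @return an `hmr_set`: data.frame of `chrom`, `start`, `end`, `n_cpg`,
#'   `mean_level` (unweighted mean of covered-site levels), `score` (sum
#'   of hypo posteriors), sorted and disjoint.
#' @export
segment_hmrs <- function(m, posterior, threshold = 0.5, maxgap = 1000L,
                         min_cpgs = 4L) {
  stopifnot(length(posterior) == nrow(m))
  hypo <- posterior > threshold
  lv <- meth_level(m)
  out <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    h <- hypo[idx]
    if (!any(h)) next
    pos <- m$pos[idx]
    # a run breaks when the state flips or the gap exceeds maxgap
    gap_break <- c(FALSE, diff(pos) > maxgap)
    run_id <- cumsum(c(TRUE, diff(h) != 0) | gap_break)
    for (rid in unique(run_id[h])) {
      members <- idx[run_id == rid & h]
      if (length(members) < min_cpgs) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = m$pos[members[1]],
        end = m$pos[members[length(members)]] + 2L,
        n_cpg = length(members),
        mean_level = mean(lv[members], na.rm = TRUE),
        score = sum(posterior[members]),
        stringsAsFactors = FALSE)
    }
  }
  hmrs <- if (length(out) == 0L) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpg = integer(), mean_level = numeric(), score = numeric())
  } else {
    sort_intervals(do.call(rbind, out))
  }
  rownames(hmrs) <- NULL
  structure(hmrs, sample_id = sample_id(m),
            class = c("hmr_set", "data.frame"))
}

#' Call hypomethylated regions from a methylome
#'
#' Convenience wrapper: fit the HMM with [baum_welch_fit()], then decode
#' with [segment_hmrs()]. The fitted parameters are attached to the result
#' (`attr(x, "params")`).
#'
#' @inheritParams baum_welch_fit
#' @inheritParams segment_hmrs
#' @return an `hmr_set` (see [segment_hmrs()]).
#' @export
call_hmrs <- function(m, min_cpgs = 4L, maxgap = 1000L, threshold = 0.5,
                      init = default_hmr_init(), tol = 1e-4,
                      max_iter = 100L) {
  if (nrow(m) == 0L) stop("empty methylome")
  fit <- baum_welch_fit(m, init = init, tol = tol, max_iter = max_iter)
  hmrs <- segment_hmrs(m, fit$posterior, threshold = threshold,
                       maxgap = maxgap, min_cpgs = min_cpgs)
  attr(hmrs, "params") <- fit$params
  attr(hmrs, "loglik_trace") <- fit$loglik_trace
  hmrs
}

#' Write an HMR set as BED6
#'
#' Names are `HMR_1`, `HMR_2`, ... in genomic order; the score column is
#' the rounded sum of hypo-state posteriors.
#'
#' @param hmrs an `hmr_set` (or any interval frame with a `score` column).
#' @param path output path.
#' @export
write_hmrs <- function(hmrs, path) {
  df <- as.data.frame(hmrs)
  df$name <- paste0("HMR_", seq_len(nrow(df)))
  df$score <- if (is.null(df$score)) 0L else round(df$score)
  df$strand <- rep(".", nrow(df))
  write_intervals(df[, c("chrom", "start", "end", "name", "score", "strand")],
                  path)
}

#' Per-segment boundary recovery error in CpG units
#'
#' For each truth segment, finds the called HMR with the largest overlap
#' and counts the CpGs of `m` lying between the true and called boundary
#' at each end; returns the worse of the two ends. Unmatched truth
#' segments get `Inf`.
#'
#' @param called called HMR interval frame.
#' @param truth_segments truth interval frame.
#' @param m the [methylome] whose CpG grid defines the error unit.
#' @return numeric vector, one error per truth segment.
#' @export
hmr_boundary_errors <- function(called, truth_segments, m) {
  n <- nrow(truth_segments)
  errs <- rep(Inf, n)
  if (n == 0L || nrow(called) == 0L) return(errs)
  ov <- overlap_pairs(truth_segments, called)
  if (nrow(ov) == 0L) return(errs)
  ov$bp <- pmin(truth_segments$end[ov$query], called$end[ov$subject]) -
    pmax(truth_segments$start[ov$query], called$start[ov$subject])
  for (i in unique(ov$query)) {
    rows <- ov[ov$query == i, ]
    j <- rows$subject[which.max(rows$bp)]
    ch <- truth_segments$chrom[i]
    pos <- m$pos[m$chrom == ch]
    count_between <- function(a, b) {
      sum(pos >= min(a, b) & pos < max(a, b))
    }
    errs[i] <- max(count_between(truth_segments$start[i], called$start[j]),
                   count_between(truth_segments$end[i], called$end[j]))
  }
  errs
}
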