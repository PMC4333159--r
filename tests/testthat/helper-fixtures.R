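# quick methylome construction from parallel vectors
mk_methylome <- function(pos, meth, cov, chrom = "chr1", strand = "+",
                         context = "CG", id = "test") {
  n <- length(pos)
  methylome(data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                       strand = rep_len(strand, n),
                       context = rep_len(context, n),
                       meth = as.integer(rep_len(meth, n)),
                       cov = as.integer(rep_len(cov, n)),
                       stringsAsFactors = FALSE), sample_id = id)
}

# hand-built truth object: one chromosome, explicit per-CpG means
mk_truth <- function(pos, mu_a, mu_b = mu_a, chrom = "chr1",
                     chrom_len = max(pos) + 1000, k = 20,
                     coverage = c(A = 36, B = 91), seed = 1L) {
  cfg <- sim_config(chrom_sizes = stats::setNames(chrom_len, chrom),
                    k = k, coverage = coverage, seed = seed)
  structure(list(
    cpg = data.frame(chrom = chrom, pos = as.integer(pos),
                     mu_A = mu_a, mu_B = mu_b, stringsAsFactors = FALSE),
    segments = data.frame(chrom = character(), start = integer(),
                          end = integer(), tissue = character(),
                          class = character(), part = character(),
                          level = numeric(), template = integer()),
    config = cfg), class = "meth_truth")
}

iv <- function(start, end, chrom = "chr1", ...) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end, ..., stringsAsFactors = FALSE)
}

# exhaustive-path forward-backward oracle for a two-state chain:
# enumerates all 2^n state paths from the log emission matrix
fb_bruteforce <- function(logemit, init, trans) {
  n <- nrow(logemit)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(init[s[1]]) + logemit[1, s[1]]
    for (i in seq_len(n - 1)) {
      lp <- lp + log(trans[s[i], s[i + 1]]) + logemit[i + 1, s[i + 1]]
    }
    lp
  })
  w <- exp(logp - max(logp))
  post <- vapply(seq_len(n), function(i) {
    sum(w[paths[, i] == 1]) / sum(w)
  }, numeric(1))
  list(posterior = post, loglik = log(sum(w)) + max(logp))
}

# quadratic brute-force overlap components + classification, following
# the stated taxonomy rules directly
taxonomy_bruteforce <- function(a, b, tau) {
  nA <- nrow(a)
  nB <- nrow(b)
  ov <- function(i, j) {
    a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
      b$start[j] < a$end[i]
  }
  adj <- matrix(FALSE, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) adj[i, j] <- ov(i, j)
  comp_a <- rep(0L, nA)
  comp_b <- rep(0L, nB)
  cid <- 0L
  for (i0 in seq_len(nA)) {
    if (comp_a[i0] != 0L) next
    cid <- cid + 1L
    qa <- i0
    qb <- integer(0)
    comp_a[i0] <- cid
    repeat {
      grew <- FALSE
      for (i in which(comp_a == cid)) {
        for (j in which(adj[i, ])) {
          if (comp_b[j] == 0L) {
            comp_b[j] <- cid
            grew <- TRUE
          }
        }
      }
      for (j in which(comp_b == cid)) {
        for (i in which(adj[, j])) {
          if (comp_a[i] == 0L) {
            comp_a[i] <- cid
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
  }
  for (j0 in seq_len(nB)) {
    if (comp_b[j0] == 0L) {
      cid <- cid + 1L
      comp_b[j0] <- cid
    }
  }
  labels <- character(0)
  for (k in seq_len(cid)) {
    ia <- which(comp_a == k)
    ib <- which(comp_b == k)
    lab <- if (length(ib) == 0L) {
      "S1_A"
    } else if (length(ia) == 0L) {
      "S1_B"
    } else if (length(ia) > 1L && length(ib) > 1L) {
      "C5"
    } else if (length(ia) > 1L || length(ib) > 1L) {
      "C4"
    } else {
      sm <- abs(a$start[ia] - b$start[ib]) <= tau
      em <- abs(a$end[ia] - b$end[ib]) <= tau
      if (sm && em) {
        "C1"
      } else if (!sm && !em) {
        "C3"
      } else if ((a$end[ia] - a$start[ia]) > (b$end[ib] - b$start[ib])) {
        "C2_A_LONGER"
      } else {
        "C2_B_LONGER"
      }
    }
    labels <- c(labels, lab)
  }
  list(comp_a = comp_a, comp_b = comp_b, labels = labels)
}

# random disjoint sorted interval set on one chromosome
random_hmr_set <- function(n, chrom_len = 100000L, chrom = "chr1") {
  if (n == 0L) return(iv(integer(0), integer(0), chrom = character(0)))
  starts <- sort(sample.int(chrom_len - 200L, n))
  width <- pmin(sample(20:400, n, replace = TRUE),
                c(diff(starts) - 1L, chrom_len - starts[n]))
  width <- pmax(width, 1L)
  iv(starts, starts + width, chrom = chrom)
}

# small, fast simulation config for pipeline-level tests
small_sim_config <- function(seed = 1L) {
  sim_config(chrom_sizes = c(chrS = 4e5),
             n_common = 8, n_spec_a = 4, n_spec_b = 4,
             n_ext_a = 3, n_ext_b = 3, n_c3 = 2, n_c4 = 2, n_c5 = 1,
             seed = seed)
}
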