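#' Simulation configuration for the two-tissue synthetic methylome
#'
#' The generator plants, on a small genome, hypomethylated segments of
#' every overlap class observed when two tissues' HMR sets are compared:
#' common HMRs (identical in both tissues), tissue-specific HMRs (hypo in
#' one tissue only), common HMRs with a one-sided tissue-specific
#' extension, and complex overlap templates (containment/stagger, one-vs-
#' many, many-vs-many). True mean methylation follows a four-level model:
#' near-zero in common HMRs (0.03), 0.25 inside a tissue's own
#' tissue-specific HMRs, 0.60 over the same span in the tissue where the
#' region is not an HMR (the "footprint"), and 0.70 over the methylated
#' background; C2 extensions carry 0.15 in the tissue where they are hypo.
#' CpG spacing is exponential with mean 12 bp inside planted segments and
#' 120 bp outside, mimicking the elevated CG density of real HMRs.
#'
#' @param chrom_sizes named vector of chromosome lengths (default two 1-Mb
#'   chromosomes).
#' @param spacing_bg,spacing_hypo mean inter-CpG gap (bp) outside/inside
#'   planted segments.
#' @param level_background,level_common,level_ts_own,level_ts_other,level_extension
#'   true mean methylation of the four levels plus the C2 extension.
#' @param k Beta concentration of per-site methylation probabilities.
#' @param coverage named vector of mean read depths per tissue.
#' @param n_common,n_spec_a,n_spec_b,n_ext_a,n_ext_b,n_c3,n_c4,n_c5 planted
#'   segment/template counts per class.
#' @param common_len,spec_len,ext_core_len,ext_len length ranges (bp).
#' @param min_separation minimum bp between neighbouring templates.
#' @param seed master seed; every generator stage derives its own
#'   substream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
                       spacing_bg = 120, spacing_hypo = 12,
                       level_background = 0.70, level_common = 0.03,
                       level_ts_own = 0.25, level_ts_other = 0.60,
                       level_extension = 0.15,
                       k = 20,
                       coverage = c(A = 36, B = 91),
                       n_common = 30, n_spec_a = 15, n_spec_b = 15,
                       n_ext_a = 10, n_ext_b = 10,
                       n_c3 = 4, n_c4 = 4, n_c5 = 2,
                       common_len = c(500, 1500), spec_len = c(400, 1200),
                       ext_core_len = c(400, 800), ext_len = c(150, 400),
                       min_separation = 3000,
                       seed = 1L) {
  chrom_sizes <- unlist(chrom_sizes)  # tolerate YAML-style lists
  coverage <- unlist(coverage)
  cfg <- as.list(environment())
  stopifnot(all(c(level_background, level_common, level_ts_own,
                  level_ts_other, level_extension) >= 0),
            all(c(level_background, level_common, level_ts_own,
                  level_ts_other, level_extension) <= 1),
            k > 0, all(coverage > 0), all(chrom_sizes > 0))
  structure(cfg, class = "sim_config")
}

# deterministic per-stage substream seed below 2^31
substream_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

runif_int <- function(n, lo, hi) as.integer(floor(runif(n, lo, hi + 1)))

# one template = the per-tissue hypo sub-segments of one planted unit,
# with start offsets relative to the template origin
template_segments <- function(cfg, class, variant = 0L) {
  rl <- function(range) runif_int(1, range[1], range[2])
  seg <- function(tissue, s, e, level, part) {
    data.frame(tissue = tissue, off = s, len = e - s, level = level,
               part = part, stringsAsFactors = FALSE)
  }
  lc <- cfg$level_common
  lo <- cfg$level_ts_own
  lx <- cfg$level_extension
  switch(class,
    COMMON = {
      len <- rl(cfg$common_len)
      rbind(seg("A", 0, len, lc, "core"), seg("B", 0, len, lc, "core"))
    },
    SPEC_A = {
      len <- rl(cfg$spec_len)
      seg("A", 0, len, lo, "core")
    },
    SPEC_B = {
      len <- rl(cfg$spec_len)
      seg("B", 0, len, lo, "core")
    },
    EXT_A = {  # common core, A-only extension on one side (C2, A longer)
      core <- rl(cfg$ext_core_len)
      ext <- rl(cfg$ext_len)
      if (variant %% 2L == 0L) {
        rbind(seg("A", 0, core, lc, "core"), seg("A", core, core + ext, lx, "ext"),
              seg("B", 0, core, lc, "core"))
      } else {
        rbind(seg("A", 0, ext, lx, "ext"), seg("A", ext, ext + core, lc, "core"),
              seg("B", ext, ext + core, lc, "core"))
      }
    },
    EXT_B = {
      core <- rl(cfg$ext_core_len)
      ext <- rl(cfg$ext_len)
      if (variant %% 2L == 0L) {
        rbind(seg("B", 0, core, lc, "core"), seg("B", core, core + ext, lx, "ext"),
              seg("A", 0, core, lc, "core"))
      } else {
        rbind(seg("B", 0, ext, lx, "ext"), seg("B", ext, ext + core, lc, "core"),
              seg("A", ext, ext + core, lc, "core"))
      }
    },
    C3 = {  # 1:1 overlap, no shared boundary: stagger or containment
      if (variant %% 2L == 0L) {
        la <- rl(cfg$common_len)
        off <- runif_int(1, 150, max(200, la %/% 2))
        lb <- rl(cfg$common_len)
        # keep the right boundaries clearly apart so the overlap class
        # stays C3 regardless of the comparison tolerance
        if (abs(off + lb - la) < 100) lb <- lb + 150L
        rbind(seg("A", 0, la, lc, "core"), seg("B", off, off + lb, lc, "core"))
      } else {
        la <- rl(cfg$common_len) + 600L
        rbind(seg("A", 0, la, lc, "core"),
              seg("B", 200, la - 200L, lc, "core"))
      }
    },
    C4 = {  # one long HMR vs two shorter ones (either direction)
      long_tissue <- if (variant %% 2L == 0L) "A" else "B"
      short_tissue <- setdiff(c("A", "B"), long_tissue)
      l1 <- rl(cfg$ext_core_len)
      l2 <- rl(cfg$ext_core_len)
      gap <- 300L
      total <- l1 + gap + l2 + 200L
      rbind(seg(long_tissue, 0, total, lc, "core"),
            seg(short_tissue, 100, 100 + l1, lc, "core"),
            seg(short_tissue, 100 + l1 + gap, 100 + l1 + gap + l2, lc, "core"))
    },
    C5 = {  # two vs two, pairwise staggered into one connected component
      rbind(seg("A", 0, 600, lc, "core"),
            seg("A", 900, 1600, lc, "core"),
            seg("B", 300, 1100, lc, "core"),
            seg("B", 1400, 1900, lc, "core"))
    },
    stop("unknown template class: ", class))
}

#' Build the planted truth of the two-tissue simulation
#'
#' Draws CpG positions (clustered inside planted segments, sparse
#' outside), places one template per planted unit with at least
#' `min_separation` bp between neighbours, and assigns every CpG its true
#' mean methylation in each tissue: the level of the covering own-tissue
#' segment, else `level_ts_other` if only the other tissue's segment
#' covers it, else `level_background`. Deterministic given the config
#' seed.
#'
#' @param cfg a [sim_config].
#' @return list of class `meth_truth` with elements `cpg` (data.frame
#'   `chrom`, `pos`, `mu_A`, `mu_B`), `segments` (per-tissue hypo
#'   sub-segments with `class`, `part`, `level`, `template`), and
#'   `config`.
#' @export
build_truth <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "truth"))
  classes <- c(rep("COMMON", cfg$n_common), rep("SPEC_A", cfg$n_spec_a),
               rep("SPEC_B", cfg$n_spec_b), rep("EXT_A", cfg$n_ext_a),
               rep("EXT_B", cfg$n_ext_b), rep("C3", cfg$n_c3),
               rep("C4", cfg$n_c4), rep("C5", cfg$n_c5))
  n_tpl <- length(classes)
  classes <- sample(classes)  # interleave classes along the genome
  chrom_names <- names(cfg$chrom_sizes)
  tpl_chrom <- rep(chrom_names, length.out = n_tpl)

  segments <- list()
  for (ci in seq_along(chrom_names)) {
    ch <- chrom_names[ci]
    idx <- which(tpl_chrom == ch)
    if (length(idx) == 0L) next
    slot <- cfg$chrom_sizes[[ch]] / length(idx)
    for (j in seq_along(idx)) {
      t <- idx[j]
      segs <- template_segments(cfg, classes[t], variant = t)
      span <- max(segs$off + segs$len)
      lo <- (j - 1) * slot + cfg$min_separation / 2
      hi <- j * slot - span - cfg$min_separation / 2
      if (hi <= lo) {
        stop("chromosome ", ch, " too small for the requested segments")
      }
      origin <- runif_int(1, lo, hi)
      segs$chrom <- ch
      segs$start <- origin + segs$off
      segs$end <- segs$start + segs$len
      segs$class <- classes[t]
      segs$template <- t
      segments[[length(segments) + 1L]] <-
        segs[, c("chrom", "start", "end", "tissue", "class", "part",
                 "level", "template")]
    }
  }
  segments <- sort_intervals(do.call(rbind, segments))
  rownames(segments) <- NULL

  # CpG positions: exponential gaps, dense inside any planted segment
  dense <- merge_intervals(segments)
  cpg <- list()
  for (ch in chrom_names) {
    L <- cfg$chrom_sizes[[ch]]
    d <- dense[dense$chrom == ch, , drop = FALSE]
    # breakpoints partition [0, L) into alternating sparse/dense pieces
    bounds <- sort(unique(c(0, d$start, d$end, L)))
    pos_list <- list()
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]
      b <- bounds[i + 1]
      inside <- nrow(d) > 0L && any(d$start <= a & d$end >= b)
      spacing <- if (inside) cfg$spacing_hypo else cfg$spacing_bg
      n_exp <- ceiling((b - a) / spacing * 1.6) + 10
      gaps <- 2 + round(rexp(n_exp, 1 / max(spacing - 2, 1)))
      p <- a + cumsum(gaps)
      p <- p[p < b - 1]
      while (length(p) > 0 && max(p) < b - 3 * spacing && n_exp < 1e6) {
        extra <- max(p) + cumsum(2 + round(rexp(n_exp, 1 / max(spacing - 2, 1))))
        p <- c(p, extra[extra < b - 1])
      }
      pos_list[[i]] <- p
    }
    pos <- sort(unique(unlist(pos_list)))
    cpg[[ch]] <- data.frame(chrom = ch, pos = as.integer(pos),
                            stringsAsFactors = FALSE)
  }
  cpg <- do.call(rbind, cpg)
  rownames(cpg) <- NULL

  mu_for_tissue <- function(tissue) {
    mu <- rep(cfg$level_background, nrow(cpg))
    other <- setdiff(c("A", "B"), tissue)
    oth <- segments[segments$tissue == other, , drop = FALSE]
    mu[sites_in_intervals(cpg$chrom, cpg$pos, oth)] <- cfg$level_ts_other
    own <- segments[segments$tissue == tissue, , drop = FALSE]
    for (i in seq_len(nrow(own))) {
      hit <- cpg$chrom == own$chrom[i] & cpg$pos >= own$start[i] &
        cpg$pos < own$end[i]
      mu[hit] <- own$level[i]
    }
    mu
  }
  cpg$mu_A <- mu_for_tissue("A")
  cpg$mu_B <- mu_for_tissue("B")

  structure(list(cpg = cpg, segments = segments, config = cfg),
            class = "meth_truth")
}

#' @export
print.meth_truth <- function(x, ...) {
  cat(sprintf("planted truth: %d CpGs, %d hypo sub-segments (%d templates) on %d chromosome(s)\n",
              nrow(x$cpg), nrow(x$segments), length(unique(x$segments$template)),
              length(x$config$chrom_sizes)))
  print(table(x$segments$class, x$segments$tissue))
  invisible(x)
}

#' True hypomethylated spans of one tissue
#'
#' Merges the tissue's contiguous planted sub-segments (e.g. a common core
#' plus its extension) into maximal hypo intervals. With
#' `clip_to_cpgs = TRUE` each span is clipped to the CpG grid
#' (`[first member CpG, last member CpG + 2)`), the same convention the
#' HMR caller uses, so recovery metrics compare like with like.
#'
#' @param truth a `meth_truth`.
#' @param tissue `"A"` or `"B"`.
#' @param clip_to_cpgs clip spans to their member CpGs.
#' @return interval data.frame.
#' @export
truth_hypo_segments <- function(truth, tissue, clip_to_cpgs = TRUE) {
  own <- truth$segments[truth$segments$tissue == tissue, , drop = FALSE]
  spans <- merge_intervals(own)
  if (!clip_to_cpgs || nrow(spans) == 0L) return(spans)
  keep <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    p <- truth$cpg$pos[truth$cpg$chrom == spans$chrom[i] &
                         truth$cpg$pos >= spans$start[i] &
                         truth$cpg$pos < spans$end[i]]
    if (length(p) > 0L) {
      spans$start[i] <- min(p)
      spans$end[i] <- max(p) + 2L
      keep[i] <- TRUE
    }
  }
  spans[keep, , drop = FALSE]
}

#' Simulate a methylome from the planted truth
#'
#' For each CpG with true mean `mu`, the per-site methylation probability
#' is Beta(k mu, k (1 - mu)), coverage is Poisson(lambda), and the
#' methylated count Binomial(coverage, p). Zero-coverage sites are kept.
#'
#' @param truth a `meth_truth` from [build_truth()].
#' @param tissue `"A"` or `"B"`.
#' @param lambda mean coverage; defaults to the config value for the
#'   tissue.
#' @param k Beta concentration; defaults to the config value.
#' @param seed seed for this draw; defaults to a substream of the config
#'   master seed keyed by tissue.
#' @return a [methylome].
#' @export
simulate_methylome <- function(truth, tissue = "A", lambda = NULL, k = NULL,
                               seed = NULL) {
  cfg <- truth$config
  if (is.null(lambda)) lambda <- cfg$coverage[[tissue]]
  if (is.null(k)) k <- cfg$k
  if (is.null(seed)) seed <- substream_seed(cfg$seed,
                                            paste0("methylome_", tissue))
  set.seed(seed)
  mu <- truth$cpg[[paste0("mu_", tissue)]]
  n <- length(mu)
  p <- numeric(n)
  pos_mu <- mu > 0 & mu < 1
  p[pos_mu] <- rbeta(sum(pos_mu), k * mu[pos_mu], k * (1 - mu[pos_mu]))
  p[mu >= 1] <- 1
  covv <- rpois(n, lambda)
  methv <- rbinom(n, covv, p)
  methylome(data.frame(chrom = truth$cpg$chrom, pos = truth$cpg$pos,
                       strand = "+", context = "CG",
                       meth = methv, cov = covv,
                       stringsAsFactors = FALSE),
            sample_id = paste0("tissue_", tissue))
}

#' Simulate both tissues' methylomes plus their truth
#'
#' @param cfg a [sim_config].
#' @return list with `truth`, `A` and `B`.
#' @export
simulate_two_tissues <- function(cfg = sim_config()) {
  truth <- build_truth(cfg)
  list(truth = truth,
       A = simulate_methylome(truth, "A"),
       B = simulate_methylome(truth, "B"))
}

#' Simulate motif occurrence intervals with a planted enrichment
#'
#' Places `n_hits` motif occurrences of length `motif_len` so that the
#' expected hit density inside the segments of `target_class` is `fold`
#' times the genome-wide uniform density; remaining hits are uniform over
#' the genome. `fold = 1` (or a null `target_class`) gives fully uniform
#' placement, the null of the enrichment score.
#'
#' @param truth a `meth_truth`.
#' @param motif_len motif length L in bp.
#' @param n_hits total number of occurrences N.
#' @param fold target enrichment f (>= 0).
#' @param target_class a class label present in `truth$segments` (e.g.
#'   `"SPEC_A"`), or NULL for uniform placement.
#' @param seed random seed (default: substream of the config seed).
#' @param motif_id name recorded for every hit.
#' @return interval data.frame with `name` column.
#' @export
simulate_motif_hits <- function(truth, motif_len = 10L, n_hits = 10000L,
                                fold = 1, target_class = NULL, seed = NULL,
                                motif_id = "motif") {
  cfg <- truth$config
  if (is.null(seed)) {
    seed <- substream_seed(cfg$seed, paste0("motif_", motif_id, fold))
  }
  set.seed(seed)
  stopifnot(fold >= 0)
  sizes <- cfg$chrom_sizes
  G <- sum(sizes)
  if (n_hits == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  uniform_hits <- function(n, avoid = NULL) {
    acc <- list()
    got <- 0L
    while (got < n) {
      need <- max(2L * (n - got), 10L)
      ch <- sample(names(sizes), need, replace = TRUE, prob = sizes)
      s <- floor(runif(need, 0, sizes[ch] - motif_len))
      cand <- data.frame(chrom = ch, start = as.integer(s),
                         end = as.integer(s + motif_len),
                         stringsAsFactors = FALSE)
      if (!is.null(avoid) && nrow(avoid) > 0L) {
        cand <- cand[!sites_in_intervals_any(cand, avoid), , drop = FALSE]
      }
      take <- min(nrow(cand), n - got)
      if (take > 0L) {
        acc[[length(acc) + 1L]] <- cand[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
    do.call(rbind, acc)
  }
  if (is.null(target_class)) {
    hits <- uniform_hits(n_hits)
  } else {
    target <- merge_intervals(
      truth$segments[truth$segments$class == target_class, , drop = FALSE])
    if (nrow(target) == 0L) stop("no segments of class ", target_class)
    Tbp <- total_bp(target)
    p_in <- fold * Tbp / G
    if (p_in > 1) stop("fold ", fold, " infeasible for target of ", Tbp, " bp")
    n_in <- rbinom(1, n_hits, p_in)
    w <- target$end - target$start
    ridx <- sample.int(nrow(target), n_in, replace = TRUE, prob = w)
    s <- floor(target$start[ridx] +
                 runif(n_in, 0, pmax(w[ridx] - motif_len, 1)))
    inside <- data.frame(chrom = target$chrom[ridx], start = as.integer(s),
                         end = as.integer(s + motif_len),
                         stringsAsFactors = FALSE)
    # remaining hits avoid the target so the planted in-target density is
    # exactly fold times the uniform density
    hits <- rbind(inside, uniform_hits(n_hits - n_in, avoid = target))
  }
  hits <- sort_intervals(hits)
  hits$name <- motif_id
  rownames(hits) <- NULL
  hits
}

#' Simulate ChIP-peak intervals with known methylation state
#'
#' `n_in_hmr` peaks are centred inside planted common hypo segments (so
#' both tissues see them inside an HMR), `n_in_methylated` inside the
#' methylated background, at least `clearance` bp away from any planted
#' segment.
#'
#' @param truth a `meth_truth`.
#' @param n_in_hmr,n_in_methylated peak counts.
#' @param width peak width in bp.
#' @param clearance minimum distance of background peaks from any planted
#'   segment.
#' @param seed random seed (default: substream of the config seed).
#' @return interval data.frame with `name` and `placement`
#'   (`"in_hmr"`/`"background"`) columns.
#' @export
simulate_peaks <- function(truth, n_in_hmr = 10L, n_in_methylated = 10L,
                           width = 200L, clearance = 500L, seed = NULL) {
  cfg <- truth$config
  if (is.null(seed)) seed <- substream_seed(cfg$seed, "peaks")
  set.seed(seed)
  stopifnot(width > 0)
  segs <- truth$segments
  common <- segs[segs$class == "COMMON", , drop = FALSE]
  common <- common[common$end - common$start >= width + 40L, , drop = FALSE]
  out <- list()
  if (n_in_hmr > 0L) {
    if (nrow(common) == 0L) stop("no common segment wide enough for peaks")
    i <- sample.int(nrow(common), n_in_hmr, replace = TRUE)
    c0 <- floor(runif(n_in_hmr, common$start[i] + 20L + width / 2,
                      common$end[i] - 20L - width / 2))
    out$hmr <- data.frame(chrom = common$chrom[i],
                          start = as.integer(c0 - width %/% 2),
                          end = as.integer(c0 + (width - width %/% 2)),
                          placement = "in_hmr", stringsAsFactors = FALSE)
  }
  if (n_in_methylated > 0L) {
    avoid <- merge_intervals(segs)
    avoid$start <- pmax(avoid$start - clearance, 0)
    avoid$end <- avoid$end + clearance
    sizes <- cfg$chrom_sizes
    acc <- list()
    got <- 0L
    while (got < n_in_methylated) {
      need <- (n_in_methylated - got) * 3L
      ch <- sample(names(sizes), need, replace = TRUE, prob = sizes)
      s <- floor(runif(need, 0, sizes[ch] - width))
      cand <- data.frame(chrom = ch, start = as.integer(s),
                         end = as.integer(s + width),
                         stringsAsFactors = FALSE)
      ok <- !(sites_in_intervals(cand$chrom, cand$start, avoid) |
                sites_in_intervals(cand$chrom, cand$end - 1L, avoid))
      cand <- cand[ok, , drop = FALSE]
      take <- min(nrow(cand), n_in_methylated - got)
      if (take > 0L) {
        cand <- cand[seq_len(take), , drop = FALSE]
        cand$placement <- "background"
        acc[[length(acc) + 1L]] <- cand
        got <- got + take
      }
    }
    out$bg <- do.call(rbind, acc)
  }
  peaks <- do.call(rbind, out)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  peaks$name <- paste0("peak_", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks[, c("chrom", "start", "end", "name", "placement")]
}

#' Simulate toy gene models over the synthetic genome
#'
#' Half of the genes are placed so that a planted common hypo segment
#' falls inside their promoter window (mimicking unmethylated promoters);
#' the rest sit entirely in the methylated background. All genes are
#' plus-strand, 2.5 kb long, with three exons and a CDS starting 200 bp
#' into the transcript.
#'
#' @param truth a `meth_truth`.
#' @param n_genes number of genes.
#' @param seed random seed (default: substream of the config seed).
#' @return gene model data.frame (see [read_genes()]).
#' @export
simulate_genes <- function(truth, n_genes = 20L, seed = NULL) {
  cfg <- truth$config
  if (is.null(seed)) seed <- substream_seed(cfg$seed, "genes")
  set.seed(seed)
  segs <- truth$segments
  common <- segs[segs$class == "COMMON", , drop = FALSE]
  n_prom <- n_genes %/% 2L
  gene_len <- 2500L
  make_gene <- function(chrom, tss, id) {
    ex <- data.frame(start = tss + c(0L, 900L, 2100L),
                     end = tss + c(400L, 1300L, gene_len))
    data.frame(chrom = chrom, strand = "+", txStart = tss,
               txEnd = tss + gene_len, cdsStart = tss + 200L,
               cdsEnd = tss + gene_len - 200L,
               name = paste0("gene_", id), exons = I(list(ex)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (n_prom > 0L) {
    i <- sample.int(nrow(common), n_prom, replace = n_prom > nrow(common))
    for (j in seq_len(n_prom)) {
      out[[j]] <- make_gene(common$chrom[i[j]], common$end[i[j]] + 100L, j)
    }
  }
  avoid <- merge_intervals(segs)
  avoid$start <- pmax(avoid$start - 500L, 0)
  avoid$end <- avoid$end + 500L
  sizes <- cfg$chrom_sizes
  id <- n_prom
  while (id < n_genes) {
    ch <- sample(names(sizes), 1, prob = sizes)
    tss <- runif_int(1, 13000L, sizes[[ch]] - gene_len - 1000L)
    span <- data.frame(chrom = ch, start = tss - 2000L,
                       end = tss + gene_len)
    if (nrow(overlap_pairs(span, avoid)) > 0L) next
    id <- id + 1L
    out[[id]] <- make_gene(ch, tss, id)
  }
  genes <- do.call(rbind, out)
  genes[order(genes$chrom, genes$txStart), , drop = FALSE]
}
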